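#' Per-voxel prediction accuracy (Pearson correlation)
#'
#' Columnwise Pearson correlation between measured and predicted voxel
#' activity, rho = Cov(y, yhat) / sqrt(Var(y) Var(yhat)). Voxels with zero
#' variance in either matrix are flagged undefined (`NA` rho) and excluded
#' from every downstream summary rather than silently zeroed. A voxel is
#' "effectively encoded" (valid) when its rho strictly exceeds the validity
#' threshold.
#'
#' @param measured,predicted `N x V` matrices, `N >= 3` samples.
#' @param threshold validity threshold on rho (default 0.27, the shuffle-null
#'   cutoff at p < 0.001 for 120 validation samples; see
#'   [permutation_threshold()]).
#' @param voxel_ids optional voxel identifiers.
#' @return an `accuracy_vector`: list with `rho`, logical `defined` and
#'   `valid`, `threshold`, `n_samples`, `voxel_ids`.
#' @examples
#' pearson_accuracy(cbind(c(1, 2, 3, 4)), cbind(c(2, 1, 4, 3)))$rho  # 0.6
#' @export
pearson_accuracy <- function(measured, predicted, threshold = 0.27,
                             voxel_ids = NULL) {
  measured <- as.matrix(measured); predicted <- as.matrix(predicted)
  if (!all(dim(measured) == dim(predicted))) {
    stop("shape mismatch: measured is ", nrow(measured), "x", ncol(measured),
         ", predicted is ", nrow(predicted), "x", ncol(predicted))
  }
  n <- nrow(measured)
  if (n < 3L) stop("need at least 3 samples, got ", n)
  mc <- scale(measured, scale = FALSE)
  pc <- scale(predicted, scale = FALSE)
  vm <- colSums(mc^2); vp <- colSums(pc^2)
  defined <- vm > 0 & vp > 0 & is.finite(vm) & is.finite(vp)
  rho <- rep(NA_real_, ncol(measured))
  rho[defined] <- colSums(mc[, defined, drop = FALSE] *
                          pc[, defined, drop = FALSE]) /
    sqrt(vm[defined] * vp[defined])
  new_accuracy_vector(rho, threshold, n, voxel_ids)
}

new_accuracy_vector <- function(rho, threshold, n_samples, voxel_ids = NULL) {
  if (is.null(voxel_ids)) voxel_ids <- seq_along(rho)
  structure(list(rho = as.numeric(rho),
                 defined = !is.na(rho),
                 valid = !is.na(rho) & rho > threshold,
                 threshold = threshold, n_samples = n_samples,
                 voxel_ids = voxel_ids),
            class = "accuracy_vector")
}

#' @export
print.accuracy_vector <- function(x, ...) {
  cat("Per-voxel prediction accuracy:", length(x$rho), "voxels,",
      x$n_samples, "samples\n")
  cat(sprintf("  defined: %d; valid (rho > %.3g): %d\n",
              sum(x$defined), x$threshold, sum(x$valid)))
  if (any(x$defined)) {
    cat(sprintf("  median rho %.3f, max rho %.3f\n",
                median(x$rho[x$defined]), max(x$rho[x$defined])))
  }
  invisible(x)
}

#' @export
plot.accuracy_vector <- function(x, ...) {
  hist(x$rho[x$defined], breaks = 30, main = "Per-voxel prediction accuracy",
       xlab = expression(rho), ...)
  abline(v = x$threshold, lty = 2, col = "blue")
  invisible(x)
}

as_accuracy_vector <- function(x, threshold = 0.27, n_samples = NA_integer_) {
  if (inherits(x, "accuracy_vector")) return(x)
  new_accuracy_vector(as.numeric(x), threshold, n_samples)
}

# Conservative upper order statistic of a null sample: with m = floor(alpha *
# n_perm) the (m+1)-th largest draw, so at alpha = 0.001 with 1000 draws the
# 2nd-largest value is used (the empirical 99.9th percentile of 1000 draws
# would otherwise be the noisy maximum).
null_upper_quantile <- function(draws, alpha) {
  m <- floor(alpha * length(draws))
  sort(draws, decreasing = TRUE)[min(m + 1L, length(draws))]
}

#' Shuffle-null validity threshold
#'
#' Randomly permutes the sample correspondence between measured and predicted
#' activity `n_perm` times, recomputing the per-voxel correlation each time,
#' to build a null distribution per voxel. Returns the per-voxel upper
#' `1 - alpha` null quantile and a global threshold (their median across
#' defined voxels). With 120 samples, 1000 shuffles and alpha = 0.001 the
#' global threshold lands near 0.27; the large-permutation limit is the
#' normal approximation `qnorm(1 - alpha) / sqrt(n - 1)` (about 0.283 for
#' n = 120).
#'
#' @param measured,predicted `N x V` matrices.
#' @param n_perm number of shuffles (default 1000).
#' @param alpha upper tail probability (default 0.001).
#' @param seed optional RNG seed.
#' @return list with `per_voxel` thresholds (`NA` for undefined voxels),
#'   `global`, `n_perm`, `alpha`.
#' @export
permutation_threshold <- function(measured, predicted, n_perm = 1000L,
                                  alpha = 0.001, seed = NULL) {
  stopifnot(n_perm >= 1L, alpha > 0, alpha < 1)
  if (!is.null(seed)) set.seed(seed)
  measured <- as.matrix(measured); predicted <- as.matrix(predicted)
  if (!all(dim(measured) == dim(predicted))) stop("shape mismatch")
  n <- nrow(measured)
  ms <- scale(measured); ps <- scale(predicted)
  ok <- apply(is.finite(ms), 2L, all) & apply(is.finite(ps), 2L, all)
  if (!any(ok)) stop("no voxel has a defined correlation")
  ms <- ms[, ok, drop = FALSE]; ps <- ps[, ok, drop = FALSE]
  nulls <- matrix(0, n_perm, ncol(ms))
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n)
    nulls[i, ] <- colSums(ms[idx, , drop = FALSE] * ps) / (n - 1)
  }
  pv <- apply(nulls, 2L, null_upper_quantile, alpha = alpha)
  per_voxel <- rep(NA_real_, length(ok))
  per_voxel[ok] <- pv
  list(per_voxel = per_voxel, global = median(pv), n_perm = n_perm,
       alpha = alpha)
}

#' Top-K average accuracy
#'
#' Mean prediction accuracy of the `k` best-predicted voxels (defined-rho
#' voxels only). The paper-scale default is k = 300; reduced-scale analyses
#' commonly use k = 50.
#'
#' @param acc an `accuracy_vector` (or bare numeric rho vector).
#' @param k number of voxels (default 300). If fewer than `k` voxels have a
#'   defined rho, the mean of all of them is returned with a warning.
#' @return scalar mean rho.
#' @export
topk_average_accuracy <- function(acc, k = 300L) {
  stopifnot(k >= 1L)
  acc <- as_accuracy_vector(acc)
  rho <- acc$rho[acc$defined]
  if (length(rho) == 0L) stop("no voxel has a defined accuracy")
  if (length(rho) < k) {
    warning("only ", length(rho), " defined voxels for Top-", k,
            "; averaging all of them")
    k <- length(rho)
  }
  mean(sort(rho, decreasing = TRUE)[seq_len(k)])
}

#' Pairwise model advantage with a coin-flip null
#'
#' Restricts to voxels effectively encoded by BOTH models (rho above the
#' validity threshold under each), and reports the proportion of those
#' joint-valid voxels on which model A predicts better. Significance comes
#' from a randomization null: each voxel's (A, B) accuracy pair is swapped
#' with probability 0.5 and the advantage recomputed, `n_perm` times; the
#' upper `1 - alpha` quantile of that null is the significance cutoff
#' (approximately `0.5 + qnorm(1 - alpha) / sqrt(4 N)` for N joint voxels —
#' the published "advantage above 53% is significant" rule corresponds to
#' this null at the paper's joint voxel counts). Exact ties (|delta rho| <
#' 1e-12) are excluded from the proportions and counted.
#'
#' @param acc_a,acc_b `accuracy_vector`s on the same voxel set.
#' @param threshold validity threshold (defaults to the threshold stored in
#'   `acc_a`).
#' @param n_perm number of randomizations (default 1000).
#' @param alpha upper tail probability of the null cutoff (default 0.05).
#' @param labels character vector of length 2 naming the models.
#' @param seed optional RNG seed.
#' @param breaks histogram bin edges for the accuracy-difference histogram.
#' @return an `advantage_result`: `n_joint`, `n_tied`, `prop_a`, `prop_b`,
#'   `cutoff`, `significant`, `null` draws, and the difference `histogram`.
#' @export
advantage_analysis <- function(acc_a, acc_b, threshold = NULL,
                               n_perm = 1000L, alpha = 0.05,
                               labels = c("A", "B"), seed = NULL,
                               breaks = seq(-0.5, 0.5, by = 0.05)) {
  acc_a <- as_accuracy_vector(acc_a); acc_b <- as_accuracy_vector(acc_b)
  if (length(acc_a$rho) != length(acc_b$rho)) {
    stop("accuracy vectors cover different voxel sets")
  }
  if (is.null(threshold)) threshold <- acc_a$threshold
  if (!is.null(seed)) set.seed(seed)
  joint <- acc_a$defined & acc_b$defined &
    acc_a$rho > threshold & acc_b$rho > threshold
  n_joint <- sum(joint)
  if (n_joint == 0L) stop("no voxel is effectively encoded by both models")
  d <- acc_a$rho[joint] - acc_b$rho[joint]
  tied <- abs(d) < 1e-12
  n_eff <- sum(!tied)
  prop_a <- if (n_eff > 0) sum(d > 0 & !tied) / n_eff else NA_real_
  if (n_eff > 0) {
    null <- vapply(seq_len(n_perm), function(i) {
      flip <- sample(c(-1, 1), n_eff, replace = TRUE)
      mean(flip * d[!tied] > 0)
    }, numeric(1))
    cutoff <- as.numeric(quantile(null, 1 - alpha, names = FALSE, type = 7))
  } else {
    null <- rep(NA_real_, n_perm)
    cutoff <- NA_real_
  }
  br <- breaks
  if (length(d) && (min(d) < min(br) || max(d) > max(br))) {
    w <- br[2] - br[1]
    br <- seq(w * floor(min(c(d, br)) / w), w * ceiling(max(c(d, br)) / w),
              by = w)
  }
  h <- hist(d, breaks = br, plot = FALSE)
  structure(list(labels = labels, n_joint = n_joint, n_tied = sum(tied),
                 prop_a = prop_a, prop_b = if (is.na(prop_a)) NA_real_
                                           else 1 - prop_a,
                 threshold = threshold, alpha = alpha, n_perm = n_perm,
                 cutoff = cutoff,
                 significant = !is.na(prop_a) && prop_a > cutoff,
                 null = null,
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "advantage_result")
}

#' @export
print.advantage_result <- function(x, ...) {
  cat(sprintf("Advantage analysis %s vs %s: %d joint-valid voxels (%d tied)\n",
              x$labels[1], x$labels[2], x$n_joint, x$n_tied))
  cat(sprintf("  %s advantage %.1f%% | null cutoff (alpha=%.3g) %.1f%% | %s\n",
              x$labels[1], 100 * x$prop_a, x$alpha, 100 * x$cutoff,
              if (isTRUE(x$significant)) "significant" else "not significant"))
  invisible(x)
}

#' @export
plot.advantage_result <- function(x, ...) {
  mids <- (head(x$histogram$breaks, -1) + x$histogram$breaks[-1]) / 2
  barplot(x$histogram$counts, names.arg = sprintf("%.2f", mids),
          main = sprintf("Accuracy difference (%s - %s)", x$labels[1],
                         x$labels[2]),
          xlab = expression(Delta * rho), ylab = "voxels", ...)
  invisible(x)
}

#' Best-encoded-voxel proportions
#'
#' For voxels effectively encoded by AT LEAST ONE of the compared models,
#' assigns each voxel to the model with the highest accuracy there, and
#' returns the proportion of best-encoded voxels per model (summing to 1).
#' Exact ties go to the earlier-listed model.
#'
#' @param models named list of `accuracy_vector`s on a common voxel set
#'   (with a single model every included voxel is trivially best-encoded by
#'   it).
#' @param threshold validity threshold (defaults to the first model's).
#' @return named numeric vector of proportions with attributes `n_included`
#'   and `counts`.
#' @export
best_encoded_proportions <- function(models, threshold = NULL) {
  stopifnot(is.list(models), length(models) >= 1L)
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("`models` must be a fully named list")
  }
  models <- lapply(models, as_accuracy_vector)
  V <- unique(vapply(models, function(m) length(m$rho), integer(1)))
  if (length(V) != 1L) stop("models cover different voxel sets")
  if (is.null(threshold)) threshold <- models[[1L]]$threshold
  R <- vapply(models, function(m) {
    r <- m$rho
    r[!m$defined] <- -Inf
    r
  }, numeric(V))
  R <- matrix(R, nrow = V)
  include <- apply(R > threshold, 1L, any)
  if (!any(include)) stop("no voxel is effectively encoded by any model")
  best <- apply(R[include, , drop = FALSE], 1L, which.max)  # ties -> earliest
  counts <- tabulate(best, nbins = length(models))
  names(counts) <- names(models)
  props <- counts / sum(counts)
  attr(props, "n_included") <- sum(include)
  attr(props, "counts") <- counts
  props
}
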