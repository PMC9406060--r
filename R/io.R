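REPORT_SCHEMA_VERSION <- "1.0"

#' Write an evaluation report
#'
#' Writes a per-voxel accuracy CSV, a JSON summary with a schema version and
#' deterministic field ordering, and a plain-text log into `out_dir`.
#'
#' @param results list with elements `models` (named list of
#'   `accuracy_vector`s), and optionally `roi`, `k` (Top-K size, default
#'   300), `advantage` (an `advantage_result`), `best_encoded` (named
#'   proportions), `config` (arbitrary snapshot list).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_report <- function(results, out_dir) {
  stopifnot(is.list(results), is.list(results$models),
            length(results$models) >= 1L)
  models <- lapply(results$models, as_accuracy_vector)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create ", out_dir)
  }
  k <- if (is.null(results$k)) 300L else as.integer(results$k)
  roi <- if (is.null(results$roi)) NA_character_ else results$roi

  df <- data.frame(voxel_id = models[[1L]]$voxel_ids, roi = roi)
  for (m in names(models)) {
    df[[paste0("rho_", m)]] <- models[[m]]$rho
    df[[paste0("valid_", m)]] <- models[[m]]$valid
  }
  csv_path <- file.path(out_dir, "voxel_accuracy.csv")
  write.csv(df, csv_path, row.names = FALSE)

  topk <- lapply(models, function(m) {
    tryCatch(suppressWarnings(topk_average_accuracy(m, k)),
             error = function(e) NULL)
  })
  summary <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    roi = roi,
    n_samples = models[[1L]]$n_samples,
    threshold = models[[1L]]$threshold,
    models = names(models),
    topk_aa = list(k = k, values = topk),
    n_valid = lapply(models, function(m) sum(m$valid))
  )
  if (!is.null(results$advantage)) {
    a <- results$advantage
    summary$advantage <- list(labels = a$labels, n_joint = a$n_joint,
                              n_tied = a$n_tied, prop_a = a$prop_a,
                              cutoff = a$cutoff, alpha = a$alpha,
                              significant = a$significant)
  }
  if (!is.null(results$best_encoded)) {
    summary$best_encoded <- as.list(results$best_encoded)
  }
  if (!is.null(results$config)) summary$config <- results$config
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  log_path <- file.path(out_dir, "run.log")
  writeLines(c(paste("report written:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               paste("models:", paste(names(models), collapse = ", ")),
               paste("schema:", REPORT_SCHEMA_VERSION)), log_path)
  invisible(c(csv = csv_path, json = json_path, log = log_path))
}

#' Read back a report summary
#' @param out_dir directory previously written by [write_report()].
#' @return the parsed JSON summary list.
#' @export
read_report <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "summary.json"),
                      simplifyVector = TRUE)
}

#' Save / load a fitted model checkpoint
#'
#' Serialises the model object together with a JSON sidecar recording the
#' class, backbone/config snapshot and package version. (The environment has
#' no R HDF5 bindings, so checkpoints use R serialization instead of the
#' HDF5 container.)
#'
#' @param model an `s2v_model`, `hier_model` or `hier_pipeline`.
#' @param path file path (`.rds`); a `.json` sidecar is written next to it.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(class = class(model)[1L],
               package_version = as.character(utils::packageVersion("hvem")),
               roi = model$roi %||% model$spec$target %||% NA,
               best_epoch = model$best_epoch %||% NA)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- vim-1 layout (MAT v7.3 / HDF5) through the bundled python bridge ------

python_bin <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no `python` interpreter on PATH; the vim-1 HDF5 reader needs one ",
       "(with h5py and numpy installed)")
}

run_bridge <- function(args) {
  script <- system.file("python", "vim1_bridge.py", package = "hvem")
  if (!nzchar(script)) stop("bundled vim1_bridge.py not found")
  out <- suppressWarnings(system2(python_bin(), c(shQuote(script), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop("vim-1 bridge failed (exit ", status, "):\n",
         paste(out, collapse = "\n"))
  }
  invisible(out)
}

#' Key map for the vim-1 file layout
#'
#' Dataset names vary across vim-1 releases; the reader takes this small map
#' instead of hard-coding. Defaults match the public release: stimuli in
#' `stimTrn` / `stimVal` (N x side x side), responses in `dataTrn<subject>` /
#' `dataVal<subject>` (voxels x samples), ROI assignment in `roi<subject>`
#' with integer codes.
#'
#' @param subject subject tag, e.g. `"S1"`.
#' @param roi_codes named integer vector mapping ROI labels to codes.
#' @export
vim1_keymap <- function(subject = "S1",
                        roi_codes = c(V1 = 1L, V2 = 2L, V4 = 6L, LO = 7L)) {
  list(stim_train = "stimTrn", stim_val = "stimVal",
       resp_train = paste0("dataTrn", subject),
       resp_val = paste0("dataVal", subject),
       roi = paste0("roi", subject),
       roi_codes = roi_codes)
}

#' Write a dataset in the vim-1 HDF5 layout
#'
#' Serialises an `hvem_dataset` into a single HDF5 file using the vim-1
#' naming convention (see [vim1_keymap()]), so that synthetic data are a
#' drop-in replacement for the real files. Requires a Python interpreter
#' with `h5py`.
#'
#' @param data an `hvem_dataset`.
#' @param path output `.h5`/`.mat` path.
#' @param subject subject tag used in the dataset names.
#' @param keymap a [vim1_keymap()].
#' @export
write_vim1 <- function(data, path, subject = "S1",
                       keymap = vim1_keymap(subject)) {
  stopifnot(inherits(data, "hvem_dataset"))
  side <- as.integer(sqrt(ncol(data$stimuli$train)))
  tmp <- tempfile("vim1w")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)

  dump <- function(M, name) {
    write.table(format(M, digits = 17, scientific = TRUE, trim = TRUE),
                file.path(tmp, paste0(name, ".csv")), sep = ",",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  rois <- names(data$responses)
  codes <- unlist(lapply(rois, function(r) {
    rep(keymap$roi_codes[[r]], ncol(data$responses[[r]]$train))
  }))
  resp_tr <- t(do.call(cbind, lapply(rois, function(r) data$responses[[r]]$train)))
  resp_va <- t(do.call(cbind, lapply(rois, function(r) data$responses[[r]]$val)))

  dump(data$stimuli$train, keymap$stim_train)
  dump(data$stimuli$val, keymap$stim_val)
  dump(resp_tr, keymap$resp_train)
  dump(resp_va, keymap$resp_val)
  dump(matrix(codes, ncol = 1L), keymap$roi)

  manifest <- list(side = side,
                   stim_keys = c(keymap$stim_train, keymap$stim_val),
                   keys = c(keymap$stim_train, keymap$stim_val,
                            keymap$resp_train, keymap$resp_val, keymap$roi))
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE)
  run_bridge(c("pack", shQuote(tmp), shQuote(path)))
  invisible(path)
}

read_bridge_matrix <- function(dir, key) {
  f <- file.path(dir, paste0(key, ".csv"))
  if (!file.exists(f)) stop("bridge did not export key `", key, "`")
  as.matrix(read.csv(f, header = FALSE))
}

#' Read a dataset in the vim-1 layout
#'
#' Loads stimuli and per-ROI voxel responses from MAT v7.3 / HDF5 files
#' through the bundled Python `h5py` bridge. Stimuli and responses may live
#' in the same file (pass the same path twice). Voxels containing non-finite
#' values are dropped with a message; for subject S1 the reader warns (not
#' errors) when the V2/V4/LO voxel counts differ from the published
#' 2083/1535/928.
#'
#' @param stimuli_path file holding the stimulus arrays.
#' @param responses_path file holding the response matrices and ROI vector.
#' @param subject subject tag (default `"S1"`).
#' @param keymap a [vim1_keymap()].
#' @return an `hvem_dataset`.
#' @export
read_vim1 <- function(stimuli_path, responses_path = stimuli_path,
                      subject = "S1", keymap = vim1_keymap(subject)) {
  for (p in unique(c(stimuli_path, responses_path))) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  tmp <- tempfile("vim1r")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  run_bridge(c("unpack", shQuote(stimuli_path), shQuote(tmp),
               paste(c(keymap$stim_train, keymap$stim_val), collapse = ",")))
  run_bridge(c("unpack", shQuote(responses_path), shQuote(tmp),
               paste(c(keymap$resp_train, keymap$resp_val, keymap$roi),
                     collapse = ",")))

  stim_tr <- read_bridge_matrix(tmp, keymap$stim_train)
  stim_va <- read_bridge_matrix(tmp, keymap$stim_val)
  resp_tr <- t(read_bridge_matrix(tmp, keymap$resp_train))  # -> N x V
  resp_va <- t(read_bridge_matrix(tmp, keymap$resp_val))
  roi_codes <- as.integer(read_bridge_matrix(tmp, keymap$roi)[, 1L])
  if (length(roi_codes) != ncol(resp_tr)) {
    stop("ROI vector length ", length(roi_codes),
         " does not match voxel count ", ncol(resp_tr))
  }
  if (nrow(stim_tr) != nrow(resp_tr) || nrow(stim_va) != nrow(resp_va)) {
    stop("stimulus/response sample counts disagree between files")
  }

  responses <- list()
  for (r in names(keymap$roi_codes)) {
    vox <- which(roi_codes == keymap$roi_codes[[r]])
    if (length(vox) == 0L) next
    tr <- resp_tr[, vox, drop = FALSE]; va <- resp_va[, vox, drop = FALSE]
    finite <- apply(is.finite(tr), 2L, all) & apply(is.finite(va), 2L, all)
    if (any(!finite)) {
      message(r, ": dropped ", sum(!finite), " voxels with missing data")
    }
    responses[[r]] <- list(train = tr[, finite, drop = FALSE],
                           val = va[, finite, drop = FALSE])
  }
  expected <- c(V2 = 2083L, V4 = 1535L, LO = 928L)
  if (identical(subject, "S1")) {
    for (r in names(expected)) {
      if (!is.null(responses[[r]]) &&
          ncol(responses[[r]]$train) != expected[[r]]) {
        warning("S1 ", r, " has ", ncol(responses[[r]]$train),
                " voxels; published count is ", expected[[r]])
      }
    }
  }

  structure(list(stimuli = list(train = stim_tr, val = stim_va),
                 responses = responses, subject = subject,
                 provenance = list(stimuli = stimuli_path,
                                   responses = responses_path)),
            class = "hvem_dataset")
}
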