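"""Tiny HDF5 <-> CSV bridge for vim-1-layout datasets.

The R package has no native HDF5 bindings in this environment, so reading
and writing MAT v7.3 / HDF5 files is delegated to h5py through this script.

Usage:
  python vim1_bridge.py pack   <csv_dir> <out.h5>
      csv_dir holds <key>.csv files plus manifest.json
      ({"side": int, "stim_keys": [...], "keys": [...]});
      stimulus keys are reshaped (N, side*side) -> (N, side, side).
  python vim1_bridge.py unpack <in.h5> <csv_dir> <key1,key2,...>
      each dataset is written to <csv_dir>/<key>.csv; 3-D stimulus arrays
      are flattened (N, S, S) -> (N, S*S) in C order.
"""
import json
import os
import sys

import h5py
import numpy as np


def pack(csv_dir, out_path):
    with open(os.path.join(csv_dir, "manifest.json")) as fh:
        manifest = json.load(fh)
    side = int(manifest["side"])
    stim_keys = set(manifest.get("stim_keys", []))
    with h5py.File(out_path, "w") as h5:
        for key in manifest["keys"]:
            arr = np.loadtxt(os.path.join(csv_dir, key + ".csv"),
                             delimiter=",", ndmin=2)
            if key in stim_keys:
                arr = arr.reshape(arr.shape[0], side, side)
            h5.create_dataset(key, data=arr)


def unpack(in_path, csv_dir, keys):
    try:
        h5open = h5py.File(in_path, "r")
    except OSError:
        sys.stderr.write(
            "%s is not an HDF5 file (MAT v7.3); older MAT files must be "
            "converted, e.g. in MATLAB: save('file.mat','-v7.3',...)\n"
            % in_path)
        sys.exit(4)
    with h5open as h5:
        for key in keys:
            if key not in h5:
                sys.stderr.write("missing dataset key: %s\n" % key)
                sys.exit(3)
            arr = np.asarray(h5[key])
            if arr.ndim == 3:
                arr = arr.reshape(arr.shape[0], -1)
            if arr.ndim == 1:
                arr = arr.reshape(-1, 1)
            np.savetxt(os.path.join(csv_dir, key + ".csv"), arr,
                       delimiter=",", fmt="%.17g")


def main(argv):
    if len(argv) < 4:
        sys.stderr.write(__doc__)
        return 2
    cmd = argv[1]
    if cmd == "pack":
        pack(argv[2], argv[3])
    elif cmd == "unpack":
        unpack(argv[2], argv[3], argv[4].split(","))
    else:
        sys.stderr.write("unknown command: %s\n" % cmd)
        return 2
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
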