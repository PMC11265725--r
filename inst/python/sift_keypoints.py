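"""SIFT keypoint detection helper.

Usage: python sift_keypoints.py IMG_BIN H W C_DOG C_EDGE OUT_CSV

IMG_BIN holds the grayscale image as row-major float64 on the [0, 1] scale.
Writes a CSV with subpixel keypoint positions (0-based row/col), the
detection scale (sigma), the orientation in degrees, and the 128-byte
descriptor (columns d0..d127). An image with no detectable features yields
a header-only CSV.
"""
import sys

import numpy as np
from skimage.feature import SIFT


def main(argv):
    img_bin, h, w = argv[1], int(argv[2]), int(argv[3])
    c_dog, c_edge, out_csv = float(argv[4]), float(argv[5]), argv[6]
    img = np.fromfile(img_bin, dtype=np.float64).reshape(h, w)
    det = SIFT(c_dog=c_dog, c_edge=c_edge)
    try:
        det.detect_and_extract(img)
        pos = det.positions
        sigmas = det.sigmas
        ori = np.degrees(det.orientations) % 360.0
        desc = det.descriptors.astype(np.int64)
    except RuntimeError:  # no features found (e.g. constant image)
        pos = np.empty((0, 2))
        sigmas = ori = np.empty(0)
        desc = np.empty((0, 128), dtype=np.int64)
    # keep subpixel positions strictly inside the image bounds
    pos = np.clip(pos, 0.0, [h - 1e-9, w - 1e-9])
    header = "row,col,scale,orientation," + ",".join(
        f"d{i}" for i in range(128))
    body = np.column_stack([pos, sigmas, ori, desc])
    with open(out_csv, "w") as fh:
        fh.write(header + "\n")
        for r in body:
            fh.write(",".join(repr(float(v)) for v in r[:4]))
            fh.write("," + ",".join(str(int(v)) for v in r[4:]) + "\n")


if __name__ == "__main__":
    main(sys.argv)
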