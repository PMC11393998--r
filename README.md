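# bovimetry

Non-contact cattle body measurement from a single side-view depth image.

Livestock phenotyping records four standard dimensions per animal — body
height, lumbar height, body oblique length, and chest girth — normally
taken with measuring sticks and tapes on a restrained animal. `bovimetry`
computes all four from one 16-bit depth image (millimeter units) and seven
named 2-D keypoints (Withers, Sole, Shoulder, Pin, Chest1, Chest2,
Lumbar) supplied by any upstream pose detector or by manual annotation.
It is aimed at researchers and engineers building RGB-D measurement rigs
who need the geometry after keypoint detection: depth cleanup, 3-D
lifting, and the curve reconstruction behind the girth.

## Method

With pinhole intrinsics (fx, fy, cx, cy), a pixel (u, v) with depth d
lifts to camera coordinates

    X = (u − cx) d / fx,  Y = (v − cy) d / fy,  Z = d.

Raw depths at landmarks are refined by **conditional filtering**: the
benchmark depth is the mean of valid samples (0 < d ≤ 7000 mm) in a 3×3
window around the Shoulder–Pin midpoint; each landmark takes the nearest
depth (growing Chebyshev rings, radius ≤ 20 px) that is valid and within
500 mm of the benchmark. Body height is the Euclidean distance
‖Withers − Sole‖, body oblique length ‖Shoulder − Pin‖; lumbar height is
measured to a ground point constructed from the lumbar column, the sole
row and the sole depth. Chest girth samples the depth map along the
Chest1→Chest2 image segment (each sample conditionally filtered),
smooths the 3-D profile with multiquadric RBF fits, mirrors it across
the girth section's vertical diameter to complete the hidden half,
closes the loop with an interpolating periodic cubic spline, and sums
the polyline length. All results are cm = mm/10.

A parametric synthetic scene generator (elliptical-cylinder torso,
cylinder legs, ground plane, ray-cast depth with dropout/jitter noise)
provides analytic ground truth, so the whole pipeline is testable
without animals or hardware. Evaluation metrics (OKS, AP@0.5, mAP, MAE,
MRE) are included.

## Worked example

Simulate one canonical scene (default animal, 3 m stand-off), then
measure it:

```r
library(bovimetry)
dir <- file.path(tempdir(), "demo")
cliSimulate(dir, n = 1, seed = 1, randomize = FALSE)
writeIntrinsics(syntheticIntrinsics(), file.path(dir, "intrinsics.yaml"))

img <- readDepthImage(file.path(dir, "depth_0001.png"))
kps <- readKeypoints(file.path(dir, "keypoints_0001.json"))
K   <- readIntrinsics(file.path(dir, "intrinsics.yaml"))
img
#> DepthImage 1280x720 px | 41.5% valid | depth range 1950-7000 mm
measureAnimal(img, kps, K)
#> BodyMeasurements | height 124.6 cm, lumbar 124.6 cm, length 148.0 cm, girth 252.1 cm
read.csv(file.path(dir, "truth.csv"))
#>   id body_height_cm lumbar_height_cm body_length_cm chest_girth_cm
#> 1  1          125.1              125            148          252.3
```

The measured dimensions sit within 0.5 % of the generator's analytic
truth (the small height deficit is the silhouette ray-entry bias of
depth lookup at topline keypoints; see the methods vignette). The
refined depths used are auditable:

```r
round(refinedDepths(localizeKeypoints(img, kps, K)))
#>  Withers     Sole Shoulder      Pin   Chest1   Chest2   Lumbar
#>     3394     3390     3000     3000     3394     3294     3394
```

A command-line front end wraps the same functions:

```sh
exec/bovimetry simulate --out scenes --n 3 --seed 7
exec/bovimetry measure  --depth scenes/depth_0001.png \
    --keypoints scenes/keypoints_0001.json \
    --intrinsics intrinsics.yaml --out measured.csv
exec/bovimetry metrics  --manual manual.csv --auto measured.csv --out errors.csv
```

`measure` exits non-zero if any dimension could not be computed (the
other columns are still filled); per-image OKS/AP come from
`exec/bovimetry evaluate`.

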