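# voxrefl

Voxel-wise reflectivity analysis of T1-weighted MRI tube phantoms.

## The problem

Gadolinium contrast agents shorten T1 and brighten T1-weighted spin-echo
images. To compare agent uptake between two cell samples, each sample is
set in agarose inside a 0.5 mL tube and both tubes are scanned; the
readout is the **reflectivity** — the percent signal difference between
the *test* and *control* tubes. The traditional approach compares two
hand-drawn ROI means,

```
R = (Test_avg − Control_avg) / Control_avg × 100 ,
```

which is operator-dependent and discards most voxels. voxrefl automates
the whole chain and computes the reflectivity voxel-on-voxel over all N
matched voxels,

```
R = Σᵢ (Iᵢ − gᵢ) / Σᵢ gᵢ × 100 ,     rᵢ = (Iᵢ − gᵢ) / gᵢ × 100 ,
```

where `Iᵢ` is the test signal and `gᵢ` the control signal at matched
voxel `i`. The pipeline:

1. background removal (Otsu threshold) + 3D region growing → tube VOIs;
2. water normalization — every scan is divided by the mean signal of its
   water tube;
3. interior Euclidean distance maps of each tube by a fast-marching
   front — intensity-free shape features;
4. 12-DOF affine registration of the target tube to the reference tube
   maximizing mutual information of the distance maps;
5. cubic B-spline elastic refinement with four-stage multiresolution
   under L-BFGS-B;
6. resampling, the reflectivity sums, and a diverging per-voxel color
   map.

Supporting tools: voxel-wise T1 mapping from arrayed-TR spin-echo series
(`S(TR) = s0·(1 − exp(−TR/T1))`), relaxivity regression of 1/T1 against
concentration, xylenol-orange Gd(III) quantification from A573/A433
absorbance ratios, paired t-tests, and a synthetic tube-phantom simulator
(Rician noise, known applied affine/B-spline misalignments) that makes
every stage testable without scanner data. Intended users: small-animal /
preclinical MRI groups benchmarking contrast agents on tube phantoms.

## Worked example

Simulate a test scan whose tube carries 1.2× the control signal and is
misaligned by a 3-voxel shift plus a 5° rotation, then run the full
pipeline (a couple of minutes on one core):

```r
library(voxrefl)

aff <- affineFromParams(angles = c(0, 0, 5), translation = c(3, -2, 1),
                        center = c(-12, 0, 0))
mkScan <- function(signal, seed, affine = NULL) {
  tubes <- list(
    tubeSpec(c(-12, 0, 0), radius = 6, length = 40, signal = signal,
             role = "test"),
    tubeSpec(c(14, 0, 0), radius = 5, length = 40, signal = 60,
             role = "water"))
  phantomSpec(tubes, gridShape = c(64L, 64L, 64L), noiseSigma = 2,
              seed = seed, appliedAffine = affine)
}
testScan    <- generatePhantom(mkScan(120, seed = 1, affine = aff))@volume
controlScan <- generatePhantom(mkScan(100, seed = 2))@volume

pl <- runPipeline(testScan, controlScan)
pl$result
#> ReflectivityResult: global R = 19.94% over 3040 voxels
#>   voxel map: median 20.01%, IQR [18.23, 21.92]%
```

The global R recovers the simulated 20% contrast despite the
misalignment; `pl$report` holds the provenance (water means ≈ 60 a.u. as
simulated, transform parameters, analysis voxel count), `pl$colorMap` the
rendered map (`writeColorMapPNG()` exports a slice), and
`writePipelineReport(pl, "out/")` writes the JSON report plus NIfTI/PNG
maps.

The quantitative side reads the same way:

```r
C <- c(0, 0.1, 0.25, 0.5)                      # mM
fitRelaxivity(C, 1000 / (0.4 + 3.75 * C))      # T1 values in ms
#> RelaxivityFit: r1 = 3.75 mM^-1 s^-1, intercept 0.4 s^-1, r^2 = 1.0000 (n = 4)

gdFromRatio(1.2, gdCalibration())              # A573/A433 ratio -> Gd
#> [1] 4.39588
```

(`gdCalibration()` warns that the published inversion coefficient B is
not the algebraic inverse of the published calibration line; an
`inverse_consistent` mode derives self-consistent coefficients instead.)

A thin CLI over the same functions ships in `inst/cli/voxrefl`
(`simulate`, `convert`, `analyze`, `register`, `t1map`, `relaxivity`,
`gd-assay`).

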