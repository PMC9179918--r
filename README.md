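# jointQMRI

Quantitative MRI biomarkers and robust statistics for experimental
osteoarthritis (OA) models.

Longitudinal small-animal OA studies — e.g. cranial cruciate ligament
transection in the rabbit stifle — monitor disease progression with
imaging biomarkers of the articular cartilage and the subchondral
trabecular bone, and compare treatment groups over survival time with
robust statistics. `jointQMRI` is aimed at imaging scientists and
biostatisticians running such studies. It provides, as one tested
pipeline:

* **Cartilage relaxometry** — voxel-wise T1 from variable flip-angle
  spoiled gradient-echo stacks via the classical linearisation of
  `S(α) = M0 sin α (1 − E1)/(1 − E1 cos α)`, `E1 = exp(−TR/T1)`
  (`fitT1Vfa()`), and voxel-wise T2 from multi-echo stacks via
  signal-weighted log-linear fits of `S(TE) = S0 exp(−TE/T2)`
  (`fitT2Monoexp()`), each with an explicit validity mask.
* **Cartilage morphometry** — deterministic six-segment parcellation
  (TM, TL, CM, CL, PM, PL) with exact volume conservation, and mean
  thickness as twice the Euclidean distance transform sampled on the
  medial axis (`parcellateCartilage()`, `segmentVolume()`,
  `segmentThickness()`).
* **Trabecular bone morphometry** — Laplacian-sharpened Otsu
  binarisation, BV/TV, Tb.Th, Tb.Sp (distance transform on the
  skeleton of each phase), TbN = BV/TV / Tb.Th, and 2D/3D box-counting
  fractal dimensions (`boneBiomarkers()` and friends).
* **Robust statistics** — the two-way ANOVA for trimmed means with
  interaction (Yuen cell variances + Johansen adjusted critical
  values; `trimmedTwoWayAnova()`), a noncentral-t power/effect-size
  solver (`powerTwoSampleT()`, `effectSizeFromPower()`),
  median/min/max/IQR descriptives and ordinal stage-frequency tables
  for heat-map reporting.
* **Synthetic phantoms** — closed-form relaxometry phantoms, periodic
  trabecular lattices with exact analytic morphometry, and factorial
  ordinal-score simulators (`makeCartilagePhantom()`,
  `makeTrabecularPhantom()`, `makeOrdinalScoreDataset()`), so the
  whole stack is validated without scan data.

Volumes travel as NIfTI with JSON sidecars for what NIfTI headers
cannot hold (TR, flip angles, echo times). A thin command-line
wrapper lives at `inst/scripts/jointqmri.R`; `runPipeline()` executes
the full simulate → fit → morphometry → statistics chain into one
reproducible JSON report.

## Worked example

```r
library(jointQMRI)

## cartilage: noisy multi-echo phantom -> T2 map -> per-region summary
ph <- makeCartilagePhantom(cartilagePhantomSpec(noiseSigma = 2, seed = 42))
t2 <- fitT2Monoexp(ph$me)
summarizeMap(t2, ph$labelmap)
#>   label n_valid     mean   median        sd
#> 1     1    3456 30.00273 30.00345 0.1103839
#> 2     2    3456 50.00610 50.00523 0.2574267
```

The two phantom regions were generated with T2 = 30 and 50 ms; the
fitted map recovers both to well under the noise floor.

```r
mask <- VolumeGrid(voxelData(ph$labelmap) > 0, spacing(ph$labelmap))
v <- segmentVolume(parcellateCartilage(mask))
v
#>   label segment voxels volume_mm3
#> 1     1      TM   1152         18
#> 2     2      TL   1152         18
#> 3     3      CM   1152         18
#> 4     4      CL   1152         18
#> 5     5      PM   1152         18
#> 6     6      PL   1152         18
attr(v, "total_mm3")
#> [1] 108
```

A symmetric slab parcellates into six equal segments whose volumes sum
exactly to the mask volume.

```r
## bone: blurred plate lattice -> binarise -> full biomarker panel
tb <- makeTrabecularPhantom(trabecularPhantomSpec(blurFwhm = 0.1, seed = 42))
boneBiomarkers(tb$gray, tb$voi)
#> BoneBiomarkers [whole]
#>   BV/TV 0.2000  Tb.Th 0.2000 mm  Tb.Sp 0.8000 mm  TbN 1.0000 /mm
#>   D2D 2.000  D3D 2.231
```

The plate lattice (strut 0.2 mm, period 1.0 mm) has analytic truth
BV/TV = 0.2, Tb.Th = 0.2 mm, Tb.Sp = 0.8 mm, TbN = 1.0 /mm; the
measured panel reproduces it through the blur-and-rebinarise path.

```r
## statistics: planted treatment effect in a 3x3 factorial design
eff <- matrix(0, 3, 3); eff[3, ] <- 1.5
d <- makeOrdinalScoreDataset(scoreSimSpec(cellEffects = eff,
                                          noise = "ordinalized", seed = 42))
trimmedTwoWayAnova(d$value, d$group, d$time_days)
#> Trimmed-means two-way ANOVA (trim = 0.2, johansen p-values)
#>            Q         p
#> A   25.70000 0.0005718
#> B    0.08491 0.9607000
#> A:B 11.54000 0.1007000

effectSizeFromPower(n = 12, alpha = 0.05, power = 0.8)
#> [1] 1.196812
```

The planted group effect is detected (p < 0.001 for factor A) while
the unplanted time effect is not, and the detectable standardized
effect size for 12 subjects per group at α = 0.05 and power 0.8 is
d ≈ 1.2.

See `vignettes/joint-qmri-methods.Rmd` for the models, parameter
conventions and design decisions.

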