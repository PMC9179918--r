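---
title: "Quantitative MRI biomarkers and robust statistics for experimental osteoarthritis models"
author: "jointQMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointQMRI)
```

# Scope

Small-animal models of osteoarthritis (OA) — typically cranial
cruciate ligament transection in the rabbit stifle — are monitored
with quantitative MRI: voxel-wise relaxation times of the articular
cartilage, cartilage volume and thickness per anatomical segment, and
morphometry of the subchondral trabecular bone. Group comparisons of
the resulting biomarkers (and of ordinal histology scores and synovial
fluid concentrations) are made with a robust trimmed-means factorial
ANOVA, because such variables are rarely normal or homoscedastic.

`jointQMRI` implements that full analysis stack, together with
synthetic phantom generators whose ground truth is known analytically,
so every stage is validated without any scan data. This vignette
records the models, the tunable parameters, and the design decisions
taken where the underlying methods literature leaves the details open.

# Relaxometry

## T1 from variable flip angles

The spoiled gradient-echo (SPGR) steady-state signal at flip angle
$\alpha$ is

$$S(\alpha) = M_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1\cos\alpha},
  \qquad E_1 = e^{-TR/T_1}.$$

With $y = S/\sin\alpha$ and $x = S/\tan\alpha$ this is the straight
line $y = E_1 x + M_0(1 - E_1)$, so `fitT1Vfa()` runs one ordinary
least-squares line per voxel and maps the slope back through
$T_1 = -TR/\log E_1$. The classical linearisation is exact on
noiseless data (the validation suite demands $10^{-6}$ relative
recovery) and, under noise, tracks a direct nonlinear least-squares
fit of the SPGR residual.

Voxels are never silently repaired: a slope outside $(0,1)$, a
degenerate design (e.g. all-zero signal) or a $T_1$ outside the
plausibility window $[50, 10000]$ ms flags the voxel in the map's
validity mask. The default acquisition emulated by the phantom is six
flip angles (2, 5, 10, 15, 25, 45 degrees); the repetition time is a
required input — it cannot be recovered from the data and is therefore
carried in the JSON sidecar, never assumed.

## T2 from multi-echo stacks

The multi-echo signal is mono-exponential, $S(TE) = S_0 e^{-TE/T_2}$.
`fitT2Monoexp()` fits $\log S$ against $TE$ by least squares weighted
with $S^2$: the weighting undoes the heteroscedasticity introduced by
the log transform, which makes the log-linear estimate a close proxy
for nonlinear least squares under additive noise. Echoes with
non-positive signal are dropped voxel-wise and at least three usable
echoes are required; non-decaying voxels and $T_2$ outside
$[1, 1000]$ ms are flagged. The phantom's default echo ladder is the
sixteen echoes 2.7–23.7 ms in steps of 1.4 ms; echo times are treated
as milliseconds throughout.

Both fits are strictly voxel-independent — there is no spatial
regularisation — and both assume co-registered stacks: registration is
a precondition of the inputs (it is usually done with dedicated
external tools), not a stage of this package.

When the validation suite speaks of "SNR 50", the noise standard
deviation is defined relative to the *peak* noiseless tissue signal of
the series (`sigma = max(S)/50`), i.e. the image SNR of the
brightest acquisition, not relative to $M_0$.

# Cartilage morphometry

`parcellateCartilage()` splits a cartilage mask into the conventional
six segments (medial/lateral crossed with anterior/central/posterior).
Because the anatomical boundary rules are not standardised, two
declared conventions are used: the medial–lateral cut is placed at the
mask centroid along the M–L axis (or at the image midline, or at an
explicit coordinate, for masks known to cover only one condyle), and
the anterior/central/posterior cuts divide the mask's bounding A–P
extent into equal thirds. These rules are deterministic, idempotent,
and guarantee an exact partition: every mask voxel gets exactly one
label, so segment volumes (voxel count times voxel volume) sum to the
whole-mask volume identically.

Mean thickness is measured as twice the Euclidean distance transform
(EDT) sampled on the medial axis and averaged over medial-axis voxels.
The medial axis is extracted as the ridge of the EDT: a voxel whose
distance value is not exceeded by any of its 26 neighbours and
strictly exceeds at least one of them. This is deterministic, needs no
topological bookkeeping, and is exact on the geometries with analytic
truth (slabs, plates, rods give their mid-plane/axis; a ball gives its
centre). On an $n$-voxel slab the estimate is $n$ voxels for even $n$
and $n+1$ voxels for odd $n$ — i.e. at most one voxel of positive
bias, which vanishes with resolution (the suite checks a ball's
thickness converges to its diameter). Anisotropic grids are resampled
to the finest spacing (nearest neighbour) before the EDT, so thickness
scales exactly with voxel spacing.

# Trabecular bone morphometry

Binarisation follows a sharpen-then-threshold scheme: the grayscale
volume is unsharpened with a discrete 6-neighbour Laplacian,
$g - \lambda \nabla^2 g$ (default $\lambda = 1$, configurable), to
counteract partial-volume blending at trabecular boundaries, then
thresholded with Otsu's criterion computed from the VOI voxels only
(a global 256-bin histogram threshold — deliberately not per-slice).
The published "local Laplacian" algorithm this stands in for is not
fully specified in the OA imaging literature; the combination here is
a documented approximation with the same intent. An `invert` flag
handles inverted-contrast acquisitions symmetrically.

The biomarkers are then:

* **BV/TV** — bone voxels over VOI voxels (exact count ratio);
* **Tb.Th** — mean of $2 \times$ EDT on the medial axis of the bone
  phase (mm), same machinery as cartilage thickness;
* **Tb.Sp** — the same measure applied to the marrow phase within the
  VOI;
* **TbN** — defined as BV/TV / Tb.Th, so the identity
  $TbN \cdot Tb.Th = BV/TV$ holds by construction;
* **D2D, D3D** — box-counting fractal dimensions (below).

## Box-counting fractal dimensions

$N(\epsilon)$ boxes of edge $\epsilon$ intersect the structure; the
dimension is $-$slope of the ordinary least-squares fit of
$\log N$ on $\log \epsilon$. By default the boxes count the structure
voxel set itself ("area" mode, the usual convention for trabecular
architecture); a "boundary" mode restricted to surface voxels is
available. D2D is the mean of per-slice 2D dimensions along a stated
axis; D3D uses 3D boxes.

The box-size ladder is the set of divisors of the smallest grid
dimension, capped at half that dimension (so every axis is covered by
at least two boxes); when more than five sizes are available the two
largest are dropped (large boxes saturate), and fewer than three
usable sizes is an error. Divisor sizes tile the grid exactly, which
keeps every count free of ragged edge boxes; a power-of-two ladder was
evaluated and rejected because on structures whose self-similarity is
not dyadic (the base-3 Sierpinski carpet and Menger sponge used as
analytic references) the partial edge boxes flatten the log–log slope
well below the true dimension. With the divisor ladder the suite
recovers a filled cube at 3.0, a straight line at 1.0, the
five-iteration Sierpinski carpet at $\log 8/\log 3 \approx 1.893$ and
the three-iteration Menger sponge at $\log 20/\log 3 \approx 2.727$.
The practical corollary: choose VOIs with composite (ideally highly
divisible) edge lengths.

# Synthetic phantoms

The generators produce exactly the inputs the pipeline consumes, with
known truth:

* **Relaxometry phantom** — regions stacked as z-slabs, each with its
  own $(T_1, T_2, M_0)$; the VFA and multi-echo stacks are evaluated
  voxel-wise from the closed-form signal equations. Noise is Rician
  by default (magnitude MRI; the suite verifies its positive bias at
  low SNR), with a Gaussian option for linear-fit unit tests.
* **Trabecular phantom** — periodic lattices. Parallel plates (normal
  to z) have exact truths: $BV/TV = t/p$, $Tb.Th = t \cdot s$,
  $Tb.Sp = (p - t)s$, $TbN = 1/(ps)$ for thickness $t$, period $p$
  (voxels) and spacing $s$ (mm). The default (thickness 2, period 10,
  spacing 0.1 mm) emulates rabbit-scale trabeculae (0.2 mm struts,
  0.8 mm marrow gaps) at high-field MRI resolution. The returned VOI
  trims the first lattice period and any trailing period lacking its
  bounding plate along z, so the distance-transform truths are free of
  volume-border effects — the analogue of placing a subchondral VOI
  away from the segmentation boundary. Orthogonal-rod and
  thresholded-random-field lattices are provided for convergence and
  robustness testing; the random field is smoothed white noise
  thresholded at the quantile that yields the requested fill fraction.
  The grayscale rendering is an isotropic Gaussian blur
  ($\sigma = FWHM/2.3548$, FFT-based circular convolution — exact for
  these periodic lattices) plus optional noise.
* **Score simulator** — a balanced groups-by-times factorial (defaults:
  three groups, three survival times, n = 6 per cell, mirroring the
  standard design of such studies) with planted location shifts;
  responses are Gaussian, optionally discretised to ordinal stages
  0..4.

All randomness flows from a single per-call seed; identical spec plus
seed reproduces bit-identical output. What the phantoms do *not*
emulate: k-space acquisition, B1 inhomogeneity, slice profiles,
chemical shift, motion, or anatomy-shaped geometry. Passing the suite
therefore demonstrates correctness of the estimators on their
generating models and robustness to the modelled noise — not
performance on real anatomy.

# Robust statistics

`trimmedMeanStats()` provides the building block: with
$g = \lfloor \gamma n \rfloor$ trimmed per tail, the trimmed mean of
the central order statistics, the winsorized variance of the clamped
sample, and the effective size $h = n - 2g$. The squared standard
error of a trimmed mean is Yuen's
$(n-1)\,s^2_w / (h(h-1))$.

`trimmedTwoWayAnova()` tests both main effects and the interaction of
a $J \times K$ design from the cell trimmed means $\hat\mu_t$ and
their Yuen variances $V$: for a contrast matrix $C$ the statistic is
$Q = \hat\mu_t' C' (C V C')^{-1} C \hat\mu_t$, with Johansen's
adjusted critical value
$c(\alpha) = q + \frac{q}{2k} A (1 + \frac{3q}{k+2})$,
$q = \chi^2_{1-\alpha,k}$, where $A$ aggregates the per-cell degrees
of freedom $h_j - 1$. The p-value is obtained by monotone root
finding on $c(\alpha) = Q$. The default trim is 0.2 per tail, the
conventional robust-ANOVA choice. With `trim = 0` the procedure is
exactly the classical heteroscedastic (Welch–James–Johansen)
factorial ANOVA. Degenerate designs (a single-level factor, an empty
cell, zero within-cell variability) are errors naming the offending
cell, never silent zeros. A seeded percentile bootstrap
(`method = "bootstrap"`, null-centred within-cell resampling) is
available to cross-check the analytic p-values.

The validation suite calibrates the test under a null
$3 \times 3$ design with n = 6 per cell over 2000 replicates: the
empirical size at $\alpha = 0.05$ must stay within $0.05 \pm 0.015$
for all three effects and the p-values must be uniform.

`powerTwoSampleT()` and `effectSizeFromPower()` implement the
noncentral-t power function for the two-sample t test
($df = 2n - 2$, $ncp = d\sqrt{n/2}$) and its inverse by root finding.
The study-design reading adopted here is that a quoted "beta error of
0.8" means *power* 0.8 ($\beta = 0.2$): that is the convention of the
standard power calculators and the only reading consistent with the
detectable effect size of 1.2 for n = 12 per group at
$\alpha = 0.05$, two-sided.

`descriptiveSummary()` (median, min, max, IQR) and
`stageFrequencyTable()` (ordinal stage counts and per-cell
frequencies by group and time, the tabulation behind stage heat maps)
complete the reporting layer. The packaged hyaluronic-acid
concentration table (`haSynovialFluid()`) is measured data shipped for
exercising these operations; its values are not recomputable.

# Problem sizes used in validation

The suite's simulation sizes are chosen to give stable statistics at
interactive runtimes: noise studies use 1000-voxel phantoms at SNR 50,
the null calibration uses 2000 replicates, power and frequency
properties use 100–500 seeds, fractal references use the
five-iteration carpet (243²) and three-iteration sponge (27³), and
convergence studies run three doublings of resolution. All seeds are
fixed in the tests.

# Known limitations

* Thickness by 2×EDT-on-medial-axis carries up to one voxel of
  positive bias on structures an odd number of voxels thick; use
  sphere-fitting local thickness if sub-voxel accuracy matters.
* The ridge medial axis is not guaranteed topology-preserving on
  highly irregular structures (it is a thickness sampler, not a
  connectivity analysis).
* The sharpen+Otsu binarisation is a stand-in for unpublished local
  Laplacian segmentation variants; on very low-contrast data the
  threshold is global per VOI, not adaptive.
* Fractal dimensions require VOIs with at least three usable divisor
  box sizes; prime edge lengths are rejected.
* The Johansen p-values are approximations; for very small cells the
  bootstrap mode is the safer cross-check.
* No B1 correction, multi-component T2, DICOM ingestion or image
  registration: inputs are co-registered NIfTI volumes.
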