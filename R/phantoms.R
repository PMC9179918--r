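## Synthetic phantom generators: every downstream stage of the
## pipeline (relaxometry, cartilage and bone morphometry, robust
## statistics) can be exercised against inputs with analytically known
## ground truth, so no scan data are required for validation.

#' Spoiled gradient-echo steady-state signal
#'
#' Closed-form SPGR signal `S(a) = M0 sin(a) (1 - E1) / (1 - E1 cos(a))`
#' with `E1 = exp(-TR / T1)`; the generating model of variable
#' flip-angle T1 mapping.
#'
#' @param M0 equilibrium magnetisation (arbitrary units, >= 0).
#' @param T1 longitudinal relaxation time, ms (> 0).
#' @param tr repetition time, ms (> 0).
#' @param flipAngles flip angles in degrees, in (0, 90].
#' @return Numeric vector, one non-negative signal per flip angle.
#' @examples
#' simulateSpgrSignal(1000, 1200, 15, c(2, 5, 10, 15, 25, 45))
#' @export
simulateSpgrSignal <- function(M0, T1, tr, flipAngles) {
  if (!is.finite(T1) || T1 <= 0) stop("T1 must be positive (ms)")
  if (!is.finite(tr) || tr <= 0) stop("TR must be positive (ms)")
  if (M0 < 0) stop("M0 must be non-negative")
  if (any(flipAngles <= 0 | flipAngles > 90))
    stop("flip angles must lie in (0, 90] degrees")
  a <- flipAngles * pi / 180
  e1 <- exp(-tr / T1)
  M0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Mono-exponential multi-echo signal
#'
#' `S(TE) = S0 exp(-TE / T2)`; the generating model of multi-echo T2
#' mapping.
#'
#' @param S0 signal at zero echo time (>= 0).
#' @param T2 transverse relaxation time, ms (> 0).
#' @param echoTimes echo times, ms.
#' @return Numeric vector of signals, strictly decreasing when
#'   `S0 > 0`.
#' @export
simulateMultiechoSignal <- function(S0, T2, echoTimes) {
  if (!is.finite(T2) || T2 <= 0) stop("T2 must be positive (ms)")
  if (S0 < 0) stop("S0 must be non-negative")
  S0 * exp(-echoTimes / T2)
}

## Rician noise: magnitude of a complex signal whose real and
## imaginary channels carry independent Gaussian noise. This is the
## distribution of magnitude MR images and introduces a positive bias
## at low signal-to-noise ratio.
.riceNoise <- function(x, sigma) {
  sqrt((x + stats::rnorm(length(x), 0, sigma))^2 +
       stats::rnorm(length(x), 0, sigma)^2)
}

.addNoise <- function(x, sigma, model) {
  if (sigma <= 0) return(x)
  switch(model,
         gaussian = x + stats::rnorm(length(x), 0, sigma),
         rician = .riceNoise(x, sigma),
         stop("unknown noise model: ", model))
}

## ---- cartilage phantom ----------------------------------------------

#' CartilagePhantomSpec: parameters of the relaxometry phantom
#'
#' Defines a piecewise-constant 3D phantom (regions stacked as slabs
#' along z, each with its own T1, T2 and M0) from which a variable
#' flip-angle SPGR stack and a multi-echo stack are simulated with the
#' closed-form signal equations, optionally degraded with Gaussian or
#' Rician noise.
#'
#' @slot shape integer(3) voxel dimensions.
#' @slot spacing numeric(3) voxel spacing, mm.
#' @slot regions data.frame with columns `label`, `T1`, `T2`, `M0`.
#' @slot tr repetition time of the VFA acquisition, ms.
#' @slot flipAngles flip angles, degrees.
#' @slot echoTimes echo times, ms.
#' @slot noiseSigma noise standard deviation (signal units).
#' @slot noiseModel `"rician"` (default; magnitude MRI) or
#'   `"gaussian"`.
#' @slot seed integer seed; all random draws in
#'   [makeCartilagePhantom()] flow from it.
#' @export
setClass("CartilagePhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 regions = "data.frame", tr = "numeric",
                 flipAngles = "numeric", echoTimes = "numeric",
                 noiseSigma = "numeric", noiseModel = "character",
                 seed = "integer"))

setValidity("CartilagePhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1))
    return("shape must be 3 positive integers")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  r <- object@regions
  if (nrow(r) == 0) return("at least one region is required")
  need <- c("label", "T1", "T2", "M0")
  if (!all(need %in% names(r)))
    return("regions needs columns label, T1, T2, M0")
  if (any(r$T1 <= 0) || any(r$T2 <= 0)) return("T1 and T2 must be > 0")
  if (any(r$M0 < 0)) return("M0 must be >= 0")
  if (object@tr <= 0) return("TR must be > 0")
  if (any(object@flipAngles <= 0 | object@flipAngles > 90))
    return("flip angles must lie in (0, 90] degrees")
  if (any(object@echoTimes <= 0) || any(diff(object@echoTimes) <= 0))
    return("echo times must be strictly increasing and > 0")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (!object@noiseModel %in% c("gaussian", "rician"))
    return("noiseModel must be 'gaussian' or 'rician'")
  TRUE
})

## Acquisition parameters mirror the study protocol: six flip angles
## and sixteen echo times; TR is a free generator parameter (it is a
## required input of the T1 fit, never assumed from data).
#' @rdname CartilagePhantomSpec-class
#' @param shape,spacing,regions,tr,flipAngles,echoTimes,noiseSigma,noiseModel,seed
#'   see the corresponding slots.
#' @return A validated `CartilagePhantomSpec`.
#' @export
cartilagePhantomSpec <- function(shape = c(24L, 24L, 12L),
                                 spacing = c(0.25, 0.25, 0.25),
                                 regions = data.frame(
                                   label = c(1L, 2L),
                                   T1 = c(1200, 900),
                                   T2 = c(30, 50),
                                   M0 = c(1000, 1000)),
                                 tr = 15,
                                 flipAngles = c(2, 5, 10, 15, 25, 45),
                                 echoTimes = c(2.7, 4.1, 5.5, 6.9, 8.3,
                                               9.7, 11.1, 12.5, 13.9,
                                               15.3, 16.7, 18.1, 19.5,
                                               20.9, 22.3, 23.7),
                                 noiseSigma = 0,
                                 noiseModel = "rician",
                                 seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("CartilagePhantomSpec", shape = as.integer(shape),
      spacing = as.numeric(spacing), regions = regions,
      tr = as.numeric(tr), flipAngles = as.numeric(flipAngles),
      echoTimes = as.numeric(echoTimes),
      noiseSigma = as.numeric(noiseSigma), noiseModel = noiseModel,
      seed = as.integer(seed))
}

#' Simulate a relaxometry phantom
#'
#' Builds the label map (regions as equal z-slabs), evaluates the
#' closed-form SPGR and mono-exponential signals voxel-wise, applies
#' noise, and returns the two series together with the ground-truth
#' parametric maps. Identical spec (including seed) gives bit-identical
#' output.
#'
#' @param spec a [cartilagePhantomSpec()].
#' @return List with elements `vfa` and `me`
#'   ([RelaxometrySeries-class]), `truth` (list of T1 and T2
#'   [ParametricMap-class] objects) and `labelmap`
#'   ([VolumeGrid-class]).
#' @export
makeCartilagePhantom <- function(spec) {
  validObject(spec)
  d <- spec@shape
  r <- spec@regions
  nr <- nrow(r)
  ## regions stacked as equal slabs along z
  zidx <- pmin(nr, 1L + ((seq_len(d[3]) - 1L) * nr) %/% d[3])
  lab <- array(rep(r$label[zidx], each = d[1] * d[2]), d)
  t1m <- array(rep(r$T1[zidx], each = d[1] * d[2]), d)
  t2m <- array(rep(r$T2[zidx], each = d[1] * d[2]), d)
  m0m <- array(rep(r$M0[zidx], each = d[1] * d[2]), d)

  a <- spec@flipAngles * pi / 180
  e1 <- exp(-spec@tr / t1m)
  vfa <- vapply(seq_along(a), function(i) {
    m0m * sin(a[i]) * (1 - e1) / (1 - e1 * cos(a[i]))
  }, array(0, d))
  dim(vfa) <- c(d, length(a))
  me <- vapply(seq_along(spec@echoTimes), function(i) {
    m0m * exp(-spec@echoTimes[i] / t2m)
  }, array(0, d))
  dim(me) <- c(d, length(spec@echoTimes))

  if (spec@noiseSigma > 0) {
    withr::with_seed(spec@seed, {
      vfa[] <- .addNoise(vfa, spec@noiseSigma, spec@noiseModel)
      me[] <- .addNoise(me, spec@noiseSigma, spec@noiseModel)
    })
  }

  ones <- VolumeGrid(array(TRUE, d), spec@spacing)
  truth <- list(
    t1 = new("ParametricMap", values = VolumeGrid(t1m, spec@spacing),
             amplitude = VolumeGrid(m0m, spec@spacing),
             validMask = ones, kind = "T1"),
    t2 = new("ParametricMap", values = VolumeGrid(t2m, spec@spacing),
             amplitude = VolumeGrid(m0m, spec@spacing),
             validMask = ones, kind = "T2"))
  list(vfa = vfaSeries(vfa, spec@flipAngles, spec@tr, spec@spacing),
       me = multiechoSeries(me, spec@echoTimes, spec@spacing),
       truth = truth,
       labelmap = VolumeGrid(lab, spec@spacing))
}

## ---- trabecular phantom ---------------------------------------------

#' TrabecularPhantomSpec: parameters of the bone phantom
#'
#' Periodic trabecular lattices with analytic morphometry. For
#' `parallel_plates` (plates normal to z) the ground truth is exact:
#' `BV/TV = thickness/period`, `Tb.Th = thickness * spacing`,
#' `Tb.Sp = (period - thickness) * spacing`,
#' `TbN = 1/(period * spacing)`. `orthogonal_rods` renders three
#' orthogonal square-rod families; `thresholded_random_field`
#' thresholds a smoothed Gaussian field at the quantile giving
#' `fillFraction`.
#'
#' @slot shape integer(3) voxel dimensions.
#' @slot spacing numeric(3) voxel spacing, mm (isotropic expected).
#' @slot lattice one of `"parallel_plates"`, `"orthogonal_rods"`,
#'   `"thresholded_random_field"`.
#' @slot thickness plate/rod thickness in voxels (0 < thickness <
#'   period).
#' @slot period lattice period in voxels.
#' @slot fillFraction target bone fraction of the random-field lattice.
#' @slot blurFwhm Gaussian blur of the grayscale rendering, mm.
#' @slot noiseSigma additive Gaussian noise of the rendering.
#' @slot seed integer seed.
#' @export
setClass("TrabecularPhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 lattice = "character", thickness = "integer",
                 period = "integer", fillFraction = "numeric",
                 blurFwhm = "numeric", noiseSigma = "numeric",
                 seed = "integer"))

setValidity("TrabecularPhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1))
    return("shape must be 3 positive integers")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  if (!object@lattice %in% c("parallel_plates", "orthogonal_rods",
                             "thresholded_random_field"))
    return("unknown lattice type")
  if (object@thickness <= 0 || object@thickness >= object@period)
    return("0 < thickness < period is required")
  if (object@fillFraction <= 0 || object@fillFraction >= 1)
    return("fillFraction must lie in (0, 1)")
  if (object@blurFwhm < 0 || object@noiseSigma < 0)
    return("blurFwhm and noiseSigma must be >= 0")
  TRUE
})

#' @rdname TrabecularPhantomSpec-class
#' @param shape,spacing,lattice,thickness,period,fillFraction,blurFwhm,noiseSigma,seed
#'   see the corresponding slots.
#' @return A validated `TrabecularPhantomSpec`.
#' @export
trabecularPhantomSpec <- function(shape = c(48L, 48L, 52L),
                                  spacing = c(0.1, 0.1, 0.1),
                                  lattice = "parallel_plates",
                                  thickness = 2L, period = 10L,
                                  fillFraction = 0.3,
                                  blurFwhm = 0, noiseSigma = 0,
                                  seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("TrabecularPhantomSpec", shape = as.integer(shape),
      spacing = as.numeric(spacing), lattice = lattice,
      thickness = as.integer(thickness), period = as.integer(period),
      fillFraction = as.numeric(fillFraction),
      blurFwhm = as.numeric(blurFwhm), noiseSigma = as.numeric(noiseSigma),
      seed = as.integer(seed))
}

#' Simulate a trabecular bone phantom
#'
#' Renders the binary lattice, its grayscale image (Gaussian-blurred
#' and noised), a volume of interest and, where defined, the analytic
#' [BoneBiomarkers-class] truth. For the plate lattice the VOI trims
#' the first period and any trailing period without a bounding plate
#' along z, so the distance-transform truths are free of volume-border
#' effects.
#'
#' @param spec a [trabecularPhantomSpec()].
#' @return List with `gray`, `binary`, `voi` ([VolumeGrid-class]) and
#'   `truth` ([BoneBiomarkers-class]; thickness truths are `NA` for
#'   lattices without an analytic value).
#' @export
makeTrabecularPhantom <- function(spec) {
  validObject(spec)
  d <- spec@shape
  sp <- spec@spacing
  t <- spec@thickness
  p <- spec@period
  x0 <- (seq_len(d[1]) - 1L) %% p
  y0 <- (seq_len(d[2]) - 1L) %% p
  z0 <- (seq_len(d[3]) - 1L) %% p
  voi <- array(TRUE, d)
  truth <- new("BoneBiomarkers")
  if (spec@lattice == "parallel_plates") {
    bin <- array(rep(z0 < t, each = d[1] * d[2]), d)
    imax <- (d[3] - t) %/% p
    if (imax >= 2L) {
      zin <- seq_len(d[3]) - 1L
      voi <- array(rep(zin >= p & zin < p * imax, each = d[1] * d[2]), d)
    }
    truth <- new("BoneBiomarkers", bvtv = t / p, tbTh = t * sp[3],
                 tbSp = (p - t) * sp[3], tbN = 1 / (p * sp[3]))
  } else if (spec@lattice == "orthogonal_rods") {
    fx <- x0 < t; fy <- y0 < t; fz <- z0 < t
    axy <- outer(fx, fy)                 # rods running along z
    bin <- array(FALSE, d)
    for (k in seq_len(d[3])) {
      bin[, , k] <- if (fz[k])
        axy | outer(fx, rep(TRUE, d[2])) | outer(rep(TRUE, d[1]), fy)
      else axy
    }
    truth <- new("BoneBiomarkers", bvtv = mean(bin))
  } else {
    field <- withr::with_seed(spec@seed,
                              array(stats::rnorm(prod(d)), d))
    field <- gaussianBlur(field, fwhm = p * sp[1] / 2, spacing = sp)
    thr <- stats::quantile(field, 1 - spec@fillFraction, names = FALSE)
    bin <- field > thr
    truth <- new("BoneBiomarkers", bvtv = mean(bin))
  }
  gray <- gaussianBlur(bin + 0, spec@blurFwhm, sp)
  if (spec@noiseSigma > 0)
    gray <- withr::with_seed(spec@seed + 1L,
      array(gray + stats::rnorm(prod(d), 0, spec@noiseSigma), d))
  list(gray = VolumeGrid(gray, sp),
       binary = VolumeGrid(bin, sp),
       voi = VolumeGrid(voi, sp),
       truth = truth)
}

## ---- ordinal score datasets -----------------------------------------

#' ScoreSimSpec: simulated factorial score datasets
#'
#' A balanced treatment-by-time design with planted location shifts,
#' matching the study layout (three treatment groups crossed with
#' three survival times, n per cell). Responses are Gaussian around
#' the cell effect; with `noise = "ordinalized"` they are discretised
#' to integer stages `0 .. nStages-1`.
#'
#' @slot levelsA treatment group labels.
#' @slot levelsB survival time labels (days).
#' @slot nPerCell records per cell (>= 2).
#' @slot cellEffects numeric matrix `|A| x |B|` of location shifts.
#' @slot noise `"normal"` or `"ordinalized"`.
#' @slot nStages number of ordinal stages.
#' @slot seed integer seed.
#' @export
setClass("ScoreSimSpec",
  representation(levelsA = "character", levelsB = "character",
                 nPerCell = "integer", cellEffects = "matrix",
                 noise = "character", nStages = "integer",
                 seed = "integer"))

setValidity("ScoreSimSpec", function(object) {
  if (object@nPerCell < 2L) return("nPerCell must be >= 2")
  if (!identical(dim(object@cellEffects),
                 c(length(object@levelsA), length(object@levelsB))))
    return("cellEffects must be |A| x |B|")
  if (!object@noise %in% c("normal", "ordinalized"))
    return("noise must be 'normal' or 'ordinalized'")
  if (object@nStages < 2L) return("nStages must be >= 2")
  TRUE
})

#' @rdname ScoreSimSpec-class
#' @param levelsA,levelsB,nPerCell,cellEffects,noise,nStages,seed see
#'   the corresponding slots.
#' @return A validated `ScoreSimSpec`.
#' @export
scoreSimSpec <- function(levelsA = c("CTR", "CGH", "CGH-NC"),
                         levelsB = c("24", "56", "84"),
                         nPerCell = 6L,
                         cellEffects = matrix(0, length(levelsA),
                                              length(levelsB)),
                         noise = "normal", nStages = 5L, seed = 1L) {
  new("ScoreSimSpec", levelsA = as.character(levelsA),
      levelsB = as.character(levelsB), nPerCell = as.integer(nPerCell),
      cellEffects = cellEffects, noise = noise,
      nStages = as.integer(nStages), seed = as.integer(seed))
}

#' Simulate an ordinal/continuous score dataset
#'
#' @param spec a [scoreSimSpec()].
#' @param variable name stored in the `variable` column.
#' @return A score-record data.frame with columns `subject_id`,
#'   `group`, `time_days`, `variable`, `value`; `nPerCell` records per
#'   (group, time) cell. Identical spec gives identical records.
#' @export
makeOrdinalScoreDataset <- function(spec, variable = "score") {
  validObject(spec)
  nA <- length(spec@levelsA)
  nB <- length(spec@levelsB)
  n <- spec@nPerCell
  cells <- expand.grid(a = seq_len(nA), b = seq_len(nB))
  withr::with_seed(spec@seed, {
    rec <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      a <- cells$a[i]; b <- cells$b[i]
      latent <- spec@cellEffects[a, b] + stats::rnorm(n)
      val <- if (spec@noise == "ordinalized")
        pmin(pmax(round(latent), 0), spec@nStages - 1L) else latent
      data.frame(group = spec@levelsA[a], time_days = spec@levelsB[b],
                 variable = variable, value = val,
                 stringsAsFactors = FALSE)
    }))
  })
  rec <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(rec))), rec)
  rownames(rec) <- NULL
  rec
}
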