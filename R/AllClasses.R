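#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' VolumeGrid: a 3D scalar image with physical voxel spacing
#'
#' The elementary data carrier of the package: a 3D array (scalar,
#' logical or integer-label) together with its voxel spacing in mm and
#' an axis-orientation tag naming what each array axis represents.
#' Voxel coordinates are 0-based indices; world coordinates are
#' `index * spacing`.
#'
#' @slot voxels 3D array of voxel values.
#' @slot spacing numeric(3), voxel edge length per axis in mm.
#' @slot axes character(3), orientation tag per axis (free-form labels
#'   such as `"ML"`, `"AP"`, `"SI"`; default `c("x","y","z")`).
#' @export
setClass("VolumeGrid",
  representation(voxels = "array", spacing = "numeric", axes = "character"),
  prototype(spacing = c(1, 1, 1), axes = c("x", "y", "z")))

setValidity("VolumeGrid", function(object) {
  if (length(dim(object@voxels)) != 3L)
    return("voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite values (mm)")
  if (length(object@axes) != 3L)
    return("axes must be a character vector of length 3")
  TRUE
})

#' Construct a VolumeGrid
#'
#' @param voxels 3D array (numeric, integer or logical).
#' @param spacing voxel spacing in mm; scalar values are recycled to
#'   all three axes.
#' @param axes axis-orientation tags, character(3).
#' @return A [VolumeGrid-class] object.
#' @examples
#' g <- VolumeGrid(array(0, c(4, 4, 4)), spacing = 0.1)
#' spacing(g)
#' @export
VolumeGrid <- function(voxels, spacing = c(1, 1, 1), axes = c("x", "y", "z")) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VolumeGrid", voxels = voxels, spacing = as.numeric(spacing),
      axes = axes)
}

#' RelaxometrySeries: co-registered signal volumes with acquisition
#' parameters
#'
#' A stack of co-registered volumes, one per acquisition: either a
#' variable flip-angle (VFA) spoiled-gradient-echo series (kind
#' `"VFA"`, carrying a repetition time and one flip angle per volume)
#' or a multi-echo series (kind `"ME"`, carrying one echo time per
#' volume). All volumes must share the grid; spatial registration is a
#' precondition, not a processing stage.
#'
#' @slot signals 4D array, last axis indexes the acquisitions.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot axes character(3), axis-orientation tags.
#' @slot kind `"VFA"` or `"ME"`.
#' @slot tr repetition time in ms (VFA only, `NA` otherwise).
#' @slot flipAngles flip angles in degrees (VFA), in (0, 90].
#' @slot echoTimes echo times in ms (ME), strictly increasing, > 0.
#' @export
setClass("RelaxometrySeries",
  representation(signals = "array", spacing = "numeric", axes = "character",
                 kind = "character", tr = "numeric",
                 flipAngles = "numeric", echoTimes = "numeric"))

setValidity("RelaxometrySeries", function(object) {
  d <- dim(object@signals)
  if (length(d) != 4L) return("signals must be a 4D array")
  if (!object@kind %in% c("VFA", "ME")) return("kind must be 'VFA' or 'ME'")
  if (object@kind == "VFA") {
    if (length(object@flipAngles) != d[4L])
      return("one flip angle per volume required")
    if (any(object@flipAngles <= 0 | object@flipAngles > 90))
      return("flip angles must lie in (0, 90] degrees")
    if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
      return("TR must be a single positive number (ms)")
  } else {
    if (length(object@echoTimes) != d[4L])
      return("one echo time per volume required")
    if (any(object@echoTimes <= 0) || any(diff(object@echoTimes) <= 0))
      return("echo times must be strictly increasing and positive (ms)")
  }
  if (any(object@spacing <= 0)) return("spacing must be positive")
  TRUE
})

#' Construct a variable flip-angle series
#'
#' @param signals 4D array, last axis matching `flipAngles`.
#' @param flipAngles flip angles in degrees.
#' @param tr repetition time in ms.
#' @param spacing voxel spacing in mm (scalar recycled).
#' @param axes axis tags.
#' @return A [RelaxometrySeries-class] of kind `"VFA"`.
#' @export
vfaSeries <- function(signals, flipAngles, tr, spacing = c(1, 1, 1),
                      axes = c("x", "y", "z")) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("RelaxometrySeries", signals = signals, spacing = as.numeric(spacing),
      axes = axes, kind = "VFA", tr = as.numeric(tr),
      flipAngles = as.numeric(flipAngles), echoTimes = numeric(0))
}

#' Construct a multi-echo series
#'
#' @param signals 4D array, last axis matching `echoTimes`.
#' @param echoTimes echo times in ms, strictly increasing.
#' @param spacing voxel spacing in mm (scalar recycled).
#' @param axes axis tags.
#' @return A [RelaxometrySeries-class] of kind `"ME"`.
#' @export
multiechoSeries <- function(signals, echoTimes, spacing = c(1, 1, 1),
                            axes = c("x", "y", "z")) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("RelaxometrySeries", signals = signals, spacing = as.numeric(spacing),
      axes = axes, kind = "ME", tr = NA_real_,
      flipAngles = numeric(0), echoTimes = as.numeric(echoTimes))
}

#' ParametricMap: voxel-wise relaxation time estimates
#'
#' Holds a voxel-wise T1 or T2 map in ms, the associated amplitude map
#' (M0 for T1, S0 for T2) and a validity mask. Values are only
#' meaningful where the mask is `TRUE`; voxels where the fit failed or
#' fell outside physiological plausibility bounds are flagged, not
#' removed.
#'
#' @slot values [VolumeGrid-class] of T1 or T2 in ms.
#' @slot amplitude [VolumeGrid-class] of M0 or S0 (signal units).
#' @slot validMask [VolumeGrid-class], logical.
#' @slot kind `"T1"` or `"T2"`.
#' @export
setClass("ParametricMap",
  representation(values = "VolumeGrid", amplitude = "VolumeGrid",
                 validMask = "VolumeGrid", kind = "character"))

setValidity("ParametricMap", function(object) {
  if (!object@kind %in% c("T1", "T2")) return("kind must be 'T1' or 'T2'")
  dv <- dim(object@values@voxels)
  if (!identical(dv, dim(object@amplitude@voxels)) ||
      !identical(dv, dim(object@validMask@voxels)))
    return("values, amplitude and validMask must share the grid")
  if (!isTRUE(all.equal(object@values@spacing, object@amplitude@spacing)) ||
      !isTRUE(all.equal(object@values@spacing, object@validMask@spacing)))
    return("values, amplitude and validMask must share the spacing")
  if (!is.logical(object@validMask@voxels))
    return("validMask must be logical")
  ok <- object@validMask@voxels
  v <- object@values@voxels[ok]
  if (length(v) && any(!is.finite(v) | v <= 0))
    return("values must be positive and finite wherever validMask is TRUE")
  TRUE
})

#' CartilageParcellation: six-segment cartilage labelling
#'
#' A labelmap splitting a cartilage mask into medial/lateral halves and
#' anterior/central/posterior thirds: segments TM, TL, CM, CL, PM, PL
#' (label codes 1-6; 0 = background). The labels partition the mask:
#' every mask voxel carries exactly one label.
#'
#' @slot labelmap [VolumeGrid-class] with integer labels 0-6.
#' @slot bone `"femoral"` or `"tibial"`.
#' @export
setClass("CartilageParcellation",
  representation(labelmap = "VolumeGrid", bone = "character"))

setValidity("CartilageParcellation", function(object) {
  if (!object@bone %in% c("femoral", "tibial"))
    return("bone must be 'femoral' or 'tibial'")
  lab <- object@labelmap@voxels
  if (!all(lab %in% 0:6)) return("labels must be integers 0..6")
  TRUE
})

#' Segment label codes used by cartilage parcellation
#'
#' Integer codes 1-6 named TM, TL, CM, CL, PM, PL (anterior, central,
#' posterior crossed with medial, lateral).
#' @export
SEGMENT_LABELS <- c(TM = 1L, TL = 2L, CM = 3L, CL = 4L, PM = 5L, PL = 6L)

#' BoneBiomarkers: trabecular morphometry of one volume of interest
#'
#' Bone volume fraction BV/TV (unitless), trabecular thickness Tb.Th
#' (mm), trabecular spacing Tb.Sp (mm), trabecular number TbN (1/mm,
#' equal to BV/TV / Tb.Th by construction), and the 2D and 3D
#' box-counting fractal dimensions of the trabecular network.
#'
#' @slot bvtv bone volume fraction in [0, 1].
#' @slot tbTh trabecular thickness, mm.
#' @slot tbSp trabecular spacing, mm.
#' @slot tbN trabecular number, 1/mm.
#' @slot d2d mean per-slice 2D fractal dimension.
#' @slot d3d 3D fractal dimension.
#' @slot voiLabel volume-of-interest label (e.g. `"medial"`,
#'   `"lateral"`).
#' @export
setClass("BoneBiomarkers",
  representation(bvtv = "numeric", tbTh = "numeric", tbSp = "numeric",
                 tbN = "numeric", d2d = "numeric", d3d = "numeric",
                 voiLabel = "character"),
  prototype(bvtv = NA_real_, tbTh = NA_real_, tbSp = NA_real_,
            tbN = NA_real_, d2d = NA_real_, d3d = NA_real_,
            voiLabel = "whole"))

setValidity("BoneBiomarkers", function(object) {
  if (!is.na(object@bvtv) && (object@bvtv < 0 || object@bvtv > 1))
    return("bvtv must lie in [0, 1]")
  if (!is.na(object@tbTh) && object@tbTh < 0) return("tbTh must be >= 0")
  if (!is.na(object@tbSp) && object@tbSp < 0) return("tbSp must be >= 0")
  TRUE
})

#' TrimmedAnovaResult: robust factorial test summary
#'
#' Johansen-type Q statistics and p-values for the two main effects and
#' the interaction of a trimmed-means heteroscedastic two-way ANOVA.
#'
#' @slot qA,qB,qAB test statistics (>= 0).
#' @slot pA,pB,pAB p-values in [0, 1].
#' @slot trim trimming fraction used per tail.
#' @slot method `"johansen"` or `"bootstrap"`.
#' @export
setClass("TrimmedAnovaResult",
  representation(qA = "numeric", qB = "numeric", qAB = "numeric",
                 pA = "numeric", pB = "numeric", pAB = "numeric",
                 trim = "numeric", method = "character"))

setValidity("TrimmedAnovaResult", function(object) {
  p <- c(object@pA, object@pB, object@pAB)
  if (any(p < 0 | p > 1)) return("p-values must lie in [0, 1]")
  q <- c(object@qA, object@qB, object@qAB)
  if (any(q < 0)) return("statistics must be non-negative")
  TRUE
})

## ---- show methods ----------------------------------------------------

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VolumeGrid %d x %d x %d voxels, spacing %s mm [%s]\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x "),
              paste(object@axes, collapse = ",")))
  v <- object@voxels
  if (is.logical(v)) {
    cat(sprintf("  logical mask: %d TRUE (%.1f%%)\n", sum(v),
                100 * mean(v)))
  } else {
    cat(sprintf("  value range: [%g, %g]\n", min(v), max(v)))
  }
})

setMethod("show", "RelaxometrySeries", function(object) {
  d <- dim(object@signals)
  cat(sprintf("RelaxometrySeries (%s), %d x %d x %d voxels, %d volumes\n",
              object@kind, d[1], d[2], d[3], d[4]))
  if (object@kind == "VFA") {
    cat(sprintf("  TR %g ms, flip angles: %s deg\n", object@tr,
                paste(object@flipAngles, collapse = ", ")))
  } else {
    cat(sprintf("  echo times: %s ms\n",
                paste(object@echoTimes, collapse = ", ")))
  }
})

setMethod("show", "ParametricMap", function(object) {
  nv <- sum(object@validMask@voxels)
  v <- object@values@voxels[object@validMask@voxels]
  cat(sprintf("ParametricMap (%s): %d valid voxels", object@kind, nv))
  if (nv > 0) cat(sprintf(", median %.1f ms", stats::median(v)))
  cat("\n")
})

setMethod("show", "CartilageParcellation", function(object) {
  lab <- object@labelmap@voxels
  counts <- vapply(SEGMENT_LABELS, function(l) sum(lab == l), integer(1))
  cat(sprintf("CartilageParcellation (%s): %d cartilage voxels\n",
              object@bone, sum(lab > 0)))
  print(counts)
})

setMethod("show", "BoneBiomarkers", function(object) {
  cat(sprintf("BoneBiomarkers [%s]\n", object@voiLabel))
  cat(sprintf("  BV/TV %.4f  Tb.Th %.4f mm  Tb.Sp %.4f mm  TbN %.4f /mm\n",
              object@bvtv, object@tbTh, object@tbSp, object@tbN))
  cat(sprintf("  D2D %.3f  D3D %.3f\n", object@d2d, object@d3d))
})

setMethod("show", "TrimmedAnovaResult", function(object) {
  cat(sprintf("Trimmed-means two-way ANOVA (trim = %g, %s p-values)\n",
              object@trim, object@method))
  tab <- data.frame(Q = c(object@qA, object@qB, object@qAB),
                    p = c(object@pA, object@pB, object@pAB),
                    row.names = c("A", "B", "A:B"))
  print(signif(tab, 4))
})
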