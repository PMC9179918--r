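## Voxel-wise relaxometry. Both fits are strictly voxel-independent
## (no spatial regularisation) and vectorised across voxels.

## Plausibility bounds: estimates outside these are kept in the map
## but flagged invalid.
.T1_BOUNDS <- c(50, 10000)    # ms
.T2_BOUNDS <- c(1, 1000)      # ms

.maskFromArg <- function(mask, d) {
  if (is.null(mask)) return(array(TRUE, d))
  m <- .asMaskArray(mask)
  if (!identical(dim(m), d)) stop("grid mismatch between series and mask")
  m
}

.emptyMap <- function(d, spacing, kind) {
  new("ParametricMap",
      values = VolumeGrid(array(NA_real_, d), spacing),
      amplitude = VolumeGrid(array(NA_real_, d), spacing),
      validMask = VolumeGrid(array(FALSE, d), spacing),
      kind = kind)
}

#' Variable flip-angle T1 mapping
#'
#' Voxel-wise T1 estimation from a spoiled-gradient-echo stack
#' acquired at two or more flip angles, by the classical
#' linearisation: with `y = S/sin(a)` and `x = S/tan(a)`, the SPGR
#' equation becomes the line `y = E1 * x + M0 (1 - E1)`, so an
#' ordinary least-squares fit gives `E1` as the slope and
#' `T1 = -TR / log(E1)`, `M0 = intercept / (1 - E1)`. Voxels whose
#' slope falls outside (0, 1), whose fit is degenerate (e.g. all-zero
#' signal), or whose T1 lies outside [50, 10000] ms are flagged
#' invalid rather than raising an error.
#'
#' @param series a VFA [RelaxometrySeries-class] (>= 2 distinct flip
#'   angles, TR set).
#' @param mask optional logical [VolumeGrid-class]/array restricting
#'   the fit.
#' @return A [ParametricMap-class] of kind `"T1"` (values in ms,
#'   amplitude = M0).
#' @export
fitT1Vfa <- function(series, mask = NULL) {
  stopifnot(is(series, "RelaxometrySeries"))
  if (series@kind != "VFA") stop("fitT1Vfa needs a VFA series")
  a <- series@flipAngles
  if (length(unique(a)) < 2L) stop("at least 2 distinct flip angles required")
  d <- dim(series@signals)[1:3]
  m <- .maskFromArg(mask, d)
  out <- .emptyMap(d, series@spacing, "T1")
  idx <- which(m)
  if (!length(idx)) return(out)

  S <- matrix(series@signals, ncol = length(a))[idx, , drop = FALSE]
  rad <- a * pi / 180
  y <- sweep(S, 2, sin(rad), "/")
  x <- sweep(S, 2, tan(rad), "/")
  n <- length(a)
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x * x); sxy <- rowSums(x * y)
  den <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / den
  icpt <- (sy - slope * sx) / n
  ok <- is.finite(slope) & is.finite(icpt) & den > 0 &
    slope > 0 & slope < 1
  t1 <- rep(NA_real_, length(idx))
  m0 <- rep(NA_real_, length(idx))
  t1[ok] <- -series@tr / log(slope[ok])
  m0[ok] <- icpt[ok] / (1 - slope[ok])
  valid <- ok & t1 >= .T1_BOUNDS[1] & t1 <= .T1_BOUNDS[2] & m0 >= 0
  valid[is.na(valid)] <- FALSE

  out@values@voxels[idx] <- t1
  out@amplitude@voxels[idx] <- m0
  out@validMask@voxels[idx] <- valid
  validObject(out)
  out
}

#' Multi-echo T2 mapping
#'
#' Voxel-wise mono-exponential T2 estimation from a multi-echo stack
#' by log-linear least squares of `log S` on TE, weighted by the
#' squared signal (which approximates nonlinear least squares under
#' additive noise by undoing the log-transform heteroscedasticity).
#' Echoes with non-positive signal are dropped voxel-wise; at least 3
#' usable echoes are required. `T2 = -1/slope`, `S0 =
#' exp(intercept)`. Non-decaying voxels (slope >= 0) and T2 outside
#' [1, 1000] ms are flagged invalid.
#'
#' @param series a multi-echo [RelaxometrySeries-class].
#' @param mask optional logical [VolumeGrid-class]/array restricting
#'   the fit.
#' @return A [ParametricMap-class] of kind `"T2"` (values in ms,
#'   amplitude = S0).
#' @export
fitT2Monoexp <- function(series, mask = NULL) {
  stopifnot(is(series, "RelaxometrySeries"))
  if (series@kind != "ME") stop("fitT2Monoexp needs a multi-echo series")
  te <- series@echoTimes
  if (length(te) < 2L) stop("at least 2 echo times required")
  d <- dim(series@signals)[1:3]
  m <- .maskFromArg(mask, d)
  out <- .emptyMap(d, series@spacing, "T2")
  idx <- which(m)
  if (!length(idx)) return(out)

  S <- matrix(series@signals, ncol = length(te))[idx, , drop = FALSE]
  usable <- S > 0
  w <- S^2 * usable
  L <- log(pmax(S, .Machine$double.xmin))
  X <- matrix(te, nrow(S), length(te), byrow = TRUE)
  sw <- rowSums(w)
  swx <- rowSums(w * X); swy <- rowSums(w * L)
  swxx <- rowSums(w * X * X); swxy <- rowSums(w * X * L)
  den <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / den
  icpt <- (swy - slope * swx) / sw
  ok <- rowSums(usable) >= 3L & is.finite(slope) & den > 0 & slope < 0
  t2 <- rep(NA_real_, length(idx))
  s0 <- rep(NA_real_, length(idx))
  t2[ok] <- -1 / slope[ok]
  s0[ok] <- exp(icpt[ok])
  valid <- ok & t2 >= .T2_BOUNDS[1] & t2 <= .T2_BOUNDS[2]
  valid[is.na(valid)] <- FALSE

  out@values@voxels[idx] <- t2
  out@amplitude@voxels[idx] <- s0
  out@validMask@voxels[idx] <- valid
  validObject(out)
  out
}

#' Per-label summary of a parametric map
#'
#' Summarises the valid voxels of a T1/T2 map within each label of a
#' co-registered labelmap: number of valid voxels, mean, median and
#' SD. Labels without valid voxels are reported with `NA` statistics,
#' not dropped.
#'
#' @param map a [ParametricMap-class].
#' @param labelmap [VolumeGrid-class]/array of integer labels sharing
#'   the map's grid (0 = background).
#' @param labels labels to report; defaults to the non-zero labels
#'   present, but absent labels may be requested explicitly.
#' @return data.frame with columns `label`, `n_valid`, `mean`,
#'   `median`, `sd`.
#' @export
summarizeMap <- function(map, labelmap, labels = NULL) {
  stopifnot(is(map, "ParametricMap"))
  lab <- if (is(labelmap, "VolumeGrid")) labelmap@voxels else labelmap
  .checkSameGrid(map@values, VolumeGrid(lab, spacing(map)), "map and labelmap")
  if (is.null(labels)) labels <- sort(unique(lab[lab != 0]))
  v <- map@values@voxels
  ok <- map@validMask@voxels
  rows <- lapply(labels, function(l) {
    x <- v[ok & lab == l]
    if (!length(x))
      data.frame(label = l, n_valid = 0L, mean = NA_real_,
                 median = NA_real_, sd = NA_real_)
    else
      data.frame(label = l, n_valid = length(x), mean = mean(x),
                 median = stats::median(x),
                 sd = if (length(x) > 1) stats::sd(x) else 0)
  })
  do.call(rbind, rows)
}
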