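## Subchondral trabecular bone morphometry: Laplacian-sharpened Otsu
## binarisation, BV/TV, distance-transform thickness and spacing,
## trabecular number, and box-counting fractal dimensions (fractal.R).

## 6-neighbour discrete Laplacian (unit voxel steps, replicated
## border). Sharpening `g - lambda * Laplacian(g)` steepens edges and
## counteracts partial-volume blur before thresholding.
.laplacian3d <- function(x) {
  d <- dim(x)
  shift <- function(a, ax, by) {
    n <- d[ax]
    src <- pmin(n, pmax(1L, seq_len(n) + by))
    switch(ax, a[src, , , drop = FALSE], a[, src, , drop = FALSE],
           a[, , src, drop = FALSE])
  }
  shift(x, 1L, 1L) + shift(x, 1L, -1L) + shift(x, 2L, 1L) +
    shift(x, 2L, -1L) + shift(x, 3L, 1L) + shift(x, 3L, -1L) - 6 * x
}

#' Binarise trabecular bone within a volume of interest
#'
#' Sharpens the grayscale volume with a discrete-Laplacian unsharp
#' filter (`gray - lambda * Laplacian`), reducing partial-volume
#' blending at trabecular boundaries, then thresholds with Otsu's
#' criterion computed over the VOI voxels only. The output is
#' restricted to the VOI.
#'
#' @param gray grayscale [VolumeGrid-class]/array.
#' @param voi logical [VolumeGrid-class]/array; non-empty.
#' @param lambda sharpening strength (default 1).
#' @param invert set `TRUE` for inverted contrast (dark trabeculae);
#'   the result is identical to binarising the negated image.
#' @return Logical [VolumeGrid-class]: bone voxels inside the VOI.
#' @export
binarizeTrabeculae <- function(gray, voi, lambda = 1, invert = FALSE) {
  sp <- if (is(gray, "VolumeGrid")) gray@spacing else c(1, 1, 1)
  g <- if (is(gray, "VolumeGrid")) gray@voxels else gray
  v <- .asMaskArray(voi, "voi")
  .checkSameGrid(g, v, "gray and voi")
  if (!any(v)) stop("empty volume of interest")
  if (invert) g <- -g
  sharp <- g - lambda * .laplacian3d(g)
  thr <- otsuThreshold(sharp[v])
  VolumeGrid(sharp > thr & v, sp)
}

#' Bone volume fraction (BV/TV)
#'
#' Ratio of trabecular (binary) voxels to all voxels of the volume of
#' interest.
#'
#' @param binary logical [VolumeGrid-class]/array of bone voxels.
#' @param voi logical [VolumeGrid-class]/array; non-empty.
#' @return Fraction in [0, 1].
#' @export
boneVolumeFraction <- function(binary, voi) {
  b <- .asMaskArray(binary, "binary")
  v <- .asMaskArray(voi, "voi")
  .checkSameGrid(b, v, "binary and voi")
  nv <- sum(v)
  if (nv == 0) stop("empty volume of interest")
  sum(b & v) / nv
}

#' Trabecular thickness (Tb.Th)
#'
#' Mean of twice the Euclidean distance transform sampled on the
#' medial axis of the bone phase, in mm. Anisotropic grids are
#' resampled to isotropic voxels first.
#'
#' @param binary logical [VolumeGrid-class]/array of bone voxels;
#'   non-empty.
#' @param voi optional VOI restricting where skeleton voxels are
#'   sampled (the distance transform always sees the full grid).
#' @param spacing voxel spacing, mm (taken from the grid if given).
#' @return Tb.Th in mm, with attributes `nSkeleton` and
#'   `lowConfidence`.
#' @export
trabecularThickness <- function(binary, voi = NULL, spacing = c(1, 1, 1)) {
  if (is(binary, "VolumeGrid")) spacing <- binary@spacing
  b <- .asMaskArray(binary, "binary")
  if (!any(b)) stop("empty bone phase")
  v <- if (is.null(voi)) NULL else .asMaskArray(voi, "voi")
  .phaseThickness(b, spacing, v)
}

#' Trabecular spacing (Tb.Sp)
#'
#' Same measure as [trabecularThickness()] applied to the marrow
#' phase (complement of the bone mask) within the VOI.
#'
#' @inheritParams trabecularThickness
#' @return Tb.Sp in mm, with attributes `nSkeleton` and
#'   `lowConfidence`.
#' @export
trabecularSpacing <- function(binary, voi = NULL, spacing = c(1, 1, 1)) {
  if (is(binary, "VolumeGrid")) spacing <- binary@spacing
  b <- .asMaskArray(binary, "binary")
  marrow <- !b
  if (!is.null(voi)) {
    v <- .asMaskArray(voi, "voi")
    if (!any(marrow & v)) stop("empty marrow phase inside the VOI")
    .phaseThickness(marrow, spacing, v)
  } else {
    if (!any(marrow)) stop("empty marrow phase")
    .phaseThickness(marrow, spacing)
  }
}

#' Trabecular number (TbN)
#'
#' `TbN = BV/TV / Tb.Th` (1/mm); the identity `TbN * Tb.Th = BV/TV`
#' holds exactly by construction.
#'
#' @param bvtv bone volume fraction in [0, 1].
#' @param tbTh trabecular thickness, mm (> 0).
#' @return TbN in 1/mm.
#' @export
trabecularNumber <- function(bvtv, tbTh) {
  if (!is.finite(tbTh) || tbTh <= 0) stop("tbTh must be > 0")
  as.numeric(bvtv) / as.numeric(tbTh)
}

#' Full trabecular biomarker panel for one VOI
#'
#' Convenience wrapper running [binarizeTrabeculae()] (skipped when
#' `gray` is already logical), [boneVolumeFraction()],
#' [trabecularThickness()], [trabecularSpacing()],
#' [trabecularNumber()], [fractalDimension2D()] and
#' [fractalDimension3D()].
#'
#' @inheritParams binarizeTrabeculae
#' @param voiLabel annotation stored in the result (`"medial"`,
#'   `"lateral"`, ...).
#' @param d2dAxis slice axis for the 2D fractal dimension.
#' @param boxMode `"area"` or `"boundary"`, see
#'   [fractalDimension3D()].
#' @return A [BoneBiomarkers-class].
#' @export
boneBiomarkers <- function(gray, voi, lambda = 1, voiLabel = "whole",
                           d2dAxis = 3L, boxMode = "area") {
  sp <- if (is(gray, "VolumeGrid")) gray@spacing else c(1, 1, 1)
  g <- if (is(gray, "VolumeGrid")) gray@voxels else gray
  bin <- if (is.logical(g)) {
    VolumeGrid(g & .asMaskArray(voi, "voi"), sp)
  } else {
    binarizeTrabeculae(gray, voi, lambda = lambda)
  }
  bvtv <- boneVolumeFraction(bin, voi)
  tbTh <- as.numeric(trabecularThickness(bin, voi = voi))
  tbSp <- as.numeric(trabecularSpacing(bin, voi = voi))
  new("BoneBiomarkers", bvtv = bvtv, tbTh = tbTh, tbSp = tbSp,
      tbN = trabecularNumber(bvtv, tbTh),
      d2d = fractalDimension2D(bin, axis = d2dAxis, mode = boxMode),
      d3d = fractalDimension3D(bin, mode = boxMode),
      voiLabel = voiLabel)
}
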