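## Shared 3D morphology primitives: Euclidean distance transform,
## medial-axis extraction, Gaussian smoothing and Otsu thresholding.
## These operate on plain arrays; user-facing functions wrap them in
## VolumeGrid semantics.

.asMaskArray <- function(x, what = "mask") {
  if (is(x, "VolumeGrid")) x <- x@voxels
  if (!is.logical(x)) x <- x != 0
  if (length(dim(x)) != 3L) stop(what, " must be a 3D volume")
  x
}

.checkSameGrid <- function(a, b, what = "volumes") {
  da <- if (is(a, "VolumeGrid")) dim(a@voxels) else dim(a)
  db <- if (is(b, "VolumeGrid")) dim(b@voxels) else dim(b)
  if (!identical(da[1:3], db[1:3]))
    stop("grid mismatch between ", what, ": ",
         paste(da[1:3], collapse = "x"), " vs ",
         paste(db[1:3], collapse = "x"))
  if (is(a, "VolumeGrid") && is(b, "VolumeGrid") &&
      !isTRUE(all.equal(a@spacing, b@spacing)))
    stop("spacing mismatch between ", what)
  invisible(TRUE)
}

#' Euclidean distance transform of a binary volume
#'
#' For every foreground voxel, the physical distance (mm) to the
#' nearest background voxel centre, computed with a separable
#' lower-envelope algorithm that respects anisotropic voxel spacing.
#' Background voxels get distance 0; if the volume contains no
#' background the result is `Inf` everywhere in the foreground.
#'
#' @param mask logical 3D array or [VolumeGrid-class].
#' @param spacing voxel spacing in mm (taken from the grid when `mask`
#'   is a `VolumeGrid`).
#' @return Numeric 3D array of distances in mm.
#' @export
distanceTransform <- function(mask, spacing = c(1, 1, 1)) {
  if (is(mask, "VolumeGrid")) spacing <- mask@spacing
  m <- .asMaskArray(mask)
  d2 <- .edt3dSq(as.vector(m), dim(m), as.numeric(spacing))
  array(sqrt(d2), dim(m))
}

## Medial axis as the ridge of the distance transform: a foreground
## voxel is on the skeleton if its distance value is >= that of all
## its 26 neighbours and strictly greater than at least one of them.
## Out-of-volume neighbours are ignored. Deterministic, and exact on
## the analytic fixtures (slabs, plates, rods: the ridge is the
## mid-plane/axis; spheres: the centre).
.dtRidge <- function(mask, dt) {
  d <- dim(dt)
  shift <- function(a, by, fill) {
    out <- array(fill, d)
    idx <- lapply(1:3, function(ax) {
      n <- d[ax]
      if (by[ax] == 0L) seq_len(n)
      else if (by[ax] == 1L) 2:n
      else 1:(n - 1)
    })
    src <- lapply(1:3, function(ax) {
      n <- d[ax]
      if (by[ax] == 0L) seq_len(n)
      else if (by[ax] == 1L) 1:(n - 1)
      else 2:n
    })
    out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  nbmax <- array(-Inf, d)
  nbmin <- array(Inf, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0L && dy == 0L && dz == 0L) next
    s <- shift(dt, c(dx, dy, dz), NA_real_)
    nbmax <- pmax(nbmax, s, na.rm = TRUE)
    nbmin <- pmin(nbmin, s, na.rm = TRUE)
  }
  mask & dt >= nbmax & nbmin < dt
}

#' Extract the medial axis (skeleton) of a binary volume
#'
#' Ridge voxels of the Euclidean distance transform; see
#' [distanceTransform()]. Used to sample local thickness as twice the
#' distance-transform value on the medial axis.
#'
#' @inheritParams distanceTransform
#' @return Logical 3D array marking skeleton voxels.
#' @export
medialAxis <- function(mask, spacing = c(1, 1, 1)) {
  if (is(mask, "VolumeGrid")) spacing <- mask@spacing
  m <- .asMaskArray(mask)
  dt <- distanceTransform(m, spacing)
  .dtRidge(m, dt)
}

## Mean of 2 x EDT over skeleton voxels of `phase`, optionally
## restricted to a VOI; the common core of all thickness measures.
## Anisotropic grids are resampled to the finest spacing first.
.phaseThickness <- function(phase, spacing, voi = NULL) {
  if (!any(phase)) stop("phase is empty: thickness undefined")
  iso <- min(spacing)
  if (max(abs(spacing - iso)) > 1e-9 * iso) {
    phase <- .resampleNearest(phase, spacing, iso)
    if (!is.null(voi)) voi <- .resampleNearest(voi, spacing, iso)
    spacing <- rep(iso, 3)
  }
  dt <- distanceTransform(phase, spacing)
  skel <- .dtRidge(phase, dt)
  if (!is.null(voi)) skel <- skel & voi
  if (!any(skel)) stop("no skeleton voxels inside the volume of interest")
  vals <- 2 * dt[skel]
  res <- mean(vals)
  attr(res, "nSkeleton") <- sum(skel)
  attr(res, "lowConfidence") <- max(dt[skel]) <= iso
  res
}

## Nearest-neighbour resampling of a 3D array to isotropic spacing.
.resampleNearest <- function(a, spacing, iso) {
  d <- dim(a)
  newd <- pmax(1L, as.integer(round(d * spacing / iso)))
  idx <- lapply(1:3, function(ax) {
    pmin(d[ax], pmax(1L, as.integer(ceiling((seq_len(newd[ax]) - 0.5) *
                                            d[ax] / newd[ax]))))
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Isotropic Gaussian smoothing of a 3D volume
#'
#' FFT-based circular convolution with an isotropic Gaussian point
#' spread function parameterised by its full width at half maximum in
#' mm (`sigma = fwhm / 2.3548`). Boundaries wrap around, which is exact
#' for the periodic phantom lattices this is used on.
#'
#' @param x numeric 3D array.
#' @param fwhm full width at half maximum, mm.
#' @param spacing voxel spacing, mm.
#' @return Smoothed numeric 3D array.
#' @export
gaussianBlur <- function(x, fwhm, spacing = c(1, 1, 1)) {
  if (fwhm <= 0) return(x)
  sigma <- fwhm / 2.3548
  d <- dim(x)
  k1 <- function(n, sp) {
    pos <- (seq_len(n) - 1)
    pos <- pmin(pos, n - pos) * sp   # wrap-around distance
    g <- exp(-pos^2 / (2 * sigma^2))
    g / sum(g)
  }
  kern <- outer(outer(k1(d[1], spacing[1]), k1(d[2], spacing[2])),
                k1(d[3], spacing[3]))
  dim(kern) <- d
  out <- Re(stats::fft(stats::fft(x) * stats::fft(kern), inverse = TRUE)) /
    prod(d)
  array(out, d)
}

#' Otsu threshold of the voxel values inside a region
#'
#' Global histogram threshold (256 bins) maximising the between-class
#' variance, computed over the supplied values only.
#'
#' @param values numeric vector of intensities.
#' @param nbins number of histogram bins.
#' @return The threshold; values strictly above it belong to the
#'   foreground class.
#' @export
otsuThreshold <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0)
    stop("constant image in region: no threshold exists")
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(values, br, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  br[which.max(sb) + 1L]
}
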