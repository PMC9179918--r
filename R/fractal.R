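## Box-counting fractal dimension of binary structures.
##
## Box-size ladder: divisors of the smallest grid dimension, capped at
## half that dimension (so every axis is covered by at least two
## boxes). Divisor sizes tile the leading axis exactly, which keeps
## the counts free of ragged-edge bias; a power-of-two ladder on grids
## whose natural self-similarity is not dyadic (e.g. base-3 test
## fractals) systematically flattens the log-log slope. When more
## than 5 sizes are available the two largest are excluded from the
## fit (large boxes saturate); fewer than 3 usable sizes is an error.

.boxSizes <- function(minDim) {
  s <- seq_len(minDim %/% 2L)
  s <- s[minDim %% s == 0L]
  if (length(s) > 5L) s <- s[seq_len(length(s) - 2L)]
  if (length(s) < 3L)
    stop("structure spans fewer than 3 usable box scales (min dim ",
         minDim, ")")
  s
}

## count boxes of edge `s` (voxels) containing any TRUE voxel;
## `coords` are 0-based voxel coordinates (matrix, one row per voxel).
.boxCount <- function(coords, s) {
  b <- coords %/% s
  if (ncol(b) == 2L) {
    key <- b[, 1] + (max(b[, 1]) + 1) * b[, 2]
  } else {
    key <- b[, 1] + (max(b[, 1]) + 1) *
      (b[, 2] + (max(b[, 2]) + 1) * b[, 3])
  }
  length(unique(key))
}

.boxDimension <- function(mask) {
  coords <- which(mask, arr.ind = TRUE) - 1L
  if (nrow(coords) == 0L) stop("empty structure")
  sizes <- .boxSizes(min(dim(mask)))
  n <- vapply(sizes, function(s) .boxCount(coords, s), numeric(1))
  x <- log(sizes)
  y <- log(n)
  -stats::cov(x, y) / stats::var(x)      # OLS slope of log N vs log eps
}

## boundary voxels: structure voxels with at least one
## face-neighbour outside the structure (or on the grid border).
.boundaryVoxels <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  interior <- array(TRUE, d)
  for (ax in seq_len(nd)) {
    n <- d[ax]
    ## face neighbours; the grid border counts as outside
    lo <- array(FALSE, d); hi <- array(FALSE, d)
    idx <- lapply(d, seq_len); src <- idx
    idx[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1)
    if (nd == 2L) lo[idx[[1]], idx[[2]]] <- mask[src[[1]], src[[2]]]
    else lo[idx[[1]], idx[[2]], idx[[3]]] <-
        mask[src[[1]], src[[2]], src[[3]]]
    idx <- lapply(d, seq_len); src <- idx
    idx[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n
    if (nd == 2L) hi[idx[[1]], idx[[2]]] <- mask[src[[1]], src[[2]]]
    else hi[idx[[1]], idx[[2]], idx[[3]]] <-
        mask[src[[1]], src[[2]], src[[3]]]
    interior <- interior & lo & hi
  }
  mask & !interior
}

#' 3D box-counting fractal dimension (D3D)
#'
#' Counts, for each box edge size of the ladder (see Details), the
#' number of boxes containing structure voxels; the dimension is minus
#' the ordinary-least-squares slope of `log N` against `log size`. In
#' `"area"` mode (the default, the usual convention for trabecular
#' architecture) the structure voxel set itself is counted; `"boundary"`
#' mode counts only surface voxels.
#'
#' @details Box sizes are the divisors of the smallest grid dimension
#'   up to half of it; with more than 5 sizes the two largest are
#'   excluded. A structure spanning fewer than 3 usable sizes raises
#'   an error.
#'
#' @param binary logical [VolumeGrid-class]/array.
#' @param mode `"area"` or `"boundary"`.
#' @return The fractal dimension (unitless, <= 3 up to fit tolerance).
#' @export
fractalDimension3D <- function(binary, mode = c("area", "boundary")) {
  mode <- match.arg(mode)
  m <- .asMaskArray(binary, "binary")
  if (!any(m)) stop("empty structure")
  if (mode == "boundary") m <- .boundaryVoxels(m)
  .boxDimension(m)
}

#' Mean per-slice 2D box-counting fractal dimension (D2D)
#'
#' Applies 2D box counting to every slice along the stated axis that
#' contains structure voxels and averages the per-slice dimensions.
#'
#' @param binary logical [VolumeGrid-class]/array.
#' @param axis slice axis (1, 2 or 3).
#' @param mode `"area"` or `"boundary"`, as in
#'   [fractalDimension3D()].
#' @return Mean slice dimension (unitless, <= 2 up to fit tolerance).
#' @export
fractalDimension2D <- function(binary, axis = 3L,
                               mode = c("area", "boundary")) {
  mode <- match.arg(mode)
  m <- .asMaskArray(binary, "binary")
  if (!any(m)) stop("empty structure")
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)
  nslice <- dim(m)[axis]
  dims <- rep(NA_real_, nslice)
  for (k in seq_len(nslice)) {
    sl <- switch(axis, m[k, , ], m[, k, ], m[, , k])
    if (!any(sl)) next
    if (mode == "boundary") sl <- .boundaryVoxels(sl)
    dims[k] <- .boxDimension(sl)
  }
  if (all(is.na(dims))) stop("no slice contains structure")
  mean(dims, na.rm = TRUE)
}
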