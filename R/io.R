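## NIfTI and tabular I/O. Volumes travel as NIfTI files with the voxel
## spacing in the header; acquisition parameters that NIfTI headers
## cannot hold (TR, flip-angle and echo-time lists) live in a JSON
## sidecar next to each volume, with BIDS-flavoured key names.

.sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a volume as NIfTI with a JSON sidecar
#'
#' The voxel array and spacing go into the NIfTI file; `meta` (plus
#' the axis tags and spacing) is serialised to `<path>.json`. The
#' round trip preserves voxel data bit-exactly and spacing to within
#' header precision.
#'
#' @param grid a [VolumeGrid-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param meta named list of acquisition parameters, e.g.
#'   `RepetitionTime` (ms), `FlipAngles` (deg), `EchoTimes` (ms).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(grid, path, meta = list()) {
  stopifnot(is(grid, "VolumeGrid"))
  v <- grid@voxels
  if (is.logical(v)) v <- array(as.integer(v), dim(v))
  attr(v, "pixdim") <- grid@spacing
  RNifti::writeNifti(RNifti::asNifti(v), path)
  meta$VoxelSpacing <- grid@spacing
  meta$AxisTags <- grid@axes
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume and its sidecar
#'
#' @param path NIfTI file path.
#' @return A [VolumeGrid-class]; the parsed sidecar (if present) is
#'   attached as attribute `"meta"`.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("malformed NIfTI header: pixdim must be positive in ", path)
  a <- array(as.vector(img), dim(img)[1:3])
  grid <- VolumeGrid(a, sp)
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$AxisTags) && length(meta$AxisTags) == 3L)
      grid@axes <- as.character(meta$AxisTags)
    attr(grid, "meta") <- meta
  }
  grid
}

#' Read a relaxometry series (4D NIfTI + sidecar)
#'
#' The sidecar must provide `RepetitionTime` and `FlipAngles` for a
#' VFA stack, or `EchoTimes` for a multi-echo stack; a missing or
#' incomplete sidecar is an error naming the missing fields, never an
#' assumed value.
#'
#' @param path 4D NIfTI file path.
#' @return A [RelaxometrySeries-class].
#' @export
readRelaxometrySeries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D volume stack in ", path)
  sp <- RNifti::pixdim(img)[1:3]
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    stop("missing sidecar ", sc, ": RepetitionTime + FlipAngles ",
         "(VFA) or EchoTimes (multi-echo) are required")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  sig <- array(as.vector(img), d)
  if (!is.null(meta$FlipAngles)) {
    if (is.null(meta$RepetitionTime))
      stop("sidecar ", sc, " has FlipAngles but no RepetitionTime (ms)")
    vfaSeries(sig, meta$FlipAngles, meta$RepetitionTime, sp)
  } else if (!is.null(meta$EchoTimes)) {
    multiechoSeries(sig, meta$EchoTimes, sp)
  } else {
    stop("sidecar ", sc, " provides neither FlipAngles (+RepetitionTime) ",
         "nor EchoTimes")
  }
}

#' Write a relaxometry series (4D NIfTI + sidecar)
#'
#' @param series a [RelaxometrySeries-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRelaxometrySeries <- function(series, path) {
  stopifnot(is(series, "RelaxometrySeries"))
  sig <- series@signals
  attr(sig, "pixdim") <- c(series@spacing, 1)
  RNifti::writeNifti(RNifti::asNifti(sig), path)
  meta <- list(VoxelSpacing = series@spacing, AxisTags = series@axes)
  if (series@kind == "VFA") {
    meta$RepetitionTime <- series@tr
    meta$FlipAngles <- series@flipAngles
  } else {
    meta$EchoTimes <- series@echoTimes
  }
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write score-record tables
#'
#' CSV with columns `subject_id`, `group`, `time_days`, `variable`,
#' `value` (one observation per row).
#'
#' @param path CSV file path.
#' @return `readScoreRecords`: the records data.frame.
#' @export
readScoreRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "time_days", "variable", "value")
  missing <- setdiff(need, names(rec))
  if (length(missing))
    stop("score table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  rec
}

#' @rdname readScoreRecords
#' @param records score-record data.frame.
#' @export
writeScoreRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Synovial fluid hyaluronic acid concentrations (study fixture)
#'
#' The packaged hyaluronic-acid concentration table (ng/mL) by
#' treatment group and survival time, for exercising the descriptive
#' and robust-ANOVA operations on measured (non-simulated) values.
#'
#' @return data.frame with columns `group`, `time_days`,
#'   `ha_ng_ml`.
#' @export
haSynovialFluid <- function() {
  path <- system.file("extdata", "ha_synovial_fluid_ng_ml.csv",
                      package = "jointQMRI", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
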