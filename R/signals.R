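#' Wrap a 4D BOLD array with its grid
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param grid A `grid_spec` matching the first three dimensions.
#' @param tr Repetition time in seconds.
#' @return A `bold4d` object.
#' @export
bold4d <- function(data, grid, tr = 2) {
  if (length(dim(data)) != 4L) stop("data must be a 4D array (x, y, z, t)")
  if (!inherits(grid, "grid_spec")) stop("grid must be a grid_spec")
  if (!identical(as.integer(dim(data)[1:3]), grid$shape))
    stop("data spatial dimensions do not match grid shape")
  if (dim(data)[4] < 3L) stop("need at least 3 frames")
  structure(list(data = data, grid = grid, tr = tr), class = "bold4d")
}

#' Read a 4D NIfTI volume
#'
#' The grid affine is taken from the image xform (sform/qform as resolved by
#' RNifti), mapping 0-based voxel indices to world mm.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param tr Repetition time in seconds; if `NULL`, taken from the header
#'   (`pixdim[4]`).
#' @return A `bold4d`.
#' @export
read_bold <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4L) stop("expected a 4D volume, got ", length(dm), "D")
  affine <- structure(RNifti::xform(img), class = NULL)
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    tr <- if (length(pd) >= 4) pd[4] else NA_real_
  }
  bold4d(array(as.numeric(img), dim = dm), grid_spec(dm[1:3], affine), tr = tr)
}

#' @export
print.bold4d <- function(x, ...) {
  cat("bold4d:", paste(dim(x$data)[1:3], collapse = " x "), "voxels,",
      dim(x$data)[4], "frames, TR =", x$tr, "s\n")
  invisible(x)
}

#' Extract per-ROI mean time courses
#'
#' For each ROI, averages the BOLD signal over all voxels of its sphere mask
#' at every frame, producing the frames x ROIs matrix that feeds the
#' correlation step.
#'
#' @param bold A `bold4d` whose grid was used to build the masks.
#' @param atlas A `roi_atlas`.
#' @return A `roi_timeseries`: numeric T x R matrix with ROI labels as
#'   column names and attributes `tr` and `subject_id`.
#' @export
extract_timeseries <- function(bold, atlas) {
  stopifnot(inherits(bold, "bold4d"), inherits(atlas, "roi_atlas"))
  dm <- dim(bold$data)
  nvox <- prod(dm[1:3])
  nt <- dm[4]
  flat <- bold$data
  dim(flat) <- c(nvox, nt)
  out <- matrix(NA_real_, nrow = nt, ncol = nrow(atlas),
                dimnames = list(NULL, atlas$label))
  for (r in seq_len(nrow(atlas))) {
    m <- sphere_mask(atlas[r, ], bold$grid)
    lin <- m[, 1] + (m[, 2] - 1L) * dm[1] + (m[, 3] - 1L) * (dm[1] * dm[2])
    vals <- flat[lin, , drop = FALSE]
    if (!all(is.finite(vals)))
      stop("non-finite voxel value inside mask of ROI '", atlas$label[r], "'")
    out[, r] <- colMeans(vals)
  }
  roi_timeseries(out, tr = bold$tr)
}

#' Construct a per-subject ROI time-series table
#'
#' @param values Numeric T x R matrix (frames x ROIs, atlas column order),
#'   with ROI labels as column names.
#' @param tr Repetition time, seconds.
#' @param subject_id Optional subject identifier.
#' @return A `roi_timeseries` matrix.
#' @export
roi_timeseries <- function(values, tr = 2, subject_id = NA_character_) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("time series must be finite")
  structure(values, tr = tr, subject_id = subject_id,
            class = c("roi_timeseries", "matrix", "array"))
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("roi_timeseries:", nrow(x), "frames x", ncol(x), "ROIs",
      if (!is.na(attr(x, "subject_id")))
        paste0("(subject ", attr(x, "subject_id"), ")"), "\n")
  invisible(x)
}

#' Write / read an ROI time-series table as TSV
#'
#' Full-precision round trip: values are written with 17 significant digits.
#'
#' @param ts A `roi_timeseries`.
#' @param path Output path.
#' @return `write_timeseries`: the path, invisibly. `read_timeseries`: a
#'   `roi_timeseries`.
#' @export
write_timeseries <- function(ts, path) {
  df <- as.data.frame(unclass(ts))
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param tr,subject_id Passed to [roi_timeseries()].
#' @export
read_timeseries <- function(path, tr = 2, subject_id = NA_character_) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  roi_timeseries(as.matrix(df), tr = tr, subject_id = subject_id)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement (FD): backward differences of the six
#' realignment parameters, rotations converted to arc length on a sphere of
#' `head_radius` mm, summed in absolute value. The first frame has FD 0.
#'
#' @param motion T x 6 numeric matrix or data frame: three translations (mm)
#'   then three rotations (radians), one row per frame.
#' @param head_radius Head radius in mm used to convert rotations to mm
#'   (default 50).
#' @return Numeric vector of length T (mm).
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  if (nrow(motion) < 2L) stop("need at least 2 frames for FD")
  if (!all(is.finite(motion))) stop("motion parameters must be finite")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Mean framewise displacement
#'
#' Arithmetic mean over all frames, including the leading zero of frame 1 —
#' the per-subject motion covariate.
#'
#' @param fd Numeric FD series from [framewise_displacement()].
#' @return Scalar mean FD in mm.
#' @export
mean_fd <- function(fd) {
  if (length(fd) == 0L) stop("empty FD series")
  if (!all(is.finite(fd))) stop("FD series must be finite")
  mean(fd)
}

#' Read a motion-parameter file
#'
#' Whitespace- or tab-separated text, six columns (3 translations in mm,
#' 3 rotations in radians), one row per frame, no header.
#'
#' @param path File path.
#' @return T x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("motion file must have 6 columns")
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  m
}
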