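#' ROI-to-ROI Pearson correlation matrix
#'
#' Correlates every pair of ROI mean time courses, giving the per-subject
#' connectivity matrix whose cells are then Fisher z-transformed.
#'
#' @param ts A `roi_timeseries` (frames x ROIs) with at least 3 frames.
#' @return Symmetric R x R correlation matrix, unit diagonal, ROI labels as
#'   dimnames.
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 frames to correlate")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance ROI time course: ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(ts)
  r <- (r + t(r)) / 2      # enforce exact symmetry
  diag(r) <- 1
  r
}

#' Fisher's r-to-z transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform applied to every correlation before averaging. For a square
#' matrix with unit diagonal the diagonal is returned as `NA` (a
#' self-correlation has no finite z and never enters a block mean).
#'
#' @param r Correlation scalar, vector or matrix with `|r| < 1` off the
#'   diagonal.
#' @param clamp If `TRUE`, values with `|r| >= 1` are clamped to
#'   `+/-(1 - 1e-7)` with a warning instead of raising an error.
#' @return z values, same shape as `r`.
#' @export
fisher_z <- function(r, clamp = FALSE) {
  is_sq <- is.matrix(r) && nrow(r) == ncol(r)
  check <- r
  if (is_sq) diag(check) <- 0
  if (any(!is.finite(check))) stop("correlations must be finite")
  if (any(abs(check) >= 1)) {
    if (!clamp)
      stop("|r| >= 1 encountered; degenerate correlation ",
           "(set clamp = TRUE to map to +/-(1 - 1e-7))")
    warning("clamping ", sum(abs(check) >= 1), " correlation(s) with |r| >= 1")
    r[r >= 1] <- 1 - 1e-7
    r[r <= -1] <- -(1 - 1e-7)
  }
  z <- atanh(r)
  if (is_sq) diag(z) <- NA_real_
  z
}

#' Six within/between-network connectivity metrics
#'
#' Reduces a Fisher-z matrix to one scalar per block: the mean z over all
#' unordered ROI pairs within each network, and over all cross pairs for
#' each network pair. Diagonal (self) entries are never included. Averaging
#' each ROI's intra-network z values first and then across ROIs gives the
#' same number, since every unordered pair appears in exactly two ROI-wise
#' averages.
#'
#' @param z R x R Fisher-z matrix (diagonal ignored).
#' @param pairs A `pair_index` from [block_index()].
#' @return Named numeric vector of length 6 (`within_CON`, `within_DMN`,
#'   `within_OST`, `between_OST_CON`, `between_OST_DMN`, `between_CON_DMN`).
#' @export
network_metrics <- function(z, pairs) {
  stopifnot(inherits(pairs, "pair_index"))
  block_mean <- function(idx, what) {
    v <- z[idx]
    if (any(!is.finite(v)))
      stop("non-finite z value in block ", what)
    mean(v)
  }
  res <- c(
    within_CON = block_mean(pairs$within$CON, "within_CON"),
    within_DMN = block_mean(pairs$within$DMN, "within_DMN"),
    within_OST = block_mean(pairs$within$OST, "within_OST"),
    between_OST_CON = block_mean(pairs$between$OST_CON, "between_OST_CON"),
    between_OST_DMN = block_mean(pairs$between$OST_DMN, "between_OST_DMN"),
    between_CON_DMN = block_mean(pairs$between$CON_DMN, "between_CON_DMN")
  )
  res[FCNET_METRICS]
}

#' Per-subject connectivity: correlation, Fisher z, block means
#'
#' Convenience wrapper running [correlation_matrix()], [fisher_z()] and
#' [network_metrics()] for one subject.
#'
#' @param ts A `roi_timeseries`.
#' @param atlas The `roi_atlas` defining column order and networks.
#' @param clamp Passed to [fisher_z()].
#' @return A `connectivity` object: list with `r`, `z` (matrices) and
#'   `metrics` (named 6-vector).
#' @export
connectivity <- function(ts, atlas, clamp = FALSE) {
  r <- correlation_matrix(ts)
  z <- fisher_z(r, clamp = clamp)
  m <- network_metrics(z, block_index(atlas))
  structure(list(r = r, z = z, metrics = m), class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat("connectivity:", nrow(x$r), "x", ncol(x$r), "ROI matrix\n")
  print(round(x$metrics, 4))
  invisible(x)
}

#' Write a connectivity matrix as TSV
#'
#' @param mat Square matrix with ROI-label dimnames (`r` or `z` variant).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_connectivity <- function(mat, path) {
  df <- data.frame(ROI = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
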