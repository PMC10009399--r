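#' @keywords internal
"_PACKAGE"

## The three resting-state networks analysed throughout the package.
FCNET_NETWORKS <- c("CON", "DMN", "OST")

## Fixed order of the six connectivity metrics (three within-network block
## means, three between-network block means).
FCNET_METRICS <- c("within_CON", "within_DMN", "within_OST",
                   "between_OST_CON", "between_OST_DMN", "between_CON_DMN")

#' Read a seed-sphere ROI atlas from a tab-separated file
#'
#' The atlas file must have a header with columns `label`, `network`, `x`,
#' `y`, `z` (MNI world coordinates in mm) and optionally `radius` (mm).
#' Networks must be one of `CON`, `DMN`, `OST` and each network needs at
#' least two ROIs so that within-network block means are defined over at
#' least one pair. Row order is preserved and fixes the row/column order of
#' every connectivity matrix downstream.
#'
#' @param path Path to a TSV file. Lines starting with `#` are ignored.
#' @param default_radius Sphere radius in mm applied where the file has no
#'   `radius` column (default 5).
#' @return A `roi_atlas`: a data frame with columns `label`, `network`,
#'   `x`, `y`, `z`, `radius`.
#' @seealso [default_atlas()], [sphere_mask()], [block_index()]
#' @export
read_atlas <- function(path, default_radius = 5) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  as_atlas(df, default_radius = default_radius)
}

#' Construct and validate an ROI atlas from a data frame
#'
#' @param df Data frame with columns `label`, `network`, `x`, `y`, `z` and
#'   optionally `radius`.
#' @param default_radius Radius (mm) used where `radius` is absent or `NA`.
#' @return A validated `roi_atlas` data frame.
#' @export
as_atlas <- function(df, default_radius = 5) {
  if (nrow(df) == 0L)
    stop("no ROIs: atlas is empty")
  need <- c("label", "network", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("atlas is missing column(s): ", paste(missing_cols, collapse = ", "))
  df$label <- as.character(df$label)
  if (anyDuplicated(df$label))
    stop("duplicate ROI label(s): ",
         paste(unique(df$label[duplicated(df$label)]), collapse = ", "))
  df$network <- as.character(df$network)
  bad <- setdiff(unique(df$network), FCNET_NETWORKS)
  if (length(bad))
    stop("unknown network token(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(FCNET_NETWORKS, collapse = ", "), ")")
  for (cc in c("x", "y", "z")) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(df[[cc]]))
      stop("non-numeric coordinate in column '", cc, "'")
  }
  if (is.null(df$radius)) df$radius <- default_radius
  df$radius <- suppressWarnings(as.numeric(df$radius))
  df$radius[is.na(df$radius)] <- default_radius
  if (any(df$radius <= 0))
    stop("ROI radius must be positive")
  counts <- table(factor(df$network, levels = FCNET_NETWORKS))
  if (any(counts < 2L))
    stop("each network needs at least 2 ROIs; too few in: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  rownames(df) <- NULL
  structure(df[c("label", "network", "x", "y", "z", "radius")],
            class = c("roi_atlas", "data.frame"))
}

#' The package's shipped synthetic ROI atlas
#'
#' A synthetic reconstruction of a three-network seed set: cingulo-opercular
#' (dorsal ACC, pre-SMA, SMA, frontal operculum, anterior insula), default
#' mode (PCC, precuneus, medial frontal pole and gyrus, angular gyrus,
#' medial temporal lobe) and orbitofrontal-striatal-thalamic (OFC, dorsal
#' caudate, dorsal-caudal putamen, thalamus) nodes at standard literature
#' MNI coordinates, 5-mm radius spheres. Intended for simulation and as a
#' worked-example seed set; it is not a transcription of any study's table.
#'
#' @return A `roi_atlas`.
#' @export
default_atlas <- function() {
  read_atlas(system.file("extdata", "atlas_synthetic.tsv", package = "fcnet"))
}

#' @export
print.roi_atlas <- function(x, ...) {
  counts <- table(factor(x$network, levels = FCNET_NETWORKS))
  cat("ROI atlas:", nrow(x), "seed spheres (",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Define a sampling grid
#'
#' A grid is a voxel lattice plus a 4x4 affine mapping 0-based voxel indices
#' `(i, j, k)` to world coordinates in mm (the NIfTI convention). R-side
#' array indices are 1-based; all functions in this package convert
#' internally.
#'
#' @param shape Integer 3-vector of grid dimensions (voxels).
#' @param affine 4x4 numeric matrix, invertible, voxel-index to world mm.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps)
    stop("affine must be invertible")
  structure(list(shape = shape, affine = affine), class = "grid_spec")
}

#' A simple axis-aligned MNI-style grid
#'
#' Convenience constructor for an isotropic grid whose voxel centers lie at
#' `origin + voxelsize * index` along each world axis.
#'
#' @param shape Integer 3-vector (voxels per axis).
#' @param voxel_size Isotropic voxel size in mm (default 2).
#' @param origin World coordinate (mm) of voxel (0, 0, 0).
#' @return A `grid_spec`.
#' @export
iso_grid <- function(shape, voxel_size = 2,
                     origin = -voxel_size * (as.integer(shape) - 1L) / 2) {
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- origin
  grid_spec(shape, affine)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("grid:", paste(x$shape, collapse = " x "), "voxels\n")
  cat("affine (voxel -> mm):\n")
  print(x$affine)
  invisible(x)
}

#' Voxel mask of a spherical ROI
#'
#' A voxel belongs to the sphere iff the Euclidean distance from its center's
#' world coordinate to the ROI center is at most the ROI radius
#' (voxel-center inclusion, not any-overlap).
#'
#' @param roi A single-row `roi_atlas` slice, or a list/one-row data frame
#'   with numeric `x`, `y`, `z` and optionally `radius` and `label`.
#' @param grid A `grid_spec`.
#' @return An n x 3 integer matrix of 1-based array indices (i, j, k), one
#'   row per voxel inside the sphere.
#' @export
sphere_mask <- function(roi, grid) {
  if (!inherits(grid, "grid_spec")) stop("grid must be a grid_spec")
  center <- as.numeric(c(roi$x, roi$y, roi$z))
  if (length(center) != 3L || anyNA(center))
    stop("ROI center must be a numeric 3-vector")
  radius <- if (is.null(roi$radius)) 5 else as.numeric(roi$radius)
  label <- if (is.null(roi$label)) "<unnamed>" else as.character(roi$label)
  inv <- solve(grid$affine)
  vc <- (inv %*% c(center, 1))[1:3]      # 0-based voxel coordinate of center
  # conservative bounding box using per-axis world step lengths
  step <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  lo <- pmax(0L, as.integer(floor(vc - radius / step - 1)))
  hi <- pmin(grid$shape - 1L, as.integer(ceiling(vc + radius / step + 1)))
  if (any(lo > hi))
    stop("sphere mask for ROI '", label, "' is empty (outside grid)")
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  world <- cand %*% t(grid$affine[1:3, 1:3])
  world <- sweep(world, 2, grid$affine[1:3, 4], "+")
  d2 <- (world[, 1] - center[1])^2 + (world[, 2] - center[2])^2 +
    (world[, 3] - center[3])^2
  keep <- d2 <= radius^2 + 1e-9
  if (!any(keep))
    stop("sphere mask for ROI '", label, "' is empty (outside grid)")
  mask <- cand[keep, , drop = FALSE] + 1L   # to 1-based array indices
  storage.mode(mask) <- "integer"
  dimnames(mask) <- list(NULL, c("i", "j", "k"))
  mask
}

#' Enumerate within- and between-network ROI pair sets
#'
#' Builds the index sets over which the six connectivity metrics average:
#' for each network the unordered pairs of its ROIs (self-pairs excluded),
#' and for each unordered network pair every cross pair, each counted once.
#'
#' @param atlas A `roi_atlas`.
#' @return A `pair_index`: list with elements `within` (named list of
#'   m x 2 index matrices, one per network) and `between` (named list, one
#'   per network pair, names `OST_CON`, `OST_DMN`, `CON_DMN`).
#' @export
block_index <- function(atlas) {
  stopifnot(inherits(atlas, "roi_atlas"))
  idx <- split(seq_len(nrow(atlas)), factor(atlas$network, FCNET_NETWORKS))
  within <- lapply(idx, function(ii) {
    t(utils::combn(ii, 2L))
  })
  pair_names <- list(c("OST", "CON"), c("OST", "DMN"), c("CON", "DMN"))
  between <- lapply(pair_names, function(nm) {
    as.matrix(expand.grid(idx[[nm[1]]], idx[[nm[2]]], KEEP.OUT.ATTRS = FALSE))
  })
  names(between) <- vapply(pair_names, paste, "", collapse = "_")
  between <- lapply(between, function(m) {
    dimnames(m) <- list(NULL, NULL); storage.mode(m) <- "integer"; m
  })
  within <- lapply(within, function(m) {
    dimnames(m) <- list(NULL, NULL); storage.mode(m) <- "integer"; m
  })
  structure(list(within = within, between = between), class = "pair_index")
}

#' Write the union of all ROI sphere masks as a NIfTI label volume
#'
#' Each voxel carries the 1-based index of the ROI covering it (ties: the
#' last ROI in atlas order wins); for inspection in standard viewers.
#'
#' @param atlas A `roi_atlas`.
#' @param grid A `grid_spec`.
#' @param path Output `.nii` or `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_atlas_mask <- function(atlas, grid, path) {
  vol <- array(0L, dim = grid$shape)
  for (r in seq_len(nrow(atlas))) {
    m <- sphere_mask(atlas[r, ], grid)
    vol[m] <- r
  }
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
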