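#' Default per-group block-mean targets (Fisher z)
#'
#' Three-row matrix (OCD, AC, HC) by six metrics used as the simulator's
#' ground truth. The within-CON and OST-CON rows reproduce the group
#' contrast pattern the package is designed to detect (OCD elevated over AC
#' and HC); the remaining four metrics are group-constant, emulating null
#' effects.
#'
#' @return 3 x 6 numeric matrix, rownames `OCD`, `AC`, `HC`, colnames the
#'   six metric names.
#' @export
default_block_targets <- function() {
  m <- rbind(
    OCD = c(0.54, 0.45, 0.50, 0.40, 0.15, 0.10),
    AC  = c(0.43, 0.45, 0.50, 0.30, 0.15, 0.10),
    HC  = c(0.46, 0.45, 0.50, 0.33, 0.15, 0.10)
  )
  colnames(m) <- FCNET_METRICS
  m
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator. Defaults emulate
#' the study design the package targets: three all-female groups of
#' 23/26/44 (OCD, anxiety control, healthy control), ages 8-21, block
#' z-targets from [default_block_targets()], log-normal mean framewise
#' displacement, C/Y-BOCS severity (mean 23.03, SD 6.41) for the OCD group
#' only, MASC for all groups with some missingness.
#'
#' @param group_sizes Named integer 3-vector (default `c(OCD = 23, AC = 26,
#'   HC = 44)`).
#' @param n_frames Frames per subject (default 200).
#' @param tr Repetition time in seconds (default 2).
#' @param block_targets 3 x 6 matrix of per-group Fisher-z block means
#'   (rows must match `names(group_sizes)`).
#' @param subject_sd_shared Between-subject SD (z-units) of a global
#'   coupling offset added to all six of a subject's block targets
#'   (default 0.08).
#' @param subject_sd_block Between-subject SD (z-units) of block-specific
#'   jitter added independently per block (default 0.05).
#' @param age_range Uniform age range in years (default `c(8, 21)`).
#' @param fd_meanlog,fd_sdlog Log-normal parameters of per-subject mean FD
#'   in mm (defaults `log(0.12)` and 0.4).
#' @param cybocs_mean,cybocs_sd Severity score distribution, first group
#'   only (defaults 23.03 and 6.41).
#' @param masc_mean Named per-group MASC means (default 55/55/40).
#' @param masc_sd MASC SD (default 15).
#' @param masc_missing_rate Probability a subject's MASC is missing
#'   (default 11/93).
#' @param depress_prob Named per-group probability of a co-morbid
#'   depressive-disorder flag (default 0.15/0.20/0).
#' @param ar1 Lag-1 autocorrelation of the latent signals (default 0,
#'   stationary white multivariate normal).
#' @param psd_tolerance Maximum allowed elementwise deviation from the
#'   block targets after positive-semidefinite repair (default 0.05).
#' @param seed Master seed; every random draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(group_sizes = c(OCD = 23, AC = 26, HC = 44),
                       n_frames = 200, tr = 2,
                       block_targets = default_block_targets(),
                       subject_sd_shared = 0.08, subject_sd_block = 0.05,
                       age_range = c(8, 21),
                       fd_meanlog = log(0.12), fd_sdlog = 0.4,
                       cybocs_mean = 23.03, cybocs_sd = 6.41,
                       masc_mean = c(OCD = 55, AC = 55, HC = 40),
                       masc_sd = 15, masc_missing_rate = 11 / 93,
                       depress_prob = c(OCD = 0.15, AC = 0.20, HC = 0),
                       ar1 = 0, psd_tolerance = 0.05, seed = 1L) {
  if (length(group_sizes) != 3L || any(group_sizes < 2L))
    stop("need 3 groups with at least 2 subjects each")
  if (is.null(names(group_sizes))) names(group_sizes) <- c("OCD", "AC", "HC")
  if (n_frames < 10L) stop("n_frames must be at least 10")
  block_targets <- as.matrix(block_targets)
  if (!identical(colnames(block_targets), FCNET_METRICS))
    stop("block_targets columns must be the six metric names in order")
  if (!all(rownames(block_targets) %in% names(group_sizes)))
    stop("block_targets rows must match group names")
  if (any(abs(tanh(block_targets)) >= 1)) stop("block targets out of range")
  structure(list(group_sizes = group_sizes, n_frames = as.integer(n_frames),
                 tr = tr, block_targets = block_targets,
                 subject_sd_shared = subject_sd_shared,
                 subject_sd_block = subject_sd_block, age_range = age_range,
                 fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog,
                 cybocs_mean = cybocs_mean, cybocs_sd = cybocs_sd,
                 masc_mean = masc_mean, masc_sd = masc_sd,
                 masc_missing_rate = masc_missing_rate,
                 depress_prob = depress_prob, ar1 = ar1,
                 psd_tolerance = psd_tolerance, seed = as.integer(seed)),
            class = "sim_config")
}

## Evaluate expr under a temporary RNG state; the global .Random.seed is
## restored afterwards so no hidden state leaks between calls.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Block-structured correlation matrix from z-targets
#'
#' Builds the R x R correlation matrix whose within-network off-diagonals
#' equal `tanh(z_within)` and cross-network entries `tanh(z_between)`,
#' diagonal 1. If the result is not positive semidefinite it is repaired by
#' clipping eigenvalues at a small floor and re-normalizing to unit
#' diagonal; the maximum elementwise deviation from the targets is attached
#' and must not exceed `psd_tolerance`.
#'
#' @param targets Named numeric 6-vector of Fisher-z block means (names the
#'   six metric names).
#' @param networks Character vector of per-ROI network labels (length R,
#'   values in `CON`, `DMN`, `OST`), fixing matrix order.
#' @param psd_tolerance Maximum allowed post-repair deviation (default
#'   0.05).
#' @param eig_floor Eigenvalue clipping floor (default 1e-6).
#' @return Correlation matrix with attributes `deviation` (max elementwise
#'   absolute deviation from targets) and `repaired` (logical).
#' @export
build_block_correlation <- function(targets, networks, psd_tolerance = 0.05,
                                    eig_floor = 1e-6) {
  targets <- targets[FCNET_METRICS]
  if (anyNA(targets)) stop("targets must be named with the six metric names")
  if (any(abs(tanh(targets)) >= 1)) stop("|tanh(target)| must be < 1")
  stopifnot(all(networks %in% FCNET_NETWORKS))
  R <- length(networks)
  block_of <- function(a, b) {
    if (a == b) paste0("within_", a)
    else {
      key <- paste(sort(c(a, b)), collapse = "_")
      switch(key, CON_OST = "between_OST_CON", DMN_OST = "between_OST_DMN",
             CON_DMN = "between_CON_DMN")
    }
  }
  r <- diag(R)
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    v <- tanh(targets[[block_of(networks[i], networks[j])]])
    r[i, j] <- r[j, i] <- v
  }
  target_r <- r
  ev <- eigen(r, symmetric = TRUE)
  repaired <- FALSE
  if (min(ev$values) < eig_floor) {
    repaired <- TRUE
    vals <- pmax(ev$values, eig_floor)
    r <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(r))
    r <- r / outer(d, d)
    r <- (r + t(r)) / 2
    diag(r) <- 1
  }
  deviation <- max(abs(r - target_r))
  if (deviation > psd_tolerance)
    stop(sprintf("PSD repair deviates %.4f from targets (> %.4f tolerance)",
                 deviation, psd_tolerance))
  structure(r, deviation = deviation, repaired = repaired)
}

#' Simulate one subject's ROI time series
#'
#' `n_frames` draws from a zero-mean multivariate normal with the given
#' correlation matrix, via its symmetric eigen square root; optionally with
#' AR(1) temporal autocorrelation in the latent innovations. Deterministic
#' for a fixed seed.
#'
#' @param corr Positive-semidefinite correlation matrix (R x R).
#' @param n_frames Number of frames T.
#' @param seed Integer seed.
#' @param tr Repetition time, seconds.
#' @param ar1 Lag-1 autocorrelation coefficient in `[0, 1)` (default 0).
#' @param subject_id Optional id attached to the result.
#' @param labels Optional ROI labels for the columns.
#' @return A `roi_timeseries` (T x R).
#' @export
simulate_subject <- function(corr, n_frames, seed, tr = 2, ar1 = 0,
                             subject_id = NA_character_, labels = NULL) {
  corr <- as.matrix(corr)
  R <- ncol(corr)
  ev <- eigen(corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("correlation matrix is not PSD")
  A <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  x <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_frames * R), n_frames, R)
    if (ar1 > 0) {
      z <- apply(z, 2, function(col) {
        as.numeric(stats::filter(col, ar1, method = "recursive")) *
          sqrt(1 - ar1^2)
      })
    }
    z %*% A
  })
  if (!is.null(labels)) colnames(x) <- labels
  roi_timeseries(x, tr = tr, subject_id = subject_id)
}

## Motion-parameter table whose mean FD equals target_fd exactly: random
## increment directions, rescaled so the Power FD sum matches, then
## integrated. Returns T x 6 matrix.
simulate_motion <- function(n_frames, target_fd, head_radius = 50) {
  d <- matrix(stats::rnorm((n_frames - 1) * 6, sd = 0.01), n_frames - 1, 6)
  fd <- rowSums(abs(d[, 1:3, drop = FALSE])) +
    head_radius * rowSums(abs(d[, 4:6, drop = FALSE]))
  scale <- target_fd * n_frames / sum(fd)
  motion <- apply(rbind(0, d * scale), 2, cumsum)
  dimnames(motion) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  motion
}

#' Simulate a full cohort
#'
#' Generates every subject of the configured three-group cohort: ROI time
#' series with per-group block-correlation structure (plus per-subject
#' target jitter, a shared global-coupling offset and block-specific
#' variation), uniform ages, log-normal mean FD
#' realized exactly by a synthetic motion-parameter table, severity scores,
#' and a depressive-disorder flag. All randomness derives from the master
#' seed; per-subject seeds are drawn once from it, so the same config is
#' reproducible bit for bit.
#'
#' @param config A `sim_config`.
#' @param atlas ROI atlas fixing R and the network labels (default the
#'   shipped synthetic atlas).
#' @return A `sim_cohort`: list with `config`, `atlas` and `subjects`, a
#'   list of per-subject records (`id`, `group`, `age`, `mean_fd`, `motion`,
#'   `cybocs`, `masc`, `depress_flag`, `ts`).
#' @export
simulate_cohort <- function(config = sim_config(), atlas = default_atlas()) {
  stopifnot(inherits(config, "sim_config"))
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  draws <- with_seed(config$seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, n),
         ages = stats::runif(n, config$age_range[1], config$age_range[2]),
         fd = stats::rlnorm(n, config$fd_meanlog, config$fd_sdlog),
         jitter = stats::rnorm(n, sd = config$subject_sd_shared) +
           matrix(stats::rnorm(n * 6, sd = config$subject_sd_block), n, 6),
         cybocs = stats::rnorm(n, config$cybocs_mean, config$cybocs_sd),
         masc = stats::rnorm(n, config$masc_mean[groups], config$masc_sd),
         masc_miss = stats::runif(n) < config$masc_missing_rate,
         depress = stats::runif(n) < config$depress_prob[groups])
  })
  first_group <- names(config$group_sizes)[1]
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    # Rare extreme jitter draws can make the block matrix unrepairable
    # within tolerance; shrink the jitter toward the group target until the
    # PSD repair fits (deterministic, documented fallback).
    shrink <- 1
    corr <- NULL
    repeat {
      targets <- config$block_targets[groups[i], ] + shrink * draws$jitter[i, ]
      names(targets) <- FCNET_METRICS
      targets <- pmin(pmax(targets, atanh(-0.98)), atanh(0.98))
      corr <- tryCatch(
        build_block_correlation(targets, atlas$network,
                                psd_tolerance = config$psd_tolerance),
        error = function(e) NULL)
      if (!is.null(corr) || shrink < 1e-3) break
      shrink <- shrink * 0.7
    }
    if (is.null(corr))
      stop("block targets for group ", groups[i], " are not realizable")
    id <- sprintf("sub-%03d", i)
    ts <- simulate_subject(corr, config$n_frames, seed = draws$seeds[i],
                           tr = config$tr, ar1 = config$ar1,
                           subject_id = id, labels = atlas$label)
    motion <- with_seed(draws$seeds[i] + 1L,
                        simulate_motion(config$n_frames, draws$fd[i]))
    subjects[[i]] <- list(
      id = id, group = groups[i], age = draws$ages[i],
      mean_fd = mean_fd(framewise_displacement(motion)),
      motion = motion,
      cybocs = if (groups[i] == first_group) draws$cybocs[i] else NA_real_,
      masc = if (draws$masc_miss[i]) NA_real_ else draws$masc[i],
      depress_flag = as.integer(draws$depress[i]),
      ts = ts)
  }
  structure(list(config = config, atlas = atlas, subjects = subjects),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat("simulated cohort:", length(x$subjects), "subjects (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "),",
      x$config$n_frames, "frames, seed", x$config$seed, "\n")
  invisible(x)
}

#' Cohort table: demographics, covariates and the six metrics
#'
#' Runs the connectivity pipeline on every simulated subject and assembles
#' the subjects x (group, age, mean_fd, severity, metrics) table consumed by
#' [group_analysis()].
#'
#' @param cohort A `sim_cohort`.
#' @return Data frame with one row per subject.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  pairs <- block_index(cohort$atlas)
  rows <- lapply(cohort$subjects, function(s) {
    z <- fisher_z(correlation_matrix(s$ts))
    m <- network_metrics(z, pairs)
    cbind(data.frame(subject_id = s$id, group = s$group, age = s$age,
                     mean_fd = s$mean_fd, cybocs = s$cybocs, masc = s$masc,
                     depress_flag = s$depress_flag, stringsAsFactors = FALSE),
          as.data.frame(as.list(m)))
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = names(cohort$config$group_sizes))
  out
}

#' Write a simulated cohort as NIfTI volumes plus motion files
#'
#' Embeds each subject's ROI series into a 4D volume: every voxel of an
#' ROI's sphere mask carries that ROI's series (overlap voxels the mean of
#' contributing ROIs), all other voxels seeded Gaussian background noise.
#' Motion-parameter text files realizing each subject's mean FD are written
#' alongside, plus a JSON manifest recording the seed and group sizes.
#'
#' @param cohort A `sim_cohort`.
#' @param grid A `grid_spec` covering all sphere masks.
#' @param dir Output directory (created if absent).
#' @param noise_sd Background noise SD (default 1).
#' @return The manifest path, invisibly.
#' @export
write_cohort_nifti <- function(cohort, grid, dir, noise_sd = 1) {
  stopifnot(inherits(cohort, "sim_cohort"), inherits(grid, "grid_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- cohort$atlas
  masks <- lapply(seq_len(nrow(atlas)), function(r) {
    m <- sphere_mask(atlas[r, ], grid)
    m[, 1] + (m[, 2] - 1L) * grid$shape[1] +
      (m[, 3] - 1L) * (grid$shape[1] * grid$shape[2])
  })
  nvox <- prod(grid$shape)
  nt <- cohort$config$n_frames
  ids <- vapply(cohort$subjects, `[[`, "", "id")
  for (s in cohort$subjects) {
    noise_seed <- (cohort$config$seed + 7919L * match(s$id, ids)) %% 2147483647L
    flat <- with_seed(noise_seed,
                      matrix(stats::rnorm(nvox * nt, sd = noise_sd), nvox, nt))
    cnt <- integer(nvox)
    sig <- matrix(0, nvox, nt)
    for (r in seq_along(masks)) {
      sig[masks[[r]], ] <- sig[masks[[r]], , drop = FALSE] +
        matrix(s$ts[, r], length(masks[[r]]), nt, byrow = TRUE)
      cnt[masks[[r]]] <- cnt[masks[[r]]] + 1L
    }
    inroi <- cnt > 0L
    flat[inroi, ] <- sig[inroi, , drop = FALSE] / cnt[inroi]
    vol <- array(flat, dim = c(grid$shape, nt))
    img <- RNifti::asNifti(vol)
    img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
    img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
    img <- RNifti::`pixdim<-`(img, c(sqrt(colSums(grid$affine[1:3, 1:3]^2)),
                                     cohort$config$tr))
    RNifti::writeNifti(img, file.path(dir, paste0(s$id, "_bold.nii.gz")))
    utils::write.table(format(s$motion, digits = 17, trim = TRUE),
                       file.path(dir, paste0(s$id, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    seed = cohort$config$seed,
    n_frames = nt, tr = cohort$config$tr,
    group_sizes = as.list(cohort$config$group_sizes),
    subjects = vapply(cohort$subjects, `[[`, "", "id"))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
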