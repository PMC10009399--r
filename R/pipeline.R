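#' Write the group-analysis result set to disk
#'
#' Emits `stats.csv` (one row per metric: F, df, p, FDR-adjusted p, partial
#' eta squared, per-group adjusted mean and SE), `posthoc.csv` (one row per
#' metric x group pair), optionally `correlations.csv`, and `results.json`
#' bundling everything. Column orders are fixed for diff-stability; floats
#' are written at full precision.
#'
#' @param result An `fc_group_analysis`.
#' @param dir Output directory (created if absent).
#' @param correlations Optional data frame from [severity_correlations()].
#' @return The directory, invisibly.
#' @export
write_group_analysis <- function(result, dir, correlations = NULL) {
  stopifnot(inherits(result, "fc_group_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$stats, file.path(dir, "stats.csv"),
                   row.names = FALSE)
  utils::write.csv(result$posthoc, file.path(dir, "posthoc.csv"),
                   row.names = FALSE)
  bundle <- list(stats = result$stats, posthoc = result$posthoc,
                 covariates = result$covariates, alpha = result$alpha)
  if (!is.null(correlations)) {
    utils::write.csv(correlations, file.path(dir, "correlations.csv"),
                     row.names = FALSE)
    bundle$correlations <- correlations
  }
  jsonlite::write_json(bundle, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' End-to-end analysis of a directory of per-subject time-series tables
#'
#' Reads one TSV time-series table per subject (columns in atlas order),
#' computes the six connectivity metrics, joins the cohort covariate table,
#' and runs the group ANCOVA analysis.
#'
#' @param cohort_csv CSV with columns `subject_id`, `group`, `age`,
#'   `mean_fd` (and optional severity columns); `subject_id` must match the
#'   time-series file names `<subject_id>.tsv`.
#' @param ts_dir Directory of per-subject TSV tables.
#' @param atlas A `roi_atlas` (default the shipped synthetic atlas).
#' @param covariates Covariates for the ANCOVA.
#' @param out_dir Optional output directory for [write_group_analysis()].
#' @return An `fc_group_analysis`, with the assembled cohort table attached
#'   as attribute `cohort`.
#' @export
run_pipeline <- function(cohort_csv, ts_dir, atlas = default_atlas(),
                         covariates = c("age", "mean_fd"), out_dir = NULL) {
  cov_tab <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(cov_tab)))
    stop("cohort CSV needs subject_id and group columns")
  pairs <- block_index(atlas)
  mets <- lapply(cov_tab$subject_id, function(id) {
    path <- file.path(ts_dir, paste0(id, ".tsv"))
    if (!file.exists(path)) stop("no time-series file for subject ", id)
    ts <- read_timeseries(path, subject_id = id)
    tryCatch(network_metrics(fisher_z(correlation_matrix(ts)), pairs),
             error = function(e)
               stop("subject ", id, ": ", conditionMessage(e), call. = FALSE))
  })
  cohort <- cbind(cov_tab, do.call(rbind, mets))
  res <- group_analysis(cohort, covariates = covariates)
  attr(res, "cohort") <- cohort
  if (!is.null(out_dir)) write_group_analysis(res, out_dir)
  res
}

#' Simulate a cohort and write it as an analysis-ready run directory
#'
#' Writes per-subject time-series TSVs, the cohort covariate CSV, and a
#' manifest JSON recording the configuration and seed, so the run can be
#' reproduced from the manifest alone.
#'
#' @param config A `sim_config`.
#' @param dir Output run directory.
#' @param atlas ROI atlas (default shipped).
#' @return The directory, invisibly.
#' @export
write_cohort_tables <- function(config, dir, atlas = default_atlas()) {
  cohort <- simulate_cohort(config, atlas)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE,
             recursive = TRUE)
  for (s in cohort$subjects)
    write_timeseries(s$ts, file.path(dir, "timeseries",
                                     paste0(s$id, ".tsv")))
  tab <- cohort_table(cohort)
  utils::write.csv(tab[c("subject_id", "group", "age", "mean_fd", "cybocs",
                         "masc", "depress_flag")],
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  manifest <- c(unclass(config)[c("group_sizes", "n_frames", "tr",
                                  "subject_sd_shared", "subject_sd_block",
                                  "age_range", "seed")],
                list(block_targets = config$block_targets,
                     n_subjects = length(cohort$subjects)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
  invisible(dir)
}

#' Replicated simulation study: recovery and rejection rates
#'
#' Repeats simulate-cohort / compute-metrics / group-ANCOVA over `n_reps`
#' master seeds and collects, per metric: the omnibus p-value, the LSD
#' p-value for one group contrast, and the per-group sample means of the
#' metric. Used for parameter-recovery checks (are the configured block
#' targets recovered without bias?) and for type-I-error calibration (with
#' group-constant targets, how often does the omnibus test reject?).
#'
#' @param n_reps Number of replicates.
#' @param config Base `sim_config`; replicate r runs with seed
#'   `base_seed + r`.
#' @param atlas ROI atlas (default shipped).
#' @param contrast Character 2-vector naming the group pair whose LSD
#'   p-value is tracked (default `c("OCD", "AC")`).
#' @param base_seed Seed origin for the replicate seeds (default the
#'   config's seed).
#' @return An `fc_simulation_study`: list with `omnibus_p` (n_reps x 6),
#'   `contrast_p` (n_reps x 6), `group_means` (n_reps x 3 x 6 array),
#'   `targets` (the config block targets), `contrast`, `n_reps`.
#' @export
simulation_study <- function(n_reps, config = sim_config(),
                             atlas = default_atlas(),
                             contrast = c("OCD", "AC"),
                             base_seed = config$seed) {
  groups <- names(config$group_sizes)
  omnibus <- matrix(NA_real_, n_reps, 6,
                    dimnames = list(NULL, FCNET_METRICS))
  contr <- omnibus
  gmeans <- array(NA_real_, c(n_reps, length(groups), 6),
                  dimnames = list(NULL, groups, FCNET_METRICS))
  pair_label <- paste(contrast[1], "vs", contrast[2])
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer((base_seed + r) %% 2147483647)
    tab <- cohort_table(simulate_cohort(cfg, atlas))
    res <- group_analysis(tab)
    omnibus[r, ] <- res$stats$p
    ph <- res$posthoc
    for (m in FCNET_METRICS) {
      row <- ph[ph$metric == m & ph$pair == pair_label, ]
      if (nrow(row)) contr[r, m] <- row$p
      gmeans[r, , m] <- tapply(tab[[m]], tab$group, mean)[groups]
    }
  }
  structure(list(omnibus_p = omnibus, contrast_p = contr,
                 group_means = gmeans, targets = config$block_targets,
                 contrast = contrast, n_reps = n_reps),
            class = "fc_simulation_study")
}

#' @export
print.fc_simulation_study <- function(x, alpha = 0.05, ...) {
  cat("simulation study:", x$n_reps, "replicates\n")
  cat("omnibus rejection rates at alpha =", alpha, ":\n")
  print(round(colMeans(x$omnibus_p < alpha), 3))
  cat("mean group-mean estimates (within_CON):\n")
  print(round(colMeans(x$group_means[, , "within_CON", drop = FALSE][, , 1]),
              4))
  invisible(x)
}
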