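#' One-way ANCOVA on a connectivity metric
#'
#' Fits `metric ~ group + covariates` by least squares (no interactions) and
#' reports the omnibus group F from the nested-model residual-sum-of-squares
#' comparison (full model vs covariates only), partial eta squared
#' `SS_group / (SS_group + SS_error)`, and per-group adjusted means: the
#' model prediction for each group at the whole-sample means of the
#' covariates, with standard errors from the coefficient covariance.
#'
#' @param formula Model formula whose response is the metric and whose
#'   right-hand side contains the grouping factor plus any numeric
#'   covariates, e.g. `within_CON ~ group + age + mean_fd`.
#' @param data Data frame (one row per subject) containing all variables.
#' @param group Name of the grouping variable in `formula` (default
#'   `"group"`); coerced to a factor.
#' @return A `network_ancova` object with components `F`, `df1`, `df2`, `p`,
#'   `eta2p`, `emmeans` (data frame: group, M, SE), `fit` (the underlying
#'   `lm`), `metric`, `covariates`, `n`.
#' @seealso [lsd_posthoc()], [group_analysis()]
#' @examples
#' cohort <- data.frame(group = rep(c("OCD", "AC", "HC"), each = 10),
#'                      age = runif(30, 8, 21), mean_fd = rlnorm(30, -2, 0.4),
#'                      within_CON = rnorm(30, 0.45, 0.1))
#' fit <- network_ancova(within_CON ~ group + age + mean_fd, cohort)
#' summary(fit)
#' @export
network_ancova <- function(formula, data, group = "group") {
  data <- as.data.frame(data)
  vars <- all.vars(formula)
  metric <- vars[1]
  rhs <- vars[-1]
  if (!group %in% rhs)
    stop("grouping variable '", group, "' must appear in the formula")
  covariates <- setdiff(rhs, group)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(data[vars])
  data <- data[keep, , drop = FALSE]
  data[[group]] <- droplevels(factor(data[[group]]))
  g <- nlevels(data[[group]])
  if (g < 2L) stop("need at least 2 groups")
  n <- nrow(data)
  if (n - g - length(covariates) < 1L)
    stop("error degrees of freedom < 1 (N = ", n, ")")
  for (cv in covariates)
    if (!all(is.finite(data[[cv]]))) stop("covariate '", cv, "' not finite")

  full <- stats::lm(formula, data = data)
  if (anyNA(stats::coef(full)))
    stop("rank-deficient design (collinear or constant predictor)")
  reduced <- stats::lm(
    stats::update.formula(formula, paste(". ~ . -", group)), data = data)
  cmp <- stats::anova(reduced, full)
  ss_group <- cmp[["Sum of Sq"]][2]
  ss_error <- sum(stats::residuals(full)^2)
  df1 <- cmp[["Df"]][2]
  df2 <- full$df.residual
  Fval <- cmp[["F"]][2]
  pval <- cmp[["Pr(>F)"]][2]
  eta2p <- ss_group / (ss_group + ss_error)

  # adjusted means at the whole-sample covariate means
  newdata <- data.frame(levels(data[[group]]), stringsAsFactors = FALSE)
  names(newdata) <- group
  for (cv in covariates) newdata[[cv]] <- mean(data[[cv]])
  newdata[[group]] <- factor(newdata[[group]], levels(data[[group]]))
  X <- stats::model.matrix(stats::delete.response(stats::terms(full)), newdata)
  beta <- stats::coef(full)
  V <- stats::vcov(full)
  emm <- data.frame(group = levels(data[[group]]),
                    M = as.numeric(X %*% beta),
                    SE = sqrt(diag(X %*% V %*% t(X))),
                    stringsAsFactors = FALSE)

  structure(list(metric = metric, group = group, covariates = covariates,
                 F = Fval, df1 = df1, df2 = df2, p = pval, eta2p = eta2p,
                 emmeans = emm, fit = full, n = n,
                 emm_design = X),
            class = "network_ancova")
}

#' @export
print.network_ancova <- function(x, digits = 4, ...) {
  cat("ANCOVA:", x$metric, "~", x$group,
      if (length(x$covariates)) paste("+", paste(x$covariates, collapse = " + ")),
      "\n")
  cat(sprintf("  F(%d, %d) = %.*g, p = %.*g, eta2p = %.*g  (N = %d)\n",
              x$df1, x$df2, digits, x$F, digits, x$p, digits, x$eta2p, x$n))
  invisible(x)
}

#' @export
summary.network_ancova <- function(object, ...) {
  print(object)
  cat("Adjusted group means (at sample covariate means):\n")
  print(object$emmeans, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.network_ancova <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.network_ancova <- function(object, ...) stats::vcov(object$fit)

#' @export
residuals.network_ancova <- function(object, ...) stats::residuals(object$fit)

#' @export
predict.network_ancova <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
simulate.network_ancova <- function(object, nsim = 1, seed = NULL, ...)
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)

#' Fisher's LSD pairwise post-hoc contrasts
#'
#' For every unordered pair of groups, tests the difference of adjusted
#' means with `t = diff / SE(diff)` using the ANCOVA coefficient covariance
#' (pooled error), `df` equal to the model error df, two-sided p with no
#' further multiplicity adjustment (least-significant-difference method).
#' The protected-LSD gate — whether the omnibus F is significant at `alpha`
#' — is reported as a flag; all pairs are always returned.
#'
#' @param model A `network_ancova` fit.
#' @param alpha Omnibus gate level (default 0.05).
#' @return Data frame: `pair`, `group1`, `group2`, `diff` (adjusted mean
#'   difference, group1 - group2), `SE`, `t`, `df`, `p`, and attribute
#'   `omnibus_significant`.
#' @export
lsd_posthoc <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "network_ancova"))
  X <- model$emm_design
  beta <- stats::coef(model$fit)
  V <- stats::vcov(model$fit)
  lv <- model$emmeans$group
  cmb <- utils::combn(seq_along(lv), 2L)
  res <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1, k]; j <- cmb[2, k]
    L <- X[i, ] - X[j, ]
    d <- sum(L * beta)
    se <- sqrt(as.numeric(t(L) %*% V %*% L))
    tval <- d / se
    data.frame(pair = paste(lv[i], "vs", lv[j]),
               group1 = lv[i], group2 = lv[j],
               diff = d, SE = se, t = tval, df = model$df2,
               p = 2 * stats::pt(-abs(tval), model$df2),
               stringsAsFactors = FALSE)
  }))
  attr(res, "omnibus_significant") <- model$p < alpha
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment: for ordered raw p-values the adjusted value is
#' `min_{j >= i} (m * p_(j) / j)`, capped at 1. Here the family is the six
#' metric-level omnibus p-values.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
fdr_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Partial eta squared from an F statistic
#'
#' The identity `eta2p = F * df1 / (F * df1 + df2)`, equivalent to
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param f F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared.
#' @export
eta2p_from_f <- function(f, df1, df2) f * df1 / (f * df1 + df2)

#' Severity-connectivity correlations
#'
#' Pearson correlation of a severity scale with each of the six metrics,
#' with two-sided p-values; missing scale or metric values are dropped
#' pairwise and the per-row `n` reported. By convention the OCD-only
#' C/Y-BOCS is scoped to the OCD group and the MASC to all groups with data.
#'
#' @param cohort Cohort data frame with the six metric columns and the scale.
#' @param scale Column name of the severity score (e.g. `"cybocs"`,
#'   `"masc"`).
#' @param groups Optional character vector restricting to these group
#'   levels; `NULL` uses all rows.
#' @param metrics Metric columns (default the six block means).
#' @return Data frame: `metric`, `r`, `p`, `n`.
#' @export
severity_correlations <- function(cohort, scale, groups = NULL,
                                  metrics = FCNET_METRICS) {
  cohort <- as.data.frame(cohort)
  if (!scale %in% names(cohort)) stop("no column '", scale, "' in cohort")
  if (!is.null(groups)) cohort <- cohort[cohort$group %in% groups, , drop = FALSE]
  out <- do.call(rbind, lapply(metrics, function(m) {
    ok <- stats::complete.cases(cohort[[scale]], cohort[[m]])
    n <- sum(ok)
    if (n < 3L) stop("fewer than 3 complete pairs for ", m)
    x <- cohort[[scale]][ok]; y <- cohort[[m]][ok]
    if (stats::sd(x) == 0) stop("scale '", scale, "' constant in scope")
    if (stats::sd(y) == 0) stop("metric '", m, "' constant in scope")
    ct <- stats::cor.test(x, y)
    data.frame(metric = m, r = unname(ct$estimate), p = ct$p.value, n = n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Group comparison across all six connectivity metrics
#'
#' The cohort-level analysis: one ANCOVA per metric (same covariates),
#' BH-FDR adjustment across the six omnibus p-values, and LSD pairwise
#' post-hocs per metric.
#'
#' @param cohort Data frame with columns `group`, the covariates, and the
#'   six metric columns.
#' @param covariates Covariate column names (default `age` and `mean_fd`).
#' @param metrics Metric columns to analyse (default the six block means;
#'   the FDR family is exactly this set).
#' @param alpha Significance level for the protected-LSD gate.
#' @return An `fc_group_analysis` object: list with `stats` (one row per
#'   metric: F, df1, df2, p, p_fdr, eta2p and per-group M/SE), `posthoc`
#'   (all pairwise rows), `models` (the `network_ancova` fits), `alpha`.
#' @export
group_analysis <- function(cohort, covariates = c("age", "mean_fd"),
                           metrics = FCNET_METRICS, alpha = 0.05) {
  cohort <- as.data.frame(cohort)
  models <- lapply(metrics, function(m) {
    f <- stats::reformulate(c("group", covariates), response = m)
    network_ancova(f, cohort)
  })
  names(models) <- metrics
  p_raw <- vapply(models, `[[`, 0, "p")
  p_fdr <- fdr_bh(p_raw)
  stats_tab <- do.call(rbind, lapply(seq_along(models), function(i) {
    mod <- models[[i]]
    row <- data.frame(metric = metrics[i], n = mod$n, F = mod$F,
                      df1 = mod$df1, df2 = mod$df2, p = mod$p,
                      p_fdr = p_fdr[i], eta2p = mod$eta2p,
                      stringsAsFactors = FALSE)
    for (k in seq_len(nrow(mod$emmeans))) {
      g <- mod$emmeans$group[k]
      row[[paste0("M_", g)]] <- mod$emmeans$M[k]
      row[[paste0("SE_", g)]] <- mod$emmeans$SE[k]
    }
    row
  }))
  posthoc <- do.call(rbind, lapply(metrics, function(m) {
    ph <- lsd_posthoc(models[[m]], alpha = alpha)
    cbind(metric = m, ph,
          omnibus_significant = attr(ph, "omnibus_significant"))
  }))
  rownames(stats_tab) <- rownames(posthoc) <- NULL
  structure(list(stats = stats_tab, posthoc = posthoc, models = models,
                 covariates = covariates, alpha = alpha),
            class = "fc_group_analysis")
}

#' @export
print.fc_group_analysis <- function(x, digits = 3, ...) {
  cat("Group ANCOVA over", nrow(x$stats), "connectivity metrics",
      "(covariates:", paste(x$covariates, collapse = ", "), ")\n")
  tab <- x$stats[c("metric", "F", "df1", "df2", "p", "p_fdr", "eta2p")]
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.fc_group_analysis <- function(object, ...) {
  print(object)
  cat("\nLSD pairwise contrasts (unadjusted p, pooled error):\n")
  ph <- object$posthoc
  ph$diff <- round(ph$diff, 4); ph$t <- round(ph$t, 3); ph$p <- signif(ph$p, 3)
  print(ph[c("metric", "pair", "diff", "t", "df", "p", "omnibus_significant")],
        row.names = FALSE)
  invisible(object)
}

#' @export
plot.fc_group_analysis <- function(x, cohort, metric = "within_CON", ...) {
  if (!metric %in% names(cohort)) stop("metric not in cohort")
  grp <- factor(cohort$group)
  graphics::boxplot(cohort[[metric]] ~ grp, outline = FALSE, border = "grey40",
                    xlab = "group", ylab = paste(metric, "(Fisher z)"),
                    main = metric, ...)
  graphics::stripchart(cohort[[metric]] ~ grp, vertical = TRUE, add = TRUE,
                       method = "jitter", pch = 19,
                       col = grDevices::adjustcolor("steelblue", 0.6))
  invisible(x)
}

#' Sensitivity re-analyses
#'
#' Two checks of the primary result: `add_depress_covariate` refits every
#' ANCOVA with a binary co-morbid depressive-disorder flag as a third
#' covariate (error df drops by one); `exclude_over_18` removes subjects
#' older than 18 years and reruns the primary analysis with df recomputed
#' from the reduced N.
#'
#' @param cohort Cohort data frame; needs `depress_flag` or `age` depending
#'   on mode.
#' @param mode `"add_depress_covariate"` or `"exclude_over_18"`.
#' @param covariates Primary covariates (default `age`, `mean_fd`).
#' @param ... Passed to [group_analysis()].
#' @return An `fc_group_analysis`.
#' @export
sensitivity_analysis <- function(cohort,
                                 mode = c("add_depress_covariate",
                                          "exclude_over_18"),
                                 covariates = c("age", "mean_fd"), ...) {
  mode <- match.arg(mode)
  cohort <- as.data.frame(cohort)
  if (mode == "add_depress_covariate") {
    if (is.null(cohort$depress_flag)) stop("cohort has no depress_flag column")
    group_analysis(cohort, covariates = c(covariates, "depress_flag"), ...)
  } else {
    if (is.null(cohort$age)) stop("cohort has no age column")
    kept <- cohort[cohort$age <= 18, , drop = FALSE]
    if (nrow(kept) == 0L) stop("all subjects excluded by age filter")
    group_analysis(kept, covariates = covariates, ...)
  }
}

#' Participant retention bookkeeping
#'
#' Applies a per-group exclusion tally to enrolled counts and returns the
#' retained sample sizes — the arithmetic that turns an enrolled cohort into
#' the analysed one.
#'
#' @param enrolled Named integer vector of enrolled subjects per group.
#' @param excluded Named integer vector of exclusions per group (names must
#'   be a subset of `names(enrolled)`).
#' @return List with `per_group` (named vector) and `total`.
#' @export
participant_retention <- function(enrolled, excluded) {
  if (is.null(names(enrolled)) || is.null(names(excluded)))
    stop("enrolled and excluded must be named")
  if (!all(names(excluded) %in% names(enrolled)))
    stop("excluded names must be a subset of enrolled names")
  kept <- enrolled
  kept[names(excluded)] <- kept[names(excluded)] - excluded
  if (any(kept < 0)) stop("more exclusions than enrolled subjects")
  list(per_group = kept, total = sum(kept))
}
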