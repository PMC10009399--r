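test_that("ANCOVA degrees of freedom follow N - G - C", {
  cohort <- toy_cohort(n_per = 31)   # N = 93
  fit <- network_ancova(within_CON ~ group + age + mean_fd, cohort)
  expect_equal(fit$df1, 2)
  expect_equal(fit$df2, 88)
  fit1 <- network_ancova(within_CON ~ group + age, cohort)
  expect_equal(fit1$df2, 89)
})

test_that("with zero-effect covariates the F equals a brute-force one-way ANOVA", {
  # 12-subject toy, covariates absent from the model
  cohort <- toy_cohort(n_per = 4, seed = 7, means = c(OCD = 0.6, AC = 0.4,
                                                      HC = 0.45))
  fit <- network_ancova(within_CON ~ group, cohort)

  y <- cohort$within_CON
  g <- cohort$group
  grand <- mean(y)
  ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  f_oracle <- (ss_between / df1) / (ss_within / df2)

  expect_equal(fit$F, f_oracle, tolerance = 1e-8)
  expect_equal(fit$df2, df2)
  # adjusted means reduce to raw group means
  expect_equal(fit$emmeans$M, as.numeric(tapply(y, g, mean)),
               tolerance = 1e-12)
  expect_equal(fit$eta2p, ss_between / (ss_between + ss_within),
               tolerance = 1e-12)
})

test_that("nested-model F equals the Type-III group F from car::Anova", {
  skip_if_not_installed("car")
  cohort <- toy_cohort(n_per = 9, seed = 21)
  fit <- network_ancova(between_OST_CON ~ group + age + mean_fd, cohort)
  a3 <- car::Anova(fit$fit, type = 3)
  expect_equal(fit$F, a3["group", "F value"], tolerance = 1e-8)
  expect_equal(fit$p, a3["group", "Pr(>F)"], tolerance = 1e-8)
})

test_that("adjusted means, SEs and LSD contrasts match emmeans", {
  skip_if_not_installed("emmeans")
  cohort <- toy_cohort(n_per = 8, seed = 13)
  fit <- network_ancova(within_CON ~ group + age + mean_fd, cohort)
  em <- summary(emmeans::emmeans(fit$fit, "group"))
  expect_equal(fit$emmeans$M, em$emmean, tolerance = 1e-8)
  expect_equal(fit$emmeans$SE, em$SE, tolerance = 1e-8)

  ph <- lsd_posthoc(fit)
  emp <- summary(emmeans::contrast(emmeans::emmeans(fit$fit, "group"),
                                   "pairwise", adjust = "none"))
  expect_equal(abs(ph$t), abs(emp$t.ratio), tolerance = 1e-8)
  expect_equal(ph$p, emp$p.value, tolerance = 1e-8)
  expect_equal(ph$df, rep(fit$df2, 3))
})

test_that("eta2p identity holds for fitted models and the printed arithmetic", {
  for (s in 1:5) {
    cohort <- toy_cohort(n_per = 7, seed = s)
    fit <- network_ancova(within_DMN ~ group + age + mean_fd, cohort)
    expect_equal(fit$eta2p, eta2p_from_f(fit$F, fit$df1, fit$df2),
                 tolerance = 1e-10)
  }
})

test_that("LSD on a toy cohort equals the pooled-MSE two-sample contrast", {
  cohort <- toy_cohort(n_per = 4, seed = 3)
  fit <- network_ancova(within_OST ~ group, cohort)
  ph <- lsd_posthoc(fit)

  y <- cohort$within_OST; g <- cohort$group
  mse <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2))) /
    (length(y) - nlevels(g))
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  for (k in seq_len(nrow(ph))) {
    i <- ph$group1[k]; j <- ph$group2[k]
    t_oracle <- (means[i] - means[j]) /
      sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    expect_equal(ph$t[k], unname(t_oracle), tolerance = 1e-8)
  }
})

test_that("identical groups give zero difference and p = 1", {
  base <- toy_cohort(n_per = 5, seed = 8)
  a <- base[base$group == "OCD", ]
  b <- a; b$group <- "AC"; b$subject_id <- paste0(b$subject_id, "b")
  c3 <- base[base$group == "HC", ]
  dup <- rbind(a, b, c3)
  dup$group <- factor(as.character(dup$group), c("OCD", "AC", "HC"))
  fit <- network_ancova(within_CON ~ group + age + mean_fd, dup)
  ph <- lsd_posthoc(fit)
  row <- ph[ph$pair == "OCD vs AC", ]
  expect_equal(row$diff, 0, tolerance = 1e-12)
  expect_equal(row$p, 1, tolerance = 1e-12)
})

test_that("pair order reversal flips the sign but keeps the p-value", {
  cohort <- toy_cohort(n_per = 6, seed = 10)
  fit <- network_ancova(within_CON ~ group + age, cohort)
  ph <- lsd_posthoc(fit)
  relev <- cohort
  relev$group <- factor(as.character(relev$group), c("AC", "OCD", "HC"))
  ph2 <- lsd_posthoc(network_ancova(within_CON ~ group + age, relev))
  r1 <- ph[ph$group1 == "OCD" & ph$group2 == "AC", ]
  r2 <- ph2[ph2$group1 == "AC" & ph2$group2 == "OCD", ]
  expect_equal(r1$diff, -r2$diff, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("omnibus F is invariant to the dummy-coding reference level", {
  cohort <- toy_cohort(n_per = 6, seed = 14)
  f1 <- network_ancova(within_CON ~ group + age + mean_fd, cohort)
  relev <- cohort
  relev$group <- stats::relevel(factor(as.character(relev$group),
                                       c("OCD", "AC", "HC")), "HC")
  f2 <- network_ancova(within_CON ~ group + age + mean_fd, relev)
  expect_equal(f1$F, f2$F, tolerance = 1e-10)
  expect_equal(f1$eta2p, f2$eta2p, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected", {
  cohort <- toy_cohort(n_per = 4, seed = 2)
  cohort$flat <- 1   # constant covariate
  expect_error(network_ancova(within_CON ~ group + flat, cohort),
               "rank-deficient")
  expect_error(network_ancova(within_CON ~ age + mean_fd, cohort),
               "grouping variable")
})

test_that("BH adjustment reproduces the printed six-test family arithmetic", {
  raw <- c(0.010, 0.015, 0.30, 0.40, 0.50, 0.60)
  adj <- fdr_bh(raw)
  expect_equal(adj[1], 0.045)
  expect_equal(adj[2], 0.045)
  expect_true(all(adj[3:6] > 0.214))
})

test_that("BH matches the literal min-formula oracle on random vectors", {
  set.seed(19)
  for (i in 1:1000) {
    p <- runif(sample(3:8, 1))
    expect_equal(fdr_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("BH is order-invariant, tie-stable, monotone and never below raw p", {
  p <- c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2)
  expect_equal(fdr_bh(p), p)
  set.seed(23)
  p <- runif(6)
  perm <- sample(6)
  expect_equal(fdr_bh(p)[perm], fdr_bh(p[perm]), tolerance = 1e-12)
  expect_true(all(fdr_bh(p) >= p))
  o <- order(p)
  expect_true(all(diff(fdr_bh(p)[o]) >= -1e-15))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("severity correlations: perfect linear, pairwise deletion, scoping", {
  cohort <- toy_cohort(n_per = 8, seed = 31)
  cohort$cybocs <- ifelse(cohort$group == "OCD",
                          rnorm(nrow(cohort), 23, 6), NA)
  ocd <- cohort$group == "OCD"
  cohort$within_CON[ocd] <- 2 * cohort$cybocs[ocd] + 3
  tab <- severity_correlations(cohort, "cybocs", groups = "OCD")
  expect_equal(tab$r[tab$metric == "within_CON"], 1, tolerance = 1e-10)
  expect_true(all(tab$n == sum(ocd)))

  cohort$masc <- rnorm(nrow(cohort), 50, 10)
  full <- severity_correlations(cohort, "masc")
  cohort$masc[5] <- NA
  less <- severity_correlations(cohort, "masc")
  expect_equal(less$n, full$n - 1L)

  cohort$within_OST <- 0.4
  expect_error(severity_correlations(cohort, "masc"), "constant")
})

test_that("a null severity scale rarely correlates strongly at n = 23", {
  set.seed(41)
  hits <- 0
  nrep <- 300
  for (i in seq_len(nrep)) {
    d <- data.frame(group = "OCD",
                    scale = rnorm(23))
    for (m in FCNET_METRICS) d[[m]] <- rnorm(23)
    tab <- severity_correlations(d, "scale")
    hits <- hits + any(abs(tab$r) >= 0.55)
  }
  expect_gte(1 - hits / nrep, 0.97)
})

test_that("sensitivity analyses adjust df and filters as specified", {
  cohort <- toy_cohort(n_per = 31, seed = 51)   # N = 93
  cohort$age <- runif(93, 8, 18)                 # nobody over 18 yet
  cohort$depress_flag <- rbinom(93, 1, 0.2)

  primary <- group_analysis(cohort)
  same <- sensitivity_analysis(cohort, "exclude_over_18")
  expect_equal(same$stats$F, primary$stats$F, tolerance = 1e-12)

  dep <- sensitivity_analysis(cohort, "add_depress_covariate")
  expect_equal(dep$stats$df2, rep(93 - 3 - 3, 6))

  cohort$age[1:5] <- 19.5                        # exactly 5 over-18s
  filt <- sensitivity_analysis(cohort, "exclude_over_18")
  expect_equal(filt$stats$df2, rep(83, 6))

  cohort$depress_flag <- 0
  expect_error(sensitivity_analysis(cohort, "add_depress_covariate"),
               "rank-deficient")
})

test_that("retention bookkeeping applies the exclusion ledger", {
  kept <- participant_retention(c(OCD = 25, AC = 27, HC = 45),
                                c(OCD = 2, AC = 1, HC = 1))
  expect_equal(kept$per_group, c(OCD = 23, AC = 26, HC = 44))
  expect_equal(kept$total, 93)
  expect_error(participant_retention(c(OCD = 2), c(OCD = 3)), "more exclusions")
})

test_that("group_analysis families exactly the six metric p-values for FDR", {
  cohort <- toy_cohort(n_per = 10, seed = 61)
  res <- group_analysis(cohort)
  expect_equal(nrow(res$stats), 6)
  expect_equal(res$stats$p_fdr, fdr_bh(res$stats$p), tolerance = 1e-12)
  expect_true(all(res$stats$p_fdr >= res$stats$p))
  expect_equal(nrow(res$posthoc), 18)   # 6 metrics x 3 pairs
})
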