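test_that("block correlation matrix realizes its targets exactly when PSD", {
  nets <- toy_atlas(k = c(CON = 3, DMN = 3, OST = 3))$network

  zero <- stats::setNames(rep(0, 6), FCNET_METRICS)
  r <- build_block_correlation(zero, nets)
  expect_equal(unclass(r), diag(9), ignore_attr = TRUE)
  expect_equal(attr(r, "deviation"), 0)
  expect_false(attr(r, "repaired"))

  equi <- stats::setNames(rep(atanh(0.4), 6), FCNET_METRICS)
  r <- build_block_correlation(equi, nets)
  off <- r[upper.tri(r)]
  expect_true(all(abs(off - 0.4) < 1e-12))
  expect_false(attr(r, "repaired"))

  expect_error(
    build_block_correlation(stats::setNames(rep(Inf, 6), FCNET_METRICS), nets),
    "< 1")
})

test_that("PSD repair matches an independent eigenvalue-clipping oracle", {
  nets <- toy_atlas(k = c(CON = 3, DMN = 3, OST = 3))$network
  # strong positive between-blocks with zero within-blocks: not PSD
  t6 <- stats::setNames(c(0, 0, 0, 1.0, 1.0, 1.0), FCNET_METRICS)
  r <- build_block_correlation(t6, nets, psd_tolerance = Inf)
  expect_true(attr(r, "repaired"))
  expect_gte(min(eigen(r, symmetric = TRUE)$values), 0)

  # oracle: same construction, clipped at the same floor, renormalized
  raw <- diag(9)
  for (i in 1:8) for (j in (i + 1):9) {
    same <- (nets[i] == nets[j])
    raw[i, j] <- raw[j, i] <- if (same) 0 else tanh(1.0)
  }
  ev <- eigen(raw, symmetric = TRUE)
  fixed <- ev$vectors %*% diag(pmax(ev$values, 1e-6)) %*% t(ev$vectors)
  d <- sqrt(diag(fixed))
  fixed <- fixed / outer(d, d); diag(fixed) <- 1
  expect_equal(attr(r, "deviation"), max(abs(fixed - raw)), tolerance = 1e-8)
  expect_equal(unclass(r), fixed, ignore_attr = TRUE, tolerance = 1e-8)

  # the same matrix fails under a tight tolerance
  expect_error(build_block_correlation(t6, nets, psd_tolerance = 0.01),
               "tolerance")
})

test_that("subject simulation is seed-deterministic with calibrated sampling error", {
  nets <- toy_atlas(k = c(CON = 3, DMN = 3, OST = 3))$network
  t6 <- stats::setNames(rep(0.3, 6), FCNET_METRICS)
  corr <- build_block_correlation(t6, nets)
  a <- simulate_subject(corr, 100, seed = 5)
  b <- simulate_subject(corr, 100, seed = 5)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a),
                         unclass(simulate_subject(corr, 100, seed = 6))))

  # identity correlation: mean |off-diagonal r| stays within 3/sqrt(T)
  nt <- 400
  id9 <- diag(9)
  devs <- vapply(1:50, function(s) {
    r <- correlation_matrix(simulate_subject(id9, nt, seed = s))
    mean(abs(r[upper.tri(r)]))
  }, 0)
  expect_lt(mean(devs), 3 / sqrt(nt))

  # a strong pair is recovered within the Fisher-z sampling band
  corr2 <- diag(2); corr2[1, 2] <- corr2[2, 1] <- 0.9
  r <- correlation_matrix(simulate_subject(corr2, 2000, seed = 8))
  expect_lt(abs(r[1, 2] - 0.9), 0.05)
})

test_that("the default cohort has the study's group structure", {
  co <- simulate_cohort(sim_config(seed = 3, n_frames = 40))
  groups <- vapply(co$subjects, `[[`, "", "group")
  expect_length(groups, 93)
  expect_equal(as.vector(table(factor(groups, c("OCD", "AC", "HC")))),
               c(23, 26, 44))
  ages <- vapply(co$subjects, `[[`, 0, "age")
  expect_true(all(ages >= 8 & ages <= 21))
  cyb <- vapply(co$subjects, `[[`, 0, "cybocs")
  expect_true(all(!is.na(cyb[groups == "OCD"])))
  expect_true(all(is.na(cyb[groups != "OCD"])))
  fd <- vapply(co$subjects, `[[`, 0, "mean_fd")
  expect_true(all(fd > 0))
  # mean FD is realized exactly by the motion table
  s <- co$subjects[[5]]
  expect_equal(mean_fd(framewise_displacement(s$motion)), s$mean_fd,
               tolerance = 1e-12)
})

test_that("cohort simulation is reproducible bit for bit from the seed", {
  cfg <- sim_config(seed = 17, n_frames = 30)
  t1 <- cohort_table(simulate_cohort(cfg))
  t2 <- cohort_table(simulate_cohort(cfg))
  expect_identical(t1, t2)
  t3 <- cohort_table(simulate_cohort(sim_config(seed = 18, n_frames = 30)))
  expect_false(identical(t1$within_CON, t3$within_CON))
})

test_that("simulation leaves the global RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_cohort(sim_config(seed = 5, n_frames = 20,
                                       group_sizes = c(OCD = 2, AC = 2,
                                                       HC = 2))))
  expect_identical(.Random.seed, before)
})

test_that("NIfTI round trip recovers the generating series exactly", {
  atlas <- toy_atlas(k = c(CON = 2, DMN = 2, OST = 2), spacing = 24,
                     radius = 4)
  grid <- iso_grid(c(40, 16, 6), voxel_size = 4,
                   origin = c(-78, -26, -10))
  cfg <- sim_config(seed = 9, n_frames = 20,
                    group_sizes = c(OCD = 2, AC = 2, HC = 2))
  co <- simulate_cohort(cfg, atlas = atlas)
  dir <- file.path(tempdir(), "niftirun")
  write_cohort_nifti(co, grid, dir)

  s <- co$subjects[[3]]
  bold <- read_bold(file.path(dir, paste0(s$id, "_bold.nii.gz")))
  expect_equal(bold$tr, cfg$tr)
  ts <- extract_timeseries(bold, atlas)
  expect_equal(unclass(ts)[, ], unclass(s$ts)[, ], tolerance = 1e-6)

  motion <- read_motion(file.path(dir, paste0(s$id, "_motion.txt")))
  expect_equal(mean_fd(framewise_displacement(motion)), s$mean_fd,
               tolerance = 1e-10)

  # background voxels: zero mean, unit SD within sampling error
  vox <- bold$data[1, 1, 1, ]
  all_bg <- as.numeric(bold$data[1:2, 1:2, 1:2, ])
  expect_lt(abs(mean(all_bg)), 0.3)
  expect_lt(abs(sd(all_bg) - 1), 0.3)

  # same seed -> byte-identical files
  dir2 <- file.path(tempdir(), "niftirun2")
  write_cohort_nifti(simulate_cohort(cfg, atlas = atlas), grid, dir2)
  f1 <- file.path(dir, paste0(s$id, "_motion.txt"))
  f2 <- file.path(dir2, paste0(s$id, "_motion.txt"))
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(file.path(dir, paste0(s$id, "_bold.nii.gz")))),
                   unname(tools::md5sum(file.path(dir2, paste0(s$id, "_bold.nii.gz")))))
})
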