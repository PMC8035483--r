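dmn7 <- unname(dmn_region_indices())

test_that("group precision build is reproducible and positive definite", {
  om0 <- build_group_precision(dmn_indices = dmn7, attenuation = 0, seed = 4)
  om0b <- build_group_precision(dmn_indices = dmn7, attenuation = 0, seed = 4)
  expect_identical(om0, om0b)
  expect_identical(om0, t(om0))
  expect_silent(chol(om0))
  # attenuation = 0 equals the unattenuated build with the same seed
  om_plain <- build_group_precision(dmn_indices = dmn7, attenuation = 0,
                                    seed = 4)
  expect_identical(om0, om_plain)
  expect_error(build_group_precision(module_partition = list(1:10, 10:20),
                                     n_regions = 20),
               "partition")
})

test_that("DMN attenuation strictly shrinks implied partial correlations", {
  om0 <- build_group_precision(dmn_indices = dmn7, attenuation = 0, seed = 4)
  om5 <- build_group_precision(dmn_indices = dmn7, attenuation = 0.5, seed = 4)
  p0 <- implied_partial_correlation(om0)
  p5 <- implied_partial_correlation(om5)
  inc <- p0[dmn7, ]
  inc5 <- p5[dmn7, ]
  nz <- abs(inc) > 1e-12
  expect_true(all(abs(inc5[nz]) < abs(inc[nz])))
})

test_that("group-level models are ordered HC > NCI > CI at every seeded edge", {
  coh <- tiny_cohort()
  ps <- lapply(coh$model$precision_by_group, implied_partial_correlation)
  dmn <- coh$model$dmn_indices
  hc <- abs(ps$HC[dmn, ]); nci <- abs(ps$NCI[dmn, ]); ci <- abs(ps$CI[dmn, ])
  nz <- hc > 1e-12
  expect_true(all(nci[nz] < hc[nz]))
  expect_true(all(ci[nz] < nci[nz]))
})

test_that("simulated series have the right shape and honour the seed", {
  om <- build_group_precision(n_regions = 90, seed = 2)
  ts1 <- simulate_subject_timeseries(om, n_volumes = 240, seed = 9)
  expect_equal(dim(ts1$values), c(240, 90))
  ts2 <- simulate_subject_timeseries(om, n_volumes = 240, seed = 9)
  expect_identical(ts1$values, ts2$values)
  expect_error(simulate_subject_timeseries(diag(0, 3), 10), "positive")
})

test_that("long simulations recover the implied partial correlation", {
  # 4-node model with known pcorr(1,2); ar = 0 so the marginal covariance
  # equals the innovation covariance
  om <- diag(4)
  om[1, 2] <- om[2, 1] <- -0.3
  p_true <- implied_partial_correlation(om)
  expect_equal(p_true[1, 2], 0.3)
  ts <- simulate_subject_timeseries(om, n_volumes = 50000, ar_coeff = 0,
                                    seed = 21)
  p_hat <- partial_correlation_matrix(ts$values, shrinkage = 0)
  expect_lt(abs(p_hat[1, 2] - 0.3), 0.02)
  # empirical covariance converges to the inverse precision
  emp <- cov(ts$values)
  expect_lt(max(abs(emp - solve(om))), 0.05)
})

test_that("cohort generation is deterministic with the documented structure", {
  coh <- tiny_cohort()
  expect_equal(as.integer(table(coh$cohort$group)[c("CI", "NCI", "HC")]),
               c(4L, 4L, 4L))
  coh2 <- generate_cohort(coh$config, master_seed = 3)
  expect_identical(coh$cohort, coh2$cohort)
  expect_identical(coh$timeseries[[1]]$values, coh2$timeseries[[1]]$values)
  # MoCA classification rule holds exactly
  expect_identical(coh$cohort$group == "CI", coh$cohort$moca < 26)
  # motion passes the QC rule
  expect_true(all(vapply(coh$motion, function(m) qc_motion(m)$pass,
                         logical(1))))
  expect_error(generate_cohort(cohort_config(
    group_sizes = c(CI = 2L, NCI = 4L, HC = 4L))), "group sizes")
})

test_that("default cohort has the study's group sizes and score coupling", {
  coh <- default_cohort()
  tab <- table(coh$cohort$group)
  expect_equal(as.integer(tab[c("CI", "NCI", "HC")]), c(36L, 30L, 48L))
  gt <- coh$ground_truth
  ci <- gt$subjects$group == "CI"
  # SDMT positively coupled to the true right-precuneus nodal strength
  pcun_r <- gt$dmn_strength_by_region[ci, "PCUN.R"]
  expect_gt(cor(coh$cohort$sdmt[coh$cohort$group == "CI"], pcun_r), 0.2)
  # within-CI coupling to overall DMN strength near the configured targets
  r_sdmt <- cor(coh$cohort$sdmt[ci], gt$subjects$dmn_strength[ci])
  expect_gt(r_sdmt, 0.25)
  r_tmta <- cor(coh$cohort$tmt_a[ci], gt$subjects$dmn_strength[ci])
  expect_lt(r_tmta, -0.25)
})

test_that("cohort files round-trip through the TSV readers", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(
    cohort_config(group_sizes = c(CI = 3L, NCI = 3L, HC = 3L),
                  n_regions = 20L, n_volumes = 60L),
    master_seed = 8, out_dir = dir)
  id <- coh$cohort$subject_id[1]
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  ts <- read_timeseries_tsv(file.path(dir, paste0(id, "_roits.tsv")))
  expect_equal(unname(ts$values), unname(coh$timeseries[[id]]$values),
               tolerance = 1e-12)
  m <- read_motion_tsv(file.path(dir, paste0(id, "_motion.tsv")))
  expect_equal(unname(m), unname(coh$motion[[id]]), tolerance = 1e-12)
})
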