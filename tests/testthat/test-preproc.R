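test_that("Friston-24 expansion has the documented layout", {
  m <- matrix(0, 10, 6)
  out <- friston24_expand(m)
  expect_equal(dim(out), c(10, 24))
  expect_true(all(out == 0))
  # a single ramp parameter: lag shifts down one, squares square
  m[, 1] <- 0:9
  out <- friston24_expand(m)
  expect_equal(out[, 7], c(0, 0:8))       # lag of the ramp
  expect_equal(out[, 13], (0:9)^2)        # square
  expect_equal(out[, 19], c(0, 0:8)^2)    # square of the lag
  expect_error(friston24_expand(matrix(0, 10, 5)), "6 columns")
})

test_that("framewise displacement follows the 50 mm arc-length formula", {
  m <- matrix(0, 6, 6)
  expect_equal(framewise_displacement(m), rep(0, 6))
  # a 0.3 mm translation step contributes 0.3 at the step and at the return
  m2 <- m; m2[3, 1] <- 0.3
  expect_equal(framewise_displacement(m2), c(0, 0, 0.3, 0.3, 0, 0))
  # a 0.01 rad rotation step contributes 50 * 0.01 = 0.5 mm
  m3 <- m; m3[3:6, 4] <- 0.01 * 180 / pi   # stored in degrees
  fd <- framewise_displacement(m3)
  expect_equal(fd[3], 0.5, tolerance = 1e-12)
  expect_equal(fd[4], 0, tolerance = 1e-12)
})

test_that("scrub mask flags exactly the volumes above threshold", {
  expect_equal(scrub_mask(c(0, 0.6, 0.1), 0.5), c(TRUE, FALSE, TRUE))
  expect_equal(scrub_mask(rep(0.1, 5), 0.5), rep(TRUE, 5))
  # boundary: FD exactly at the threshold is retained
  expect_equal(scrub_mask(c(0, 0.5), 0.5), c(TRUE, TRUE))
  expect_error(scrub_mask(c(0, 1), 0), "positive")
})

test_that("motion QC applies strict 1.0 mm / 1.0 degree bounds", {
  m <- matrix(0, 10, 6)
  expect_true(qc_motion(m)$pass)
  m2 <- m; m2[4, 2] <- 1.2
  res <- qc_motion(m2)
  expect_false(res$pass)
  expect_equal(res$offending, "trans_y")
  m3 <- m; m3[4, 5] <- 1.0   # exactly at the bound passes
  expect_true(qc_motion(m3)$pass)
  m4 <- m; m4[4, 5] <- 1.0000001
  expect_false(qc_motion(m4)$pass)
})

test_that("cleaning discards volumes and band-passes as specified", {
  om <- build_group_precision(n_regions = 20, module_partition = list(1:20),
                              seed = 3)
  ts <- simulate_subject_timeseries(om, n_volumes = 240, tr = 2, seed = 5)
  cl <- clean_timeseries(ts, discard = 10)
  expect_equal(nrow(cl$values), 230)

  # tones through the same filter: 0.005 Hz (below band) loses > 90 % power,
  # 0.04 Hz (in band) keeps > 50 %
  t_sec <- (1:240) * 2
  tone <- function(f) {
    x <- matrix(sin(2 * pi * f * t_sec), ncol = 2, nrow = 240)
    x[, 2] <- cos(2 * pi * f * t_sec)
    clean_timeseries(timeseries_matrix(x, tr = 2), discard = 10)
  }
  pwr <- function(v) mean(v^2)
  lo <- tone(0.005)
  input_lo <- sin(2 * pi * 0.005 * t_sec)[11:240]
  expect_lt(pwr(lo$values[, 1]) / pwr(input_lo - mean(input_lo)), 0.10)
  mid <- tone(0.04)
  input_mid <- sin(2 * pi * 0.04 * t_sec)[11:240]
  expect_gt(pwr(mid$values[, 1]) / pwr(input_mid), 0.5)
})

test_that("detrending is idempotent and nuisance residuals are orthogonal", {
  set.seed(7)
  x <- matrix(rnorm(200 * 4), 200, 4) + outer(1:200, c(0.01, -0.02, 0.03, 0))
  d1 <- connsweep:::detrend_columns(x)
  d2 <- connsweep:::detrend_columns(d1)
  expect_lt(max(abs(d1 - d2)), 1e-10)
  slope <- apply(d1, 2, function(v) coef(lm(v ~ seq_along(v)))[2])
  expect_lt(max(abs(slope)), 1e-8)

  # nuisance regression removes a planted in-band motion artifact
  set.seed(8)
  motion <- matrix(rnorm(240 * 6, sd = 0.02), 240, 6)
  motion[, 1] <- motion[, 1] + 0.2 * sin(2 * pi * 0.03 * (1:240) * 2)
  base_sig <- matrix(rnorm(240 * 5), 240, 5)
  contaminated <- base_sig + 5 * motion[, 1]
  cl_reg <- clean_timeseries(timeseries_matrix(contaminated, tr = 2),
                             nuisance = friston24_expand(motion),
                             discard = 10)
  cl_no <- clean_timeseries(timeseries_matrix(contaminated, tr = 2),
                            discard = 10)
  # band-passed artifact reference
  art <- clean_timeseries(timeseries_matrix(cbind(motion[, 1], motion[, 1]),
                                            tr = 2), discard = 10)$values[, 1]
  r_with <- max(abs(cor(cl_reg$values, art)))
  r_without <- max(abs(cor(cl_no$values, art)))
  expect_lt(r_with, 0.15)
  expect_gt(r_without, 0.8)
})

test_that("scrubbing marks planted spike volumes and keeps rows intact", {
  coh <- tiny_cohort()
  gt <- coh$ground_truth
  spiked <- gt$subjects$subject_id[gt$subjects$n_planted_scrub > 0]
  expect_gt(length(spiked), 0)
  for (id in spiked) {
    cl <- clean_timeseries(coh$timeseries[[id]], motion = coh$motion[[id]])
    expect_equal(which(!cl$volume_mask), gt$planted_scrub_volumes[[id]])
    expect_equal(sum(cl$volume_mask),
                 nrow(cl$values) - gt$subjects$n_planted_scrub[
                   gt$subjects$subject_id == id])
  }
  # surviving rows are bit-identical whether or not masking is applied
  id <- spiked[1]
  cl <- clean_timeseries(coh$timeseries[[id]], motion = coh$motion[[id]])
  expect_identical(cl$values[cl$volume_mask, ],
                   cl$values[which(cl$volume_mask), ])
})

test_that("collinear nuisance regressors are rejected by name", {
  ts <- timeseries_matrix(matrix(rnorm(240 * 3), 240, 3), tr = 2)
  bad <- cbind(a = rnorm(240), b = rnorm(240))
  bad <- cbind(bad, c = bad[, "a"] + bad[, "b"])
  expect_error(clean_timeseries(ts, nuisance = bad), "collinear")
})
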