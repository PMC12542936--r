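test_that("calibration is exactly linear with selectivity superposition", {
  cal <- sensor_calibration(slope = 25, intercept = 2)
  expect_equal(calibration_current(cal, 0), 2)
  c1 <- calibration_current(cal, 0.7)
  c2 <- calibration_current(cal, 1.4)
  expect_equal(c2 - 2, 2 * (c1 - 2))
  # named mixture reduces to the pure calibration for h2o2 alone
  expect_equal(calibration_current(cal, c(h2o2 = 0.7)), c1)
  # interferents contribute by their selectivity weights
  mix <- calibration_current(cal, c(h2o2 = 1, k = 2, na = 2))
  expect_equal(mix, 25 * (1 + 0.005 * 2 + 0.005 * 2) + 2)
  expect_error(calibration_current(cal, -1), "concentration")
  expect_error(calibration_current(cal, c(h2o2 = 1, unknown = 1)), "unknown")
})

test_that("simulated depletion obeys the sealed-chamber identities", {
  tr <- simulate_depletion_trace(i0 = 20, tau = 12, baseline = 3,
                                 window = 120, noise_sd = 0)
  t <- trace_time(tr)
  # exponential identity at t = tau
  i_tau <- tr$current[which.min(abs(t - 12))]
  expect_equal(i_tau - 3, 20 / exp(1), tolerance = 1e-3)
  # quadrature oracle: integral of (i - baseline) = i0 * tau on a 10-tau
  # window
  expect_equal(sum(tr$current - 3) / tr$sample_rate, 20 * 12,
               tolerance = 0.01)
  # seeded noise is reproducible
  a <- simulate_depletion_trace(noise_sd = 1, seed = 5)
  b <- simulate_depletion_trace(noise_sd = 1, seed = 5)
  expect_identical(a$current, b$current)
})

test_that("depletion fit: exact noiseless recovery and noisy accuracy", {
  tr <- simulate_depletion_trace(i0 = 20, tau = 12, baseline = 3,
                                 window = 60)
  f <- fit_depletion(tr)
  expect_equal(f$i0, 20, tolerance = 1e-6)
  expect_equal(f$tau, 12, tolerance = 1e-6)
  expect_equal(f$baseline, 3, tolerance = 1e-6)
  expect_equal(f$volume_estimate, f$tau)   # A = 1 by default
  # SNR-20 Monte-Carlo recovery (deeper 100-seed version in acceptance)
  errs <- vapply(1:20, function(s) {
    trn <- simulate_depletion_trace(i0 = 20, tau = 12, baseline = 0,
                                    window = 60, noise_sd = 1, seed = s)
    abs(fit_depletion(trn)$tau - 12) / 12
  }, numeric(1))
  expect_lt(median(errs), 0.05)
  expect_error(fit_depletion(nt_trace(rep(1, 50))), "100 samples")
})

test_that("depletion fit is scale-equivariant to 1e-9", {
  trn <- simulate_depletion_trace(i0 = 20, tau = 12, baseline = 3,
                                  window = 60, noise_sd = 1, seed = 77)
  f1 <- fit_depletion(trn)
  trs <- trn
  trs$current <- trn$current * 137.5
  f2 <- fit_depletion(trs)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-9)
  expect_equal(f2$i0 / f1$i0, 137.5, tolerance = 1e-9)
  expect_equal(f2$baseline / f1$baseline, 137.5, tolerance = 1e-9)
})

test_that("zero-phase filter: DC gain, phase and noise attenuation", {
  flat <- nt_trace(rep(5, 1000))
  expect_equal(filter_trace(flat, 50)$current, rep(5, 1000))
  # step location preserved by forward-backward symmetry
  step <- nt_trace(c(rep(0, 500), rep(10, 500)))
  y <- filter_trace(step, 30)$current
  expect_equal(which.min(abs(y - 5)), 500, tolerance = 2)
  # white-noise variance cut at least by the band ratio (2 passes)
  set.seed(12)
  wn <- nt_trace(rnorm(5000))
  ratio <- var(filter_trace(wn, 50)$current) / var(wn$current)
  expect_lt(ratio, 50 / 500 * 1.2)
  expect_gt(ratio, 0.02)
  expect_error(filter_trace(flat, 0), "cutoff")
  expect_error(filter_trace(flat, 600), "cutoff")
})

test_that("filtered fit matches the unfiltered noiseless fit within 1%", {
  tr <- simulate_depletion_trace(i0 = 20, tau = 12, window = 60)
  tau0 <- fit_depletion(tr)$tau
  trn <- simulate_depletion_trace(i0 = 20, tau = 12, window = 60,
                                  noise_sd = 1, seed = 3)
  tauf <- fit_depletion(filter_trace(trn, 50))$tau
  expect_equal(tauf, tau0, tolerance = 0.01)
})

test_that("penetration detector finds steps and reports deformations", {
  # flat noiseless trace: nothing to detect
  expect_false(detect_penetration(nt_trace(rep(1, 2000)))$detected)
  # constructed 10-pA step at t = 1.0 s
  x <- c(rep(0, 1000), rep(10, 1000))
  d <- detect_penetration(nt_trace(x))
  expect_true(d$detected)
  expect_lt(abs(d$t_insert - 1.0), 0.005)
  # programmed membrane compliance on a synthetic cell
  dish <- make_dish(1, fov = c(100, 100), seed = 6)
  cell <- dish$cells[[1]]
  tr <- make_trace(cell, noise_sd = 0.3, seed = 21)
  dd <- detect_penetration(tr)
  expect_true(dd$detected)
  expect_lt(abs(dd$t_insert - tr$truth$t_insert), 0.01)
  expect_gte(dd$insertion_deformation, 0)
  expect_gte(dd$withdrawal_deformation, 0)
  expect_equal(dd$insertion_deformation, tr$truth$insertion_deformation,
               tolerance = 0.25)
})

test_that("threshold detector: levels, debounce and monotonicity", {
  expect_false(detect_mitochondrion(nt_trace(rep(5, 1000)))$detected)
  d10 <- detect_mitochondrion(nt_trace(rep(10, 1000)))
  expect_true(d10$detected)
  expect_equal(d10$t_detect, 0)
  # a 10-ms burst dies against the 50-ms debounce (unfiltered)
  b <- rep(0, 1000); b[301:310] <- 8.5
  expect_false(detect_mitochondrion(nt_trace(b), cutoff = NULL)$detected)
  # raising the threshold never converts FALSE into TRUE
  set.seed(9)
  for (i in 1:20) {
    tr <- nt_trace(rnorm(600, mean = runif(1, 4, 12), sd = 2))
    dets <- vapply(c(2, 5, 8, 11, 14), function(th)
      detect_mitochondrion(tr, threshold = th)$detected, logical(1))
    expect_true(all(diff(as.integer(dets)) <= 0))
  }
})

test_that("correlation machinery: exact, null and coverage cases", {
  x <- 1:50
  r <- correlate_current_fluorescence(cbind(x, 2 * x))
  expect_equal(r$r, 1)
  p0 <- make_paired_measurements(1000, 0, seed = 13)
  expect_lt(abs(correlate_current_fluorescence(p0)$r), 0.1)
  expect_error(correlate_current_fluorescence(cbind(1:10, rep(1, 10))),
               "variance")
  expect_error(correlate_current_fluorescence(cbind(1:2, 1:2)), "3 pairs")
  # Fisher CI covers the generating coupling (deeper version in acceptance)
  hits <- vapply(1:20, function(s) {
    p <- make_paired_measurements(89, 0.65, seed = s)
    ci <- correlate_current_fluorescence(p)$ci
    ci[1] <= 0.65 && 0.65 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
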