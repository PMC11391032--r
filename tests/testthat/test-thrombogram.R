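test_that("H-transform inverts the tanh inner-filter model", {
  Finf <- 60000; F0 <- 200
  x <- seq(0, 3 * Finf, length.out = 200)   # linear signal far beyond Finf
  F_obs <- F0 + Finf * tanh(x / Finf)
  tr <- roi_trace("h", seq_along(x), F_obs)
  ht <- h_transform(tr, Finf = Finf, F0 = F0)
  rel <- abs(ht$F[-1] - x[-1]) / x[-1]
  expect_lt(max(rel), 1e-9)
  expect_equal(ht$F[1], 0)
  # closed-form check at half saturation: atanh(0.5)
  tr2 <- roi_trace("m", 1:3, rep(F0 + 0.5 * Finf, 3))
  expect_equal(h_transform(tr2, Finf, F0)$F,
               rep(Finf * atanh(0.5), 3))
  expect_equal(Finf * atanh(0.5) / Finf, 0.5493, tolerance = 1e-4)
})

test_that("H-transform guards saturation and bad parameters", {
  tr <- roi_trace("s", 1:5, c(100, 200, 300, 400, 70500))
  expect_error(h_transform(tr, Finf = -1), "Finf")
  expect_warning(ht <- h_transform(tr, Finf = 60000, F0 = 100),
                 "saturation")
  expect_true(all(is.finite(ht$F)))
  allsat <- roi_trace("a", 1:3, rep(70000, 3))
  expect_error(h_transform(allsat, Finf = 60000, F0 = 100), "saturation")
})

test_that("Savitzky-Golay derivative is exact on low-order polynomials", {
  t <- 0:60
  lin <- roi_trace("l", t, 5 * t + 20)
  expect_equal(smooth_derivative(lin), rep(5, 61))   # edges included
  quad <- roi_trace("q", t, t^2)
  d <- smooth_derivative(quad, window = 7, order = 2)
  expect_equal(d[4:58], 2 * t[4:58])
  expect_error(smooth_derivative(lin, window = 6), "odd")
  expect_error(smooth_derivative(lin, window = 7, order = 7), "order")
  short <- roi_trace("s", 1:3, 1:3)
  expect_error(smooth_derivative(short, window = 7), "shorter")
})

test_that("derivative of a noisy ramp is unbiased", {
  # Monte-Carlo check: the mean interior derivative estimates the slope
  set.seed(101)
  reps <- 200
  means <- replicate(reps, {
    tr <- roi_trace("n", 0:60, 5 * (0:60) + rnorm(61, 0, 1))
    mean(smooth_derivative(tr)[4:58])
  })
  se <- sd(means) / sqrt(reps)
  expect_lt(abs(mean(means) - 5), 3 * se + 1e-3)
})

test_that("calibrator factor follows its definition", {
  # slope 50 RFU/min after H-transform, activity 100 nM -> Cf = 2
  Finf <- 60000; F0 <- 200
  t <- 0:60
  F_obs <- F0 + Finf * tanh(50 * t / Finf)
  cal <- fit_calibrator(roi_trace("c", t, F_obs), cal_activity = 100,
                        Finf = Finf, F0 = F0)
  expect_equal(cal$Cf, 2, tolerance = 1e-6)
  expect_equal(cal$cal_rate, 50, tolerance = 1e-6)
})

test_that("fitted Cf matches the analytic initial-rate value", {
  kin <- kinetics_spec(sigma = 0)
  tr <- simulate_calibrator(100, kin)
  cal <- fit_calibrator(tr, 100, Finf = kin$Finf, F0 = kin$F0)
  Cf_analytic <- 100 / calibrator_initial_rate(100, kin)
  expect_equal(cal$Cf, Cf_analytic, tolerance = 0.01)
})

test_that("flat or degenerate calibrator traces fail loudly", {
  flat <- roi_trace("f", 0:20, rep(500, 21))
  expect_error(fit_calibrator(flat, 100, Finf = 60000, F0 = 500),
               "calibration failure")
  expect_error(fit_calibrator(flat, 0, Finf = 60000), "cal_activity")
})

test_that("a blank trace inverts to zero thrombin", {
  kin <- kinetics_spec(sigma = 0)
  cal <- fit_calibrator(simulate_calibrator(100, kin), 100,
                        Finf = kin$Finf, F0 = kin$F0)
  blank <- simulate_fluorescence(function(t) rep_len(0, length(t)), kin)
  tg <- thrombin_curve_from_trace(blank, cal)
  expect_true(all(abs(tg$T_nM) < 1e-9))
})

test_that("a calibrator through its own calibration returns its activity", {
  kin <- kinetics_spec(sigma = 0)
  tr <- simulate_calibrator(100, kin)
  cal <- fit_calibrator(tr, 100, Finf = kin$Finf, F0 = kin$F0)
  tg <- thrombin_curve_from_trace(tr, cal, baseline_frames = 0)
  expect_equal(mean(tg$T_nM[2:11]), 100, tolerance = 0.02)
  expect_lt(max(abs(tg$T_nM[2:11] - 100)) / 100, 0.02)
})

test_that("end-to-end noise-free inversion tracks the true curve", {
  kin <- kinetics_spec(sigma = 0)
  spec <- default_curve(80.78)
  cal <- fit_calibrator(simulate_calibrator(100, kin), 100,
                        Finf = kin$Finf, F0 = kin$F0)
  tr <- simulate_fluorescence(spec, kin)
  T_true <- thrombin_curve(spec, tr$t)
  # the short window tracks the steep flanks most closely ...
  tg7 <- thrombin_curve_from_trace(tr, cal, window = 7)
  expect_lt(max(abs(tg7$T_nM - T_true)) / spec$P, 0.02)
  # ... the default window trades a little flank lag for noise
  # robustness but must stay close
  tg <- thrombin_curve_from_trace(tr, cal)
  expect_lt(max(abs(tg$T_nM - T_true)) / spec$P, 0.05)
  expect_lt(abs(max(tg$T_nM) - spec$P) / spec$P, 0.005)
})

test_that("thrombogram parameters match hand-computed cases", {
  # all-zero curve
  z <- thrombogram("z", 0:10, rep(0, 11))
  pz <- thrombogram_params(z)
  expect_equal(pz$peak_nM, 0)
  expect_equal(pz$ETP_nM_min, 0)
  expect_true(is.na(pz$lag_min))
  # triangle: 0 at t=0, 10 nM at t=10, 0 at t=20 on a 1-min grid
  t <- 0:20
  tri <- thrombogram("t", t, c(0:10, 9:0))
  p <- thrombogram_params(tri)
  expect_equal(p$ETP_nM_min, 100)       # hand trapezoid
  expect_equal(p$peak_nM, 10)
  expect_equal(p$t_peak_min, 10)
  expect_equal(p$lag_min, 1)            # threshold max(1, 0.5) = 1 nM
  expect_equal(p$velocity_index, 10 / 9)
  expect_error(thrombogram_params(thrombogram("x", 1:2, 1:2)), "samples")
})

test_that("recovered ETP matches the closed form of the true curve", {
  scn <- condition_scenario(list(tf = 80.78), n = 1, seed = 2)
  rec <- recover_params(scn)
  smp <- rec[rec$role == "sample", ]
  expect_equal(smp$ETP_nM_min, smp$true_ETP_nM_min, tolerance = 0.02)
})

test_that("recovery is scale-equivariant in the linear regime", {
  kin <- kinetics_spec(sigma = 0)
  cal <- fit_calibrator(simulate_calibrator(100, kin), 100,
                        Finf = kin$Finf, F0 = kin$F0)
  tr <- simulate_fluorescence(default_curve(20), kin)
  c_fac <- 3
  scaled <- roi_trace(tr$chip_id, tr$t, kin$F0 + c_fac * (tr$F - kin$F0))
  p1 <- thrombogram_params(thrombin_curve_from_trace(tr, cal))
  p2 <- thrombogram_params(thrombin_curve_from_trace(scaled, cal))
  expect_equal(p2$peak_nM / p1$peak_nM, c_fac, tolerance = 0.01)
  expect_equal(p2$ETP_nM_min / p1$ETP_nM_min, c_fac, tolerance = 0.01)
})

test_that("calibration cancels the fluorescence gain", {
  spec <- default_curve(80.78)
  p <- lapply(c(1000, 2000), function(g) {
    kin <- kinetics_spec(gain = g, sigma = 0)
    cal <- fit_calibrator(simulate_calibrator(100, kin), 100,
                          Finf = kin$Finf, F0 = kin$F0)
    tg <- thrombin_curve_from_trace(simulate_fluorescence(spec, kin), cal)
    thrombogram_params(tg)
  })
  expect_equal(p[[2]]$peak_nM / p[[1]]$peak_nM, 1, tolerance = 0.01)
  expect_equal(p[[2]]$ETP_nM_min / p[[1]]$ETP_nM_min, 1, tolerance = 0.01)
})

test_that("strong inner filter requires the H-transform", {
  # gain chosen so the peak linear signal reaches 1.5 * Finf
  spec <- default_curve(80.78)
  kin_probe <- kinetics_spec(Finf = 1e12, sigma = 0)
  probe <- simulate_fluorescence(spec, kin_probe)
  peak_lin <- max(probe$F - kin_probe$F0)  # RFU at gain 1000
  Finf <- peak_lin / 1.5
  kin <- kinetics_spec(Finf = Finf, sigma = 0)
  cal <- fit_calibrator(simulate_calibrator(100, kin), 100,
                        Finf = kin$Finf, F0 = kin$F0)
  tr <- simulate_fluorescence(spec, kin)
  with_h <- thrombogram_params(thrombin_curve_from_trace(tr, cal))
  without <- thrombogram_params(
    thrombin_curve_from_trace(tr, cal, use_h_transform = FALSE))
  truth <- etp_closed_form(spec)
  expect_lt(abs(with_h$ETP_nM_min - truth) / truth, 0.05)
  expect_lt(without$ETP_nM_min, truth)   # strictly negative bias
  expect_lt(without$ETP_nM_min, 0.95 * with_h$ETP_nM_min)
})

test_that("parameter recovery holds across a seeded scenario grid", {
  set.seed(2024)
  n_scn <- 20
  peak_err <- etp_err <- numeric(n_scn)
  for (i in seq_len(n_scn)) {
    P <- runif(1, 5, 150)
    t0 <- runif(1, 2, 10)
    rise <- runif(1, 3, 20)
    spec <- thrombin_curve_spec(t0, t0 + rise, P, a = 3)
    # noise up to 1% of this scenario's own noise-free trace range
    rng <- diff(range(simulate_fluorescence(spec,
                                            kinetics_spec(sigma = 0))$F))
    kin <- kinetics_spec(sigma = runif(1, 0, 0.01) * rng)
    cal <- fit_calibrator(simulate_calibrator(100, kin, seed = 1000 + i),
                          100, Finf = kin$Finf, F0 = kin$F0)
    tr <- simulate_fluorescence(spec, kin, seed = 2000 + i)
    p <- thrombogram_params(thrombin_curve_from_trace(tr, cal))
    peak_err[i] <- abs(p$peak_nM - P) / P
    etp_err[i] <- abs(p$ETP_nM_min - etp_closed_form(spec)) /
      etp_closed_form(spec)
  }
  expect_lt(median(peak_err), 0.05)
  expect_lt(median(etp_err), 0.05)
})
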