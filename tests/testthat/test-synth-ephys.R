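test_that("peak-series simulation is deterministic and well-formed", {
  a <- simulate_peak_series("activation", "wt_ca", 3, seed = 5)
  b <- simulate_peak_series("activation", "wt_ca", 3, seed = 5)
  expect_identical(a, b)
  expect_setequal(unique(a$conc_mM), c(2, 1e-4))
  expect_equal(nrow(a), 3 * 2 * 8)  # 3 oocytes x 2 arms x 8 pH points
  expect_true(all(a$peak_nA < 0))   # inward currents
  expect_error(simulate_peak_series("activation", "wt_ca", 0, seed = 1),
               "domain error")
  expect_error(get_preset("made_up"), "registry error")
})

test_that("noise-free simulation round-trips the preset parameters", {
  p <- get_preset("wt_ca")
  p$noise_sigma <- 0
  p$activation$sd_high <- 0
  p$activation$delta_sd <- 0
  peaks <- simulate_peak_series("activation", p, 2, seed = 1)
  for (oo in unique(peaks$oocyte_id)) {
    ser <- normalize_series(
      peaks[peaks$oocyte_id == oo & peaks$conc_mM == 2, ], "activation")
    fit <- fit_hill(ser, "activation")
    expect_equal(fit$estimate$pH50, 6.50, tolerance = 1e-6)
    expect_equal(fit$estimate$nH, 1.5, tolerance = 1e-6)
    low <- normalize_series(
      peaks[peaks$oocyte_id == oo & peaks$conc_mM == 1e-4, ], "activation")
    expect_equal(fit_hill(low, "activation")$estimate$pH50, 6.75,
                 tolerance = 1e-6)
  }
  pk <- get_preset("wt_kinetics")
  pk$noise_sigma <- 0
  pk$kinetics$recovery$cv <- 1e-12
  rec <- simulate_peak_series("recovery", pk, 1, seed = 1)
  ser <- normalize_series(rec[rec$conc_mM == 0.1, ], "recovery")
  fit <- fit_recovery(ser[is.finite(ser$stimulus), ])
  expect_equal(fit$estimate$tau, 22.8, tolerance = 1e-4)
})

test_that("the preset registry encodes the modulation ground truth", {
  reg <- ephys_presets()
  expect_true(all(c("wt_ca", "wt_mg", "wt_kinetics", "wt_inhibition",
                    "asic1b", "nonmodulated", "ap_act", "d409a",
                    "ap_ssd", "cv_ssd", "asic1b_cv_ssd") %in% names(reg)))
  expect_equal(reg$wt_ca$activation$delta_mean, 0.25)
  expect_equal(reg$ap_act$activation$delta_mean, 0.10)
  expect_equal(reg$asic1b_cv_ssd$ssd$delta_mean, -0.14)
  # the analytic block at 10 mM, computed independently from the
  # inhibition equation with IC50 = 9.6 mM, nH = 1, NonIn = 0
  manual <- 100 * (10 / 9.6) / (1 + 10 / 9.6)
  expect_equal(percent_block(reg$wt_inhibition, 10), manual,
               tolerance = 1e-12)
  expect_equal(round(manual), 51)
  # the midpoint-vs-concentration curve passes the printed endpoints
  expect_equal(ph50_vs_conc(reg$wt_ca, 2), 6.50, tolerance = 0.01)
  expect_equal(ph50_vs_conc(reg$wt_ca, 1e-4), 6.78, tolerance = 0.01)
})

test_that("simulated midpoint curve points scatter around the truth", {
  pts <- simulate_ph50_curve("wt_ca", n_per_conc = 200, seed = 12)
  truth <- ph50_vs_conc(get_preset("wt_ca"), pts$conc_mM)
  expect_true(all(abs(pts$mean_ph50 - truth) <
                    3 * 0.11 / sqrt(200)))
})

test_that("gating occupancies are conserved and rest closed", {
  m <- gating_model()
  sched <- data.frame(pH = c(7.8, 5.0, 7.4), ca_mM = 2,
                      duration_s = c(20, 10, 40),
                      stim = c(FALSE, TRUE, FALSE))
  tr <- simulate_three_state_trace(m, sched)
  expect_lt(max(abs(tr$C + tr$O + tr$D - 1)), 1e-9)
  expect_true(all(tr$C >= -1e-9 & tr$O >= -1e-9 & tr$D >= -1e-9))
  # no activation at pH 7.8
  expect_lt(max(tr$O[tr$step == 1]), 1e-3)
  # acidic stimulation opens transiently, then desensitizes
  expect_gt(max(tr$O[tr$step == 2]), 0.05)
  expect_error(
    simulate_three_state_trace(m, data.frame(pH = 7, ca_mM = 2,
                                             duration_s = -1)),
    "schedule error")
})

test_that("lower Ca2+ shifts the simulated activation curve alkaline", {
  m <- gating_model()
  mids <- vapply(c(1e-4, 0.5, 2, 10), function(ca) {
    curve <- gating_activation_curve(m, ca_mM = ca)
    fit_hill(curve, "activation")$estimate$pH50
  }, numeric(1))
  # monotone: more Ca2+, more acidic midpoint
  expect_true(all(diff(mids) < 0))
  # the 2 mM vs 100 nM shift approaches the closed-form competition limit
  shift <- mids[1] - mids[3]
  expect_equal(shift, log10(1 + 2 / 3.5), tolerance = 0.02)
})
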