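test_that("normalization follows the protocol's reference", {
  act <- normalize_series(
    data.frame(stimulus = c(7, 6, 5), peak_nA = c(-1000, -2000, -4000)),
    "activation")
  expect_equal(act$response, c(0.25, 0.5, 1.0))
  one <- normalize_series(data.frame(stimulus = 6, peak_nA = -3000),
                          "activation")
  expect_equal(one$response, 1)
  rec <- normalize_series(
    data.frame(stimulus = c(10, Inf), peak_nA = c(-1500, -3000)),
    "recovery")
  expect_equal(rec$response[1], 0.5)
  expect_error(
    normalize_series(data.frame(stimulus = c(10, Inf),
                                peak_nA = c(-1, 0)), "recovery"),
    "degenerate-series")
  expect_error(
    normalize_series(data.frame(stimulus = 10, peak_nA = -1), "recovery"),
    "control")
})

test_that("Hill fits recover noiseless parameters and the midpoint identity", {
  pH <- c(7.4, 7.1, 6.9, 6.7, 6.5, 6.3, 6.0, 5.0)
  dat <- hill_points(pH, 6.5, 1.5)
  fit <- fit_hill(dat, "activation")
  expect_equal(fit$estimate$pH50, 6.5, tolerance = 1e-6)
  expect_equal(fit$estimate$nH, 1.5, tolerance = 1e-6)
  expect_equal(fit$estimate$Imax, 1, tolerance = 1e-6)
  # the fitted curve passes Imax/2 exactly at the fitted midpoint
  with(fit$estimate,
       expect_equal(Imax / (1 + 10^(nH * (pH50 - pH50))), Imax / 2))
  # SSD: availability falls with conditioning acidity
  ssd <- hill_points(seq(7.8, 6.6, length.out = 8), 7.14, 3,
                     activation = FALSE)
  fit2 <- fit_hill(ssd, "ssd")
  expect_equal(fit2$estimate$pHD50, 7.14, tolerance = 1e-6)
  expect_equal(fit2$estimate$nH, 3, tolerance = 1e-6)
  expect_error(fit_hill(dat[1:3, ], "activation"), "4 distinct")
})

test_that("fits are idempotent under refitting their own curve", {
  pH <- seq(7.6, 5.2, length.out = 9)
  fit <- fit_hill(hill_points(pH, 6.4, 2.2, Imax = 0.97), "activation")
  regen <- with(fit$estimate,
                data.frame(stimulus = pH,
                           response = Imax / (1 + 10^(nH * (pH - pH50)))))
  fit2 <- fit_hill(regen, "activation")
  expect_equal(unlist(fit2$estimate), unlist(fit$estimate),
               tolerance = 1e-9)
})

test_that("inhibition fits recover the curve and its half-block identity", {
  x <- c(0.1, 1, 3, 10, 30, 100)
  resp <- 1 / (1 + x / 9.6)
  fit <- fit_inhibition(data.frame(stimulus = x, response = resp))
  expect_equal(fit$estimate$IC50, 9.6, tolerance = 1e-6)
  expect_equal(fit$estimate$nH, 1, tolerance = 1e-6)
  expect_equal(fit$estimate$NonIn, 0, tolerance = 1e-6)
  # at x = IC50 with NonIn = 0 the curve is at half of Imax
  with(fit$estimate,
       expect_equal(NonIn + (Imax - NonIn) / (1 + (IC50 / IC50)^nH),
                    Imax / 2, tolerance = 1e-6))
  expect_error(
    fit_inhibition(data.frame(stimulus = x, response = rep(1, 6))),
    "unidentifiable")
  # fixed-slope variant used for midpoint-vs-concentration curves
  ph <- 6.01 + 0.77 / (1 + x / 3.5)
  fitc <- fit_inhibition(data.frame(stimulus = x, response = ph),
                         fix_nH = 1)
  expect_equal(fitc$estimate$IC50, 3.5, tolerance = 1e-6)
  expect_equal(fitc$estimate$nH, 1)
})

test_that("recovery fits return the time constant and 1 - 1/e point", {
  t <- c(1, 2.5, 5, 10, 20, 40)
  fit <- fit_recovery(data.frame(stimulus = t,
                                 response = 1 - exp(-t / 4)))
  expect_equal(fit$estimate$tau, 4, tolerance = 1e-6)
  expect_equal(fit$estimate$Imax, 1, tolerance = 1e-6)
  with(fit$estimate,
       expect_equal(Imax * (1 - exp(-tau / tau)), Imax * (1 - exp(-1))))
  expect_error(fit_recovery(data.frame(stimulus = t[1:3],
                                       response = (1:3) / 3)),
               "4 intervals")
})

test_that("onset fits recover tau and the non-desensitizing plateau", {
  t <- c(2.5, 5, 10, 20, 40, 80, 160, 300)
  resp <- 0.05 + 0.95 * exp(-t / 63.6)
  fit <- fit_onset(data.frame(stimulus = t, response = resp))
  expect_equal(fit$estimate$tau, 63.6, tolerance = 1e-5)
  expect_equal(fit$estimate$NonDes, 0.05, tolerance = 1e-6)
  # long-time limit of the fitted curve is the plateau
  with(fit$estimate,
       expect_equal(NonDes + (Imax - NonDes) * exp(-1e9 / tau), NonDes))
  expect_error(fit_onset(data.frame(stimulus = t, response = rep(0.5, 8))),
               "unidentifiable")
})
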