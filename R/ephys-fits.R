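#' Normalize a peak-current series
#'
#' Peak currents are recorded as signed (inward-negative) amplitudes; all
#' downstream fitting uses magnitudes of normalized responses.
#' Activation and steady-state desensitization (SSD) series are divided by
#' the series maximum magnitude, so their normalized maximum is exactly 1.
#' Recovery and onset series are divided by the magnitude of a designated
#' control response: the record with `stimulus == Inf` for recovery (a
#' fully recovered interval) and `stimulus == 0` for onset (no
#' desensitizing exposure).
#'
#' @param records Data frame for one oocyte/protocol/condition with at
#'   least `stimulus` and `peak_nA`.
#' @param protocol One of `"activation"`, `"ssd"`, `"inhibition"`,
#'   `"recovery"`, `"onset"`.
#' @return The records with an added `response` column (dimensionless
#'   magnitude).
#' @export
#' @examples
#' normalize_series(data.frame(stimulus = c(7, 6, 5),
#'                             peak_nA = c(-1000, -2000, -4000)),
#'                  "activation")
normalize_series <- function(records,
                             protocol = c("activation", "ssd", "inhibition",
                                          "recovery", "onset")) {
  protocol <- match.arg(protocol)
  if (!nrow(records)) stop("empty-input: no records", call. = FALSE)
  amp <- abs(records$peak_nA)
  ref <- switch(protocol,
    activation = ,
    ssd = ,
    inhibition = max(amp),
    recovery = {
      ctrl <- amp[is.infinite(records$stimulus)]
      if (!length(ctrl)) {
        stop("recovery series needs a control record (stimulus = Inf)",
             call. = FALSE)
      }
      ctrl[1]
    },
    onset = {
      ctrl <- amp[records$stimulus == 0]
      if (!length(ctrl)) {
        stop("onset series needs a control record (stimulus = 0)",
             call. = FALSE)
      }
      ctrl[1]
    })
  if (!is.finite(ref) || ref == 0) {
    stop("degenerate-series: zero control/maximal amplitude", call. = FALSE)
  }
  records$response <- amp / ref
  records
}

# least squares over a list of start values, boxed; returns the best nlsLM
# fit or NULL
multistart_nls <- function(formula, data, starts, lower, upper) {
  best <- NULL
  best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-10, ptol = 1e-10))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  best
}

se_or_na <- function(fit, params) {
  out <- setNames(rep(NA_real_, length(params)), params)
  s <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (!is.null(s)) {
    hit <- intersect(rownames(s), params)
    out[hit] <- s[hit, "Std. Error"]
  }
  out
}

new_casite_fit <- function(subclass, estimate, se, fit, data, extra = list()) {
  structure(c(list(estimate = estimate, se = se,
                   rss = sum(resid(fit)^2),
                   n = nrow(data), data = data,
                   converged = TRUE), extra),
            class = c(subclass, "casite_fit"))
}

#' @export
print.casite_fit <- function(x, ...) {
  cat("<", class(x)[1], "> n = ", x$n, ", rss = ",
      formatC(x$rss, digits = 4, format = "g"), "\n", sep = "")
  est <- x$estimate
  se <- x$se[names(est)]
  for (p in names(est)) {
    cat(sprintf("  %-6s %10.5g  (se %.3g)\n", p, est[[p]], se[[p]]))
  }
  invisible(x)
}

#' Hill fit of pH dependence
#'
#' Fits `I = Imax / (1 + (10^-pH50 / 10^-pH)^nH)` by unweighted least
#' squares, i.e. `I = Imax / (1 + 10^(nH (pH - pH50)))`: the response
#' rises towards `Imax` as the stimulation pH becomes more acidic. For
#' steady-state desensitization the analogous reflected form is used (the
#' response, channel availability, falls with conditioning acidity) and
#' the midpoint is reported as pHD50. A 5-point multistart grid on the
#' midpoint guards against local minima; bounds are pH50 in [3, 9] and
#' nH in (0, 10].
#'
#' @param series Data frame with `stimulus` (pH) and `response`
#'   (normalized magnitude), e.g. from [normalize_series()].
#' @param kind `"activation"` or `"ssd"`.
#' @return A `hill_fit` with estimates `Imax`, `pH50`, `nH`, standard
#'   errors and diagnostics.
#' @export
fit_hill <- function(series, kind = c("activation", "ssd")) {
  kind <- match.arg(kind)
  series <- series[is.finite(series$stimulus) & is.finite(series$response), ]
  if (length(unique(series$stimulus)) < 4) {
    stop("fit-failure: need >= 4 distinct pH values", call. = FALSE)
  }
  s <- if (kind == "activation") 1 else -1
  dat <- data.frame(pH = series$stimulus, I = series$response, s = s)
  starts <- lapply(seq(min(dat$pH), max(dat$pH), length.out = 5),
                   function(m) list(Imax = max(dat$I), pH50 = m, nH = 2))
  fit <- multistart_nls(
    I ~ Imax / (1 + 10^(s * nH * (pH - pH50))), dat, starts,
    lower = c(Imax = 1e-6, pH50 = 3, nH = 1e-3),
    upper = c(Imax = 100, pH50 = 9, nH = 10))
  if (is.null(fit)) {
    stop("fit-failure: Hill fit did not converge; residual response range ",
         paste(range(dat$I), collapse = " - "), call. = FALSE)
  }
  est <- as.list(coef(fit))
  out <- new_casite_fit("hill_fit", est, se_or_na(fit, names(est)), fit, dat,
                        extra = list(kind = kind))
  names(out$estimate) <- c("Imax", if (kind == "ssd") "pHD50" else "pH50",
                           "nH")
  names(out$se) <- names(out$estimate)
  out
}

#' Inhibition-curve fit
#'
#' Fits `I = NonIn + (Imax - NonIn) / (1 + (x / IC50)^nH)` against
#' concentration (mM). `Imax` is the response at the near-zero reference
#' concentration and `NonIn` the non-inhibited floor. The same routine
#' fits midpoint-versus-concentration curves (pH50 values as the
#' response) to extract the apparent affinity of divalent modulation.
#'
#' @param series Data frame with `stimulus` (concentration, mM) and
#'   `response`.
#' @param fix_nH Optional fixed Hill slope. Pore-block concentration-
#'   response curves are fitted with `nH` free (default); for
#'   midpoint-versus-concentration curves a single competing site implies
#'   a unit slope, so those fits pass `fix_nH = 1`.
#' @return An `inhibition_fit` with `Imax`, `NonIn`, `IC50`, `nH`.
#' @export
fit_inhibition <- function(series, fix_nH = NULL) {
  series <- series[is.finite(series$stimulus) & is.finite(series$response), ]
  if (length(unique(series$stimulus)) < 4) {
    stop("fit-failure: need >= 4 concentrations", call. = FALSE)
  }
  if (diff(range(series$response)) < 1e-12) {
    stop("unidentifiable: all responses equal", call. = FALSE)
  }
  dat <- data.frame(x = series$stimulus, I = series$response)
  pos <- dat$x[dat$x > 0]
  grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = 5))
  if (is.null(fix_nH)) {
    starts <- lapply(grid, function(m) {
      list(Imax = max(dat$I), NonIn = min(dat$I), IC50 = m, nH = 1)
    })
    fit <- multistart_nls(
      I ~ NonIn + (Imax - NonIn) / (1 + (x / IC50)^nH), dat, starts,
      lower = c(Imax = 1e-6, NonIn = 0, IC50 = 1e-4, nH = 1e-3),
      upper = c(Imax = 100, NonIn = 100, IC50 = 1e3, nH = 10))
  } else {
    dat$nH <- fix_nH
    starts <- lapply(grid, function(m) {
      list(Imax = max(dat$I), NonIn = min(dat$I), IC50 = m)
    })
    fit <- multistart_nls(
      I ~ NonIn + (Imax - NonIn) / (1 + (x / IC50)^nH), dat, starts,
      lower = c(Imax = 1e-6, NonIn = 0, IC50 = 1e-4),
      upper = c(Imax = 100, NonIn = 100, IC50 = 1e3))
  }
  if (is.null(fit)) stop("fit-failure: inhibition fit did not converge",
                         call. = FALSE)
  est <- as.list(coef(fit))
  if (!is.null(fix_nH)) est$nH <- fix_nH
  if (est$NonIn > est$Imax) {
    stop("fit-failure: fitted NonIn exceeds Imax", call. = FALSE)
  }
  new_casite_fit("inhibition_fit", est, se_or_na(fit, names(est)), fit, dat)
}

#' Exponential kinetics fits
#'
#' `fit_recovery()` fits the single-exponential rise
#' `I = Imax (1 - e^(-t/tau))` of recovery from desensitization;
#' `fit_onset()` fits the decay to a plateau
#' `I = NonDes + (Imax - NonDes) e^(-t/tau)` of desensitization onset,
#' where `NonDes` is the non-desensitizing fraction. Stimulus is the
#' interval/conditioning duration in seconds; control records (`Inf` for
#' recovery) are excluded from the fit after normalization.
#'
#' @param series Data frame with `stimulus` (s) and `response`.
#' @return An `exp_fit` with `Imax`, `tau` (and `NonDes` for onset).
#' @export
fit_recovery <- function(series) {
  series <- series[is.finite(series$stimulus) & is.finite(series$response), ]
  if (length(unique(series$stimulus)) < 4) {
    stop("fit-failure: need >= 4 intervals", call. = FALSE)
  }
  dat <- data.frame(t = series$stimulus, I = series$response)
  grid <- exp(seq(log(max(min(dat$t[dat$t > 0]), 1e-3)),
                  log(max(dat$t)), length.out = 5))
  starts <- lapply(grid, function(m) list(Imax = max(dat$I), tau = m))
  fit <- multistart_nls(
    I ~ Imax * (1 - exp(-t / tau)), dat, starts,
    lower = c(Imax = 1e-6, tau = 1e-6),
    upper = c(Imax = 100, tau = 1e5))
  if (is.null(fit) || coef(fit)[["tau"]] <= 0) {
    stop("fit-failure: recovery fit did not yield a positive tau",
         call. = FALSE)
  }
  est <- as.list(coef(fit))
  new_casite_fit("exp_fit", est, se_or_na(fit, names(est)), fit, dat,
                 extra = list(kind = "recovery"))
}

#' @rdname fit_recovery
#' @export
fit_onset <- function(series) {
  series <- series[is.finite(series$stimulus) & is.finite(series$response), ]
  if (length(unique(series$stimulus)) < 4) {
    stop("fit-failure: need >= 4 conditioning durations", call. = FALSE)
  }
  if (diff(range(series$response)) < 1e-12) {
    stop("unidentifiable: constant series has no time constant",
         call. = FALSE)
  }
  dat <- data.frame(t = series$stimulus, I = series$response)
  grid <- exp(seq(log(max(min(dat$t[dat$t > 0]), 1e-3)),
                  log(max(dat$t)), length.out = 5))
  starts <- lapply(grid, function(m) {
    list(Imax = max(dat$I), NonDes = min(dat$I), tau = m)
  })
  fit <- multistart_nls(
    I ~ NonDes + (Imax - NonDes) * exp(-t / tau), dat, starts,
    lower = c(Imax = 1e-6, NonDes = 0, tau = 1e-6),
    upper = c(Imax = 100, NonDes = 100, tau = 1e5))
  if (is.null(fit) || coef(fit)[["tau"]] <= 0) {
    stop("fit-failure: onset fit did not yield a positive tau",
         call. = FALSE)
  }
  est <- as.list(coef(fit))
  new_casite_fit("exp_fit", est, se_or_na(fit, names(est)), fit, dat,
                 extra = list(kind = "onset"))
}
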