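hill_response <- function(pH, mid, nH, s) 1 / (1 + 10^(s * nH * (pH - mid)))

# default stimulus grids per protocol
protocol_grid <- function(protocol) {
  switch(protocol,
    activation = c(7.4, 7.1, 6.9, 6.7, 6.5, 6.3, 6.0, 5.0),
    ssd = c(7.8, 7.6, 7.45, 7.3, 7.15, 7.0, 6.8, 6.6),
    inhibition = c(0.1, 1, 3, 10, 30),
    recovery = c(1, 2.5, 5, 10, 20, 40, 80, 160),
    onset = c(2.5, 5, 10, 20, 40, 80, 160, 300),
    stop("unknown protocol '", protocol, "'", call. = FALSE))
}

#' Simulate per-oocyte peak-current tables
#'
#' Draws each oocyte's true parameters from the preset (high-divalent
#' midpoint from a normal; the low-divalent midpoint as the high one plus
#' an independent per-oocyte paired shift; kinetics time constants with
#' independent mean-1 lognormal multipliers per arm), evaluates the
#' protocol's response equation on its stimulus grid, and applies
#' multiplicative measurement noise `(1 + N(0, sigma))`. Both condition
#' arms are emitted for the same oocyte, so the table supports paired
#' analyses directly. Peak currents are stored inward-negative in nA.
#'
#' Stimulus grids: activation, 8 pH points 7.4 to 5.0; SSD, 8 conditioning
#' pH points 7.8 to 6.6; inhibition, 0.1/1/3/10/30 mM at pH 5.5 (single
#' arm); recovery and onset, interval ladders in seconds plus the control
#' record (`Inf` for recovery, `0` for onset).
#'
#' @param protocol One of `"activation"`, `"ssd"`, `"inhibition"`,
#'   `"recovery"`, `"onset"`.
#' @param preset An `ephys_preset` or registry key string.
#' @param n_oocytes Number of oocytes (>= 1).
#' @param seed Integer seed.
#' @return A tibble with columns `oocyte_id`, `construct`, `protocol`,
#'   `divalent`, `conc_mM`, `stimulus`, `peak_nA`.
#' @export
#' @examples
#' head(simulate_peak_series("activation", "wt_ca", n_oocytes = 2, seed = 1))
simulate_peak_series <- function(protocol, preset, n_oocytes, seed) {
  if (is.character(preset)) preset <- get_preset(preset)
  stopifnot(inherits(preset, "ephys_preset"))
  if (!is.numeric(n_oocytes) || n_oocytes < 1) {
    stop("domain error: n_oocytes must be >= 1", call. = FALSE)
  }
  protocol <- match.arg(protocol, c("activation", "ssd", "inhibition",
                                    "recovery", "onset"))
  grid <- protocol_grid(protocol)
  sigma <- preset$noise_sigma %||% 0.03
  with_seed(seed, {
    rows <- lapply(seq_len(n_oocytes), function(i) {
      oid <- sprintf("oo%03d", i)
      imax <- -stats::rlnorm(1, log(5000), 0.3)  # inward peak, nA
      noisy <- function(v) v * (1 + stats::rnorm(length(v), 0, sigma))
      emit <- function(conc, stim, resp) {
        tibble(oocyte_id = oid, construct = preset$construct,
               protocol = protocol, divalent = preset$divalent,
               conc_mM = conc, stimulus = stim, peak_nA = imax * resp)
      }
      if (protocol %in% c("activation", "ssd")) {
        p <- preset[[protocol]]
        s <- if (protocol == "activation") 1 else -1
        mid_high <- stats::rnorm(1, p$mid_high, p$sd_high)
        mid_low <- mid_high + stats::rnorm(1, p$delta_mean, p$delta_sd)
        dplyr::bind_rows(
          emit(p$conc_high, grid,
               noisy(hill_response(grid, mid_high, p$nH, s))),
          emit(p$conc_low, grid,
               noisy(hill_response(grid, mid_low, p$nH, s))))
      } else if (protocol == "inhibition") {
        p <- preset$inhibition
        resp <- p$NonIn + (1 - p$NonIn) / (1 + (grid / p$IC50)^p$nH)
        emit(p$conc_mM, grid, noisy(resp))
      } else {
        k <- preset$kinetics[[protocol]]
        if (is.null(k)) {
          stop("preset has no ", protocol, " kinetics", call. = FALSE)
        }
        sdlog <- sqrt(log(1 + k$cv^2))
        taus <- c(high = k$tau_high, low = k$tau_low) *
          stats::rlnorm(2, -sdlog^2 / 2, sdlog)
        out <- lapply(c("high", "low"), function(arm) {
          tau <- taus[[arm]]
          conc <- if (arm == "high") k$conc_high else k$conc_low
          if (protocol == "recovery") {
            stim <- c(grid, Inf)
            resp <- c(1 - exp(-grid / tau), 1)
          } else {
            stim <- c(0, grid)
            resp <- c(1, k$NonDes + (1 - k$NonDes) * exp(-grid / tau))
          }
          emit(conc, stim, noisy(resp))
        })
        dplyr::bind_rows(out)
      }
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulated midpoints along the divalent-modulation curve
#'
#' Generates per-concentration mean pH50 values on the preset's
#' pH50-versus-concentration curve with between-oocyte normal noise,
#' emulating the activation midpoints measured at several free divalent
#' concentrations.
#'
#' @param preset An `ephys_preset` (or key) with a `ph50_vs_ca` curve.
#' @param conc_mM Concentration grid (mM).
#' @param n_per_conc Oocytes per concentration.
#' @param seed Integer seed.
#' @return A tibble with `conc_mM`, `mean_ph50`, `sd_ph50`, `n`.
#' @export
simulate_ph50_curve <- function(preset,
                                conc_mM = c(1e-4, 0.1, 1, 3, 10, 30),
                                n_per_conc = 20, seed = 3) {
  if (is.character(preset)) preset <- get_preset(preset)
  truth <- ph50_vs_conc(preset, conc_mM)
  sdo <- preset$ph50_vs_ca$oocyte_sd
  with_seed(seed, {
    dplyr::bind_rows(lapply(seq_along(conc_mM), function(j) {
      vals <- stats::rnorm(n_per_conc, truth[j], sdo)
      tibble(conc_mM = conc_mM[j], mean_ph50 = mean(vals),
             sd_ph50 = stats::sd(vals), n = n_per_conc)
    }))
  })
}

#' Write or read a peak-record table
#'
#' Plain-CSV persistence of the `oocyte_id,construct,protocol,divalent,
#' conc_mM,stimulus,peak_nA` contract.
#'
#' @param records Peak-record tibble.
#' @param path CSV path.
#' @return `path` invisibly / the tibble.
#' @export
write_peak_series <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_series
#' @export
read_peak_series <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("oocyte_id", "construct", "protocol", "divalent", "conc_mM",
            "stimulus", "peak_nA")
  if (!all(need %in% names(tab))) {
    stop("peak table must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  as_tibble(tab)
}
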