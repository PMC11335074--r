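#' Three-state gating model with proton/Ca2+ competition
#'
#' A minimal closed (C) / open (O) / desensitized (D) scheme in which
#' protons drive both activation and desensitization and Ca2+ competes
#' with protons for the same sites, shifting the apparent proton
#' affinities: `pK_app = pK0 - log10(1 + [Ca] / K_Ca)`. Transition rates
#' are
#' `k_CO = k1 * theta_a`, `k_OC = k2 * (1 - theta_a)`, `k_OD = k3`,
#' `k_CD = k4 * theta_d`, `k_DC = k5 * (1 - theta_d)`, with
#' `theta_x(pH) = 1 / (1 + 10^(n_x (pH - pK_x,app)))` the proton occupancy
#' of the activation/desensitization sensor.
#'
#' Rate constants are illustrative (chosen for sensible resting/activated
#' behaviour), not fitted to recorded current traces.
#'
#' @param k1,k2,k3,k4,k5 Rate parameters (1/s), all >= 0.
#' @param pk_act,pk_des Zero-Ca2+ proton-binding midpoints of the
#'   activation and desensitization sensors (pH units).
#' @param n_act,n_des Sensor Hill slopes.
#' @param k_ca Ca2+ competition constant (mM).
#' @return A `gating_model`.
#' @export
gating_model <- function(k1 = 2, k2 = 50, k3 = 5, k4 = 0.05, k5 = 0.25,
                         pk_act = 6.70, pk_des = 7.34,
                         n_act = 1.5, n_des = 3, k_ca = 3.5) {
  ks <- c(k1, k2, k3, k4, k5)
  if (any(!is.finite(ks)) || any(ks < 0)) {
    stop("all rates must be finite and >= 0", call. = FALSE)
  }
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
                 pk_act = pk_act, pk_des = pk_des,
                 n_act = n_act, n_des = n_des, k_ca = k_ca),
            class = "gating_model")
}

theta_occ <- function(pH, pk0, n, ca_mM, k_ca) {
  pk_app <- pk0 - log10(1 + ca_mM / k_ca)
  1 / (1 + 10^(n * (pH - pk_app)))
}

#' Integrate the gating model over a perfusion schedule
#'
#' The schedule is a step sequence of solution changes; within each step
#' the pH and free Ca2+ concentration are constant, and the occupancy
#' ODEs are integrated with a stiff-capable adaptive solver
#' (`deSolve::lsoda`, rtol 1e-8). Current is proportional to `-O`
#' (inward). The channel starts fully closed.
#'
#' @param model A [gating_model()].
#' @param schedule Data frame with columns `pH`, `ca_mM`, `duration_s`;
#'   optional logical `stim` marking stimulation steps for peak
#'   extraction.
#' @param dt_out Output sampling interval (s).
#' @return A tibble `time_s`, `pH`, `conc_mM`, `C`, `O`, `D`,
#'   `current_norm` (= -O), `step`; stimulation-step peak occupancies in
#'   the `peaks` attribute (`step`, `pH`, `conc_mM`, `peak_O`).
#' @export
simulate_three_state_trace <- function(model, schedule, dt_out = 0.05) {
  stopifnot(inherits(model, "gating_model"))
  if (any(schedule$duration_s <= 0)) {
    stop("schedule error: step durations must be positive", call. = FALSE)
  }
  state <- c(C = 1, O = 0, D = 0)
  t0 <- 0
  out <- list()
  for (i in seq_len(nrow(schedule))) {
    pH <- schedule$pH[i]
    ca <- schedule$ca_mM[i]
    th_a <- theta_occ(pH, model$pk_act, model$n_act, ca, model$k_ca)
    th_d <- theta_occ(pH, model$pk_des, model$n_des, ca, model$k_ca)
    k_co <- model$k1 * th_a
    k_oc <- model$k2 * (1 - th_a)
    k_od <- model$k3
    k_cd <- model$k4 * th_d
    k_dc <- model$k5 * (1 - th_d)
    deriv <- function(t, y, parms) {
      dC <- -(k_co + k_cd) * y["C"] + k_oc * y["O"] + k_dc * y["D"]
      dO <- k_co * y["C"] - (k_oc + k_od) * y["O"]
      dD <- k_cd * y["C"] + k_od * y["O"] - k_dc * y["D"]
      list(c(dC, dO, dD))
    }
    times <- unique(c(seq(0, schedule$duration_s[i], by = dt_out),
                      schedule$duration_s[i]))
    sol <- deSolve::lsoda(state, times, deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    seg <- as.data.frame(sol)
    out[[i]] <- tibble(time_s = t0 + seg$time, pH = pH, conc_mM = ca,
                       C = seg$C, O = seg$O, D = seg$D,
                       current_norm = -seg$O, step = i)
    last <- seg[nrow(seg), ]
    state <- c(C = last$C, O = last$O, D = last$D)
    t0 <- t0 + schedule$duration_s[i]
  }
  trace <- dplyr::bind_rows(out)
  stim <- if ("stim" %in% names(schedule)) which(schedule$stim) else integer()
  peaks <- dplyr::bind_rows(lapply(stim, function(i) {
    seg <- trace[trace$step == i, ]
    tibble(step = i, pH = schedule$pH[i], conc_mM = schedule$ca_mM[i],
           peak_O = max(seg$O))
  }))
  attr(trace, "peaks") <- peaks
  trace
}

#' Peak activation curve of the gating model
#'
#' Runs, for each stimulation pH, a brief alkaline conditioning step
#' followed by a stimulation step, and collects the peak open occupancy --
#' the simulated analogue of a peak-current pH-dependence measurement.
#'
#' @param model A [gating_model()].
#' @param stim_pH Stimulation pH grid.
#' @param ca_mM Free Ca2+ concentration (mM) in both solutions.
#' @param cond_pH Conditioning pH.
#' @param cond_s,stim_s Step durations (s).
#' @return A tibble `stimulus` (pH), `response` (peak O, normalized to
#'   the grid maximum).
#' @export
gating_activation_curve <- function(model, stim_pH = protocol_grid("activation"),
                                    ca_mM = 2, cond_pH = 7.8,
                                    cond_s = 20, stim_s = 10) {
  peaks <- vapply(stim_pH, function(p) {
    sched <- tibble(pH = c(cond_pH, p), ca_mM = ca_mM,
                    duration_s = c(cond_s, stim_s), stim = c(FALSE, TRUE))
    tr <- simulate_three_state_trace(model, sched)
    attr(tr, "peaks")$peak_O
  }, numeric(1))
  tibble(stimulus = stim_pH, response = peaks / max(peaks))
}
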