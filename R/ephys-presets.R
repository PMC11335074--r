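#' Registry of electrophysiology presets
#'
#' Each preset encodes, as simulation ground truth, the population
#' parameters of a construct/divalent combination: activation and SSD
#' midpoints with between-oocyte s.d. for the high- and low-divalent arms
#' (the low arm is parameterized as the high arm plus a per-oocyte paired
#' shift), Hill slopes, the pore-block inhibition curve, the
#' midpoint-versus-concentration curve of divalent modulation, and
#' exponential kinetics with lognormal between-oocyte variability.
#'
#' Hill coefficients are not constrained by published estimates; the
#' registry assumes nH = 1.5 for activation and 3 for SSD (SSD curves are
#' visibly steeper). Concentrations are mM throughout; "100 nM free
#' Ca2+" is stored as 1e-4 mM.
#'
#' @return Named list of `ephys_preset` objects. Registry keys:
#'   `wt_ca`, `wt_mg`, `wt_kinetics`, `wt_inhibition`, `asic1b`,
#'   `nonmodulated`, and the shift presets `ap_act`, `d409a`, `ap_ssd`,
#'   `cv_ssd`, `asic1b_cv_ssd`.
#' @export
#' @examples
#' names(ephys_presets())
#' ephys_presets()[["wt_ca"]]$activation
ephys_presets <- function() {
  act <- function(mid, sd, conc_high, conc_low, dmean, dsd, nH = 1.5) {
    list(mid_high = mid, sd_high = sd, conc_high = conc_high,
         conc_low = conc_low, delta_mean = dmean, delta_sd = dsd, nH = nH)
  }
  registry <- list(
    wt_ca = list(
      construct = "WT", divalent = "Ca",
      activation = act(6.50, 0.12, 2, 1e-4, 0.25, 0.09),
      ssd = act(7.14, 0.04, 2, 0.1, 0.28, 0.05, nH = 3),
      inhibition = list(IC50 = 9.6, nH = 1, NonIn = 0, conc_mM = 2,
                        stim_pH = 5.5),
      ph50_vs_ca = list(floor = 6.01, ceiling = 6.78, IC50 = 3.5, nH = 1,
                        oocyte_sd = 0.11),
      kinetics = list(
        recovery = list(tau_high = 4.0, tau_low = 22.8,
                        conc_high = 2, conc_low = 0.1, cv = 0.4),
        onset = list(tau_high = 63.6, tau_low = 3.9, NonDes = 0.05,
                     conc_high = 2, conc_low = 0.1, cv = 0.4)),
      noise_sigma = 0.03),
    wt_mg = list(
      construct = "WT", divalent = "Mg",
      activation = act(6.59, 0.11, 2, 1e-4, 0.13, 0.07),
      ssd = act(6.97, 0.07, 10, 0.1, 0.39, 0.03, nH = 3),
      noise_sigma = 0.03),
    asic1b = list(
      construct = "ASIC1b", divalent = "Ca",
      activation = act(6.13, 0.06, 2, 1e-4, 0.20, 0.07),
      ssd = act(7.13, 0.07, 2, 0.1, 0.24, 0.06, nH = 3),
      noise_sigma = 0.03),
    nonmodulated = list(
      construct = "nonmodulated", divalent = "Ca",
      activation = act(6.50, 0.12, 2, 1e-4, 0, 0.05),
      ssd = act(7.14, 0.04, 2, 0.1, 0, 0.03, nH = 3),
      noise_sigma = 0.03)
  )
  # mutant / variant presets defined by their printed paired shifts
  shift_preset <- function(construct, which, dmean, dsd) {
    base <- registry$wt_ca
    base$construct <- construct
    base[[which]]$delta_mean <- dmean
    base[[which]]$delta_sd <- dsd
    base
  }
  registry$ap_act <- shift_preset("AP-Act", "activation", 0.10, 0.09)
  registry$d409a <- shift_preset("D409A", "activation", 0.41, 0.09)
  registry$ap_ssd <- shift_preset("AP-SSD", "ssd", 0.05, 0.11)
  registry$cv_ssd <- shift_preset("CV-SSD", "ssd", 0.13, 0.03)
  asic1b_cv <- registry$asic1b
  asic1b_cv$construct <- "ASIC1b CV-SSD"
  asic1b_cv$ssd$delta_mean <- -0.14
  asic1b_cv$ssd$delta_sd <- 0.30
  registry$asic1b_cv_ssd <- asic1b_cv
  registry$wt_kinetics <- registry$wt_ca
  registry$wt_kinetics$construct <- "WT"
  registry$wt_inhibition <- registry$wt_ca
  lapply(registry, function(p) structure(p, class = "ephys_preset"))
}

#' Fetch one preset from the registry
#'
#' @param name Registry key (see [ephys_presets()]).
#' @return An `ephys_preset`.
#' @export
get_preset <- function(name) {
  reg <- ephys_presets()
  if (!name %in% names(reg)) {
    stop("registry error: unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

#' Midpoint-versus-concentration curve of a preset
#'
#' Evaluates the preset's pH50-versus-divalent-concentration curve
#' `floor + (ceiling - floor) / (1 + (x / IC50)^nH)`.
#'
#' @param preset An `ephys_preset` with a `ph50_vs_ca` entry.
#' @param conc_mM Concentrations (mM).
#' @return Numeric pH50 values.
#' @export
ph50_vs_conc <- function(preset, conc_mM) {
  p <- preset$ph50_vs_ca
  if (is.null(p)) stop("preset has no ph50_vs_ca curve", call. = FALSE)
  p$floor + (p$ceiling - p$floor) / (1 + (conc_mM / p$IC50)^p$nH)
}

#' Analytic percent block of an inhibition preset
#'
#' Evaluates `100 * (1 - I(x) / Imax)` from the preset's inhibition
#' parameters via the inhibition equation with `Imax = 1`.
#'
#' @param preset An `ephys_preset` with an `inhibition` entry.
#' @param conc_mM Concentration (mM).
#' @return Percent inhibition of the maximal current.
#' @export
#' @examples
#' percent_block(get_preset("wt_inhibition"), 10)
percent_block <- function(preset, conc_mM) {
  p <- preset$inhibition
  if (is.null(p)) stop("preset has no inhibition curve", call. = FALSE)
  I <- p$NonIn + (1 - p$NonIn) / (1 + (conc_mM / p$IC50)^p$nH)
  100 * (1 - I)
}
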