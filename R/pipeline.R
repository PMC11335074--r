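#' Run the full trajectory screening pipeline
#'
#' Distance table, pre-screen, departure detection, second-passage mask,
#' refinement and per-group metrics in one call, with a run manifest
#' (configuration echo, per-stage row counts, output paths). Deterministic
#' given its inputs.
#'
#' @param input A [traj_bundle()], or a preset name understood by
#'   [preset_bundle()].
#' @param config A [screening_config()].
#' @param seed Seed forwarded to [preset_bundle()] when `input` is a
#'   preset name.
#' @param out_dir Optional output directory; when given, the report,
#'   distance table and manifest are written there.
#' @return A list with `report` ([candidate_report()]), `table`,
#'   `departures` and `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_traj_pipeline("escape", seed = 7)
#' res$report[res$report$candidate, "group_id"]
#' }
run_traj_pipeline <- function(input, config = screening_config(), seed = 1,
                              out_dir = NULL) {
  bundle <- if (is.character(input)) preset_bundle(input, seed = seed)
            else input
  validate_traj_bundle(bundle)
  report <- candidate_report(bundle, config)
  table <- build_distance_table(bundle, config$screen_interval)
  manifest <- list(
    stage = "traj_pipeline",
    config = unclass(config),
    seed = if (is.character(input)) seed else NULL,
    preset = if (is.character(input)) input else NULL,
    n_segments = length(bundle$segments),
    n_ions = length(bundle_ions(bundle)),
    n_groups = length(bundle_groups(bundle)),
    n_distance_records = nrow(table),
    n_candidates = sum(report$candidate),
    outputs = list())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(out_dir, "candidate_report.csv")
    p2 <- file.path(out_dir, "distance_table.csv")
    write_candidate_report(report, p1)
    write_distance_table(table, p2)
    manifest$outputs <- list(report = p1, table = p2)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(report = report, table = table,
       departures = attr(report, "departures"), manifest = manifest)
}

# split a peak table into arms by concentration; low = smaller conc
arm_of <- function(records) {
  concs <- sort(unique(records$conc_mM))
  if (length(concs) == 1) {
    return(rep("single", nrow(records)))
  }
  ifelse(records$conc_mM == concs[1], "low", "high")
}

# per-oocyte midpoint (or tau) fits for one arm of a peak table
fit_arm <- function(records, protocol) {
  param <- switch(protocol, activation = "pH50", ssd = "pHD50",
                  recovery = , onset = "tau", inhibition = "IC50")
  ids <- unique(records$oocyte_id)
  vals <- vapply(ids, function(oid) {
    ser <- normalize_series(records[records$oocyte_id == oid, ], protocol)
    fit <- switch(protocol,
      activation = fit_hill(ser, "activation"),
      ssd = fit_hill(ser, "ssd"),
      inhibition = fit_inhibition(ser),
      recovery = fit_recovery(ser[is.finite(ser$stimulus), ]),
      onset = fit_onset(ser))
    fit$estimate[[param]]
  }, numeric(1))
  tibble(oocyte_id = ids, value = vals)
}

#' Run the electrophysiology analysis pipeline
#'
#' Normalizes and fits every oocyte in both condition arms, then computes
#' the paired midpoint shift (low-divalent minus high-divalent), the
#' paired t-test across arms, and for kinetics protocols the per-oocyte
#' tau ratios.
#'
#' @param input A peak-record tibble (see [simulate_peak_series()] /
#'   [read_peak_series()]) or a preset registry key.
#' @param protocol Protocol name.
#' @param n_oocytes,seed Used only when `input` is a preset key.
#' @param out_dir Optional output directory for CSV/JSON artefacts.
#' @return A list with `fits` (per oocyte and arm), `shift`
#'   ([paired_shift()]), `stats` (paired t), `tau_ratio` (kinetics
#'   protocols) and `manifest`.
#' @export
#' @examples
#' res <- run_ephys_pipeline("wt_ca", "activation", n_oocytes = 5, seed = 1)
#' res$shift
run_ephys_pipeline <- function(input, protocol, n_oocytes = 20, seed = 1,
                               out_dir = NULL) {
  protocol <- match.arg(protocol, c("activation", "ssd", "inhibition",
                                    "recovery", "onset"))
  peaks <- if (is.character(input)) {
    simulate_peak_series(protocol, input, n_oocytes, seed)
  } else {
    as_tibble(input)
  }
  peaks <- peaks[peaks$protocol == protocol, ]
  if (!nrow(peaks)) stop("empty-input: no records for protocol '", protocol,
                         "'", call. = FALSE)
  peaks$arm <- arm_of(peaks)
  arms <- unique(peaks$arm)
  fits <- dplyr::bind_rows(lapply(arms, function(a) {
    f <- fit_arm(peaks[peaks$arm == a, ], protocol)
    f$arm <- a
    f
  }))
  shift <- NULL
  stats_out <- NULL
  ratio <- NULL
  if (all(c("low", "high") %in% arms)) {
    f_low <- fits[fits$arm == "low", c("oocyte_id", "value")]
    f_high <- fits[fits$arm == "high", c("oocyte_id", "value")]
    if (protocol %in% c("activation", "ssd")) {
      shift <- paired_shift(f_low, f_high)
    }
    if (protocol %in% c("recovery", "onset")) {
      ratio <- tau_ratio(f_low, f_high, protocol)
    }
    long <- dplyr::bind_rows(
      tibble(id = f_low$oocyte_id, value = f_low$value, group = "low"),
      tibble(id = f_high$oocyte_id, value = f_high$value, group = "high"))
    stats_out <- tryCatch(compare_groups(long, "paired-t"),
                          error = function(e) NULL)
  }
  manifest <- list(
    stage = "ephys_pipeline", protocol = protocol,
    preset = if (is.character(input)) input else NULL,
    seed = if (is.character(input)) seed else NULL,
    n_oocytes = length(unique(peaks$oocyte_id)),
    n_records = nrow(peaks), n_fits = nrow(fits),
    outputs = list())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(out_dir, "fits.csv")
    utils::write.csv(as.data.frame(fits), p1, row.names = FALSE)
    manifest$outputs$fits <- p1
    summ <- list(
      shift = if (!is.null(shift)) shift[c("mean", "sd", "n")],
      tau_ratio = if (!is.null(ratio)) ratio[c("mean", "sd", "n")],
      paired_t = if (!is.null(stats_out)) {
        stats_out[c("statistic", "p_value", "n")]
      })
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(fits = fits, shift = shift, stats = stats_out, tau_ratio = ratio,
       manifest = manifest)
}
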