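#' Screening configuration for ion-carboxylate contact analysis
#'
#' Bundles every threshold of the two-step candidate-residue screen: a
#' coarse pre-screen retaining ion/group pairs that ever approach within
#' `screen_cutoff`, a fine re-measurement of retained pairs at
#' `refine_interval`, and a residency criterion (distance below
#' `candidate_cutoff` during at least `min_fraction` of a segment's
#' sampled frames). Distances are in Angstrom, times in nanoseconds;
#' nothing is converted silently.
#'
#' All distance thresholds are applied strictly (`<`), matching the
#' "smaller than"/"closer than" reading used throughout the analysis.
#'
#' @param screen_interval Coarse sampling interval for the pre-screen (ns).
#' @param refine_interval Fine sampling interval for retained pairs (ns).
#' @param screen_cutoff Pre-screen retention cutoff (Angstrom).
#' @param candidate_cutoff Residency cutoff for candidacy (Angstrom).
#' @param min_fraction Minimum fraction of a segment's sampled frames the
#'   residency criterion must hold for (need not be contiguous).
#' @param occupancy_cutoffs Cutoffs for the reported occupancy fractions
#'   (Angstrom).
#' @param mean_cap Distances above this cap are excluded from the reported
#'   mean ion-group distance (Angstrom).
#' @param departure_radius Distance from the home-vestibule centroid beyond
#'   which an ion is considered to have left the vestibule (Angstrom).
#' @param departure_dwell Minimum time the departure radius must be
#'   exceeded continuously to declare a departure (ns).
#' @return An object of class `screening_config`.
#' @export
#' @examples
#' screening_config(candidate_cutoff = 5)
screening_config <- function(screen_interval = 10,
                             refine_interval = 0.4,
                             screen_cutoff = 10,
                             candidate_cutoff = 6,
                             min_fraction = 0.10,
                             occupancy_cutoffs = c(4, 6, 20),
                             mean_cap = 10,
                             departure_radius = 25,
                             departure_dwell = 5) {
  cfg <- list(
    screen_interval = as.numeric(screen_interval),
    refine_interval = as.numeric(refine_interval),
    screen_cutoff = as.numeric(screen_cutoff),
    candidate_cutoff = as.numeric(candidate_cutoff),
    min_fraction = as.numeric(min_fraction),
    occupancy_cutoffs = sort(as.numeric(occupancy_cutoffs)),
    mean_cap = as.numeric(mean_cap),
    departure_radius = as.numeric(departure_radius),
    departure_dwell = as.numeric(departure_dwell)
  )
  lens <- c(cfg$screen_interval, cfg$refine_interval, cfg$screen_cutoff,
            cfg$candidate_cutoff, cfg$occupancy_cutoffs, cfg$mean_cap,
            cfg$departure_radius, cfg$departure_dwell)
  if (!all(is.finite(lens)) || any(lens <= 0)) {
    stop("all screening lengths and intervals must be positive and finite",
         call. = FALSE)
  }
  if (cfg$candidate_cutoff >= cfg$screen_cutoff) {
    stop("candidate_cutoff must be smaller than screen_cutoff", call. = FALSE)
  }
  if (!is.finite(cfg$min_fraction) || cfg$min_fraction <= 0 ||
      cfg$min_fraction >= 1) {
    stop("min_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(cfg, class = "screening_config")
}

#' @export
print.screening_config <- function(x, ...) {
  cat("Screening configuration\n")
  cat(sprintf("  pre-screen : every %g ns, retain pairs < %g A\n",
              x$screen_interval, x$screen_cutoff))
  cat(sprintf("  refinement : every %g ns, candidate if < %g A during >= %g%% of a segment\n",
              x$refine_interval, x$candidate_cutoff, 100 * x$min_fraction))
  cat(sprintf("  occupancy cutoffs: %s A; mean capped at %g A\n",
              paste(x$occupancy_cutoffs, collapse = ", "), x$mean_cap))
  cat(sprintf("  departure  : > %g A from home centroid for >= %g ns\n",
              x$departure_radius, x$departure_dwell))
  invisible(x)
}

#' Read or write a screening configuration as YAML
#'
#' The YAML file mirrors the fields of [screening_config()] one-for-one.
#'
#' @param path Path to a YAML file.
#' @return `read_screening_config()` returns a `screening_config`;
#'   `write_screening_config()` returns `path` invisibly.
#' @export
read_screening_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(screening_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown screening config fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(screening_config, raw)
}

#' @rdname read_screening_config
#' @param config A `screening_config` object.
#' @export
write_screening_config <- function(config, path) {
  stopifnot(inherits(config, "screening_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
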