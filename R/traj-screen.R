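#' Frame sampling at a fixed interval
#'
#' Selects, for each target time `t0 + k * interval`, the stored frame
#' nearest to it (no interpolation). Used by both the coarse pre-screen
#' and the fine refinement pass.
#'
#' @param times Strictly increasing frame times (ns).
#' @param interval Sampling interval (ns); must be at least the frame
#'   spacing.
#' @return Integer vector of frame indices (unique, increasing).
#' @keywords internal
sample_frame_indices <- function(times, interval) {
  if (interval < min(diff(times)) - 1e-9) {
    stop("sampling interval is finer than the frame spacing", call. = FALSE)
  }
  targets <- seq(times[1], times[length(times)] + 1e-9, by = interval)
  lo <- findInterval(targets, times)
  lo[lo == 0L] <- 1L
  hi <- pmin(lo + 1L, length(times))
  idx <- ifelse(abs(times[lo] - targets) <= abs(times[hi] - targets), lo, hi)
  unique(as.integer(idx))
}

euclid_rows <- function(a, b) sqrt(rowSums((a - b)^2))

#' Build the ion-group distance table
#'
#' For every segment, every (ion, group) pair yields one distance per
#' sampled frame: the Euclidean distance between the ion and the midpoint
#' of the group's two carboxylate oxygens. Frames are sampled every
#' `interval` ns (nearest stored frame, no interpolation), so a 100 ns
#' segment at the default 10 ns interval contributes ten measurements per
#' pair, plus the initial frame.
#'
#' @param bundle A [traj_bundle()].
#' @param interval Sampling interval in ns.
#' @return A tibble of class `distance_table` with columns `segment_id`,
#'   `time_ns`, `ion_id`, `group_id`, `distance`, plus bookkeeping columns
#'   `ion_vestibule` and `group_vestibule` used by the passage mask. The
#'   sampling interval is stored in the `sampling_interval` attribute.
#' @export
build_distance_table <- function(bundle, interval) {
  validate_traj_bundle(bundle)
  out <- vector("list", length(bundle$segments))
  k <- 0L
  for (seg in bundle$segments) {
    idx <- sample_frame_indices(seg$times, interval)
    tt <- seg$times[idx]
    centers <- lapply(seg$groups, function(g) group_center_series(g)[idx, , drop = FALSE])
    for (ion in seg$ions) {
      ipos <- ion$pos[idx, , drop = FALSE]
      for (gi in seq_along(seg$groups)) {
        g <- seg$groups[[gi]]
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          segment_id = seg$segment_id,
          time_ns = tt,
          ion_id = ion$ion_id,
          group_id = g$group_id,
          distance = euclid_rows(ipos, centers[[gi]]),
          ion_vestibule = ion$home_vestibule,
          group_vestibule = if (is.null(g$vestibule)) NA_character_ else g$vestibule
        )
      }
    }
  }
  tab <- dplyr::bind_rows(out[seq_len(k)])
  attr(tab, "sampling_interval") <- interval
  class(tab) <- c("distance_table", class(tab))
  tab
}

#' Bookkeeping count of pre-screen distances
#'
#' The number of distances evaluated in the coarse pre-screen is the plain
#' product of channels, tagged ions per channel, acidic residues, 100 ns
#' segments and samples per segment; this is the bookkeeping twin of the
#' record count of [build_distance_table()].
#'
#' @param n_channels,n_ions_per_channel,n_acidic,n_segments,n_samples
#'   Positive integers.
#' @return The product, as a double (the full-study count exceeds
#'   `.Machine$integer.max` for larger designs).
#' @export
#' @examples
#' count_screening_distances(2, 18, 183, 6, 10)
count_screening_distances <- function(n_channels, n_ions_per_channel,
                                      n_acidic, n_segments, n_samples) {
  args <- c(n_channels, n_ions_per_channel, n_acidic, n_segments, n_samples)
  if (length(args) != 5 || !all(is.finite(args)) || any(args < 1) ||
      any(args != round(args))) {
    stop("all arguments must be positive integers", call. = FALSE)
  }
  prod(as.numeric(args))
}

#' Pre-screen: retain pairs that ever come close
#'
#' Retains every (ion, group) pair with at least one recorded distance
#' strictly below `cutoff`.
#'
#' @param table A `distance_table`.
#' @param cutoff Retention cutoff (Angstrom); strict inequality.
#' @return A tibble with columns `ion_id`, `group_id` (unique pairs).
#' @export
screen_pairs <- function(table, cutoff) {
  if (!nrow(table)) stop("empty-input: distance table has no records",
                         call. = FALSE)
  out <- table %>%
    dplyr::filter(distance < cutoff) %>%
    dplyr::distinct(ion_id, group_id) %>%
    dplyr::arrange(ion_id, group_id)
  attr(out, "sampling_interval") <- NULL
  class(out) <- setdiff(class(out), "distance_table")
  tibble::as_tibble(out)
}

#' Fraction of sampled frames within a cutoff
#'
#' @param distance_series Numeric vector of distances (Angstrom), one per
#'   sampled frame (typically the distance to the closest relevant ion).
#' @param cutoff Cutoff (Angstrom); strict inequality.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' fraction_within(c(3, 5, 7), 6)
fraction_within <- function(distance_series, cutoff) {
  if (!length(distance_series)) {
    stop("empty-input: distance series has no records", call. = FALSE)
  }
  mean(distance_series < cutoff)
}

#' Mean distance with far frames excluded
#'
#' Mean over records with distance at most `cap`; frames farther away are
#' treated as "no contact" and excluded. When no record qualifies the mean
#' is undefined and flagged (`no_contact = TRUE`), never reported as zero.
#'
#' @param distance_series Numeric vector of distances (Angstrom).
#' @param cap Exclusion cap (Angstrom, inclusive).
#' @return A list with `mean` (NA when undefined), `n_used` and
#'   `no_contact`.
#' @export
#' @examples
#' capped_mean_distance(c(4, 6, 12), 10)
capped_mean_distance <- function(distance_series, cap) {
  if (!length(distance_series)) {
    stop("empty-input: distance series has no records", call. = FALSE)
  }
  used <- distance_series[distance_series <= cap]
  if (!length(used)) {
    list(mean = NA_real_, n_used = 0L, no_contact = TRUE)
  } else {
    list(mean = mean(used), n_used = length(used), no_contact = FALSE)
  }
}

#' Vestibule centroids of a bundle
#'
#' The centroid of a vestibule is the mean of its groups' carboxylate
#' centers at the first frame of the first segment; it anchors departure
#' detection.
#'
#' @param bundle A [traj_bundle()].
#' @return Named list of length-3 centroids, one per vestibule label.
#' @export
vestibule_centers <- function(bundle) {
  seg <- bundle$segments[[1]]
  vest <- group_vestibules(bundle)
  labs <- unique(stats::na.omit(vest))
  out <- lapply(labs, function(v) {
    ctrs <- vapply(seg$groups[names(vest)[!is.na(vest) & vest == v]],
                   function(g) group_center(g$o1[1, ], g$o2[1, ]),
                   numeric(3))
    rowMeans(ctrs)
  })
  names(out) <- labs
  out
}

#' Detect a vestibule departure of one ion
#'
#' A departure is declared at the first time the ion's distance to its
#' home-vestibule centroid exceeds `config$departure_radius` continuously
#' for at least `config$departure_dwell` ns; the reported departure time is
#' the start of that excursion.
#'
#' @param times Frame times (ns), concatenated over segments in order.
#' @param pos `n x 3` ion positions aligned with `times`.
#' @param center Either a length-3 centroid or an `n x 3` series aligned
#'   with `times`.
#' @param config A [screening_config()].
#' @return Departure time (ns) or `NULL` if the ion never leaves.
#' @export
detect_departures <- function(times, pos, center, config = screening_config()) {
  if (nrow(pos) != length(times)) {
    stop("alignment error: position series does not match frame times",
         call. = FALSE)
  }
  if (is.matrix(center)) {
    if (nrow(center) != length(times)) {
      stop("alignment error: center series does not match ion frames",
           call. = FALSE)
    }
    d <- euclid_rows(pos, center)
  } else {
    d <- euclid_rows(pos, matrix(center, nrow(pos), 3, byrow = TRUE))
  }
  out <- which(d > config$departure_radius)
  if (!length(out)) return(NULL)
  runs <- split(out, cumsum(c(1L, diff(out) != 1L)))
  for (r in runs) {
    # continuous excursion must span at least the dwell time
    if (times[r[length(r)]] - times[r[1]] >= config$departure_dwell) {
      return(times[r[1]])
    }
  }
  NULL
}

#' Detect departures for every ion of a bundle
#'
#' @param bundle A [traj_bundle()].
#' @param config A [screening_config()].
#' @return A tibble with columns `ion_id`, `vestibule`, `departure_time`
#'   (zero rows when no ion departs).
#' @export
bundle_departures <- function(bundle, config = screening_config()) {
  centers <- vestibule_centers(bundle)
  times <- unlist(lapply(bundle$segments, function(s) s$times),
                  use.names = FALSE)
  rows <- list()
  for (id in bundle_ions(bundle)) {
    home <- bundle$segments[[1]]$ions[[id]]$home_vestibule
    if (!home %in% names(centers)) next
    pos <- do.call(rbind, lapply(bundle$segments,
                                 function(s) s$ions[[id]]$pos))
    t_dep <- detect_departures(times, pos, centers[[home]], config)
    if (!is.null(t_dep)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ion_id = id, vestibule = home, departure_time = t_dep)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(ion_id = character(), vestibule = character(),
                          departure_time = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Second-passage exclusion
#'
#' After an ion has left its home vestibule, any later contact it makes
#' with groups of *other* vestibules is a second passage and is excluded
#' from the analysis: those records are removed. Records before the
#' departure, and records with the ion's own home-vestibule groups, are
#' untouched.
#'
#' @param table A `distance_table` (carries ion/group vestibule columns).
#' @param departures Tibble as returned by [bundle_departures()].
#' @return The masked `distance_table`.
#' @export
apply_passage_mask <- function(table, departures) {
  if (is.null(departures) || !nrow(departures)) return(table)
  att <- attr(table, "sampling_interval")
  dep <- departures %>% dplyr::select(ion_id, departure_time)
  out <- table %>%
    dplyr::left_join(dep, by = "ion_id") %>%
    dplyr::mutate(keep = is.na(departure_time) |
                    time_ns <= departure_time |
                    (!is.na(group_vestibule) &
                       group_vestibule == ion_vestibule)) %>%
    dplyr::filter(keep) %>%
    dplyr::select(-keep, -departure_time)
  attr(out, "sampling_interval") <- att
  class(out) <- c("distance_table", setdiff(class(out), "distance_table"))
  out
}

# refined distance series for one (ion, group) pair, with passage masking;
# returns tibble(segment_id, time_ns, distance, masked)
pair_refined_series <- function(bundle, ion_id, group_id, config,
                                departures = NULL) {
  dep_t <- Inf
  if (!is.null(departures) && nrow(departures)) {
    hit <- departures$departure_time[departures$ion_id == ion_id]
    if (length(hit)) dep_t <- hit[1]
  }
  rows <- lapply(bundle$segments, function(seg) {
    ion <- seg$ions[[ion_id]]
    grp <- seg$groups[[group_id]]
    idx <- sample_frame_indices(seg$times, config$refine_interval)
    d <- euclid_rows(ion$pos[idx, , drop = FALSE],
                     group_center_series(grp)[idx, , drop = FALSE])
    gv <- if (is.null(grp$vestibule)) NA_character_ else grp$vestibule
    masked <- seg$times[idx] > dep_t &
      !(!is.na(gv) && gv == ion$home_vestibule)
    tibble::tibble(segment_id = seg$segment_id, time_ns = seg$times[idx],
                   distance = d, masked = masked)
  })
  dplyr::bind_rows(rows)
}

#' Refine retained pairs and flag candidate groups
#'
#' Recomputes distances at the fine `refine_interval` for the retained
#' pairs only. A group passes a segment when its distance to a retained
#' ion stays below `candidate_cutoff` during at least `min_fraction` of
#' that segment's sampled frames; the below-cutoff frames need not be
#' contiguous. Frames excluded by the second-passage mask can never count
#' towards the criterion but remain in the denominator (the criterion is a
#' fraction of the simulated time). Overall candidacy requires passing in
#' at least one segment.
#'
#' @param bundle A [traj_bundle()].
#' @param pairs Tibble with `ion_id`, `group_id` (from [screen_pairs()]).
#' @param config A [screening_config()].
#' @param departures Optional departure tibble ([bundle_departures()]).
#' @return A list with `flags` (tibble `group_id`, `candidate`) and
#'   `per_segment` (tibble `group_id`, `segment_id`, `best_fraction`,
#'   `pass`).
#' @export
refine_candidates <- function(bundle, pairs, config = screening_config(),
                              departures = NULL) {
  ions <- bundle_ions(bundle)
  groups <- bundle_groups(bundle)
  bad <- !(pairs$ion_id %in% ions & pairs$group_id %in% groups)
  if (any(bad)) {
    stop("unknown-pair: ", pairs$ion_id[bad][1], " / ",
         pairs$group_id[bad][1], " not present in bundle", call. = FALSE)
  }
  seg_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    ser <- pair_refined_series(bundle, pairs$ion_id[i], pairs$group_id[i],
                               config, departures)
    frac <- ser %>%
      dplyr::group_by(segment_id) %>%
      dplyr::summarise(
        fraction = mean(distance < config$candidate_cutoff & !masked),
        .groups = "drop") %>%
      dplyr::mutate(group_id = pairs$group_id[i])
    seg_rows[[i]] <- frac
  }
  per_seg_all <- dplyr::bind_rows(seg_rows)
  all_segments <- vapply(bundle$segments, function(s) s$segment_id,
                         character(1))
  grid <- tidyr::expand_grid(group_id = groups, segment_id = all_segments)
  per_segment <- per_seg_all %>%
    dplyr::group_by(group_id, segment_id) %>%
    dplyr::summarise(best_fraction = max(fraction), .groups = "drop") %>%
    dplyr::right_join(grid, by = c("group_id", "segment_id")) %>%
    dplyr::mutate(best_fraction = ifelse(is.na(best_fraction), 0,
                                         best_fraction),
                  pass = best_fraction >= config$min_fraction) %>%
    dplyr::arrange(group_id, segment_id)
  flags <- per_segment %>%
    dplyr::group_by(group_id) %>%
    dplyr::summarise(candidate = any(pass), .groups = "drop")
  list(flags = flags, per_segment = per_segment)
}

# distance to the closest home-matched ion per refined frame, for one
# group, after passage masking; NULL when the group has no matching ion
closest_ion_series <- function(bundle, group_id, config, departures = NULL) {
  seg1 <- bundle$segments[[1]]
  grp <- seg1$groups[[group_id]]
  gv <- if (is.null(grp$vestibule)) NA_character_ else grp$vestibule
  ivest <- ion_vestibules(bundle)
  match_ids <- if (!is.na(gv)) {
    names(ivest)[ivest == gv]
  } else {
    names(ivest)[vapply(ivest, vestibule_matches_region, logical(1),
                        region = grp$region)]
  }
  if (!length(match_ids)) return(NULL)
  per_ion <- lapply(match_ids, function(id) {
    ser <- pair_refined_series(bundle, id, group_id, config, departures)
    ifelse(ser$masked, Inf, ser$distance)
  })
  template <- pair_refined_series(bundle, match_ids[1], group_id, config,
                                  departures)
  d <- do.call(pmin, per_ion)
  tibble::tibble(segment_id = template$segment_id,
                 time_ns = template$time_ns,
                 distance = d)[is.finite(d), ]
}

#' Full candidate-residue report
#'
#' Runs the whole screening stack: coarse distance table, pre-screen,
#' departure detection, second-passage masking, fine refinement and the
#' per-group occupancy/distance metrics. For each group the occupancy
#' fractions (`fraction_lt_*`, distance to the closest home-matched ion
#' strictly below each cutoff) and the capped mean distance are reported;
#' spreads across subunit copies of the same residue are in the
#' `residue_summary` attribute (both s.d. and s.e.m.).
#'
#' @param bundle A [traj_bundle()].
#' @param config A [screening_config()].
#' @return A tibble of class `candidate_report`, one row per group, with
#'   attributes `config`, `departures`, `per_segment` and
#'   `residue_summary`.
#' @export
candidate_report <- function(bundle, config = screening_config()) {
  validate_traj_bundle(bundle)
  tab <- build_distance_table(bundle, config$screen_interval)
  departures <- bundle_departures(bundle, config)
  tab <- apply_passage_mask(tab, departures)
  pairs <- tryCatch(screen_pairs(tab, config$screen_cutoff),
                    error = function(e) tibble::tibble(ion_id = character(),
                                                       group_id = character()))
  ref <- refine_candidates(bundle, pairs, config, departures)
  seg1 <- bundle$segments[[1]]
  cuts <- config$occupancy_cutoffs
  rows <- lapply(bundle_groups(bundle), function(gid) {
    g <- seg1$groups[[gid]]
    ser <- closest_ion_series(bundle, gid, config, departures)
    fr <- rep(NA_real_, length(cuts))
    cm <- list(mean = NA_real_, n_used = 0L, no_contact = TRUE)
    if (!is.null(ser) && nrow(ser)) {
      fr <- vapply(cuts, function(cc) fraction_within(ser$distance, cc),
                   numeric(1))
      cm <- capped_mean_distance(ser$distance, config$mean_cap)
    }
    out <- tibble::tibble(
      group_id = gid,
      residue_name = g$residue_name,
      residue_number = g$residue_number,
      subunit = g$subunit,
      region = g$region,
      vestibule = if (is.null(g$vestibule)) NA_character_ else g$vestibule
    )
    for (j in seq_along(cuts)) {
      out[[paste0("fraction_lt_", as.character(cuts[j]))]] <- fr[j]
    }
    out$capped_mean_distance <- cm$mean
    out$n_capped <- cm$n_used
    out$no_contact <- cm$no_contact
    out
  })
  rep_tbl <- dplyr::bind_rows(rows) %>%
    dplyr::left_join(ref$flags, by = "group_id") %>%
    dplyr::mutate(candidate = !is.na(candidate) & candidate)
  segs_passed <- ref$per_segment %>%
    dplyr::group_by(group_id) %>%
    dplyr::summarise(segments_passed = sum(pass),
                     segments_total = dplyr::n(), .groups = "drop")
  rep_tbl <- rep_tbl %>% dplyr::left_join(segs_passed, by = "group_id")
  frac_cols <- paste0("fraction_lt_", as.character(cuts))
  residue_summary <- rep_tbl %>%
    dplyr::group_by(residue_name, residue_number, region) %>%
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c(frac_cols, "capped_mean_distance")),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~stats::sd(.x, na.rm = TRUE),
                         sem = ~stats::sd(.x, na.rm = TRUE) /
                           sqrt(sum(!is.na(.x))))),
      n_pairings = dplyr::n(), .groups = "drop")
  structure(rep_tbl,
            class = c("candidate_report", class(rep_tbl)),
            config = config,
            departures = departures,
            per_segment = ref$per_segment,
            residue_summary = residue_summary)
}

#' Fine-resolution distance time courses
#'
#' Full-resolution (refinement-interval) ion-group distance traces for
#' plotting or export.
#'
#' @param bundle A [traj_bundle()].
#' @param ion_id One ion identifier.
#' @param group_ids Character vector of group identifiers.
#' @param interval Sampling interval (ns); defaults to the refinement
#'   interval of the default [screening_config()].
#' @return A tibble with `segment_id`, `time_ns`, `group_id`, `distance`.
#' @export
distance_timecourse <- function(bundle, ion_id, group_ids,
                                interval = screening_config()$refine_interval) {
  if (!ion_id %in% bundle_ions(bundle)) {
    stop("lookup error: unknown ion '", ion_id, "'", call. = FALSE)
  }
  missing_g <- setdiff(group_ids, bundle_groups(bundle))
  if (length(missing_g)) {
    stop("lookup error: unknown group '", missing_g[1], "'", call. = FALSE)
  }
  cfg <- screening_config(refine_interval = interval)
  rows <- lapply(group_ids, function(gid) {
    ser <- pair_refined_series(bundle, ion_id, gid, cfg)
    tibble::tibble(segment_id = ser$segment_id, time_ns = ser$time_ns,
                   group_id = gid, distance = ser$distance)
  })
  dplyr::bind_rows(rows)
}

#' Classify acidic-pocket ions as inner or outer site
#'
#' Acidic-pocket (AP) ions are labelled by their first-frame proximity to
#' anchor residues: the "inner" site lies near the E219/D409-homologous
#' groups, the "outer" site near the E97 homolog. Central-vestibule ions
#' are labelled `CV`. Ties go to `inner_AP` (deterministic).
#'
#' @param bundle A [traj_bundle()].
#' @param reference_groups A list with one entry per acidic pocket, each a
#'   list with `vestibule` (the AP label), `inner` and `outer` (character
#'   vectors of anchor group ids).
#' @return A tibble with `ion_id`, `home_vestibule`, `site` (one of
#'   `inner_AP`, `outer_AP`, `CV`).
#' @export
classify_initial_sites <- function(bundle, reference_groups) {
  seg <- bundle$segments[[1]]
  anchors <- list()
  for (p in reference_groups) anchors[[p$vestibule]] <- p
  centroid_of <- function(ids) {
    miss <- setdiff(ids, names(seg$groups))
    if (length(miss)) {
      stop("configuration error: unknown anchor group '", miss[1], "'",
           call. = FALSE)
    }
    rowMeans(vapply(seg$groups[ids],
                    function(g) group_center(g$o1[1, ], g$o2[1, ]),
                    numeric(3)))
  }
  rows <- lapply(seg$ions, function(ion) {
    if (identical(ion$home_vestibule, "CV")) {
      site <- "CV"
    } else {
      p <- anchors[[ion$home_vestibule]]
      if (is.null(p)) {
        stop("configuration error: no anchors configured for vestibule '",
             ion$home_vestibule, "'", call. = FALSE)
      }
      d_in <- sqrt(sum((ion$pos[1, ] - centroid_of(p$inner))^2))
      d_out <- sqrt(sum((ion$pos[1, ] - centroid_of(p$outer))^2))
      site <- if (d_in <= d_out) "inner_AP" else "outer_AP"
    }
    tibble::tibble(ion_id = ion$ion_id, home_vestibule = ion$home_vestibule,
                   site = site)
  })
  dplyr::bind_rows(rows)
}
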