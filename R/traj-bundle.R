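#' Trajectory bundle: tagged ions and carboxylate groups over time
#'
#' A `traj_bundle` holds one or more simulation segments (nominally 100 ns
#' each). Every segment shares a single frame-time axis across all tagged
#' ions and all acidic-residue carboxylate groups, so distances can be
#' evaluated frame by frame. Coordinates are in Angstrom, times in
#' nanoseconds.
#'
#' @section Structure:
#' * `segments`: named list; each element has `segment_id`, `times`
#'   (strictly increasing numeric vector, ns), `ions` (named list of ion
#'   entries with `ion_id`, `home_vestibule`, `home_site` and an `n x 3`
#'   position matrix `pos`), and `groups` (named list of group entries
#'   with `group_id`, `residue_number`, `residue_name` ("ASP"/"GLU"),
#'   `subunit`, `region` ("AP"/"CV"/"other"), `vestibule` and two `n x 3`
#'   oxygen matrices `o1`, `o2`).
#' * `metadata`: free-form list (number of channels, construct label,
#'   generator ground truth where applicable).
#'
#' @param segments List of segments as described above.
#' @param metadata Optional metadata list.
#' @return A validated `traj_bundle`.
#' @export
traj_bundle <- function(segments, metadata = list()) {
  bundle <- structure(list(segments = segments, metadata = metadata),
                      class = "traj_bundle")
  validate_traj_bundle(bundle)
}

#' @rdname traj_bundle
#' @param bundle A `traj_bundle` to validate.
#' @export
validate_traj_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "traj_bundle"))
  if (!length(bundle$segments)) {
    stop("empty-input: bundle has no segments", call. = FALSE)
  }
  for (seg in bundle$segments) {
    n <- length(seg$times)
    if (n < 2) stop("segment '", seg$segment_id, "' has fewer than 2 frames",
                    call. = FALSE)
    if (any(diff(seg$times) <= 0)) {
      stop("segment '", seg$segment_id, "' times are not strictly increasing",
           call. = FALSE)
    }
    for (ion in seg$ions) {
      if (!all(is.finite(ion$pos))) {
        stop("invalid-coordinate: non-finite ion position in '",
             ion$ion_id, "'", call. = FALSE)
      }
      if (nrow(ion$pos) != n) {
        stop("ion '", ion$ion_id, "' not present in all frames of segment '",
             seg$segment_id, "'", call. = FALSE)
      }
      cv_home <- identical(ion$home_vestibule, "CV")
      if (!is.null(ion$home_site) && !is.na(ion$home_site)) {
        if (cv_home != identical(ion$home_site, "CV")) {
          stop("ion '", ion$ion_id,
               "': home_site is CV if and only if home_vestibule is CV",
               call. = FALSE)
        }
      }
    }
    for (grp in seg$groups) {
      if (!all(is.finite(grp$o1)) || !all(is.finite(grp$o2))) {
        stop("invalid-coordinate: non-finite oxygen position in group '",
             grp$group_id, "'", call. = FALSE)
      }
      if (nrow(grp$o1) != n || nrow(grp$o2) != n) {
        stop("group '", grp$group_id,
             "' must have exactly two oxygen positions per frame of segment '",
             seg$segment_id, "'", call. = FALSE)
      }
      if (!grp$residue_name %in% c("ASP", "GLU")) {
        stop("group '", grp$group_id, "': residue_name must be ASP or GLU",
             call. = FALSE)
      }
      if (!grp$region %in% c("AP", "CV", "other")) {
        stop("group '", grp$group_id, "': region must be AP, CV or other",
             call. = FALSE)
      }
    }
  }
  bundle
}

#' @export
print.traj_bundle <- function(x, ...) {
  seg1 <- x$segments[[1]]
  cat(sprintf("<traj_bundle> %d segment(s), %d ion(s), %d group(s)\n",
              length(x$segments), length(seg1$ions), length(seg1$groups)))
  for (seg in x$segments) {
    cat(sprintf("  %s: %d frames, %.4g - %.4g ns\n", seg$segment_id,
                length(seg$times), min(seg$times), max(seg$times)))
  }
  invisible(x)
}

#' Midpoint of the two carboxylate oxygens
#'
#' The reference point for all ion-residue distances is the unweighted
#' midpoint ("gravity centre") of the two side-chain carboxylate oxygens.
#'
#' @param o1,o2 Numeric length-3 coordinates (Angstrom), or `n x 3`
#'   matrices of positions over frames.
#' @return The midpoint, with the same shape as the inputs.
#' @export
#' @examples
#' group_center(c(0, 0, 0), c(2, 0, 0))
group_center <- function(o1, o2) {
  if (!all(is.finite(o1)) || !all(is.finite(o2))) {
    stop("invalid-coordinate: non-finite input to group_center", call. = FALSE)
  }
  (o1 + o2) / 2
}

# n x 3 matrix of a group's center across a segment's frames
group_center_series <- function(grp) {
  group_center(grp$o1, grp$o2)
}

# named list: ion_id -> home_vestibule, and group_id -> vestibule label
ion_vestibules <- function(bundle) {
  seg <- bundle$segments[[1]]
  vapply(seg$ions, function(i) i$home_vestibule, character(1))
}

group_vestibules <- function(bundle) {
  seg <- bundle$segments[[1]]
  vapply(seg$groups, function(g) {
    v <- g$vestibule
    if (is.null(v) || is.na(v)) NA_character_ else v
  }, character(1))
}

# does an ion's home vestibule match a group's region?
vestibule_matches_region <- function(vestibule, region) {
  if (region == "AP") startsWith(vestibule, "AP") else vestibule == region
}

#' Ion and group identifiers of a bundle
#'
#' @param bundle A `traj_bundle`.
#' @return Character vector of identifiers (taken from the first segment;
#'   the data model requires every particle in every segment).
#' @export
bundle_ions <- function(bundle) names(bundle$segments[[1]]$ions)

#' @rdname bundle_ions
#' @export
bundle_groups <- function(bundle) names(bundle$segments[[1]]$groups)
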