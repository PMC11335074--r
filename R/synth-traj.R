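# run expr with a private RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Configuration for the synthetic-trajectory generator
#'
#' Defines a toy system of static carboxylate groups and diffusing ions.
#' Ions perform an overdamped (Brownian/Langevin) random walk in a field
#' of attractive Gaussian wells planted at chosen groups, inside a
#' reflective sphere. Well depths are in units of kT, so the drift step is
#' `-grad U * D * dt` with `U = sum(-depth * exp(-r^2 / (2 width^2)))`,
#' and the diffusive step has standard deviation `sqrt(2 D dt)` per axis.
#'
#' @param groups Data frame of static groups: `group_id`, `residue_name`
#'   ("ASP"/"GLU"), `residue_number`, `subunit`, `region`, `vestibule`,
#'   `x`, `y`, `z` (carboxylate center, Angstrom). The two oxygens are
#'   placed 1.1 Angstrom either side of the center along x.
#' @param ions Data frame: `ion_id`, `home_vestibule`, `home_site`, `x`,
#'   `y`, `z` (start position).
#' @param wells Data frame: `group_id`, `depth` (kT, > 0), `width`
#'   (Angstrom, > 0) and optional `t_off` (ns; NA = always on). May have
#'   zero rows.
#' @param diffusion Diffusion coefficient D (Angstrom^2/ns).
#' @param timestep Integration and frame-storage step (ns).
#' @param n_segments Number of segments.
#' @param segment_length Nominal segment duration (ns).
#' @param boundary_radius Reflective sphere radius (Angstrom); must
#'   enclose all groups and ion starts.
#' @param seed Integer seed (mandatory; no clock seeding).
#' @param drift_events Optional data frame `ion_id`, `start_ns`, `speed`
#'   (Angstrom/ns), `duration_ns`: a constant outward radial drift (away
#'   from the ion's home-vestibule centroid) used to script vestibule
#'   escapes with a known departure time.
#' @return An object of class `synth_traj_config`.
#' @export
synth_traj_config <- function(groups, ions, wells = NULL,
                              diffusion = 0.5, timestep = 0.1,
                              n_segments = 6, segment_length = 100,
                              boundary_radius = 40, seed = 1,
                              drift_events = NULL) {
  groups <- as_tibble(groups)
  ions <- as_tibble(ions)
  if (is.null(wells)) {
    wells <- tibble(group_id = character(), depth = numeric(),
                    width = numeric(), t_off = numeric())
  }
  wells <- as_tibble(wells)
  if (!"t_off" %in% names(wells)) wells$t_off <- NA_real_
  if (nrow(wells)) {
    stopifnot(all(is.finite(wells$depth)), all(wells$depth > 0),
              all(is.finite(wells$width)), all(wells$width > 0))
    miss <- setdiff(wells$group_id, groups$group_id)
    if (length(miss)) stop("well planted at unknown group '", miss[1], "'",
                           call. = FALSE)
  }
  if (timestep >= segment_length) {
    stop("timestep must be smaller than segment_length", call. = FALSE)
  }
  gr <- sqrt(groups$x^2 + groups$y^2 + groups$z^2)
  if (any(gr >= boundary_radius)) {
    stop("config error: boundary sphere does not enclose all groups",
         call. = FALSE)
  }
  ir <- sqrt(ions$x^2 + ions$y^2 + ions$z^2)
  if (any(ir >= boundary_radius)) {
    stop("config error: ion start position outside the boundary",
         call. = FALSE)
  }
  structure(list(groups = groups, ions = ions, wells = wells,
                 diffusion = diffusion, timestep = timestep,
                 n_segments = n_segments, segment_length = segment_length,
                 boundary_radius = boundary_radius, seed = as.integer(seed),
                 drift_events = drift_events),
            class = "synth_traj_config")
}

#' Generate a synthetic trajectory bundle
#'
#' Integrates the overdamped Langevin dynamics of [synth_traj_config()]
#' and packages the result as a [traj_bundle()]. Ground truth (planted
#' binder groups and scripted departure times) is attached under
#' `metadata$ground_truth`.
#'
#' @param config A [synth_traj_config()].
#' @return A [traj_bundle()].
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "synth_traj_config"))
  dt <- config$timestep
  L <- config$segment_length
  steps_per_seg <- round(L / dt)
  n_steps <- config$n_segments * steps_per_seg
  times <- seq(0, by = dt, length.out = n_steps + 1)
  gx <- as.matrix(config$groups[, c("x", "y", "z")])
  n_ions <- nrow(config$ions)
  n_wells <- nrow(config$wells)
  wells <- config$wells
  wc <- if (n_wells) {
    gx[match(wells$group_id, config$groups$group_id), , drop = FALSE]
  } else {
    matrix(0, 0, 3)
  }
  # home centroids for scripted drifts: mean of home-vestibule group centers
  home_centroid <- function(vest) {
    sel <- !is.na(config$groups$vestibule) & config$groups$vestibule == vest
    if (!any(sel)) return(c(0, 0, 0))
    colMeans(gx[sel, , drop = FALSE])
  }
  drifts <- config$drift_events
  pos <- array(NA_real_, dim = c(n_steps + 1, 3, n_ions))
  x <- as.matrix(config$ions[, c("x", "y", "z")])
  pos[1, , ] <- t(x)
  sig <- sqrt(2 * config$diffusion * dt)
  ddt <- config$diffusion * dt
  R <- config$boundary_radius
  with_seed(config$seed, {
    for (s in seq_len(n_steps)) {
      t_now <- times[s]
      if (n_wells) {
        active <- is.na(wells$t_off) | t_now < wells$t_off
        for (w in which(active)) {
          diff_w <- sweep(x, 2, wc[w, ])
          r2 <- rowSums(diff_w^2)
          coef_w <- wells$depth[w] / wells$width[w]^2 *
            exp(-r2 / (2 * wells$width[w]^2))
          x <- x - diff_w * coef_w * ddt
        }
      }
      if (!is.null(drifts) && nrow(drifts)) {
        for (dr in seq_len(nrow(drifts))) {
          if (t_now >= drifts$start_ns[dr] &&
              t_now < drifts$start_ns[dr] + drifts$duration_ns[dr]) {
            i <- match(drifts$ion_id[dr], config$ions$ion_id)
            hc <- home_centroid(config$ions$home_vestibule[i])
            u <- x[i, ] - hc
            nu <- sqrt(sum(u^2))
            u <- if (nu < 1e-8) c(1, 0, 0) else u / nu
            x[i, ] <- x[i, ] + drifts$speed[dr] * dt * u
          }
        }
      }
      x <- x + matrix(stats::rnorm(n_ions * 3, 0, sig), n_ions, 3)
      rr <- sqrt(rowSums(x^2))
      over <- rr > R
      if (any(over)) {
        x[over, ] <- x[over, , drop = FALSE] * ((2 * R - rr[over]) / rr[over])
      }
      pos[s + 1, , ] <- t(x)
    }
  })
  # carve into segments sharing boundary frames
  segs <- vector("list", config$n_segments)
  for (k in seq_len(config$n_segments)) {
    lo <- (k - 1) * steps_per_seg + 1
    hi <- k * steps_per_seg + 1
    idx <- lo:hi
    ions_k <- lapply(seq_len(n_ions), function(i) {
      list(ion_id = config$ions$ion_id[i],
           home_vestibule = config$ions$home_vestibule[i],
           home_site = config$ions$home_site[i],
           pos = pos[idx, , i])
    })
    names(ions_k) <- config$ions$ion_id
    n_f <- length(idx)
    groups_k <- lapply(seq_len(nrow(config$groups)), function(g) {
      ctr <- gx[g, ]
      o1 <- matrix(ctr + c(1.1, 0, 0), n_f, 3, byrow = TRUE)
      o2 <- matrix(ctr - c(1.1, 0, 0), n_f, 3, byrow = TRUE)
      list(group_id = config$groups$group_id[g],
           residue_number = config$groups$residue_number[g],
           residue_name = config$groups$residue_name[g],
           subunit = config$groups$subunit[g],
           region = config$groups$region[g],
           vestibule = config$groups$vestibule[g],
           o1 = o1, o2 = o2)
    })
    names(groups_k) <- config$groups$group_id
    segs[[k]] <- list(segment_id = sprintf("seg%02d", k),
                      times = times[idx],
                      ions = ions_k, groups = groups_k)
  }
  names(segs) <- vapply(segs, function(s) s$segment_id, character(1))
  truth <- list(
    binders = unique(config$wells$group_id),
    departures = if (!is.null(config$drift_events)) {
      config$drift_events[, c("ion_id", "start_ns")]
    } else {
      NULL
    }
  )
  traj_bundle(segs, metadata = list(
    n_channels = 1, construct = "synthetic",
    config = config, ground_truth = truth))
}

# --- preset layouts ---------------------------------------------------------

wt_like_layout <- function() {
  g <- function(id, name, num, sub, region, vest, x, y, z) {
    tibble(group_id = id, residue_name = name, residue_number = num,
           subunit = sub, region = region, vestibule = vest,
           x = x, y = y, z = z)
  }
  groups <- dplyr::bind_rows(
    # acidic pocket AP-1: inner site cluster
    g("GLU219.A", "GLU", 219L, "A", "AP", "AP-1", -15.0,  0.0,  0.0),
    g("ASP409.A", "ASP", 409L, "A", "AP", "AP-1", -13.2,  0.8,  0.6),
    g("ASP347.A", "ASP", 347L, "A", "AP", "AP-1", -16.4,  1.2, -0.8),
    g("ASP351.A", "ASP", 351L, "A", "AP", "AP-1", -14.6, -1.6,  1.0),
    # acidic pocket AP-1: outer site cluster
    g("GLU97.A",  "GLU",  97L, "A", "AP", "AP-1", -15.0,  9.0,  0.0),
    g("GLU238.A", "GLU", 238L, "A", "AP", "AP-1", -13.6,  9.8,  0.8),
    g("GLU242.A", "GLU", 242L, "A", "AP", "AP-1", -16.2, 10.0, -0.6),
    # AP non-binders, far from every well
    g("ASP237.A", "ASP", 237L, "A", "AP", "AP-1", -15.0, -20.0,  0.0),
    g("GLU355.A", "GLU", 355L, "A", "AP", "AP-1", -11.5, -20.5,  3.0),
    g("GLU177.A", "GLU", 177L, "A", "AP", "AP-1", -20.0, -18.0, -5.0),
    # central vestibule binders
    g("GLU375.A", "GLU", 375L, "A", "CV", "CV",    15.0,  0.0,  0.0),
    g("GLU413.A", "GLU", 413L, "A", "CV", "CV",    16.6,  0.8, -0.6),
    g("GLU418.A", "GLU", 418L, "A", "CV", "CV",    14.0, -1.4,  0.9),
    # CV non-binders
    g("GLU79.A",  "GLU",  79L, "A", "CV", "CV",    15.0, 20.0,  0.0),
    g("ASP433.A", "ASP", 433L, "A", "CV", "CV",    18.0, 18.0, -4.0)
  )
  ions <- tibble(
    ion_id = c("CA_AP1_IN", "CA_AP1_OUT", "CA_CV1"),
    home_vestibule = c("AP-1", "AP-1", "CV"),
    home_site = c("inner_AP", "outer_AP", "CV"),
    x = c(-15.0, -15.0, 15.5),
    y = c(0.3, 9.2, 0.0),
    z = c(0.0, 0.0, 0.1)
  )
  list(groups = groups, ions = ions)
}

#' Preset synthetic bundles with known ground truth
#'
#' * `wt_like`: two clusters of binder groups in one acidic pocket (an
#'   inner site near the E219/D409 homologs and an outer site near the
#'   E97 homolog) plus binder groups in the central vestibule; Gaussian
#'   wells are planted at every binder, and far-away non-binder groups
#'   probe the screen's specificity.
#' * `nonbinding`: the same layout with no wells; ions start between the
#'   clusters and diffuse freely.
#' * `escape`: one acidic-pocket cluster whose wells are switched off at a
#'   known time, with a scripted outward drift, to exercise departure
#'   detection.
#'
#' @param name One of `"wt_like"`, `"nonbinding"`, `"escape"`.
#' @param seed Integer seed.
#' @param n_segments Number of 100 ns segments (defaults: 6 for
#'   `wt_like`/`nonbinding`, matching a 600 ns run; 2 for `escape`).
#' @return A [traj_bundle()] with ground truth in
#'   `metadata$ground_truth`.
#' @export
#' @examples
#' b <- preset_bundle("escape", seed = 7)
#' b$metadata$ground_truth$departures
preset_bundle <- function(name = c("wt_like", "nonbinding", "escape"),
                          seed = 1, n_segments = NULL) {
  name <- match.arg(name)
  lay <- wt_like_layout()
  if (name == "wt_like") {
    binders <- c("GLU219.A", "ASP409.A", "ASP347.A", "ASP351.A",
                 "GLU97.A", "GLU238.A", "GLU242.A",
                 "GLU375.A", "GLU413.A", "GLU418.A")
    wells <- tibble(group_id = binders, depth = 5, width = 2.5,
                    t_off = NA_real_)
    cfg <- synth_traj_config(lay$groups, lay$ions, wells,
                             n_segments = n_segments %||% 6, seed = seed)
  } else if (name == "nonbinding") {
    ions <- lay$ions
    ions$x <- c(0, 0, 0)
    ions$y <- c(0, 5, -5)
    ions$z <- c(0, 0, 0)
    cfg <- synth_traj_config(lay$groups, ions, wells = NULL,
                             n_segments = n_segments %||% 6, seed = seed)
  } else {
    groups <- lay$groups[lay$groups$vestibule == "AP-1", ][1:4, ]
    ions <- lay$ions[1, ]
    # centre the pocket so every direction of escape clears the
    # departure radius well inside the reflective boundary
    groups$x <- groups$x + 15
    ions$x <- ions$x + 15
    wells <- tibble(group_id = groups$group_id, depth = 5, width = 2.5,
                    t_off = 50)
    drift <- tibble(ion_id = ions$ion_id, start_ns = 50, speed = 6,
                    duration_ns = 10)
    cfg <- synth_traj_config(groups, ions, wells,
                             n_segments = n_segments %||% 2, seed = seed,
                             drift_events = drift)
  }
  generate_bundle(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
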