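# Small hand-built bundles and independent brute-force oracles.
# The oracles deliberately use plain loops and their own midpoint/distance
# arithmetic so they share no code path with the package functions.

make_ion <- function(id, pos, home = "AP-1",
                     site = if (home == "CV") "CV" else "inner_AP") {
  list(ion_id = id, home_vestibule = home, home_site = site, pos = pos)
}

make_group <- function(id, o1, o2, name = "GLU", num = 1L, sub = "A",
                       region = "AP", vestibule = "AP-1") {
  list(group_id = id, residue_number = num, residue_name = name,
       subunit = sub, region = region, vestibule = vestibule,
       o1 = o1, o2 = o2)
}

make_bundle <- function(times, ions, groups, segment_id = "seg01") {
  names(ions) <- vapply(ions, function(i) i$ion_id, character(1))
  names(groups) <- vapply(groups, function(g) g$group_id, character(1))
  seg <- list(segment_id = segment_id, times = times, ions = ions,
              groups = groups)
  traj_bundle(stats::setNames(list(seg), segment_id))
}

# static-coordinate bundle: each ion/group held at one position for all
# frames
static_bundle <- function(times, ion_xyz, group_xyz, ...) {
  n <- length(times)
  rep_mat <- function(p) matrix(unlist(p), n, 3, byrow = TRUE)
  ions <- lapply(names(ion_xyz), function(id) {
    make_ion(id, rep_mat(ion_xyz[[id]]))
  })
  groups <- lapply(names(group_xyz), function(id) {
    ctr <- unlist(group_xyz[[id]])
    make_group(id, rep_mat(ctr + c(1, 0, 0)), rep_mat(ctr - c(1, 0, 0)))
  })
  make_bundle(times, ions, groups)
}

# random toy bundle for oracle-equivalence tests
random_toy_bundle <- function(seed, n_frames = 5, n_ions = 3, n_groups = 5) {
  set.seed(seed)
  times <- seq(0, by = 2.5, length.out = n_frames)
  ions <- lapply(seq_len(n_ions), function(i) {
    home <- if (i == n_ions) "CV" else "AP-1"
    make_ion(paste0("ion", i),
             matrix(runif(n_frames * 3, -15, 15), n_frames, 3), home)
  })
  groups <- lapply(seq_len(n_groups), function(g) {
    vest <- if (g %% 2 == 0) "CV" else "AP-1"
    make_group(paste0("grp", g),
               matrix(runif(n_frames * 3, -15, 15), n_frames, 3),
               matrix(runif(n_frames * 3, -15, 15), n_frames, 3),
               region = if (vest == "CV") "CV" else "AP",
               vestibule = vest)
  })
  make_bundle(times, ions, groups)
}

# brute-force distance table: explicit per-frame loops, own nearest-frame
# search and own midpoint arithmetic
oracle_distance_table <- function(bundle, interval) {
  rows <- NULL
  for (seg in bundle$segments) {
    targets <- seq(seg$times[1], max(seg$times) + 1e-9, by = interval)
    idx <- integer(0)
    for (tg in targets) {
      idx <- c(idx, which.min(abs(seg$times - tg)))
    }
    idx <- unique(idx)
    for (ion in seg$ions) {
      for (grp in seg$groups) {
        for (f in idx) {
          ctr <- (grp$o1[f, ] + grp$o2[f, ]) / 2
          d <- sqrt(sum((ion$pos[f, ] - ctr)^2))
          rows <- rbind(rows, data.frame(
            segment_id = seg$segment_id, time_ns = seg$times[f],
            ion_id = ion$ion_id, group_id = grp$group_id, distance = d,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  rows[order(rows$segment_id, rows$ion_id, rows$group_id, rows$time_ns), ]
}

# brute-force pair pre-screen
oracle_screen <- function(oracle_tab, cutoff) {
  keep <- NULL
  for (i in unique(oracle_tab$ion_id)) {
    for (g in unique(oracle_tab$group_id)) {
      d <- oracle_tab$distance[oracle_tab$ion_id == i &
                                 oracle_tab$group_id == g]
      if (any(d < cutoff)) {
        keep <- rbind(keep, data.frame(ion_id = i, group_id = g,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  keep[order(keep$ion_id, keep$group_id), ]
}

# sort a distance table into oracle order for comparison
sorted_table <- function(tab) {
  df <- as.data.frame(tab)[, c("segment_id", "time_ns", "ion_id",
                               "group_id", "distance")]
  df <- df[order(df$segment_id, df$ion_id, df$group_id, df$time_ns), ]
  rownames(df) <- NULL
  df
}

# noiseless response generators for fit self-consistency checks
hill_points <- function(pH, pH50, nH, Imax = 1, activation = TRUE) {
  s <- if (activation) 1 else -1
  data.frame(stimulus = pH, response = Imax / (1 + 10^(s * nH * (pH - pH50))))
}
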