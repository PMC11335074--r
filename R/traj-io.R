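#' Write and read the flat coordinate-table CSV dialect
#'
#' The dialect has columns
#' `segment,time_ns,particle_id,kind,group_id,x,y,z` with `kind` either
#' `ion` or `oxygen`; each carboxylate group contributes two oxygen rows
#' per frame (`<group_id>:O1`, `<group_id>:O2`). Because the flat table
#' cannot carry residue/region/home-site annotations, the writer emits a
#' JSON sidecar `<path>.meta.json` which the reader picks up
#' automatically; without it, groups default to region `"other"` and ions
#' to a `CV` home.
#'
#' @param bundle A [traj_bundle()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bundle_csv <- function(bundle, path) {
  rows <- list()
  for (seg in bundle$segments) {
    tt <- seg$times
    for (ion in seg$ions) {
      rows[[length(rows) + 1L]] <- data.frame(
        segment = seg$segment_id, time_ns = tt, particle_id = ion$ion_id,
        kind = "ion", group_id = "", x = ion$pos[, 1], y = ion$pos[, 2],
        z = ion$pos[, 3])
    }
    for (grp in seg$groups) {
      rows[[length(rows) + 1L]] <- data.frame(
        segment = seg$segment_id, time_ns = tt,
        particle_id = paste0(grp$group_id, ":O1"), kind = "oxygen",
        group_id = grp$group_id, x = grp$o1[, 1], y = grp$o1[, 2],
        z = grp$o1[, 3])
      rows[[length(rows) + 1L]] <- data.frame(
        segment = seg$segment_id, time_ns = tt,
        particle_id = paste0(grp$group_id, ":O2"), kind = "oxygen",
        group_id = grp$group_id, x = grp$o2[, 1], y = grp$o2[, 2],
        z = grp$o2[, 3])
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  seg1 <- bundle$segments[[1]]
  meta <- list(
    ions = lapply(seg1$ions, function(i) {
      list(ion_id = i$ion_id, home_vestibule = i$home_vestibule,
           home_site = i$home_site)
    }),
    groups = lapply(seg1$groups, function(g) {
      list(group_id = g$group_id, residue_name = g$residue_name,
           residue_number = g$residue_number, subunit = g$subunit,
           region = g$region,
           vestibule = if (is.null(g$vestibule) || is.na(g$vestibule)) {
             NULL
           } else {
             g$vestibule
           })
    })
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_bundle_csv
#' @param meta Optional metadata list with `ions` and `groups` entries
#'   (as written in the JSON sidecar); when `NULL` the sidecar
#'   `<path>.meta.json` is used if present.
#' @export
read_bundle_csv <- function(path, meta = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "time_ns", "particle_id", "kind", "group_id",
            "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("coordinate table must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  side <- paste0(path, ".meta.json")
  if (is.null(meta) && file.exists(side)) {
    meta <- jsonlite::read_json(side)
  }
  ion_meta <- list()
  grp_meta <- list()
  if (!is.null(meta)) {
    for (m in meta$ions) ion_meta[[m$ion_id]] <- m
    for (m in meta$groups) grp_meta[[m$group_id]] <- m
  }
  segs <- list()
  for (sid in unique(tab$segment)) {
    sub <- tab[tab$segment == sid, ]
    tt <- sort(unique(sub$time_ns))
    ions <- list()
    for (id in unique(sub$particle_id[sub$kind == "ion"])) {
      rows <- sub[sub$particle_id == id, ]
      rows <- rows[order(rows$time_ns), ]
      m <- ion_meta[[id]]
      ions[[id]] <- list(
        ion_id = id,
        home_vestibule = if (is.null(m)) "CV" else m$home_vestibule,
        home_site = if (is.null(m)) "CV" else m$home_site,
        pos = as.matrix(rows[, c("x", "y", "z")]))
    }
    groups <- list()
    for (gid in unique(sub$group_id[sub$kind == "oxygen"])) {
      oxy <- sub[sub$kind == "oxygen" & sub$group_id == gid, ]
      pids <- sort(unique(oxy$particle_id))
      if (length(pids) != 2) {
        stop("group '", gid, "' must have exactly two oxygen particles",
             call. = FALSE)
      }
      r1 <- oxy[oxy$particle_id == pids[1], ]
      r2 <- oxy[oxy$particle_id == pids[2], ]
      r1 <- r1[order(r1$time_ns), ]
      r2 <- r2[order(r2$time_ns), ]
      m <- grp_meta[[gid]]
      groups[[gid]] <- list(
        group_id = gid,
        residue_number = if (is.null(m)) NA_integer_ else m$residue_number,
        residue_name = if (is.null(m)) "GLU" else m$residue_name,
        subunit = if (is.null(m)) "A" else m$subunit,
        region = if (is.null(m)) "other" else m$region,
        vestibule = if (is.null(m) || is.null(m$vestibule)) {
          NA_character_
        } else {
          m$vestibule
        },
        o1 = as.matrix(r1[, c("x", "y", "z")]),
        o2 = as.matrix(r2[, c("x", "y", "z")]))
    }
    segs[[sid]] <- list(segment_id = sid, times = tt, ions = ions,
                        groups = groups)
  }
  segs <- segs[order(names(segs))]
  traj_bundle(segs)
}

#' Write and read bundles as multi-model PDB
#'
#' Each frame becomes one `MODEL`/`ENDMDL` block: ions as `HETATM` records
#' (atom name `CA`, residue name `CAL` by default) and each carboxylate
#' group as its two side-chain oxygens (`OD1`/`OD2` for Asp, `OE1`/`OE2`
#' for Glu), with the chain identifier carrying the subunit. PDB stores
#' neither time nor region/home annotations, so the reader takes the frame
#' spacing and optional metadata as arguments. Coordinates survive a
#' round trip to 1e-3 Angstrom (fixed three-decimal PDB fields).
#'
#' @param bundle A [traj_bundle()] (segments are concatenated into one
#'   model sequence; shared boundary frames are written once).
#' @param path Output PDB path.
#' @param ion_resname Residue name used for ion records.
#' @return `path`, invisibly.
#' @export
write_bundle_pdb <- function(bundle, path, ion_resname = "CAL") {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(record, serial, name, resname, chain, resno, xyz) {
    sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            record, serial, name, resname, chain, resno,
            xyz[1], xyz[2], xyz[3])
  }
  model <- 0L
  last_t <- -Inf
  for (seg in bundle$segments) {
    for (f in seq_along(seg$times)) {
      if (seg$times[f] <= last_t) next  # shared boundary frame
      last_t <- seg$times[f]
      model <- model + 1L
      writeLines(sprintf("MODEL     %4d", model), con)
      serial <- 0L
      lines <- character(0)
      for (ion in seg$ions) {
        serial <- serial + 1L
        lines <- c(lines, fmt("HETATM", serial, "CA", ion_resname, "X",
                              serial, ion$pos[f, ]))
      }
      for (grp in seg$groups) {
        nms <- if (grp$residue_name == "ASP") c("OD1", "OD2")
               else c("OE1", "OE2")
        serial <- serial + 1L
        lines <- c(lines, fmt("ATOM", serial, nms[1], grp$residue_name,
                              grp$subunit, grp$residue_number, grp$o1[f, ]))
        serial <- serial + 1L
        lines <- c(lines, fmt("ATOM", serial, nms[2], grp$residue_name,
                              grp$subunit, grp$residue_number, grp$o2[f, ]))
      }
      writeLines(lines, con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_bundle_pdb
#' @param dt Frame spacing in ns assigned to successive models.
#' @param segment_length Segment duration in ns used to carve models into
#'   segments (default: everything in one segment).
#' @param ion_meta,group_meta Optional data frames keyed by `ion_id`
#'   (columns `home_vestibule`, `home_site`) and by `group_id` (columns
#'   `region`, `vestibule`); group ids are `<RES><number>.<chain>`.
#' @export
read_bundle_pdb <- function(path, dt, segment_length = NULL,
                            ion_resname = c("CAL", "CA2"),
                            ion_meta = NULL, group_meta = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  xyz <- pdb$xyz  # n_models x 3N
  n_models <- nrow(xyz)
  times <- (seq_len(n_models) - 1) * dt
  is_ion <- atoms$resid %in% ion_resname
  oxy_names <- c("OD1", "OD2", "OE1", "OE2")
  is_oxy <- atoms$resid %in% c("ASP", "GLU") & atoms$elety %in% oxy_names
  coord_of <- function(i) {
    cols <- (3 * (i - 1) + 1):(3 * i)
    xyz[, cols, drop = FALSE]
  }
  ions <- list()
  ion_rows <- which(is_ion)
  for (k in seq_along(ion_rows)) {
    id <- paste0("ION", k)
    m <- NULL
    if (!is.null(ion_meta) && k <= nrow(ion_meta)) m <- ion_meta[k, ]
    if (!is.null(m) && "ion_id" %in% names(m)) id <- m$ion_id
    ions[[id]] <- list(
      ion_id = id,
      home_vestibule = if (is.null(m)) "CV" else m$home_vestibule,
      home_site = if (is.null(m)) "CV" else m$home_site,
      pos = coord_of(ion_rows[k]))
  }
  groups <- list()
  oxy <- atoms[is_oxy, , drop = FALSE]
  oxy$row <- which(is_oxy)
  key <- paste(oxy$resid, oxy$resno, oxy$chain, sep = ".")
  for (kk in unique(key)) {
    sub <- oxy[key == kk, , drop = FALSE]
    if (nrow(sub) != 2) {
      stop("residue ", kk, " does not have exactly two carboxylate oxygens",
           call. = FALSE)
    }
    sub <- sub[order(sub$elety), ]
    gid <- paste0(sub$resid[1], sub$resno[1], ".", sub$chain[1])
    gm <- NULL
    if (!is.null(group_meta)) {
      hit <- which(group_meta$group_id == gid)
      if (length(hit)) gm <- group_meta[hit[1], ]
    }
    groups[[gid]] <- list(
      group_id = gid,
      residue_number = as.integer(sub$resno[1]),
      residue_name = sub$resid[1],
      subunit = sub$chain[1],
      region = if (is.null(gm)) "other" else gm$region,
      vestibule = if (is.null(gm) || is.na(gm$vestibule)) NA_character_
                  else gm$vestibule,
      o1 = coord_of(sub$row[1]),
      o2 = coord_of(sub$row[2]))
  }
  # carve into segments
  if (is.null(segment_length)) {
    seg_breaks <- list(seq_len(n_models))
  } else {
    steps <- round(segment_length / dt)
    n_seg <- ceiling((n_models - 1) / steps)
    seg_breaks <- lapply(seq_len(n_seg), function(k) {
      lo <- (k - 1) * steps + 1
      hi <- min(k * steps + 1, n_models)
      lo:hi
    })
  }
  segs <- lapply(seq_along(seg_breaks), function(k) {
    idx <- seg_breaks[[k]]
    list(segment_id = sprintf("seg%02d", k),
         times = times[idx],
         ions = lapply(ions, function(i) {
           i$pos <- i$pos[idx, , drop = FALSE]; i
         }),
         groups = lapply(groups, function(g) {
           g$o1 <- g$o1[idx, , drop = FALSE]
           g$o2 <- g$o2[idx, , drop = FALSE]
           g
         }))
  })
  names(segs) <- vapply(segs, function(s) s$segment_id, character(1))
  traj_bundle(segs)
}

#' Export screening outputs
#'
#' `write_candidate_report()` writes the per-group report as CSV plus a
#' JSON summary echoing the configuration, departures and per-residue
#' spreads; `write_distance_table()` writes a `distance_table` (or any
#' tibble of distances/time courses) as CSV.
#'
#' @param report A `candidate_report`.
#' @param path Output CSV path (the JSON summary goes to
#'   `<path>.summary.json`).
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  cfg <- attr(report, "config")
  summ <- list(
    config = unclass(cfg),
    departures = attr(report, "departures"),
    residue_summary = attr(report, "residue_summary"),
    n_groups = nrow(report),
    n_candidates = sum(report$candidate)
  )
  jsonlite::write_json(summ, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_candidate_report
#' @param table A tibble (distance table or time course).
#' @export
write_distance_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
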