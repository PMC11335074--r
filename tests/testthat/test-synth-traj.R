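free_config <- function(n_ions = 50, seed = 1, boundary = 500) {
  ions <- tibble::tibble(
    ion_id = sprintf("i%02d", seq_len(n_ions)),
    home_vestibule = "CV", home_site = "CV", x = 0, y = 0, z = 0)
  groups <- tibble::tibble(
    group_id = "g1", residue_name = "GLU", residue_number = 1L,
    subunit = "A", region = "CV", vestibule = "CV", x = 0, y = 0, z = 0)
  synth_traj_config(groups, ions, wells = NULL, n_segments = 1,
                    boundary_radius = boundary, seed = seed)
}

test_that("generation is deterministic under a fixed seed", {
  cfg <- free_config(n_ions = 3, seed = 99)
  expect_identical(generate_bundle(cfg), generate_bundle(cfg))
  b1 <- preset_bundle("escape", seed = 5)
  b2 <- preset_bundle("escape", seed = 5)
  expect_identical(b1$segments[[1]]$ions[[1]]$pos,
                   b2$segments[[1]]$ions[[1]]$pos)
})

test_that("free diffusion satisfies the Einstein relation", {
  cfg <- free_config(n_ions = 50, seed = 7)
  b <- generate_bundle(cfg)
  seg <- b$segments[[1]]
  Tns <- max(seg$times)
  msd <- mean(vapply(seg$ions, function(i) {
    sum((i$pos[nrow(i$pos), ] - i$pos[1, ])^2)
  }, numeric(1)))
  expected <- 6 * cfg$diffusion * Tns
  expect_lt(abs(msd - expected) / expected, 0.20)
})

test_that("well-free displacements have no preferred direction", {
  cfg <- free_config(n_ions = 50, seed = 8)
  b <- generate_bundle(cfg)
  seg <- b$segments[[1]]
  units <- t(vapply(seg$ions, function(i) {
    d <- i$pos[nrow(i$pos), ] - i$pos[1, ]
    d / sqrt(sum(d^2))
  }, numeric(3)))
  # mean unit displacement of n isotropic directions ~ length 1/sqrt(n)
  expect_lt(sqrt(sum(colMeans(units)^2)), 3 / sqrt(50))
})

test_that("a deep well traps its ion and the boundary is respected", {
  groups <- tibble::tibble(
    group_id = "g1", residue_name = "GLU", residue_number = 1L,
    subunit = "A", region = "CV", vestibule = "CV", x = 0, y = 0, z = 0)
  ions <- tibble::tibble(ion_id = "i1", home_vestibule = "CV",
                         home_site = "CV", x = 0, y = 0, z = 0)
  wells <- tibble::tibble(group_id = "g1", depth = 8, width = 2)
  cfg <- synth_traj_config(groups, ions, wells, n_segments = 1, seed = 11,
                           boundary_radius = 40)
  b <- generate_bundle(cfg)
  d <- distance_timecourse(b, "i1", "g1", interval = 0.4)
  expect_gt(fraction_within(d$distance, 6), 0.9)
  for (seg in b$segments) {
    for (ion in seg$ions) {
      expect_true(all(sqrt(rowSums(ion$pos^2)) <= 40 + 1e-9))
    }
  }
})

test_that("config validation rejects impossible geometries", {
  lay <- tibble::tibble(
    group_id = "g1", residue_name = "GLU", residue_number = 1L,
    subunit = "A", region = "CV", vestibule = "CV", x = 0, y = 0, z = 0)
  ion_out <- tibble::tibble(ion_id = "i1", home_vestibule = "CV",
                            home_site = "CV", x = 100, y = 0, z = 0)
  expect_error(synth_traj_config(lay, ion_out, boundary_radius = 40),
               "outside the boundary")
  grp_out <- lay; grp_out$x <- 60
  ion_in <- ion_out; ion_in$x <- 0
  expect_error(synth_traj_config(grp_out, ion_in, boundary_radius = 40),
               "enclose")
  expect_error(
    synth_traj_config(lay, ion_in,
                      wells = tibble::tibble(group_id = "zz", depth = 1,
                                             width = 1)),
    "unknown group")
})

test_that("presets carry usable ground truth", {
  nb <- preset_bundle("nonbinding", seed = 2, n_segments = 2)
  expect_length(nb$metadata$ground_truth$binders, 0)
  rep_nb <- candidate_report(nb)
  expect_false(any(rep_nb$candidate))

  wt <- preset_bundle("wt_like", seed = 2, n_segments = 2)
  # the inner-site ion stays within 6 A of its two anchor groups for most
  # of the run
  for (g in c("GLU219.A", "ASP409.A")) {
    d <- distance_timecourse(wt, "CA_AP1_IN", g)
    expect_gt(fraction_within(d$distance, 6), 0.5)
  }
  expect_error(preset_bundle("mystery"), "arg")
})

test_that("coordinate CSV and multi-model PDB round-trip a bundle", {
  b <- preset_bundle("escape", seed = 9, n_segments = 1)
  td <- withr::local_tempdir()
  csv <- file.path(td, "bundle.csv")
  write_bundle_csv(b, csv)
  b2 <- read_bundle_csv(csv)
  expect_equal(b2$segments[[1]]$times, b$segments[[1]]$times)
  expect_equal(b2$segments[[1]]$ions[["CA_AP1_IN"]]$pos,
               b$segments[[1]]$ions[["CA_AP1_IN"]]$pos,
               ignore_attr = TRUE)
  expect_equal(b2$segments[[1]]$ions[["CA_AP1_IN"]]$home_vestibule, "AP-1")
  expect_equal(b2$segments[[1]]$groups[["GLU219.A"]]$region, "AP")
  # screening results are identical through the round trip
  expect_equal(as.data.frame(build_distance_table(b2, 10)),
               as.data.frame(build_distance_table(b, 10)),
               tolerance = 1e-12)

  pdb <- file.path(td, "bundle.pdb")
  write_bundle_pdb(b, pdb)
  b3 <- read_bundle_pdb(pdb, dt = 0.1)
  expect_equal(b3$segments[[1]]$ions[[1]]$pos,
               b$segments[[1]]$ions[[1]]$pos,
               tolerance = 2e-3, ignore_attr = TRUE)
  expect_equal(b3$segments[[1]]$groups[["GLU219.A"]]$o1,
               b$segments[[1]]$groups[["GLU219.A"]]$o1,
               tolerance = 2e-3, ignore_attr = TRUE)
})
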