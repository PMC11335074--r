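test_that("group center is the unweighted oxygen midpoint", {
  expect_equal(group_center(c(0, 0, 0), c(2, 0, 0)), c(1, 0, 0))
  p <- c(-3.2, 1.5, 8)
  expect_equal(group_center(p, p), p)
  a <- c(1, 2, 3); b <- c(-4, 0, 7)
  expect_equal(group_center(a, b), group_center(b, a))
  expect_error(group_center(c(NaN, 0, 0), b), "invalid-coordinate")
})

test_that("distance table obeys its record-count and distance contracts", {
  # 3-4-5 triangle, one sampled frame
  b <- static_bundle(c(0, 1), list(ion1 = c(0, 0, 0)),
                     list(grpA = c(3, 4, 0)))
  # oxygens are center +/- (1,0,0): midpoint is the center itself
  tab <- build_distance_table(b, interval = 10)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$distance, 5)

  # 2 ions x 3 groups x 10 sampled frames = 60 records
  b2 <- static_bundle(0:9,
                      list(i1 = c(0, 0, 0), i2 = c(5, 5, 5)),
                      list(g1 = c(1, 0, 0), g2 = c(0, 8, 0),
                           g3 = c(-4, 4, 4)))
  tab2 <- build_distance_table(b2, interval = 1)
  expect_equal(nrow(tab2), 60L)
  expect_equal(nrow(tab2),
               count_screening_distances(1, 2, 3, 1, 10))
})

test_that("distance table matches a brute-force frame-by-frame oracle", {
  for (seed in c(11, 12)) {
    b <- random_toy_bundle(seed)
    tab <- build_distance_table(b, interval = 2.5)
    expect_equal(sorted_table(tab), oracle_distance_table(b, 2.5),
                 tolerance = 1e-12)
  }
})

test_that("pre-screen distance bookkeeping multiplies out", {
  expect_equal(count_screening_distances(2, 18, 183, 6, 10), 395280)
  expect_equal(count_screening_distances(1, 1, 1, 1, 1), 1)
  # the alternative per-channel ion count documented alongside the study
  expect_equal(count_screening_distances(2, 9, 183, 6, 10), 197640)
  expect_error(count_screening_distances(0, 1, 1, 1, 1), "positive")
  expect_error(count_screening_distances(2, 1.5, 1, 1, 1), "positive")
})

test_that("pair pre-screen retains strictly-below-cutoff pairs only", {
  b <- static_bundle(c(0, 1),
                     list(i1 = c(0, 0, 0), i2 = c(50, 0, 0)),
                     list(gA = c(9.9, 0, 0), gB = c(10.0, 0, 0)))
  tab <- build_distance_table(b, interval = 1)
  pairs <- screen_pairs(tab, 10)
  expect_true(any(pairs$ion_id == "i1" & pairs$group_id == "gA"))
  # exactly at the cutoff is excluded (strict inequality)
  expect_false(any(pairs$ion_id == "i1" & pairs$group_id == "gB"))
  # oracle equivalence on random bundles
  for (seed in c(21, 22)) {
    bt <- random_toy_bundle(seed)
    tt <- build_distance_table(bt, interval = 2.5)
    got <- as.data.frame(screen_pairs(tt, 12))
    rownames(got) <- NULL
    want <- oracle_screen(oracle_distance_table(bt, 2.5), 12)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("occupancy fraction counts strictly-close frames", {
  expect_equal(fraction_within(c(3, 5, 7), 6), 2 / 3)
  expect_equal(fraction_within(c(3, 5, 7), 0), 0)
  expect_error(fraction_within(numeric(0), 6), "empty-input")
  # monotone nondecreasing in the cutoff on generated series
  set.seed(5)
  for (i in 1:10) {
    d <- runif(50, 0, 25)
    fr <- vapply(c(4, 6, 20), function(cc) fraction_within(d, cc),
                 numeric(1))
    expect_true(all(diff(fr) >= 0))
  }
})

test_that("capped mean excludes far frames and flags no-contact", {
  cm <- capped_mean_distance(c(4, 6, 12), 10)
  expect_equal(cm$mean, 5)
  expect_equal(cm$n_used, 2L)
  d <- c(2, 3, 9.5)
  expect_equal(capped_mean_distance(d, 10)$mean, mean(d))
  nc <- capped_mean_distance(c(11, 12), 10)
  expect_true(nc$no_contact)
  expect_equal(nc$n_used, 0L)
  expect_true(is.na(nc$mean))
})

test_that("departure detection needs a sustained excursion", {
  cfg <- screening_config()
  times <- seq(0, 500, by = 1)
  center <- c(0, 0, 0)
  # ion pinned at the vestibule centre never departs
  still <- matrix(0, length(times), 3)
  expect_null(detect_departures(times, still, center, cfg))
  # step to 30 A at t = 300 ns and stay: event at 300 ns
  pos <- matrix(0, length(times), 3)
  pos[times >= 300, 1] <- 30
  expect_equal(detect_departures(times, pos, center, cfg), 300)
  # a brief 2 ns spike does not trigger (dwell is 5 ns)
  spike <- matrix(0, length(times), 3)
  spike[times >= 100 & times <= 102, 1] <- 30
  expect_null(detect_departures(times, spike, center, cfg))
  expect_error(detect_departures(times[-1], pos, center, cfg), "alignment")
})

test_that("scripted escape is detected near its scheduled time", {
  b <- preset_bundle("escape", seed = 3)
  truth <- b$metadata$ground_truth$departures$start_ns
  dep <- bundle_departures(b)
  expect_equal(nrow(dep), 1L)
  cfg <- screening_config()
  # detection cannot precede the scheduled switch-off and must land
  # within one dwell window of it (the scripted drift clears the radius
  # in ~4 ns)
  expect_gte(dep$departure_time, truth)
  expect_lte(dep$departure_time, truth + cfg$departure_dwell)
})

test_that("second-passage mask removes only post-departure foreign contacts", {
  b <- random_toy_bundle(31)
  tab <- build_distance_table(b, interval = 2.5)
  # no departures: identity
  none <- tibble::tibble(ion_id = character(), vestibule = character(),
                         departure_time = numeric())
  expect_equal(nrow(apply_passage_mask(tab, none)), nrow(tab))
  # ion1 (home AP-1) departs at t = 4: CV-group records after 4 vanish
  dep <- tibble::tibble(ion_id = "ion1", vestibule = "AP-1",
                        departure_time = 4)
  masked <- apply_passage_mask(tab, dep)
  df <- as.data.frame(tab)
  drop_expected <- sum(df$ion_id == "ion1" & df$time_ns > 4 &
                         df$group_vestibule != "AP-1")
  expect_equal(nrow(masked), nrow(tab) - drop_expected)
  expect_false(any(masked$ion_id == "ion1" & masked$time_ns > 4 &
                     masked$group_vestibule == "CV"))
  # pre-departure and home-vestibule records untouched
  expect_equal(sum(masked$ion_id == "ion1" & masked$group_vestibule == "AP-1"),
               sum(df$ion_id == "ion1" & df$group_vestibule == "AP-1"))
})

test_that("residency refinement applies the 10% criterion per segment", {
  mk <- function(frac) {
    n <- 100
    times <- seq(0, 99, by = 1)
    pos <- matrix(c(rep(3, round(frac * n)), rep(9, n - round(frac * n))),
                  ncol = 1)
    pos <- cbind(pos, 0, 0)
    make_bundle(times, list(make_ion("i1", pos)),
                list(make_group("g1", matrix(c(1, 0, 0), n, 3, byrow = TRUE),
                                matrix(c(-1, 0, 0), n, 3, byrow = TRUE))))
  }
  cfg <- screening_config(refine_interval = 1)
  pairs <- tibble::tibble(ion_id = "i1", group_id = "g1")
  # within 6 A during 15% of frames: candidate
  expect_true(refine_candidates(mk(0.15), pairs, cfg)$flags$candidate)
  # only 5%: not a candidate
  expect_false(refine_candidates(mk(0.05), pairs, cfg)$flags$candidate)
  # flags are nondecreasing when the residency threshold is relaxed
  cfg_loose <- screening_config(refine_interval = 1, min_fraction = 0.04)
  expect_true(refine_candidates(mk(0.05), pairs, cfg_loose)$flags$candidate)
  expect_error(
    refine_candidates(mk(0.15),
                      tibble::tibble(ion_id = "nope", group_id = "g1"), cfg),
    "unknown-pair")
})

test_that("initial ion sites are classified against anchor centroids", {
  b <- static_bundle(c(0, 1),
                     list(i1 = c(0, 0, 0), i2 = c(10, 0, 0)),
                     list(inner1 = c(0, 0, 0), outer1 = c(10, 0, 0)))
  refs <- list(list(vestibule = "AP-1", inner = "inner1", outer = "outer1"))
  sites <- classify_initial_sites(b, refs)
  expect_equal(sites$site[sites$ion_id == "i1"], "inner_AP")
  expect_equal(sites$site[sites$ion_id == "i2"], "outer_AP")
  # equidistant tie breaks deterministically to inner
  b_tie <- static_bundle(c(0, 1), list(i1 = c(5, 0, 0)),
                         list(inner1 = c(0, 0, 0), outer1 = c(10, 0, 0)))
  expect_equal(classify_initial_sites(b_tie, refs)$site, "inner_AP")
  expect_error(classify_initial_sites(b, list()), "configuration error")
})

test_that("site classification recovers generator labels", {
  b <- preset_bundle("wt_like", seed = 4, n_segments = 2)
  refs <- list(list(vestibule = "AP-1",
                    inner = c("GLU219.A", "ASP409.A"),
                    outer = "GLU97.A"))
  sites <- classify_initial_sites(b, refs)
  truth <- vapply(b$segments[[1]]$ions, function(i) i$home_site,
                  character(1))
  expect_equal(sites$site[match(names(truth), sites$ion_id)],
               unname(truth))
})

test_that("distance time courses match direct recomputation", {
  b <- random_toy_bundle(41)
  tc <- distance_timecourse(b, "ion1", c("grp1", "grp3"), interval = 2.5)
  orc <- oracle_distance_table(b, 2.5)
  for (g in c("grp1", "grp3")) {
    got <- tc$distance[tc$group_id == g][order(tc$time_ns[tc$group_id == g])]
    want <- orc$distance[orc$ion_id == "ion1" & orc$group_id == g]
    expect_equal(got, want, tolerance = 1e-12)
  }
  # static pair gives a constant trace of full sampled length
  bs <- static_bundle(0:9, list(i1 = c(0, 0, 0)), list(g1 = c(3, 4, 0)))
  tcs <- distance_timecourse(bs, "i1", "g1", interval = 1)
  expect_equal(nrow(tcs), 10L)
  expect_equal(unique(tcs$distance), 5)
  expect_error(distance_timecourse(b, "ghost", "grp1"), "lookup")
  expect_error(distance_timecourse(b, "ion1", "ghost"), "lookup")
})

test_that("candidate report keeps fraction ordering and is deterministic", {
  b <- preset_bundle("wt_like", seed = 6, n_segments = 2)
  rep1 <- candidate_report(b)
  ok <- !is.na(rep1$fraction_lt_4)
  expect_true(all(rep1$fraction_lt_4[ok] <= rep1$fraction_lt_6[ok]))
  expect_true(all(rep1$fraction_lt_6[ok] <= rep1$fraction_lt_20[ok]))
  expect_true(all(rep1$capped_mean_distance[!rep1$no_contact] <= 10))
  rep2 <- candidate_report(b)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
})
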