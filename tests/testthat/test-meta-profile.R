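test_that("single-terminus aggregation lands at the documented offsets", {
  dyads <- feature_set("chrI", 100L, score = 1, kind = "nucleosome_dyad")
  # + strand fragment [95, 260): 5' at 95, offset 95 - 100 = -5
  plus <- fragment_records("chrI", 95L, 260L, "+")
  p <- aggregate_termini(plus, dyads, "five_prime", 50L)
  expect_equal(p$values[p$offsets == -5], 1)
  expect_equal(sum(p$values), 1)
  # - strand fragment [90, 105): 5' at 104, offset 100 - 104 = -4
  minus <- fragment_records("chrI", 90L, 105L, "-")
  p <- aggregate_termini(minus, dyads, "five_prime", 50L)
  expect_equal(p$values[p$offsets == -4], 1)

  # a terminus within the window of two dyads counts toward both
  two <- feature_set(c("chrI", "chrI"), c(100L, 265L), score = c(1, 1),
                     kind = "nucleosome_dyad")
  mid <- fragment_records("chrI", 182L, 300L, "+")  # 5' at 182, within 100 of both
  p <- aggregate_termini(mid, two, "five_prime", 100L)
  expect_equal(p$n_termini, 2L)
  expect_equal(sum(p$values), 2)
})

test_that("aggregation equals the exhaustive double-loop oracle", {
  set.seed(501)
  for (rep in 1:3) {
    frags <- random_fragments(100, max_pos = 2000L, with_junctions = FALSE)
    feats <- feature_set(
      chrom = sample(c("chrA", "chrB"), 10, replace = TRUE),
      midpoint = sample.int(2300L, 10),
      score = stats::runif(10, 1, 10), kind = "nucleosome_dyad")
    for (ek in c("five_prime", "three_prime")) {
      p <- aggregate_termini(frags, feats, ek, 100L)
      expect_equal(p$values, oracle_aggregate(frags, feats, ek, 100L))
      expect_equal(sum(p$values), p$n_termini)  # mass = terminus-feature pairs
    }
  }
})

test_that("aggregation rejects empty features and flags empty fragments", {
  frags <- random_fragments(5)
  empty_feats <- feature_set(character(0), integer(0), score = numeric(0),
                             kind = "nucleosome_dyad")
  expect_error(aggregate_termini(frags, empty_feats), "empty")
  feats <- feature_set("chrA", 100L, score = 1, kind = "nucleosome_dyad")
  p <- aggregate_termini(frags[0, ], feats)
  expect_true(all(p$values == 0))
  expect_true(isTRUE(attr(p, "empty_input")))
})

test_that("moving-average smoothing spreads an impulse and fixes constants", {
  dyads <- feature_set("chrI", 100L, score = 1, kind = "nucleosome_dyad")
  base <- aggregate_termini(fragment_records("chrI", 100L, 200L, "+"),
                            dyads, "five_prime", 10L)
  imp <- base
  imp$values <- rep(0, 21)
  imp$values[imp$offsets == 0] <- 10
  sm <- smooth_profile(imp, 5L)
  expect_equal(sm$values[abs(sm$offsets) <= 2], rep(2, 5))
  expect_equal(sm$values[abs(sm$offsets) > 3], rep(0, 21 - 7))

  expect_equal(smooth_profile(imp, 1L)$values, imp$values)  # identity

  const <- base
  const$values <- rep(3.5, 21)
  expect_equal(smooth_profile(const, 5L)$values, rep(3.5, 21))  # edges too

  expect_error(smooth_profile(imp, 4L), "odd")
})

test_that("max and median normalization rescale exactly and are idempotent", {
  dyads <- feature_set("chrI", 100L, score = 1, kind = "nucleosome_dyad")
  p <- aggregate_termini(fragment_records("chrI", 100L, 200L, "+"),
                         dyads, "five_prime", 1L)
  p$values <- c(2, 4, 8)
  expect_equal(normalize_profile(p, "max")$values, c(0.25, 0.5, 1))
  expect_equal(normalize_profile(p, "median")$values, c(0.5, 1, 2))
  expect_equal(max(normalize_profile(p, "max")$values), 1)
  expect_equal(stats::median(normalize_profile(p, "median")$values), 1)
  once <- normalize_profile(p, "max")
  expect_equal(normalize_profile(once, "max")$values, once$values)

  zero <- p; zero$values <- c(0, 0, 0)
  expect_error(normalize_profile(zero, "max"), "all-zero")
  degenerate <- p; degenerate$values <- c(0, 0, 5)
  expect_error(normalize_profile(degenerate, "median"), "median")
})

test_that("peak location uses the smallest-absolute, then negative, tie-break", {
  dyads <- feature_set("chrI", 100L, score = 1, kind = "nucleosome_dyad")
  p <- aggregate_termini(fragment_records("chrI", 100L, 200L, "+"),
                         dyads, "five_prime", 5L)
  p$values <- rep(0, 11)
  p$values[p$offsets == 0] <- 2
  expect_equal(profile_peak_offset(p), 0L)
  p$values <- rep(0, 11)
  p$values[p$offsets %in% c(-3, 3)] <- 2
  expect_equal(profile_peak_offset(p), -3L)
  p$values <- rep(0, 11)
  expect_error(profile_peak_offset(p), "all-zero")
})

test_that("cross-correlation shift is exact on translated copies", {
  dyads <- feature_set("chrI", 500L, score = 1, kind = "nucleosome_dyad")
  set.seed(502)
  start <- 400L + sample.int(200L, 400, replace = TRUE)
  frags <- fragment_records("chrI", start, start + 150L, "+")
  a <- dyad_profile(frags, dyads, "five_prime", window = 60L, smoothing = 5L)
  b <- a
  b$values <- c(rep(0, 7), a$values[seq_len(length(a$values) - 7)])
  # parabolic sub-bin refinement may move the estimate slightly off the
  # integer lag because truncation breaks exact symmetry at the edges
  expect_equal(compare_profiles(a, b), 7, tolerance = 0.05)
  expect_equal(compare_profiles(a, a), 0, tolerance = 1e-6)

  wrong <- dyad_profile(frags, dyads, "five_prime", window = 50L)
  expect_error(compare_profiles(a, wrong), "window")
})

test_that("decoupling statistic requires one profile of each end kind", {
  dyads <- feature_set("chrI", 500L, score = 1, kind = "nucleosome_dyad")
  set.seed(503)
  start <- 400L + sample.int(200L, 400, replace = TRUE)
  frags <- fragment_records("chrI", start, start + 150L, "+")
  p5 <- dyad_profile(frags, dyads, "five_prime", window = 60L)
  p3 <- dyad_profile(frags, dyads, "three_prime", window = 60L)
  expect_error(end_decoupling_statistic(p3, p3), "five_prime")
  res <- end_decoupling_statistic(p5, p3)
  expect_true(res$verdict %in% c("coupled", "decoupled"))
  # identical profiles are perfectly coupled
  p5b <- p5
  p3b <- p3
  p3b$values <- p5$values
  same <- end_decoupling_statistic(p5b, p3b)
  expect_equal(same$delta, 0, tolerance = 1e-6)
  expect_equal(same$verdict, "coupled")
})

test_that("length autocorrelation finds exact ladders and rejects empty input", {
  ex <- fragment_records("chrI", rep(0L, 300),
                         rep(c(165L, 330L, 495L), each = 100), "+")
  res <- length_autocorrelation(ex)
  expect_equal(res$best_lag, 165L)
  expect_true(isTRUE(res$low_n))
  empty <- fragment_records(character(0), integer(0), integer(0), character(0))
  expect_error(length_autocorrelation(empty), "fragments")
})

test_that("meta-profiles are invariant under a genome-wide mirror", {
  cfg <- test_config(5000, seed = 61)
  g <- build_genome(cfg)
  sim <- simulate_fragments(cfg, g)
  top <- select_top_occupied(g$dyads, 0.5)
  for (ek in c("five_prime", "three_prime")) {
    p <- aggregate_termini(sim$fragments, top, ek, 100L)
    pm <- aggregate_termini(mirror_fragments(sim$fragments, cfg$chrom_lengths),
                            mirror_features(top, cfg$chrom_lengths),
                            ek, 100L)
    expect_identical(p$values, pm$values)
  }
})

test_that("profile TSVs round-trip with their metadata header", {
  cfg <- test_config(2000, seed = 62)
  g <- build_genome(cfg)
  sim <- simulate_fragments(cfg, g)
  top <- select_top_occupied(g$dyads, 0.5)
  p <- dyad_profile(sim$fragments, top, "three_prime")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, path)
  back <- read_profile(path)
  expect_equal(back$values, p$values)
  expect_equal(back$raw_counts, p$raw_counts)
  expect_equal(back$window, p$window)
  expect_equal(back$normalization, p$normalization)
  expect_equal(back$smoothing_bp, p$smoothing_bp)
  expect_equal(back$n_termini, p$n_termini)
})
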