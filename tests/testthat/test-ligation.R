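test_that("junctions are labeled nick / gap / flap_overlap from coordinates", {
  fr <- fragment_records("chrI", c(100L, 200L), c(200L, 300L), c("+", "+"))
  j <- classify_junctions(fr)
  expect_equal(j$label, "nick")
  expect_equal(j$separation, 0L)

  fr <- fragment_records("chrI", c(100L, 205L), c(200L, 300L), c("+", "+"))
  j <- classify_junctions(fr)
  expect_equal(j$label, "gap")
  expect_equal(j$separation, 5L)

  fr <- fragment_records("chrI", c(100L, 195L), c(200L, 300L), c("+", "+"))
  j <- classify_junctions(fr)
  expect_equal(j$label, "flap_overlap")
  expect_equal(j$separation, -5L)

  # different chromosomes or strands: no junction between them
  fr <- fragment_records(c("chrI", "chrII"), c(100L, 200L), c(200L, 300L),
                         c("+", "+"))
  expect_equal(nrow(classify_junctions(fr)), 0L)

  unsorted <- fragment_records("chrI", c(200L, 100L), c(300L, 200L),
                               c("+", "+"))
  expect_error(classify_junctions(unsorted), "sorted")
})

test_that("simulated junction states override coordinate labels", {
  # coordinates abut (a nick) but the 5'-side fragment records a gap
  fr <- fragment_records("chrI", c(100L, 200L), c(200L, 300L), c("+", "+"),
                         junction_state = c(NA, "gap"),
                         junction_len = c(NA, 3L))
  j <- classify_junctions(fr)
  expect_equal(j$label, "gap")
  expect_equal(j$coordinate_label, "nick")
  expect_equal(attr(j, "state_coordinate_mismatches"), 1L)
  expect_equal(nrow(ligate_in_silico(fr)), 2L)

  # on the minus strand the 5'-side fragment of the pair is the left one
  fr <- fragment_records("chrI", c(100L, 200L), c(200L, 300L), c("-", "-"),
                         junction_state = c("nick", "gap"),
                         junction_len = c(NA, 3L))
  j <- classify_junctions(fr)
  expect_equal(j$label, "nick")
  expect_equal(nrow(ligate_in_silico(fr)), 1L)
})

test_that("in-silico ligation merges nick runs and conserves counts and coverage", {
  fr <- fragment_records("chrI", c(100L, 200L), c(200L, 300L), c("+", "+"))
  out <- ligate_in_silico(fr)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 300L)

  chain <- fragment_records("chrI", c(100L, 200L, 300L),
                            c(200L, 300L, 400L), rep("+", 3))
  out <- ligate_in_silico(chain)
  expect_equal(nrow(out), 1L)  # count drops by the 2 nick junctions
  expect_equal(out$end - out$start, sum(chain$end - chain$start))

  apart <- fragment_records("chrI", c(100L, 205L), c(200L, 300L), c("+", "+"))
  expect_equal(ligate_in_silico(apart), apart)
})

test_that("ligation is idempotent and removes exactly the nick junctions", {
  set.seed(601)
  for (rep in 1:5) {
    # chains whose junction states are consistent with their coordinates:
    # the count drops by exactly the number of nick junctions, and the
    # genomic coverage of nick runs is conserved by merging
    fr <- chain_fragments()
    j <- classify_junctions(fr)
    once <- ligate_in_silico(fr)
    expect_equal(nrow(fr) - nrow(once), sum(j$label == "nick"))
    twice <- ligate_in_silico(once)
    expect_equal(twice, once)
    # nick junctions abut, so merging them conserves covered length
    gain <- sum(fr$end - fr$start) - sum(once$end - once$start)
    expect_equal(gain, 0L)
    # mixed / coordinate-labeled data: still idempotent
    mixed <- sort_fragments(random_fragments(40))
    expect_equal(ligate_in_silico(ligate_in_silico(mixed)),
                 ligate_in_silico(mixed))
  }
})

test_that("ligation agrees with the exhaustive pairwise merge oracle", {
  set.seed(602)
  for (rep in 1:6) {
    fr <- sort_fragments(random_fragments(30))
    mine <- ligate_in_silico(fr)
    ref <- oracle_ligate(fr)
    expect_equal(nrow(mine), nrow(ref))
    expect_equal(mine$start, ref$start)
    expect_equal(mine$end, ref$end)
    expect_equal(mine$chrom, ref$chrom)
    expect_equal(mine$strand, ref$strand)
  }
})

test_that("end-label signal counts fragments below the size cutoff", {
  fr <- fragment_records("chrI", c(0L, 0L, 0L), c(150L, 300L, 1200L),
                         rep("+", 3))
  expect_equal(end_label_signal(fr, 1000L), 2L)
  expect_equal(end_label_signal(fr, 1L), 0L)
  empty <- fr[0, ]
  expect_equal(end_label_signal(empty, 1000L), 0L)
})

test_that("percent lost is the relative drop in sub-cutoff signal", {
  pre <- fragment_records("chrI", seq(0L, by = 200L, length.out = 100),
                          seq(0L, by = 200L, length.out = 100) + 150L, "+")
  post <- pre[1:55, ]
  rep1 <- percent_signal_lost(pre, post, 1000L)
  expect_equal(rep1$percent_lost, 45)
  expect_equal(rep1$signal_pre, 100L)

  # no nicks anywhere: ligation changes nothing, no signal lost
  gaps <- fragment_records("chrI", c(100L, 205L), c(200L, 300L), c("+", "+"),
                           junction_state = c("gap", "gap"),
                           junction_len = c(2L, 2L))
  out <- ligate_in_silico(gaps)
  expect_equal(percent_signal_lost(gaps, out)$percent_lost, 0)

  big <- fragment_records("chrI", 0L, 2000L, "+")
  expect_error(percent_signal_lost(big, big, 1000L), "signal")
})

test_that("percent lost on a simulated ensemble matches the oracle pipeline", {
  cfg <- test_config(2000, seed = 71)
  sim <- simulate_fragments(cfg)
  fr <- sort_fragments(sim$fragments)
  small <- utils::head(fr[fr$chrom == "chrT", , drop = FALSE], 40)
  rownames(small) <- NULL
  mine <- percent_signal_lost(small, ligate_in_silico(small))
  ref <- percent_signal_lost(small, oracle_ligate(small))
  expect_equal(mine$percent_lost, ref$percent_lost)
})

test_that("paired t-test matches the closed-form oracle", {
  # worked difference set 2, 4, 6
  minus <- c(10, 12, 14)
  plus <- c(8, 8, 8)
  res <- paired_t_test(minus, plus)
  ref <- oracle_paired_t(minus - plus)
  expect_equal(res$t, ref$t, tolerance = 1e-10)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(res$p, ref$p, tolerance = 1e-10)
  expect_equal(round(res$p, 4), 0.0742)

  near <- paired_t_test(c(5, 5.000001, 4.999999), c(0, 0, 0))
  expect_lt(near$p, 0.001)

  sym <- paired_t_test(c(-1, 1), c(0, 0))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)

  expect_error(paired_t_test(c(1), c(2)), "2")
  expect_error(paired_t_test(c(3, 3), c(1, 1)), "variance")
})
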