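test_that("BED6 fragment lines map directly onto records", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t100\t265\tf1\t0\t+",
               "chrI\t100\t265\tf2\t0\t+\tgap:3",
               "chrII\t40\t90\tf3\t1.5\t-\tnick",
               "chrII\t40\t95\tf4\t0\t-\tflap:7"), path)
  fr <- read_fragments(path)
  expect_equal(nrow(fr), 4)
  expect_equal(fr$chrom[1], "chrI")
  expect_equal(fr$start[1], 100L)
  expect_equal(fr$end[1], 265L)
  expect_equal(fr$strand[1], "+")
  expect_true(is.na(fr$junction_state[1]))
  expect_equal(fr$junction_state[2], "gap")
  expect_equal(fr$junction_len[2], 3L)
  expect_equal(fr$junction_state[3], "nick")
  expect_true(is.na(fr$junction_len[3]))
  expect_equal(fr$junction_state[4], "flap")
  expect_equal(fr$junction_len[4], 7L)
})

test_that("empty fragment files give empty tables and malformed input names the line", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), path)
  expect_equal(nrow(read_fragments(path)), 0)

  writeLines(c("chrI\t1\t10\tf\t0\t+", "chrI\t5\t20"), path)
  expect_error(read_fragments(path), "line 2")
  writeLines("chrI\t1\t10\tf\t0\t.", path)
  expect_error(read_fragments(path), "strand")
  writeLines("chrI\t1\t10\tf\t0\t+\tbroken:x", path)
  expect_error(read_fragments(path), "junction")
})

test_that("write then read is the identity on random fragment tables", {
  set.seed(401)
  for (rep in 1:10) {
    fr <- random_fragments(sample(0:40, 1))
    path <- withr::local_tempfile(fileext = ".bed")
    write_fragments(fr, path)
    back <- read_fragments(path)
    expect_equal(back, fr)
  }
  # junction dialect survives serialization verbatim
  fr <- fragment_records("chrI", 10L, 60L, "+", junction_state = "flap",
                         junction_len = 7L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_fragments(fr, path)
  expect_match(readLines(path), "\tflap:7$")
  # empty in, empty file out
  write_fragments(fr[0, ], path)
  expect_identical(readLines(path), character(0))
})

test_that("terminus extraction follows strand and stays inside the fragment", {
  plus <- fragment_records("chrI", 10L, 20L, "+")
  minus <- fragment_records("chrI", 10L, 20L, "-")
  tp <- fragment_termini(plus)
  tm <- fragment_termini(minus)
  expect_equal(tp$five_prime, 10L)
  expect_equal(tp$three_prime, 19L)
  expect_equal(tm$five_prime, 19L)
  expect_equal(tm$three_prime, 10L)
  # degenerate length-1 fragment: both termini coincide
  one <- fragment_termini(fragment_records("chrI", 10L, 11L, "+"))
  expect_equal(one$five_prime, one$three_prime)
  expect_equal(one$five_prime, 10L)

  set.seed(402)
  fr <- random_fragments(60, with_junctions = FALSE)
  tt <- fragment_termini(fr)
  expect_true(all(tt$five_prime >= fr$start & tt$five_prime < fr$end))
  expect_true(all(tt$three_prime >= fr$start & tt$three_prime < fr$end))
  plus <- fr$strand == "+"
  expect_true(all(tt$five_prime[plus] <= tt$three_prime[plus]))
  expect_true(all(tt$five_prime[!plus] >= tt$three_prime[!plus]))
})

test_that("mirroring fragments mirrors their termini", {
  set.seed(403)
  fr <- random_fragments(50, with_junctions = FALSE)
  L <- c(chrA = 6000L, chrB = 6000L)
  mt <- fragment_termini(mirror_fragments(fr, L))
  tt <- fragment_termini(fr)
  expect_equal(mt$five_prime, L[fr$chrom] - 1L - tt$five_prime,
               ignore_attr = TRUE)
  expect_equal(mt$three_prime, L[fr$chrom] - 1L - tt$three_prime,
               ignore_attr = TRUE)
})

test_that("feature BED reading handles 1-bp and wider intervals", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t500\t501\tn1\t88\t.",
               "chrI\t490\t512\tn2\t12\t+"), path)
  fs <- read_features(path, kind = "nucleosome_dyad")
  expect_equal(fs$midpoint, c(500L, 501L))
  expect_equal(fs$midpoint[2], (490L + 512L) %/% 2L)
  expect_equal(fs$score, c(88, 12))
  expect_equal(fs$orientation, c("none", "+"))
  expect_equal(feature_kind(fs), "nucleosome_dyad")

  writeLines(character(0), path)
  empty <- read_features(path, kind = "tf_site")
  expect_equal(nrow(empty), 0)
  expect_error(aggregate_termini(random_fragments(3), empty), "empty")

  writeLines("chrI\t500\t501\tn1\tNA\t.", path)
  expect_error(read_features(path, kind = "nucleosome_dyad"), "score")
})

test_that("occupancy filtering keeps the top scorers with a deterministic tie-break", {
  fs <- feature_set(rep("chrI", 4), c(10L, 20L, 30L, 40L),
                    score = c(1, 2, 3, 4), kind = "nucleosome_dyad")
  top <- select_top_occupied(fs, 0.5)
  expect_setequal(top$score, c(3, 4))
  expect_equal(select_top_occupied(fs, 1.0)$midpoint, fs$midpoint)

  tie <- feature_set(rep("chrI", 3), c(30L, 10L, 20L),
                     score = c(5, 5, 5), kind = "nucleosome_dyad")
  picked <- select_top_occupied(tie, 0.5)
  expect_equal(nrow(picked), 2)  # ceiling(1.5)
  expect_equal(sort(picked$midpoint), c(10L, 20L))  # (chrom, midpoint) order
  empty <- feature_set(character(0), integer(0), score = numeric(0),
                       kind = "nucleosome_dyad")
  expect_error(select_top_occupied(empty, 0.5), "empty")
  expect_error(select_top_occupied(fs, 0), "fraction")
  expect_error(select_top_occupied(fs, 1.2), "fraction")
})
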