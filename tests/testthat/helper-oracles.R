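# Independent oracles and fixture builders shared across the test files.
# Each oracle re-derives the expected result by a route deliberately
# different from the package implementation (exhaustive loops, closed forms).

# Exhaustive double-loop aggregation: every terminus against every feature.
oracle_aggregate <- function(fragments, features, end_kind, window) {
  counts <- rep(0, 2 * window + 1)
  for (i in seq_len(nrow(fragments))) {
    f <- fragments[i, ]
    t5 <- if (f$strand == "+") f$start else f$end - 1L
    t3 <- if (f$strand == "+") f$end - 1L else f$start
    pos <- if (end_kind == "five_prime") t5 else t3
    for (j in seq_len(nrow(features))) {
      g <- features[j, ]
      if (g$chrom != f$chrom) next
      if (abs(pos - g$midpoint) > window) next
      off <- if (f$strand == "+") pos - g$midpoint else g$midpoint - pos
      counts[off + window + 1] <- counts[off + window + 1] + 1
    }
  }
  counts
}

# Exhaustive in-silico ligation: repeatedly scan for any adjacent
# same-(chrom, strand) pair labeled nick and merge it, until none remain.
# Labeling mirrors the documented rule (simulated junction state of the
# 5'-side fragment wins over coordinates) but is applied one pair at a time.
oracle_ligate <- function(fragments) {
  repeat {
    fragments <- fragments[order(fragments$chrom, fragments$strand,
                                 fragments$start, fragments$end), ,
                           drop = FALSE]
    rownames(fragments) <- NULL
    merged_any <- FALSE
    n <- nrow(fragments)
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        a <- fragments[i, ]; b <- fragments[i + 1, ]
        if (a$chrom != b$chrom || a$strand != b$strand) next
        five_side <- if (a$strand == "+") b else a
        state <- five_side$junction_state
        label <- if (!is.na(state)) {
          if (state == "flap") "flap_overlap" else state
        } else if (b$start == a$end) "nick"
        else if (b$start > a$end) "gap" else "flap_overlap"
        if (label != "nick") next
        head_row <- if (a$strand == "+") {
          if (a$start <= b$start) a else b
        } else {
          if (a$end >= b$end) a else b
        }
        head_row$start <- min(a$start, b$start)
        head_row$end <- max(a$end, b$end)
        fragments <- rbind(fragments[seq_len(n)[-c(i, i + 1)], , drop = FALSE],
                           head_row)
        merged_any <- TRUE
        break
      }
    }
    if (!merged_any) break
  }
  fragments <- fragments[order(fragments$chrom, fragments$start,
                               fragments$end), , drop = FALSE]
  rownames(fragments) <- NULL
  fragments
}

# Closed-form paired t statistic and two-sided p from the reference
# t distribution.
oracle_paired_t <- function(d) {
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# Random valid fragment table on a couple of chromosomes.
random_fragments <- function(n, max_pos = 5000L, with_junctions = TRUE,
                             complete_junctions = FALSE) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(300L, n, replace = TRUE)
  js <- rep(NA_character_, n)
  jl <- rep(NA_integer_, n)
  if (with_junctions) {
    states <- if (complete_junctions) c("nick", "gap", "flap")
              else c(NA, "nick", "gap", "flap")
    pick <- sample(states, n, replace = TRUE)
    js <- pick
    needs <- !is.na(pick) & pick != "nick"
    jl[needs] <- sample.int(20L, sum(needs), replace = TRUE)
  }
  fragment_records(
    chrom = sample(c("chrA", "chrB"), n, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    junction_state = js, junction_len = jl)
}

# Chains of consecutive lagging-strand fragments whose junction states are
# consistent with their coordinates (nick = abutting, gap = separated, flap =
# overlapping by the stated length).  The junction state lives on the
# fragment whose 5' end sits at the junction: the genomic right fragment on
# "+", the left one on "-".
chain_fragments <- function(n_chains = 6, per_chain = 6) {
  rows <- vector("list", n_chains)
  for (cc in seq_len(n_chains)) {
    chrom <- c("chrA", "chrB")[cc %% 2 + 1]
    strand <- c("+", "-")[(cc %/% 2) %% 2 + 1]
    pos <- 5000L * cc
    start <- integer(per_chain); end <- integer(per_chain)
    js <- rep(NA_character_, per_chain); jl <- rep(NA_integer_, per_chain)
    junction_state <- sample(c("nick", "gap", "flap"), per_chain - 1,
                             replace = TRUE)
    junction_len <- sample.int(10L, per_chain - 1, replace = TRUE)
    for (i in seq_len(per_chain)) {
      if (i > 1) {
        st <- junction_state[i - 1]
        off <- switch(st, nick = 0L, gap = junction_len[i - 1],
                      flap = -junction_len[i - 1])
        pos <- end[i - 1] + off
        carrier <- if (strand == "+") i else i - 1L
        js[carrier] <- st
        jl[carrier] <- if (st == "nick") NA_integer_ else junction_len[i - 1]
      }
      start[i] <- pos
      end[i] <- pos + sample(80:200, 1)
    }
    rows[[cc]] <- fragment_records(rep(chrom, per_chain), start, end,
                                   rep(strand, per_chain),
                                   junction_state = js, junction_len = jl)
  }
  sort_fragments(do.call(rbind, rows))
}

# Sort a fragment table the way the ligation module expects.
sort_fragments <- function(fragments) {
  out <- fragments[order(fragments$chrom, fragments$strand, fragments$start,
                         fragments$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Small simulation config without TF-barrier relocation, for tests that
# check the bare terminus draw.
test_config <- function(n_fragments, seed, condition = "WT", ...) {
  simulation_config(
    chrom_lengths = c(chrT = 200000L),
    origins = data.frame(chrom = "chrT", position = 100000L,
                         stringsAsFactors = FALSE),
    tf_barrier_weight = 0,
    n_fragments = as.integer(n_fragments),
    condition = condition, seed = as.integer(seed), ...)
}

# Kolmogorov-Smirnov distance between two profiles read as distributions
# over offsets.
profile_ks_distance <- function(a, b) {
  ca <- cumsum(a$values) / sum(a$values)
  cb <- cumsum(b$values) / sum(b$values)
  max(abs(ca - cb))
}

dyad_profile <- function(fragments, dyads, end_kind, window = 100L,
                         smoothing = 5L, normalization = "max") {
  p <- aggregate_termini(fragments, dyads, end_kind, window)
  normalize_profile(smooth_profile(p, smoothing), normalization)
}
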