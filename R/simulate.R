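#' Conditions of the nuclease-depletion panel
#'
#' The eight strain backgrounds modeled by the simulator: wild type, the three
#' single nuclease depletions (Rad27, Exo1, Dna2), the three pairwise
#' combinations, and the triple.
#'
#' @return character vector of condition names.
#' @export
panel_conditions <- function() {
  c("WT", "rad27", "exo1", "dna2",
    "rad27_exo1", "rad27_dna2", "exo1_dna2", "triple")
}

# Deterministic per-component seed stream; stays below 2^31.
derive_seed <- function(seed, k) {
  ((seed %% 1000003) * 1009 + k * 7919) %% 2147483629L + 1L
}

#' Build a simulation configuration
#'
#' Holds every generative parameter of the lagging-strand fragment simulator.
#' Fragments are nucleosome-repeat sized; their 3' termini are centered on
#' nucleosome dyads with a condition-specific signed shift (negative = toward
#' the replication-fork-proximal nucleosome edge, the signature of reduced
#' nick translation), and the junction at each 5' end is a ligatable nick, a
#' gap or a 5' flap with condition-specific frequencies.
#'
#' Per-condition defaults encode the qualitative regimes of the biology being
#' modeled: a pronounced fork-proximal shift and loss of ligatability without
#' Rad27, a lesser shift without Exo1, no effect of Dna2 depletion, and an
#' additive shift when Rad27 and Exo1 are both absent.  Magnitudes are free
#' parameters of the simulator.
#'
#' @param chrom_lengths named integer vector, chromosome lengths in nt.
#' @param origins data.frame with columns `chrom`, `position`: replication
#'   origins.  Forks move rightward (`+`) right of an origin and leftward
#'   (`-`) left of it; between two origins the boundary sits at their
#'   midpoint.
#' @param nucleosome_repeat nucleosome repeat length in nt (>= 100).
#' @param dyad_jitter_sd SD in nt of the fragment-length jitter around the
#'   repeat-length ladder.
#' @param multi_span_prob probability in `[0, 1)` that a fragment extends
#'   across one further nucleosome (geometric continuation), producing the
#'   ladder of lengths at 1x, 2x, 3x the repeat seen on fragment gels.
#' @param n_fragments number of fragments to draw.
#' @param condition one of [panel_conditions()].
#' @param terminus_shift named numeric, signed 3'-terminus shift in nt per
#'   condition.
#' @param terminus_sd named numeric, SD in nt of terminus placement noise per
#'   condition.
#' @param ligatable_fraction named numeric in `[0, 1]`, probability that a 5'
#'   junction is a ligatable nick, per condition.
#' @param gap_flap_len_mean mean extra length of gaps/flaps; lengths are
#'   drawn as `1 + Poisson(gap_flap_len_mean)` so every gap/flap is >= 1 nt.
#' @param tf_sites data.frame with columns `chrom`, `midpoint`, `orientation`:
#'   transcription-factor binding-site midpoints acting as hard barriers.
#' @param tf_barrier_weight probability in `[0, 1]` that a fragment assigned
#'   within one repeat of a TF site has its 3' terminus relocated to the
#'   fork-proximal edge of the site.
#' @param tf_footprint nominal TF footprint in nt; the fork-proximal edge
#'   lies `tf_footprint / 2` nt upstream (in synthesis direction) of the
#'   midpoint.
#' @param decoupled_flap_mode if `TRUE`, flap junctions displace only the 5'
#'   terminus upstream by the flap length, leaving the 3' terminus in place —
#'   the strand-displacement regime in which 5' and 3' ends peak at different
#'   positions.  If `FALSE` (default), both termini move together and the
#'   junction state is bookkeeping only — the reduced-nick-translation regime.
#' @param seed integer RNG seed; identical configs give identical output.
#' @return a list of class `okz_sim_config`.
#' @export
simulation_config <- function(
    chrom_lengths = c(chrI = 400000L, chrII = 350000L),
    origins = data.frame(chrom = c("chrI", "chrI", "chrII"),
                         position = c(100000L, 300000L, 175000L),
                         stringsAsFactors = FALSE),
    nucleosome_repeat = 165L,
    dyad_jitter_sd = 15,
    multi_span_prob = 0.25,
    n_fragments = 50000L,
    condition = "WT",
    terminus_shift = c(WT = 0, rad27 = -20, exo1 = -10, dna2 = 0,
                       rad27_exo1 = -30, rad27_dna2 = -20,
                       exo1_dna2 = -10, triple = -30),
    terminus_sd = c(WT = 15, rad27 = 15, exo1 = 15, dna2 = 15,
                    rad27_exo1 = 15, rad27_dna2 = 15,
                    exo1_dna2 = 15, triple = 15),
    ligatable_fraction = c(WT = 0.8, rad27 = 0.05, exo1 = 0.7, dna2 = 0.8,
                           rad27_exo1 = 0.05, rad27_dna2 = 0.05,
                           exo1_dna2 = 0.65, triple = 0.05),
    gap_flap_len_mean = 4,
    tf_sites = NULL,
    tf_barrier_weight = 0.3,
    tf_footprint = 16L,
    decoupled_flap_mode = FALSE,
    seed = 1L) {
  if (is.null(tf_sites)) tf_sites <- default_tf_sites(chrom_lengths)
  cfg <- list(
    chrom_lengths = chrom_lengths,
    origins = origins,
    nucleosome_repeat = as.integer(nucleosome_repeat),
    dyad_jitter_sd = dyad_jitter_sd,
    multi_span_prob = multi_span_prob,
    n_fragments = as.integer(n_fragments),
    condition = condition,
    terminus_shift = terminus_shift,
    terminus_sd = terminus_sd,
    ligatable_fraction = ligatable_fraction,
    gap_flap_len_mean = gap_flap_len_mean,
    tf_sites = tf_sites,
    tf_barrier_weight = tf_barrier_weight,
    tf_footprint = as.integer(tf_footprint),
    decoupled_flap_mode = isTRUE(decoupled_flap_mode),
    seed = as.integer(seed)
  )
  class(cfg) <- "okz_sim_config"
  validate_sim_config(cfg)
  cfg
}

# TF sites tiled sparsely across the genome, stranded alternately; stands in
# for the genomic density of Abf1/Reb1/Rap1-class general regulatory factors.
default_tf_sites <- function(chrom_lengths) {
  out <- lapply(names(chrom_lengths), function(ch) {
    if (chrom_lengths[[ch]] < 6001L) return(NULL)
    mids <- seq(3000L, chrom_lengths[[ch]] - 3000L, by = 6000L)
    if (!length(mids)) return(NULL)
    data.frame(chrom = ch, midpoint = as.integer(mids),
               orientation = rep(c("+", "-"), length.out = length(mids)),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(chrom = character(0), midpoint = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

validate_sim_config <- function(cfg) {
  if (!length(cfg$chrom_lengths) || is.null(names(cfg$chrom_lengths))) {
    stop("chrom_lengths must be a named vector")
  }
  if (any(cfg$chrom_lengths < 1)) stop("chromosome lengths must be positive")
  if (nrow(cfg$origins) == 0) stop("at least one replication origin is required")
  bad <- !(cfg$origins$chrom %in% names(cfg$chrom_lengths)) |
    cfg$origins$position < 0 |
    cfg$origins$position >= cfg$chrom_lengths[cfg$origins$chrom]
  if (any(bad)) stop("origin outside chromosome bounds")
  if (cfg$nucleosome_repeat < 100) stop("nucleosome_repeat must be >= 100")
  probs <- cfg$ligatable_fraction
  if (any(probs < 0 | probs > 1)) stop("ligatable_fraction must be in [0, 1]")
  if (cfg$tf_barrier_weight < 0 || cfg$tf_barrier_weight > 1) {
    stop("tf_barrier_weight must be in [0, 1]")
  }
  if (cfg$multi_span_prob < 0 || cfg$multi_span_prob >= 1) {
    stop("multi_span_prob must be in [0, 1)")
  }
  if (!all(is.finite(cfg$terminus_shift))) stop("terminus_shift must be finite")
  if (!cfg$condition %in% names(cfg$terminus_shift)) {
    stop("condition '", cfg$condition, "' has no terminus_shift entry")
  }
  invisible(cfg)
}

#' Build the simulated genome: dyads, TF sites and fork directions
#'
#' Dyads are tiled every `nucleosome_repeat` nt along each chromosome (one
#' per complete repeat, centered in it) with lognormal occupancy scores so
#' occupancy filtering is exercisable.  Every genomic position has exactly
#' one fork direction, determined by the nearest origin.
#'
#' @param config an `okz_sim_config`.
#' @return list with elements `dyads` (nucleosome-dyad feature set),
#'   `tf_sites` (TF-site feature set) and `fork_direction`, a function
#'   `(chrom, position) -> "+"/"-"`.
#' @export
build_genome <- function(config) {
  validate_sim_config(config)
  rep_len <- config$nucleosome_repeat
  set.seed(derive_seed(config$seed, 1L))
  dyad_list <- lapply(names(config$chrom_lengths), function(ch) {
    n_dyads <- config$chrom_lengths[[ch]] %/% rep_len
    if (n_dyads < 1) return(NULL)
    mids <- rep_len %/% 2L + rep_len * (seq_len(n_dyads) - 1L)
    data.frame(chrom = ch, midpoint = as.integer(mids),
               stringsAsFactors = FALSE)
  })
  dyads_df <- do.call(rbind, dyad_list[!vapply(dyad_list, is.null, logical(1))])
  occupancy <- stats::rlnorm(nrow(dyads_df), meanlog = 0, sdlog = 0.5)
  dyads <- feature_set(dyads_df$chrom, dyads_df$midpoint,
                       score = occupancy, kind = "nucleosome_dyad")
  tf <- config$tf_sites
  tf_sites <- feature_set(tf$chrom, tf$midpoint, score = rep(1, nrow(tf)),
                          orientation = tf$orientation, kind = "tf_site")
  list(dyads = dyads, tf_sites = tf_sites,
       fork_direction = make_fork_direction(config))
}

# Fork direction from origins: "+" (rightward) at and right of the nearest
# origin, "-" left of it; the divide between two origins on a chromosome is
# their midpoint.
make_fork_direction <- function(config) {
  origin_tab <- split(config$origins$position, config$origins$chrom)
  origin_tab <- lapply(origin_tab, sort)
  function(chrom, position) {
    out <- character(length(position))
    for (ch in unique(chrom)) {
      ori <- origin_tab[[ch]]
      if (is.null(ori)) stop("no origin on chromosome ", ch)
      sel <- chrom == ch
      pos <- position[sel]
      if (length(ori) == 1L) {
        nearest <- rep(ori, length(pos))
      } else {
        bounds <- (ori[-length(ori)] + ori[-1]) / 2
        nearest <- ori[findInterval(pos, bounds + 0.5) + 1L]
      }
      out[sel] <- ifelse(pos >= nearest, "+", "-")
    }
    out
  }
}

#' Simulate an Okazaki fragment ensemble with ground truth
#'
#' Each fragment is assigned a dyad uniformly at random; the fork direction
#' at the dyad fixes the strand (`+` under rightward forks, so synthesis runs
#' left to right).  The 3' terminus is placed at
#' `dyad + s * (shift + Normal(0, sd))` with `s = +1` on `+` and `-1` on `-`,
#' so a fork-proximal shift points in opposite genomic directions on the two
#' strands.  Fragment length is `span * nucleosome_repeat +
#' Normal(0, jitter_sd)` with `span` geometric (`multi_span_prob`
#' continuation, so mostly 1), rounded, floored at 50 nt — the nucleosome
#' ladder of sizes; the 5' terminus sits `length - 1` nt upstream
#' of the 3' terminus in synthesis direction.  The 5' junction is a nick with
#' probability `ligatable_fraction`, else a gap or flap (equal odds, length
#' `1 + Poisson(gap_flap_len_mean)`).  In `decoupled_flap_mode` flap lengths
#' additionally displace the 5' terminus upstream, decoupling the two end
#' distributions.  Fragments assigned within one repeat of a TF site have
#' their 3' terminus relocated to the fork-proximal site edge with
#' probability `tf_barrier_weight`.
#'
#' @param config an `okz_sim_config`.
#' @param genome optional pre-built genome from [build_genome()] (rebuilt
#'   from the config if omitted).
#' @return list with `fragments` (fragment table, genome-sorted) and `truth`
#'   (per-fragment draws plus realized summary statistics).
#' @export
simulate_fragments <- function(config, genome = NULL) {
  validate_sim_config(config)
  if (config$n_fragments <= 0) stop("n_fragments must be positive")
  if (is.null(genome)) genome <- build_genome(config)
  dyads <- genome$dyads
  n <- config$n_fragments
  cond <- config$condition
  shift <- config$terminus_shift[[cond]]
  sd3 <- config$terminus_sd[[cond]]
  lig <- config$ligatable_fraction[[cond]]

  set.seed(derive_seed(config$seed, 2L))
  dyad_idx <- sample.int(nrow(dyads), n, replace = TRUE)
  d_chrom <- dyads$chrom[dyad_idx]
  d_pos <- dyads$midpoint[dyad_idx]
  strand <- genome$fork_direction(d_chrom, d_pos)
  sgn <- ifelse(strand == "+", 1L, -1L)

  pos3 <- as.integer(round(d_pos + sgn * (shift + stats::rnorm(n, 0, sd3))))
  # lengths form a ladder at multiples of the repeat: most fragments span one
  # nucleosome, a geometric minority continue across further nucleosomes
  span <- pmin(1L + stats::rgeom(n, 1 - config$multi_span_prob), 5L)
  len <- pmax(50L, as.integer(round(
    span * config$nucleosome_repeat +
      stats::rnorm(n, 0, config$dyad_jitter_sd))))

  is_nick <- stats::runif(n) < lig
  junction_state <- rep("nick", n)
  if (config$decoupled_flap_mode) {
    junction_state[!is_nick] <- "flap"
  } else {
    junction_state[!is_nick] <- ifelse(stats::runif(n)[!is_nick] < 0.5,
                                       "gap", "flap")
  }
  junction_len <- rep(NA_integer_, n)
  n_jl <- sum(!is_nick)
  if (n_jl > 0) {
    junction_len[!is_nick] <-
      1L + stats::rpois(n_jl, config$gap_flap_len_mean)
  }

  # In the strand-displacement regime an unprocessed flap extends the mapped
  # fragment at its 5' end; only the 5' terminus moves.
  ext <- integer(n)
  if (config$decoupled_flap_mode) {
    flap <- junction_state == "flap"
    ext[flap] <- junction_len[flap]
  }
  pos5 <- pos3 - sgn * (len - 1L + ext)

  tf_locked <- rep(FALSE, n)
  tf <- config$tf_sites
  if (!is.null(tf) && nrow(tf) > 0 && config$tf_barrier_weight > 0) {
    lock_draw <- stats::runif(n) < config$tf_barrier_weight
    half_fp <- config$tf_footprint %/% 2L
    for (ch in unique(tf$chrom)) {
      mids <- sort(tf$midpoint[tf$chrom == ch])
      sel <- which(d_chrom == ch & lock_draw)
      if (!length(sel)) next
      near_idx <- findInterval(d_pos[sel], mids)
      cand_lo <- mids[pmax(near_idx, 1L)]
      cand_hi <- mids[pmin(near_idx + 1L, length(mids))]
      dist_lo <- abs(d_pos[sel] - cand_lo)
      dist_hi <- abs(d_pos[sel] - cand_hi)
      site <- ifelse(dist_lo <= dist_hi, cand_lo, cand_hi)
      near <- pmin(dist_lo, dist_hi) <= config$nucleosome_repeat
      hit <- sel[near]
      if (!length(hit)) next
      new3 <- as.integer(site[near] - sgn[hit] * half_fp)
      # barrier stops synthesis early; keep the primer (5') end, require a
      # valid fragment after relocation
      valid <- sgn[hit] * (new3 - pos5[hit]) >= 0L
      hit <- hit[valid]
      pos3[hit] <- new3[valid]
      tf_locked[hit] <- TRUE
    }
  }

  # clamp into chromosome bounds
  L <- config$chrom_lengths[d_chrom]
  pos3 <- pmin(pmax(pos3, 0L), as.integer(L - 1L))
  pos5 <- pmin(pmax(pos5, 0L), as.integer(L - 1L))

  start <- pmin(pos5, pos3)
  end <- pmax(pos5, pos3) + 1L
  frag <- fragment_records(d_chrom, start, end, strand,
                           name = paste0("frag", seq_len(n)),
                           junction_state = junction_state,
                           junction_len = junction_len)
  truth_frag <- data.frame(
    name = frag$name,
    dyad_index = dyad_idx,
    dyad_chrom = d_chrom,
    dyad_pos = d_pos,
    strand = strand,
    offset3 = sgn * (pos3 - d_pos),
    offset5 = sgn * (pos5 - d_pos),
    junction_state = junction_state,
    junction_len = junction_len,
    tf_locked = tf_locked,
    stringsAsFactors = FALSE
  )
  ord <- order(frag$chrom, frag$start, frag$end)
  frag <- frag[ord, , drop = FALSE]
  truth_frag <- truth_frag[ord, , drop = FALSE]
  rownames(frag) <- rownames(truth_frag) <- NULL
  list(
    fragments = frag,
    truth = list(
      per_fragment = truth_frag,
      realized_shift = mean(truth_frag$offset3[!truth_frag$tf_locked]),
      realized_ligatable_fraction = mean(truth_frag$junction_state == "nick"),
      condition = cond
    )
  )
}

#' Simulate the full condition panel to files
#'
#' Simulates each requested condition over a shared genome (one BED of
#' fragments per condition), writes the dyad and TF-site feature BEDs, and a
#' manifest recording every generative parameter so the run can be reproduced
#' from the manifest alone.  Per-condition seeds are derived deterministically
#' from the base seed.
#'
#' @param config base `okz_sim_config`.
#' @param outdir output directory (created if needed).
#' @param conditions conditions to simulate (default: the full panel).
#' @return named list of file paths (`fragments` per condition, `dyads`,
#'   `tf_sites`, `manifest`), invisibly.
#' @export
simulate_condition_panel <- function(config, outdir,
                                     conditions = panel_conditions()) {
  validate_sim_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- build_genome(config)
  frag_paths <- character(0)
  for (k in seq_along(conditions)) {
    cond <- conditions[k]
    cfg_k <- config
    cfg_k$condition <- cond
    cfg_k$seed <- derive_seed(config$seed, 100L + k)
    sim <- simulate_fragments(cfg_k, genome = genome)
    p <- file.path(outdir, paste0("fragments_", cond, ".bed"))
    write_fragments(sim$fragments, p)
    frag_paths[cond] <- p
  }
  dyad_path <- file.path(outdir, "dyads.bed")
  tf_path <- file.path(outdir, "tf_sites.bed")
  write_features(genome$dyads, dyad_path)
  write_features(genome$tf_sites, tf_path)
  manifest_path <- file.path(outdir, "manifest.txt")
  write_sim_config(config, manifest_path, conditions = conditions)
  invisible(list(fragments = frag_paths, dyads = dyad_path,
                 tf_sites = tf_path, manifest = manifest_path))
}
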