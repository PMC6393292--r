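#!/usr/bin/env Rscript
# Quantitative comparison of the panel against wild type: cross-correlation
# shift of the dyad meta-profiles (negative = toward the fork-proximal
# nucleosome edge, i.e. reduced nick translation), the 5'/3' decoupling
# statistic (strand displacement would move 5' ends away from 3' ends), and
# fragment-length periodicity (the nucleosome repeat).

source("analysis/00_common.R")
ensure_panel()
dir.create(RESULTS_DIR, showWarnings = FALSE)

dyads <- read_features(file.path(PANEL_DIR, "dyads.bed"), "nucleosome_dyad")
top <- select_top_occupied(dyads, 0.5)

prof <- function(fr, ek) {
  normalize_profile(smooth_profile(aggregate_termini(fr, top, ek, 100L), 5L),
                    "max")
}

wt <- panel_fragments("WT")
wt5 <- prof(wt, "five_prime")
wt3 <- prof(wt, "three_prime")

rows <- lapply(panel_conditions(), function(cond) {
  fr <- panel_fragments(cond)
  p5 <- prof(fr, "five_prime")
  p3 <- prof(fr, "three_prime")
  dec <- end_decoupling_statistic(p5, p3)
  per <- length_autocorrelation(fr)
  data.frame(
    condition = cond,
    shift_3prime_nt = round(compare_profiles(wt3, p3), 2),
    shift_5prime_nt = round(compare_profiles(wt5, p5), 2),
    decoupling_delta_nt = round(dec$delta, 2),
    verdict = dec$verdict,
    repeat_length_nt = per$best_lag,
    periodicity_score = round(per$score, 3),
    stringsAsFactors = FALSE)
})
tab <- do.call(rbind, rows)
write.table(tab, file.path(RESULTS_DIR, "shift_decoupling_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("terminus shifts vs WT and 5'/3' coupling:")
print(tab, row.names = FALSE)

# the strand-displacement counterfactual: flaps displace only 5' termini
cfg_flap <- simulation_config(
  n_fragments = 50000L, seed = PANEL_SEED + 7L,
  decoupled_flap_mode = TRUE, gap_flap_len_mean = 15,
  ligatable_fraction = stats::setNames(rep(0, 8), panel_conditions()))
sim_flap <- simulate_fragments(cfg_flap)
g_flap <- build_genome(cfg_flap)
top_flap <- select_top_occupied(g_flap$dyads, 0.5)
p5 <- normalize_profile(smooth_profile(
  aggregate_termini(sim_flap$fragments, top_flap, "five_prime", 100L), 5L), "max")
p3 <- normalize_profile(smooth_profile(
  aggregate_termini(sim_flap$fragments, top_flap, "three_prime", 100L), 5L), "max")
dec <- end_decoupling_statistic(p5, p3)
message(sprintf(
  "strand-displacement control (flap mean 16 nt, 5' ends only): delta = %.1f nt -> %s",
  dec$delta, dec$verdict))
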