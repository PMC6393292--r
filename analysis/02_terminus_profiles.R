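#!/usr/bin/env Rscript
# Meta-profiles of Okazaki fragment 5' and 3' termini for every condition:
# max-normalized around the top-occupied nucleosome dyads, median-normalized
# around TF binding sites, all in synthesis orientation and smoothed to 5 bp.

source("analysis/00_common.R")
ensure_panel()

dir.create(file.path(RESULTS_DIR, "profiles"), recursive = TRUE,
           showWarnings = FALSE)
dyads <- read_features(file.path(PANEL_DIR, "dyads.bed"), "nucleosome_dyad")
tf <- read_features(file.path(PANEL_DIR, "tf_sites.bed"), "tf_site")
top <- select_top_occupied(dyads, 0.5)
message(nrow(top), " of ", nrow(dyads), " dyads kept (top 50% occupancy); ",
        nrow(tf), " TF sites")

peaks <- list()
for (cond in panel_conditions()) {
  fr <- panel_fragments(cond)
  for (ek in c("five_prime", "three_prime")) {
    pd <- normalize_profile(
      smooth_profile(aggregate_termini(fr, top, ek, 100L), 5L), "max")
    write_profile(pd, file.path(RESULTS_DIR, "profiles",
                                sprintf("dyad_%s_%s.tsv", ek, cond)))
    pt <- normalize_profile(
      smooth_profile(aggregate_termini(fr, tf, ek, 250L), 5L), "median")
    write_profile(pt, file.path(RESULTS_DIR, "profiles",
                                sprintf("tf_%s_%s.tsv", ek, cond)))
    peaks[[paste(cond, ek)]] <- data.frame(
      condition = cond, end_kind = ek,
      dyad_peak_offset_nt = profile_peak_offset(pd),
      tf_peak_offset_nt = profile_peak_offset(pt),
      stringsAsFactors = FALSE)
  }
}
peak_tab <- do.call(rbind, peaks)
rownames(peak_tab) <- NULL
write.table(peak_tab, file.path(RESULTS_DIR, "profile_peaks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("peak offsets in synthesis orientation (negative = fork-proximal):")
print(peak_tab, row.names = FALSE)

# overview figure (disposable, so under scratch/)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("scratch/figures", recursive = TRUE, showWarnings = FALSE)
  show <- c("WT", "exo1", "rad27", "rad27_exo1")
  prof <- lapply(stats::setNames(show, show), function(cond) {
    read_profile(file.path(RESULTS_DIR, "profiles",
                           sprintf("dyad_three_prime_%s.tsv", cond)))
  })
  ggplot2::ggsave("scratch/figures/dyad_three_prime_profiles.pdf",
                  plot_profiles(prof), width = 7, height = 4)
  message("figure: scratch/figures/dyad_three_prime_profiles.pdf")
}
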