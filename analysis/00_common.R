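# Shared setup for the analysis scripts: the study configuration and the
# location of the simulated panel.  Fragment-level BED files are bulky and
# regenerable, so they live under scratch/; only summary tables and profiles
# go to results/.

library(okazakir)

PANEL_DIR <- "scratch/panel"
RESULTS_DIR <- "results"
PANEL_SEED <- 101L

panel_config <- function() {
  simulation_config(n_fragments = 50000L, seed = PANEL_SEED)
}

# Re-simulate the panel if its manifest is absent (scratch/ is disposable).
ensure_panel <- function() {
  manifest <- file.path(PANEL_DIR, "manifest.txt")
  if (!file.exists(manifest)) {
    message("simulating the eight-condition panel into ", PANEL_DIR)
    simulate_condition_panel(panel_config(), PANEL_DIR)
  }
  invisible(manifest)
}

panel_fragments <- function(condition) {
  read_fragments(file.path(PANEL_DIR, paste0("fragments_", condition, ".bed")))
}
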