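# Shared configuration for the numbered analysis drivers.  Each driver is run
# from the repository root as, e.g.:
#   Rscript analysis/01-simulate-reference.R
# and writes its tables under results/.  The panel and the depth ladder are
# regenerated deterministically from the seeds below, so the drivers can be
# run independently and in any order.

suppressPackageStartupMessages(library(depthsat))

PANEL_SEED <- 2024L
LADDER_SEED <- 77L
SC_SEED <- 15L
N_TRANSCRIPTS <- 5000L
DEPTHS <- c(1e5, 2e5, 5e5, 1e6, 2e6)
REPLICATES <- c(20L, 10L, 4L, 2L, 1L)
RESULTS_DIR <- "results"

dir.create(RESULTS_DIR, showWarnings = FALSE)

load_panel <- function() {
  generate_reference(sim_config(n_transcripts = N_TRANSCRIPTS,
                                seed = PANEL_SEED))
}

load_ladder <- function(panel) {
  simulate_depth_series(panel, DEPTHS, REPLICATES, seed = LADDER_SEED)
}

write_tsv <- function(x, name) {
  path <- file.path(RESULTS_DIR, name)
  data.table::fwrite(as.data.frame(x), path, sep = "\t")
  message("wrote ", path)
}
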