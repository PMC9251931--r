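#!/usr/bin/env Rscript
# Single-cell tag-count detection: median-of-ratios normalization, per-cell
# and per-transcript detection statistics, depth-detection correlation, and
# the effect of guiding detection with a transcript subset.
# Outputs: results/sc_size_factors.tsv, results/sc_per_transcript.tsv,
#          results/sc_per_cell.tsv, results/sc_correlation.tsv,
#          results/sc_guided_summary.tsv

source("analysis/config.R")

panel <- load_panel()
cm <- generate_cell_matrix(panel, n_cells = 500, seed = SC_SEED)

norm <- normalize_median_of_ratios(cm)
write_tsv(data.frame(barcode = names(norm$size_factors),
                     size_factor = unname(norm$size_factors),
                     fallback_used = norm$fallback_used),
          "sc_size_factors.tsv")

st <- detection_stats(cm, normalized = norm$normalized)
write_tsv(st$per_transcript, "sc_per_transcript.tsv")
write_tsv(st$per_cell, "sc_per_cell.tsv")
write_tsv(depth_detection_correlation(st), "sc_correlation.tsv")

set.seed(SC_SEED)
sub_ids <- sample(rownames(cm$counts), round(0.7 * nrow(cm$counts)))
cmp <- compare_guided_detection(subset_cell_matrix(cm, sub_ids), cm)
write_tsv(cmp$summary, "sc_guided_summary.tsv")
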