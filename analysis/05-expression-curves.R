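#!/usr/bin/env Rscript
# Expression-ranked cumulative curves for the deepest sample: cumulative
# precision, coding:noncoding class ratio, expression-share quantiles, and
# precision strata by expression percentile.
# Outputs: results/expression_ranked.tsv, results/expression_quantiles.tsv,
#          results/precision_classes.tsv

source("analysis/config.R")

panel <- load_panel()
samples <- load_ladder(panel)
depth_of <- vapply(samples, `[[`, numeric(1), "depth")
deepest <- samples[[which.max(depth_of)]]
asm <- filter_assembly(deepest$assembly)

tab <- expression_table(deepest, panel, assembly = asm)
tab <- cumulative_precision(tab)
tab <- cumulative_class_ratio(tab)
write_tsv(tab, "expression_ranked.tsv")

shares <- c(25, 50, 75, 90, 99)
write_tsv(data.frame(
  expression_share_pct = shares,
  transcript_percentile = vapply(shares, function(s)
    quantile_for_share(tab, s), numeric(1))),
  "expression_quantiles.tsv")

pc <- assign_precision_classes(tab, boundaries = c(30, 60))
summ <- as.data.frame(pc$summary)
pct_matched <- tapply(as.logical(pc$table$matched),
                      pc$table$precision_class, mean) * 100
summ$pct_matched <- as.vector(pct_matched[summ$precision_class])
write_tsv(summ, "precision_classes.tsv")
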