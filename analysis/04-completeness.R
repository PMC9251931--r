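#!/usr/bin/env Rscript
# Exon/splice completeness structure of the assemblies: per-depth completeness
# strata, bimodality of exon completeness, annotation-status classification of
# the assembled transcripts, and recurrence filtering across replicates.
# Outputs: results/completeness_strata.tsv, results/bimodality.tsv,
#          results/annotation_status.tsv, results/recurrence.tsv

source("analysis/config.R")

panel <- load_panel()
samples <- load_ladder(panel)
filtered <- lapply(samples, function(s) filter_assembly(s$assembly))
cls <- setNames(panel$assembly$transcripts$coding_class,
                panel$assembly$transcripts$transcript_id)
depth_of <- vapply(samples, `[[`, numeric(1), "depth")
matches <- lapply(filtered, match_assembly, reference = panel$assembly)

strata <- do.call(rbind, lapply(seq_along(matches), function(i) {
  t <- as.data.frame(completeness_table(matches[[i]], cls))
  t$sample_id <- names(matches)[i]
  t$depth <- depth_of[i]
  t
}))
write_tsv(strata, "completeness_strata.tsv")

bimod <- do.call(rbind, lapply(unique(depth_of), function(d) {
  frac <- mean(vapply(which(depth_of == d), function(i) {
    v <- matches[[i]]$exon_completeness
    mean(v <= 1e-9 | v >= 100 - 1e-9)
  }, numeric(1)))
  data.frame(depth = d, frac_at_0_or_100 = frac)
}))
write_tsv(bimod, "bimodality.tsv")

status <- do.call(rbind, lapply(seq_along(filtered), function(i) {
  st <- classify_annotation_status(filtered[[i]], panel$assembly)
  tab <- as.data.frame(table(status = st), stringsAsFactors = FALSE)
  names(tab) <- c("status", "n")
  tab$sample_id <- names(filtered)[i]
  tab$depth <- depth_of[i]
  tab
}))
write_tsv(status, "annotation_status.tsv")

# recurrence across the replicates of the shallowest depth
shallow <- filtered[depth_of == min(depth_of)]
rec <- recurrence_filter(shallow, min_samples = ceiling(length(shallow) / 2))
write_tsv(as.data.frame(rec$transcripts), "recurrence.tsv")
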