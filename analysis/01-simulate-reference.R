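#!/usr/bin/env Rscript
# Generate the synthetic reference panel: a mixed coding/noncoding transcript
# catalogue with expression levels, annotation status and TE content.
# Outputs: results/reference.gtf, results/reference_classes.tsv,
#          results/reference_summary.tsv

source("analysis/config.R")

panel <- load_panel()
asm <- panel$assembly

write_gtf(asm, file.path(RESULTS_DIR, "reference.gtf"))
message("wrote ", file.path(RESULTS_DIR, "reference.gtf"))

tx <- as.data.frame(asm$transcripts[, .(transcript_id, gene_id, chrom, strand,
                                        coding_class, annotation_status,
                                        te_containing, expression, n_exons,
                                        length)])
write_tsv(tx, "reference_classes.tsv")

summary_tab <- aggregate(
  cbind(n = rep(1, nrow(tx)), n_exons = tx$n_exons, length = tx$length,
        expression = tx$expression),
  by = list(coding_class = tx$coding_class,
            annotation_status = tx$annotation_status),
  FUN = mean)
summary_tab$n <- as.vector(table(paste(tx$coding_class,
                                       tx$annotation_status))[
  paste(summary_tab$coding_class, summary_tab$annotation_status)])
names(summary_tab) <- c("coding_class", "annotation_status", "n",
                        "mean_exons", "mean_length", "mean_expression")
write_tsv(summary_tab, "reference_summary.tsv")
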