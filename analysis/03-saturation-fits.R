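#!/usr/bin/env Rscript
# Fit transcript count against depth per class, derive per-step increments and
# saturation depths, and compute the coding:noncoding ratio curve and
# per-group observed-minus-predicted deviations.
# Outputs: results/loess_fit.tsv, results/increments.tsv,
#          results/saturation_depths.tsv, results/ratio_curve.tsv,
#          results/deviations.tsv

source("analysis/config.R")

panel <- load_panel()
samples <- load_ladder(panel)
filtered <- lapply(samples, function(s) filter_assembly(s$assembly))
series <- depth_series(filtered)
cls <- panel$assembly$transcripts$coding_class
n_cod <- sum(cls == "coding")
n_nc <- sum(cls == "noncoding")

# span = 1: five distinct design depths; a narrower tricube neighborhood is
# dominated by a single replicate cluster and plateaus between design points
fit_c <- loess_fit(series$depth, series$n_coding, span = 1)
fit_n <- loess_fit(series$depth, series$n_noncoding, span = 1)

grid <- seq(min(DEPTHS), max(DEPTHS), by = 1e4)
pred_c <- predict(fit_c, grid, se = TRUE)
pred_n <- predict(fit_n, grid, se = TRUE)
write_tsv(data.frame(depth = grid,
                     fit_coding = pred_c$fit, se_coding = pred_c$se,
                     fit_noncoding = pred_n$fit, se_noncoding = pred_n$se),
          "loess_fit.tsv")

inc_c <- increments(fit_c, max(DEPTHS), step = 1e5)
inc_n <- increments(fit_n, max(DEPTHS), step = 1e5)
inc <- rbind(cbind(coding_class = "coding", as.data.frame(inc_c)),
             cbind(coding_class = "noncoding", as.data.frame(inc_n)))
write_tsv(inc, "increments.tsv")

# clamped steps carry no slope information and are excluded before the scan
sat <- data.frame(
  coding_class = c("coding", "noncoding"),
  threshold = c(0.01 * n_cod, 0.01 * n_nc),
  saturation_depth = c(
    saturation_depth(inc_c[!inc_c$clamped], threshold = 0.01 * n_cod),
    saturation_depth(inc_n[!inc_n$clamped], threshold = 0.01 * n_nc)))
write_tsv(sat, "saturation_depths.tsv")

write_tsv(coding_noncoding_ratio(series), "ratio_curve.tsv")

fit_all <- loess_fit(series$depth, series$n_all, span = 1)
omp <- observed_minus_predicted(series, fit_all, min_replicates = 4)
write_tsv(omp, "deviations.tsv")
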