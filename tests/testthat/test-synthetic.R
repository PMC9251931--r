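test_that("reference generation is deterministic and structurally valid", {
  cfg <- sim_config(n_transcripts = 200, seed = 11)
  p1 <- generate_reference(cfg)
  p2 <- generate_reference(cfg)
  expect_equal(as.data.frame(p1$assembly$exons),
               as.data.frame(p2$assembly$exons))
  tx <- p1$assembly$transcripts
  expect_equal(nrow(tx), 200)
  expect_true(all(tx$length >= cfg$min_tx_length))
  expect_true(all(tx$coding_class %in% c("coding", "noncoding")))
  expect_true(all(tx$expression > 0))
  # exons fit inside the reported genome
  ex <- merge(as.data.frame(p1$assembly$exons),
              data.frame(chrom = names(p1$genome), glen = unname(p1$genome)))
  expect_true(all(ex$end <= ex$glen))
  # a different seed gives a different panel
  p3 <- generate_reference(sim_config(n_transcripts = 200, seed = 12))
  expect_false(identical(as.data.frame(p1$assembly$exons),
                         as.data.frame(p3$assembly$exons)))
})

test_that("class fraction follows the configured binomial law", {
  n <- 4000
  p <- generate_reference(sim_config(n_transcripts = n, coding_fraction = 0.6,
                                     seed = 21))
  k <- sum(p$assembly$transcripts$coding_class == "coding")
  # 5-sigma binomial band around 0.6 * n
  expect_lt(abs(k - 0.6 * n), 5 * sqrt(n * 0.6 * 0.4))
})

test_that("configured class contrasts show up in the panel", {
  p <- generate_reference(sim_config(n_transcripts = 3000, seed = 31))
  tx <- p$assembly$transcripts
  cod <- tx[tx$coding_class == "coding"]
  nc <- tx[tx$coding_class == "noncoding"]
  expect_gt(mean(log(cod$expression)), mean(log(nc$expression)))
  expect_gt(mean(cod$n_exons), mean(nc$n_exons))
  expect_lt(mean(cod$te_containing), mean(nc$te_containing))
  expect_lt(mean(cod$annotation_status == "novel"),
            mean(nc$annotation_status == "novel"))
})

test_that("a fixed genome too small for the panel is rejected", {
  cfg <- sim_config(n_transcripts = 100, seed = 1,
                    genome = c(chr1 = 1000, chr2 = 1000, chr3 = 1000,
                               chr4 = 1000, chr5 = 1000))
  expect_error(generate_reference(cfg), "genome too small")
})

test_that("simulation is deterministic in (seed, sample_id) and depth-capped", {
  panel <- small_panel(150, seed = 41)
  s1 <- simulate_assembly(panel, 2e4, seed = 5, sample_id = "a")
  s2 <- simulate_assembly(panel, 2e4, seed = 5, sample_id = "a")
  expect_equal(as.data.frame(s1$assembly$exons),
               as.data.frame(s2$assembly$exons))
  expect_equal(s1$read_counts, s2$read_counts)
  expect_equal(sum(s1$read_counts), 2e4)
  s3 <- simulate_assembly(panel, 2e4, seed = 5, sample_id = "b")
  expect_false(identical(s1$read_counts, s3$read_counts))
  # metadata depth levels follow the configured fractions
  expect_equal(s1$assembly$meta$total_reads, 2e4)
  expect_equal(s1$assembly$meta$mapped_reads,
               round(2e4 * panel$config$mapped_fraction))
})

test_that("saturating read counts with no noise recover every transcript", {
  cfg <- sim_config(n_transcripts = 80, k = 1, m = 1, noise_rate = 0,
                    unstranded_fraction = 0, short_fraction = 0, seed = 51)
  panel <- generate_reference(cfg)
  # drive the detection layer directly with uniformly huge per-transcript
  # counts: every junction's expected support is then >= hundreds of reads
  ids <- panel$assembly$transcripts$transcript_id
  counts <- stats::setNames(rep(10000, length(ids)), ids)
  s <- depthsat:::build_sim_assembly(panel, counts, sum(counts), cfg,
                                     seed = 6, sample_id = "deep")
  res <- match_assembly(filter_assembly(s$assembly), panel$assembly)
  expect_true(all(res$correctly_assembled))
  expect_true(all(res$exon_completeness == 100))
  expect_true(all(res$splice_completeness == 100))
})

test_that("zero depth emits nothing but noise-free empty assemblies", {
  panel <- small_panel(50, seed = 61)
  s <- simulate_assembly(panel, 0, seed = 1, sample_id = "zero")
  expect_equal(n_transcripts(s$assembly), 0)
  expect_equal(sum(s$read_counts), 0)
})

test_that("noise transcripts appear at the configured rate with NOISE truth", {
  cfg <- sim_config(n_transcripts = 100, noise_rate = 200, seed = 71)
  panel <- generate_reference(cfg)
  s <- simulate_assembly(panel, 1e5, cfg, seed = 9, sample_id = "n")
  noise_ids <- s$truth_map[s$truth_map$ref_id == "NOISE"]$transcript_id
  # Poisson(20): a 5-sigma band
  expect_gt(length(noise_ids), 0)
  expect_lt(abs(length(noise_ids) - 20), 5 * sqrt(20))
  # noise chains are absent from the panel
  expect_true(all(grepl("^noise", noise_ids)))
})

test_that("the truth map covers every emitted transcript exactly once", {
  panel <- small_panel(120, seed = 81)
  s <- simulate_assembly(panel, 5e4, seed = 3, sample_id = "t")
  ids <- s$assembly$transcripts$transcript_id
  expect_setequal(s$truth_map$transcript_id, ids)
  expect_false(anyDuplicated(s$truth_map$transcript_id) > 0)
})

test_that("depth series uses the requested design and shared detection", {
  panel <- small_panel(100, seed = 91)
  series <- simulate_depth_series(panel, depths = c(1e4, 5e4),
                                  replicates = c(3, 1), seed = 2)
  expect_equal(length(series), 4)
  expect_setequal(names(series),
                  c("d10000_r1", "d10000_r2", "d10000_r3", "d50000_r1"))
  # a series member equals the standalone simulation with the same sample_id
  solo <- simulate_assembly(panel, 1e4, seed = 2, sample_id = "d10000_r2")
  expect_equal(as.data.frame(series$d10000_r2$assembly$exons),
               as.data.frame(solo$assembly$exons))
})

test_that("subsample partitions are disjoint and recompose the read pool", {
  panel <- small_panel(100, seed = 101)
  s <- simulate_assembly(panel, 4e4, seed = 4, sample_id = "parent")
  parts <- partition_subsample(s, panel, fractions = 0.25, replicates = 4,
                               seed = 7)
  expect_equal(length(parts), 4)
  sizes <- vapply(parts, function(p) sum(p$read_counts), numeric(1))
  expect_equal(unname(sizes), rep(1e4, 4))
  recomposed <- Reduce(`+`, lapply(parts, `[[`, "read_counts"))
  expect_equal(recomposed, s$read_counts)
  # subsampled detection is contained in the parent's
  parent_ok <- match_assembly(filter_assembly(s$assembly), panel$assembly)
  for (p in parts) {
    sub_ok <- match_assembly(filter_assembly(p$assembly), panel$assembly)
    expect_true(all(sub_ok$correctly_assembled <= parent_ok$correctly_assembled))
  }
  # full fraction returns the sample itself
  same <- partition_subsample(s, panel, fractions = 1, replicates = 1)
  expect_identical(same$f1_r1, s)
  expect_error(partition_subsample(s, panel, fractions = 0.5, replicates = 3),
               "exceeds 1")
})

test_that("merging samples is a superset at the summed depth", {
  panel <- small_panel(150, seed = 111)
  a <- simulate_assembly(panel, 2e4, seed = 8, sample_id = "a")
  b <- simulate_assembly(panel, 3e4, seed = 8, sample_id = "b")
  m <- merge_samples(list(a, b), panel)
  expect_equal(m$depth, 5e4)
  expect_equal(m$read_counts, a$read_counts + b$read_counts)
  ok_a <- match_assembly(filter_assembly(a$assembly), panel$assembly)
  ok_m <- match_assembly(filter_assembly(m$assembly), panel$assembly)
  expect_true(all(ok_m$correctly_assembled >= ok_a$correctly_assembled))
  # different seeds cannot be merged
  c2 <- simulate_assembly(panel, 1e4, seed = 9, sample_id = "c")
  expect_error(merge_samples(list(a, c2), panel), "share one simulation seed")
})

test_that("derived seeds are valid set.seed inputs and collision-resistant", {
  seeds <- vapply(1:2000, function(i)
    depthsat:::derive_seed(1, "detect", i), numeric(1))
  expect_true(all(seeds >= 1 & seeds <= 2^31 - 2))
  expect_true(all(seeds == round(seeds)))
  expect_gt(length(unique(seeds)), 1990)
  expect_false(depthsat:::derive_seed(1, "a") == depthsat:::derive_seed(1, "b"))
  expect_false(depthsat:::derive_seed(1, "reads", "x") ==
                 depthsat:::derive_seed(2, "reads", "x"))
})

test_that("simulated single-cell matrices follow the multinomial law", {
  cfg <- sim_config(n_transcripts = 40, seed = 121)
  panel <- generate_reference(cfg)
  cm <- generate_cell_matrix(panel, n_cells = 300, dropout_max = 0,
                             seed = 13)
  expect_equal(dim(cm$counts), c(40, 300))
  expect_equal(unname(cm$tag_total), unname(colSums(cm$counts)))
  # expected allocation proportional to expression * length (no dropout)
  tx <- panel$assembly$transcripts
  w <- tx$expression * tx$length
  p_exp <- w / sum(w)
  p_obs <- rowSums(cm$counts) / sum(cm$counts)
  # compare on the transcripts holding most mass; 5-sigma multinomial bands
  n_tot <- sum(cm$counts)
  sel <- p_exp > 0.005
  expect_true(all(abs(p_obs[sel] - p_exp[sel]) <
                    5 * sqrt(p_exp[sel] * (1 - p_exp[sel]) / n_tot)))
  # dropout strictly reduces counts cellwise
  cm_drop <- generate_cell_matrix(panel, n_cells = 300, dropout_max = 0.5,
                                  dropout_scale = 50, seed = 13)
  expect_true(all(cm_drop$counts <= cm$counts))
  expect_lt(sum(cm_drop$counts), sum(cm$counts))
})
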