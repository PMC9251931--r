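#' Simulation configuration
#'
#' Parameters of the synthetic transcriptome and of the depth-dependent
#' assembly-detection model. Defaults encode the qualitative contrasts between
#' transcript classes seen in human data: coding transcripts are more highly
#' expressed (log-mean gap 1.5 natural-log units), have more exons, fewer
#' transposable-element overlaps (0.25 vs 0.65) and a lower novel fraction
#' (0.05 vs 0.30) than noncoding ones.
#'
#' The detection model replaces an assembler's internal heuristics with two
#' thresholds: a splice junction (or exon) is detected when its Poisson-thinned
#' read support reaches `k`, and a transcript is emitted fully only when all of
#' its junctions are detected and it has at least `m` reads in total.
#'
#' @param n_transcripts panel size.
#' @param coding_fraction probability a panel transcript is coding.
#' @param expr_meanlog,expr_sdlog per-class log-normal expression parameters
#'   (named `coding`/`noncoding`, natural-log scale, arbitrary abundance
#'   units).
#' @param te_probability per-class probability of containing a TE.
#' @param novel_fraction per-class probability of `annotation_status =
#'   "novel"` (else `"annotated"`).
#' @param exon_lambda per-class Poisson rate; exon count = 1 + Poisson.
#' @param exon_meanlog,exon_sdlog,min_exon exon-length log-normal (nt).
#' @param intron_meanlog,intron_sdlog,min_intron intron-length log-normal (nt).
#' @param min_tx_length panel transcripts are extended to at least this summed
#'   exon length (nt), matching the usual assembly length filter.
#' @param junction_window nt of a transcript informative for one junction
#'   (the typical paired-end fragment span: any fragment spanning a junction
#'   supports it);
#'   expected junction support for a transcript with `n` reads of length `L`
#'   is `n * junction_window / L`.
#' @param k junction/exon detection threshold (reads).
#' @param m minimum reads for full transcript emission.
#' @param noise_rate false transcripts per million reads.
#' @param noise_coding_prob probability a noise transcript is labeled coding.
#' @param unstranded_fraction,short_fraction fractions of emitted transcripts
#'   degraded to unstranded, or truncated below the length filter, to exercise
#'   downstream filtering.
#' @param mapped_fraction,assigned_fraction fractions filling the
#'   mapped/assigned read levels of the sample metadata.
#' @param n_chroms number of synthetic chromosomes (used when `genome` is
#'   auto-sized).
#' @param spacing gap (nt) between placed transcripts.
#' @param genome optional named vector of chromosome lengths; `NULL` sizes the
#'   genome to fit the panel.
#' @param seed root seed for panel generation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 10000,
                       coding_fraction = 0.6,
                       expr_meanlog = c(coding = 1.5, noncoding = 0.0),
                       expr_sdlog = c(coding = 2.0, noncoding = 2.0),
                       te_probability = c(coding = 0.25, noncoding = 0.65),
                       novel_fraction = c(coding = 0.05, noncoding = 0.30),
                       exon_lambda = c(coding = 7, noncoding = 2),
                       exon_meanlog = log(150), exon_sdlog = 0.6,
                       min_exon = 30,
                       intron_meanlog = log(1500), intron_sdlog = 1.0,
                       min_intron = 60,
                       min_tx_length = 200,
                       junction_window = 350,
                       k = 2, m = 3,
                       noise_rate = 100, noise_coding_prob = 0.2,
                       unstranded_fraction = 0.02, short_fraction = 0.02,
                       mapped_fraction = 0.95, assigned_fraction = 0.85,
                       n_chroms = 5, spacing = 1000, genome = NULL,
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$coding_fraction, cfg$te_probability, cfg$novel_fraction,
             cfg$noise_coding_prob, cfg$unstranded_fraction,
             cfg$short_fraction, cfg$mapped_fraction, cfg$assigned_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$k < 1 || cfg$m < 1) stop("detection thresholds k, m must be >= 1")
  if (cfg$noise_rate < 0) stop("noise_rate must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

class_par <- function(par, cls) unname(par[cls])

#' Generate a ground-truth reference transcriptome panel
#'
#' Draws `n_transcripts` transcripts with class-dependent expression, TE
#' content, novelty and exon structure (see [sim_config()]) and places their
#' exon chains on a synthetic genome without intra-transcript overlap.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `reference_panel`: list with `assembly` (all
#'   attributes set), `genome` (named chromosome lengths) and `config`.
#' @export
generate_reference <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_transcripts
  if (n == 0) {
    asm <- new_assembly(data.table(transcript_id = character(),
                                   chrom = character(), start = numeric(),
                                   end = numeric(), strand = character()),
                        meta = sample_meta(sample_id = "reference"))
    return(structure(list(assembly = asm,
                          genome = config$genome %||%
                            setNames(rep(1e6, config$n_chroms),
                                     paste0("chr", seq_len(config$n_chroms))),
                          config = config),
                     class = "reference_panel"))
  }
  with_seed(derive_seed(config$seed, "panel"), {
    cls <- ifelse(runif(n) < config$coding_fraction, "coding", "noncoding")
    expr <- rlnorm(n, class_par(config$expr_meanlog, cls),
                   class_par(config$expr_sdlog, cls))
    te <- runif(n) < class_par(config$te_probability, cls)
    status <- ifelse(runif(n) < class_par(config$novel_fraction, cls),
                     "novel", "annotated")
    strand <- sample(c("+", "-"), n, replace = TRUE)
    n_ex <- 1L + rpois(n, class_par(config$exon_lambda, cls))
    tot_ex <- sum(n_ex)
    ex_len <- pmax(config$min_exon,
                   round(rlnorm(tot_ex, config$exon_meanlog, config$exon_sdlog)))
    in_len <- pmax(config$min_intron,
                   round(rlnorm(tot_ex, config$intron_meanlog,
                                config$intron_sdlog)))
  })
  ex <- data.table(tx = rep(seq_len(n), n_ex), len = ex_len)
  ex[, exon_rank := seq_len(.N), by = tx]
  # extend the last exon so every transcript reaches the minimum length
  tx_len <- ex[, sum(len), by = tx]$V1
  deficit <- pmax(0, config$min_tx_length - tx_len)
  last_rows <- cumsum(n_ex)
  ex[last_rows, len := len + deficit]
  # intron before each exon (0 for the first exon of a transcript)
  ex[, intron_before := ifelse(exon_rank == 1L, 0, in_len[seq_len(nrow(ex))])]
  ex[, rel_start := cumsum(data.table::shift(len, fill = 0) + intron_before) -
       intron_before[1L], by = tx]
  spans <- ex[, rel_start[.N] + len[.N], by = tx]$V1
  # place transcripts round-robin across chromosomes, tiled with spacing
  chrom_of <- rep_len(seq_len(config$n_chroms), n)
  offset <- numeric(n)
  for (cidx in seq_len(config$n_chroms)) {
    on_c <- which(chrom_of == cidx)
    offset[on_c] <- config$spacing +
      cumsum(c(0, head(spans[on_c] + config$spacing, -1)))
  }
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  if (is.null(config$genome)) {
    genome <- vapply(seq_len(config$n_chroms), function(cidx) {
      on_c <- which(chrom_of == cidx)
      if (!length(on_c)) return(1e5)
      max(offset[on_c] + spans[on_c]) + config$spacing
    }, numeric(1))
    names(genome) <- chrom_names
  } else {
    genome <- config$genome
    need <- vapply(seq_len(config$n_chroms), function(cidx) {
      on_c <- which(chrom_of == cidx)
      if (!length(on_c)) 0 else max(offset[on_c] + spans[on_c])
    }, numeric(1))
    if (length(genome) < config$n_chroms || any(genome[seq_len(config$n_chroms)] < need))
      stop("genome too small to place ", n, " transcripts")
    chrom_names <- names(genome)[seq_len(config$n_chroms)]
  }
  ids <- sprintf("tx%06d", seq_len(n))
  ex[, `:=`(transcript_id = ids[tx],
            chrom = chrom_names[chrom_of[tx]],
            start = offset[tx] + rel_start,
            strand = strand[tx])]
  ex[, end := start + len]
  attrs <- data.table(transcript_id = ids, gene_id = sprintf("g%06d", seq_len(n)),
                      coding_class = cls, annotation_status = status,
                      te_containing = te, expression = expr)
  asm <- new_assembly(ex[, .(transcript_id, chrom, start, end, strand)],
                      tx_attrs = attrs,
                      meta = sample_meta(sample_id = "reference"))
  structure(list(assembly = asm, genome = genome, config = config),
            class = "reference_panel")
}

utils::globalVariables(c("tx", "intron_before", "rel_start", "tx_start",
                         "tx_end", "ord", "strand_out"))

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d transcripts on %d chromosomes\n",
              n_transcripts(x$assembly), length(x$genome)))
  invisible(x)
}

panel_signature <- function(panel) {
  tx <- panel$assembly$transcripts
  paste(nrow(tx), if (nrow(tx)) tx$transcript_id[1L] else "",
        sum(tx$length), sep = "|")
}

# panel geometry used by the detection model, in the canonical transcript
# order (sorted transcript_id)
panel_geometry <- function(panel) {
  tx <- panel$assembly$transcripts       # keyed by transcript_id
  ex <- panel$assembly$exons[order(transcript_id, start)]
  n_ex <- tx$n_exons
  geom <- list(
    ids = tx$transcript_id,
    len = tx$length,
    weight = tx$expression * tx$length,
    n_ex = n_ex,
    n_junc = pmax(n_ex - 1L, 0L),
    ex_tx = rep(seq_len(nrow(tx)), n_ex),
    ex_len = ex$end - ex$start,
    exons = ex
  )
  geom$junc_tx <- rep(seq_len(nrow(tx)), geom$n_junc)
  geom
}

#' Pre-draw the detection uniforms for a (panel, seed) pair
#'
#' One uniform per exon, per junction and per degradation decision, keyed by
#' transcript only. Draw order within a transcript's stream is fixed: exon
#' uniforms (5' to 3' in genomic order), junction uniforms, then two
#' degradation uniforms. Sharing these across samples from one root seed
#' couples detection monotonically in read count (support is the Poisson
#' quantile of a fixed uniform).
#'
#' @param panel a [generate_reference()] panel.
#' @param seed root simulation seed.
#' @return list with `exon_u`, `junc_u` (aligned with the panel's exon and
#'   junction tables in canonical order) and `deg_u` (n x 2 matrix).
#' @export
detection_draws <- function(panel, seed) {
  geom <- panel_geometry(panel)
  n <- length(geom$ids)
  exon_u <- vector("list", n); junc_u <- vector("list", n)
  deg_u <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, "detect", i))
    exon_u[[i]] <- runif(geom$n_ex[i])
    junc_u[[i]] <- if (geom$n_junc[i] > 0) runif(geom$n_junc[i]) else numeric(0)
    deg_u[i, ] <- runif(2)
  }
  list(exon_u = unlist(exon_u), junc_u = unlist(junc_u), deg_u = deg_u,
       seed = seed)
}

#' Simulate an assembled sample at a given sequencing depth
#'
#' Reads (represented as per-transcript counts, the sufficient statistic for
#' every downstream computation) are allocated multinomially with weight
#' `expression x length`. Per transcript: each junction's support is a Poisson
#' draw with mean `n * junction_window / L` and each exon's support a Poisson
#' draw with mean `n * exon_length / L`; the transcript is emitted fully
#' (correctly assembled) iff all junctions are detected (support `>= k`) and
#' `n >= m`; otherwise, if at least one exon is detected, a partial transcript
#' with the detected exon subset (original boundaries) is emitted. Poisson
#' noise transcripts with intron chains absent from the panel are added at
#' `noise_rate` per million reads, and small configured fractions of emitted
#' transcripts are made unstranded or truncated below the length filter.
#'
#' @param panel reference panel.
#' @param depth total simulated read pairs (>= 0).
#' @param config simulation config (defaults to the panel's).
#' @param seed root simulation seed (shared across samples of one experiment).
#' @param sample_id sample identifier (keys the read-allocation and noise
#'   streams).
#' @param draws optional cached [detection_draws()] for this (panel, seed).
#' @return object of class `simulated_sample`: list with `assembly`,
#'   `truth_map` (emitted transcript id -> reference id or `"NOISE"`),
#'   `read_counts` (named, per panel transcript), `depth`, `seed`,
#'   `sample_id`.
#' @export
simulate_assembly <- function(panel, depth, config = panel$config, seed = 1,
                              sample_id = "sample", draws = NULL) {
  stopifnot(inherits(panel, "reference_panel"))
  if (depth < 0) stop("depth must be >= 0")
  depth <- round(depth)
  geom <- panel_geometry(panel)
  n <- length(geom$ids)
  counts <- if (n == 0 || depth == 0) rep(0, n) else
    with_seed(derive_seed(seed, "reads", sample_id),
              as.numeric(rmultinom(1, depth, geom$weight)))
  names(counts) <- geom$ids
  build_sim_assembly(panel, counts, depth, config, seed, sample_id,
                     draws = draws, geom = geom)
}

# detection + emission given per-transcript read counts
build_sim_assembly <- function(panel, counts, depth, config, seed, sample_id,
                               draws = NULL, geom = NULL) {
  if (is.null(geom)) geom <- panel_geometry(panel)
  n <- length(geom$ids)
  if (is.null(draws)) draws <- detection_draws(panel, seed)
  L <- geom$len
  # supports via quantile coupling: monotone in the read count
  lam_e <- counts[geom$ex_tx] * geom$ex_len / L[geom$ex_tx]
  sup_e <- qpois(draws$exon_u, lam_e)
  lam_j <- counts[geom$junc_tx] *
    pmin(config$junction_window, L[geom$junc_tx]) / L[geom$junc_tx]
  sup_j <- qpois(draws$junc_u, lam_j)
  ex_det <- sup_e >= config$k
  junc_ok <- rep(TRUE, n)
  if (length(sup_j)) {
    miss <- tapply(sup_j < config$k, geom$junc_tx, any)
    junc_ok[as.integer(names(miss))] <- !miss
  }
  full <- junc_ok & counts >= config$m
  any_ex <- tapply(ex_det, geom$ex_tx, any)
  has_ex <- rep(FALSE, n); has_ex[as.integer(names(any_ex))] <- any_ex
  partial <- !full & has_ex
  # assemble emitted exon tables
  panel_ex <- geom$exons
  tx_ref <- panel$assembly$transcripts
  emit_full <- which(full); emit_part <- which(partial)
  pieces <- list()
  truth <- list()
  if (length(emit_full)) {
    fe <- panel_ex[geom$ex_tx %in% emit_full]
    fe_tx <- geom$ex_tx[geom$ex_tx %in% emit_full]
    fe <- copy(fe)[, transcript_id := paste0(geom$ids[fe_tx], ".asm")]
    pieces$full <- fe
    truth$full <- data.table(transcript_id = paste0(geom$ids[emit_full], ".asm"),
                             ref_id = geom$ids[emit_full],
                             ref_idx = emit_full, kind = "full")
  }
  if (length(emit_part)) {
    sel <- geom$ex_tx %in% emit_part & ex_det
    pe <- copy(panel_ex[sel])
    pe_tx <- geom$ex_tx[sel]
    pe[, transcript_id := paste0(geom$ids[pe_tx], ".part")]
    pieces$part <- pe
    truth$part <- data.table(transcript_id = paste0(geom$ids[emit_part], ".part"),
                             ref_id = geom$ids[emit_part],
                             ref_idx = emit_part, kind = "partial")
  }
  empty_ex <- data.table(transcript_id = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         strand = character())
  emitted_ex <- if (length(pieces))
    rbindlist(pieces)[, .(transcript_id, chrom, start, end, strand)] else
    copy(empty_ex)
  truth_map <- if (length(truth)) rbindlist(truth) else
    data.table(transcript_id = character(), ref_id = character(),
               ref_idx = integer(), kind = character())
  # degradation draws are transcript-keyed, so coupled across samples
  if (nrow(truth_map)) {
    u <- draws$deg_u[truth_map$ref_idx, , drop = FALSE]
    unstrand <- u[, 1L] < config$unstranded_fraction
    shorten <- !unstrand & u[, 2L] < config$short_fraction
    if (any(unstrand)) {
      ids_u <- truth_map$transcript_id[unstrand]
      emitted_ex[transcript_id %in% ids_u, strand := "*"]
    }
    if (any(shorten)) {
      ids_s <- truth_map$transcript_id[shorten]
      first <- emitted_ex[transcript_id %in% ids_s,
                          .SD[which.min(start)], by = transcript_id]
      first[, end := start + pmin(end - start, config$min_tx_length - 50)]
      emitted_ex <- rbind(emitted_ex[!transcript_id %in% ids_s], first)
    }
  }
  # reads -> abundance (reads per kb per million simulated reads)
  emit_reads <- counts[truth_map$ref_idx]
  emit_len <- if (nrow(emitted_ex))
    emitted_ex[, .(len = sum(end - start)), by = transcript_id] else
    data.table(transcript_id = character(), len = numeric())
  # noise transcripts
  noise <- simulate_noise(panel, depth, config, seed, sample_id, geom)
  all_ex <- rbind(emitted_ex[, .(transcript_id, chrom, start, end, strand)],
                  noise$exons)
  fpkm <- function(reads, len)
    if (depth > 0) reads / (len / 1000) / (depth / 1e6) else 0
  attrs <- NULL
  if (nrow(truth_map) || nrow(noise$attrs)) {
    ref_at <- tx_ref[match(truth_map$ref_id, tx_ref$transcript_id)]
    elen <- emit_len$len[match(truth_map$transcript_id, emit_len$transcript_id)]
    attrs <- rbindlist(list(
      if (nrow(truth_map))
        data.table(transcript_id = truth_map$transcript_id,
                   gene_id = ref_at$gene_id,
                   coding_class = ref_at$coding_class,
                   annotation_status = ref_at$annotation_status,
                   te_containing = ref_at$te_containing,
                   expression = fpkm(emit_reads, elen)),
      noise$attrs))
  }
  meta <- sample_meta(sample_id = sample_id, group_label = "simulated",
                      total_reads = depth,
                      mapped_reads = round(depth * config$mapped_fraction),
                      assigned_reads = round(depth * config$mapped_fraction *
                                               config$assigned_fraction))
  asm <- new_assembly(all_ex, tx_attrs = attrs, meta = meta)
  tm <- rbindlist(list(truth_map[, .(transcript_id, ref_id)],
                       data.table(transcript_id = noise$attrs$transcript_id,
                                  ref_id = rep("NOISE", nrow(noise$attrs)))))
  structure(list(assembly = asm, truth_map = tm, read_counts = counts,
                 depth = depth, seed = seed, sample_id = sample_id,
                 panel_signature = panel_signature(panel)),
            class = "simulated_sample")
}

utils::globalVariables(c("ref_idx", "kind"))

simulate_noise <- function(panel, depth, config, seed, sample_id, geom) {
  empty <- list(exons = data.table(transcript_id = character(),
                                   chrom = character(), start = numeric(),
                                   end = numeric(), strand = character()),
                attrs = data.table(transcript_id = character(),
                                   gene_id = character(),
                                   coding_class = character(),
                                   annotation_status = character(),
                                   te_containing = logical(),
                                   expression = numeric()))
  if (config$noise_rate <= 0 || depth <= 0) return(empty)
  with_seed(derive_seed(seed, "noise", sample_id), {
    n_noise <- rpois(1, config$noise_rate * depth / 1e6)
    res <- empty
    if (n_noise > 0) {
      panel_chains <- chain_keys_from_exons(geom$exons)
      chroms <- names(panel$genome)
      ex_list <- vector("list", n_noise)
      for (i in seq_len(n_noise)) {
        repeat {
          ne <- 1L + rpois(1, 1.5)
          lens <- round(runif(ne, 100, 300))
          ins <- if (ne > 1) round(runif(ne - 1, 200, 2000)) else numeric(0)
          span <- sum(lens) + sum(ins)
          cidx <- sample(length(chroms), 1)
          if (panel$genome[cidx] <= span + 1) next
          s0 <- floor(runif(1, 0, panel$genome[cidx] - span))
          starts <- s0 + cumsum(c(0, head(lens, -1) + ins))
          dt <- data.table(transcript_id = sprintf("noise%04d", i),
                           chrom = chroms[cidx], start = starts,
                           end = starts + lens,
                           strand = sample(c("+", "-"), 1))
          key <- chain_keys_from_exons(dt)
          if (ne == 1L || !key %in% panel_chains) break
        }
        ex_list[[i]] <- dt
      }
      reads <- 1 + rpois(n_noise, config$m)
      cls <- ifelse(runif(n_noise) < config$noise_coding_prob,
                    "coding", "noncoding")
      exons <- rbindlist(ex_list)
      lens <- exons[, .(len = sum(end - start)), by = transcript_id]
      res <- list(exons = exons,
                  attrs = data.table(transcript_id = lens$transcript_id,
                                     gene_id = lens$transcript_id,
                                     coding_class = cls,
                                     annotation_status = "unknown",
                                     te_containing = NA,
                                     expression = reads / (lens$len / 1000) /
                                       (depth / 1e6)))
    }
    res
  })
}

#' @export
print.simulated_sample <- function(x, ...) {
  cat(sprintf("<simulated_sample> %s: depth %s, %d emitted transcripts\n",
              x$sample_id, format(x$depth, big.mark = ","),
              n_transcripts(x$assembly)))
  invisible(x)
}

#' Simulate a ladder of sequencing depths with replicates
#'
#' Mirrors a depth-sweep experimental design (e.g. 20 replicates at the
#' shallowest depth down to 1 at the deepest): independent samples are drawn
#' per (depth, replicate) with per-sample read allocations but shared
#' detection streams (see [detection_draws()]).
#'
#' @param panel reference panel.
#' @param depths vector of read depths.
#' @param replicates scalar or per-depth vector of replicate counts.
#' @param config simulation config.
#' @param seed root seed.
#' @return list of [simulate_assembly()] samples, names `d<depth>_r<rep>`.
#' @export
simulate_depth_series <- function(panel, depths, replicates = 1,
                                  config = panel$config, seed = 1) {
  if (!length(depths)) stop("depths must be non-empty")
  replicates <- rep_len(replicates, length(depths))
  draws <- detection_draws(panel, seed)
  out <- list()
  for (i in seq_along(depths)) {
    for (r in seq_len(replicates[i])) {
      sid <- sprintf("d%s_r%d", format(depths[i], scientific = FALSE,
                                       trim = TRUE), r)
      out[[sid]] <- simulate_assembly(panel, depths[i], config, seed,
                                      sample_id = sid, draws = draws)
    }
  }
  out
}

#' Subsample a simulated sample's read pool without replacement
#'
#' For each requested fraction `f` with `r` replicates, the read pool is
#' permuted once and cut into `r` disjoint blocks of `round(f * N)` reads
#' (when `f * r = 1` the blocks exactly partition the pool). Detection is
#' re-applied per subsample with the parent's detection streams, so a
#' subsample's correctly-assembled set is contained in its parent's.
#'
#' @param sample a [simulate_assembly()] result.
#' @param fractions vector of fractions in (0, 1].
#' @param replicates scalar or per-fraction replicate counts; `f * r <= 1` is
#'   required for each fraction.
#' @param seed seed for the permutations (independent of the simulation seed).
#' @param config simulation config.
#' @param panel the reference panel the sample came from.
#' @return list of simulated_sample objects, names `f<fraction>_r<rep>`.
#' @export
partition_subsample <- function(sample, panel, fractions, replicates = 1,
                                seed = 1, config = panel$config) {
  stopifnot(inherits(sample, "simulated_sample"))
  if (sample$panel_signature != panel_signature(panel))
    stop("sample was not generated from this panel")
  replicates <- rep_len(replicates, length(fractions))
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  if (any(fractions * replicates > 1 + 1e-9))
    stop("cannot sample disjointly: fraction x replicates exceeds 1")
  counts <- sample$read_counts
  N <- sum(counts)
  labels <- rep(seq_along(counts), counts)
  geom <- panel_geometry(panel)
  draws <- detection_draws(panel, sample$seed)
  out <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]; r <- replicates[i]
    if (f == 1 && r == 1) {
      out[[sprintf("f1_r1")]] <- sample
      next
    }
    perm <- with_seed(derive_seed(seed, "subsample", sample$sample_id, i),
                      sample.int(N))
    sizes <- rep(round(f * N), r)
    if (abs(f * r - 1) < 1e-9) sizes[r] <- N - sum(sizes[-r])
    at <- 0
    for (j in seq_len(r)) {
      take <- if (sizes[j] > 0) perm[(at + 1):(at + sizes[j])] else integer(0)
      at <- at + sizes[j]
      sub_counts <- as.numeric(tabulate(labels[take], nbins = length(counts)))
      names(sub_counts) <- names(counts)
      sid <- sprintf("%s.f%s_r%d", sample$sample_id,
                     format(f, trim = TRUE), j)
      out[[sprintf("f%s_r%d", format(f, trim = TRUE), j)]] <-
        build_sim_assembly(panel, sub_counts, sizes[j], config, sample$seed,
                           sid, draws = draws, geom = geom)
    }
  }
  out
}

#' Merge simulated samples into one deeper sample
#'
#' Read pools are summed and detection is re-applied at the combined depth.
#' With shared detection streams the merged correctly-assembled set is a
#' superset of each input's.
#'
#' @param samples list of simulated_sample objects from one panel and one root
#'   seed.
#' @param panel the shared reference panel.
#' @param config simulation config.
#' @return a simulated_sample at the summed depth.
#' @export
merge_samples <- function(samples, panel, config = panel$config) {
  stopifnot(length(samples) >= 1)
  if (length(samples) == 1L) return(samples[[1L]])
  sig <- vapply(samples, `[[`, "", "panel_signature")
  if (length(unique(sig)) != 1L || sig[1L] != panel_signature(panel))
    stop("samples come from different reference panels")
  seeds <- vapply(samples, `[[`, numeric(1), "seed")
  if (length(unique(seeds)) != 1L)
    stop("samples must share one simulation seed")
  counts <- Reduce(`+`, lapply(samples, `[[`, "read_counts"))
  depth <- sum(vapply(samples, `[[`, numeric(1), "depth"))
  sid <- paste(vapply(samples, `[[`, "", "sample_id"), collapse = "+")
  build_sim_assembly(panel, counts, depth, config, seeds[1L], sid)
}
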