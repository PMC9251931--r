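#' Filter an assembly on strand confidence and transcript length
#'
#' Discards transcripts with no inferred strand and transcripts whose summed
#' exon length is below `min_length` (a 200 nt transcript is retained; a
#' 199 nt one is not). The input is not modified.
#'
#' @param assembly an assembly.
#' @param min_length minimum summed exon length in nt.
#' @param require_strand drop unstranded (`"*"`) transcripts.
#' @return the filtered assembly.
#' @export
filter_assembly <- function(assembly, min_length = 200, require_strand = TRUE) {
  tx <- assembly$transcripts
  keep <- tx$length >= min_length
  if (require_strand) keep <- keep & tx$strand %in% c("+", "-")
  subset_assembly(assembly, tx$transcript_id[keep])
}

#' Intron chain of a transcript
#'
#' The ordered list of splice junctions: for exons sorted by start, junction
#' `i` is `(exon_i.end, exon_{i+1}.start)` in 0-based half-open coordinates.
#' Single-exon transcripts have an empty chain.
#'
#' @param record a [transcript_record()] (or any list with `chrom`, `strand`
#'   and a sorted `exons` table).
#' @return list with `chrom`, `strand` and `junctions` (data.table with
#'   columns `donor`, `acceptor`).
#' @export
intron_chain <- function(record) {
  ex <- record$exons[order(start)]
  j <- if (nrow(ex) > 1L)
    data.table(donor = ex$end[-nrow(ex)], acceptor = ex$start[-1L]) else
    data.table(donor = numeric(), acceptor = numeric())
  list(chrom = record$chrom, strand = record$strand, junctions = j)
}

# per-transcript chain key string; NA for single-exon transcripts
chain_keys_from_exons <- function(ex) {
  ex <- ex[order(transcript_id, start)]
  k <- ex[, .(key = if (.N == 1L) NA_character_ else
                paste(chrom[1L], strand[1L],
                      paste(end[-.N], start[-1L], sep = "-", collapse = ";"),
                      sep = "|")),
          by = transcript_id]
  setNames(k$key, k$transcript_id)
}

# junction table: one row per junction of every multi-exon transcript
junction_table <- function(assembly) {
  ex <- assembly$exons[order(transcript_id, start)]
  multi <- ex[, .N, by = transcript_id][N > 1L]$transcript_id
  ex <- ex[transcript_id %in% multi]
  if (!nrow(ex))
    return(data.table(transcript_id = character(), chrom = character(),
                      strand = character(), donor = numeric(),
                      acceptor = numeric()))
  ex[, .(chrom = chrom[-.N], strand = strand[-.N],
         donor = end[-.N], acceptor = start[-1L]), by = transcript_id]
}

utils::globalVariables("N")

# single-exon transcript table
single_exon_table <- function(assembly) {
  tx <- assembly$transcripts[n_exons == 1L,
                             .(transcript_id, chrom, strand)]
  if (!nrow(tx))
    return(data.table(transcript_id = character(), chrom = character(),
                      strand = character(), start = numeric(),
                      end = numeric(), len = numeric()))
  ex <- assembly$exons[transcript_id %in% tx$transcript_id]
  merge(tx, ex[, .(transcript_id, start, end, len = end - start)],
        by = "transcript_id")
}

# reciprocal-overlap matches between two single-exon tables; returns pairs
# with overlap length, restricted to same chrom and strand
single_exon_pairs <- function(a, b, frac) {
  if (!nrow(a) || !nrow(b)) {
    return(data.table(a_id = character(), b_id = character(), ovl = numeric()))
  }
  bb <- copy(b)[, end1 := end - 1]
  setkey(bb, chrom, strand, start, end1)
  aa <- copy(a)[, end1 := end - 1]
  hits <- foverlaps(aa, bb,
                    by.x = c("chrom", "strand", "start", "end1"),
                    type = "any", nomatch = NULL)
  if (!nrow(hits)) {
    return(data.table(a_id = character(), b_id = character(), ovl = numeric()))
  }
  # foverlaps: b columns keep names, a columns prefixed i.
  hits[, ovl := pmin(end, i.end) - pmax(start, i.start)]
  hits <- hits[ovl >= frac * len & ovl >= frac * i.len]
  hits[, .(a_id = i.transcript_id, b_id = transcript_id, ovl = ovl)]
}

utils::globalVariables(c("end1", "i.len", "a_id", "b_id"))

#' Match a query assembly against a reference
#'
#' Reference-based evaluation of an assembly. For every reference transcript:
#'
#' * `splice_completeness`: percent of its junctions present in any query
#'   transcript on the same chromosome and strand.
#' * `correctly_assembled`: a query transcript has an intron chain identical
#'   to the reference's (multi-exon), or, for a single-exon reference, a
#'   same-strand single-exon query overlaps it reciprocally by at least
#'   `single_exon_overlap`. Terminal exon outer boundaries are not required to
#'   match (junctions are what short-read assembly determines reliably).
#' * `exon_completeness`: percent of its exons recovered in the best-matching
#'   query transcript; internal exons need both boundaries exact, terminal
#'   exons only the splice-side boundary. Single-exon references score 100
#'   when the reciprocal-overlap rule succeeds and 0 otherwise.
#' * `best_query_id`: the query transcript sharing the most junctions (ties:
#'   most shared exon boundaries, then lexicographically smallest id); for
#'   single-exon references, the qualifying query with the largest overlap.
#'
#' @param query,reference assemblies (normally both already passed through
#'   [filter_assembly()]).
#' @param single_exon_overlap reciprocal-overlap fraction for the single-exon
#'   match rule.
#' @return data.table with one row per reference transcript: `reference_id`,
#'   `exon_completeness`, `splice_completeness` (percent, 0-100),
#'   `correctly_assembled`, `best_query_id` (NA when nothing is shared).
#' @export
match_assembly <- function(query, reference, single_exon_overlap = 0.9) {
  if (n_transcripts(reference) == 0)
    stop("empty reference: nothing to evaluate")
  rj <- junction_table(reference)
  qj <- junction_table(query)
  ref_tx <- reference$transcripts
  res <- data.table(reference_id = ref_tx$transcript_id,
                    n_junc = pmax(ref_tx$n_exons - 1L, 0L))
  # splice completeness against the union of query junctions
  res[, n_found := 0L]
  qj_set <- unique(qj[, .(chrom, strand, donor, acceptor)])
  if (nrow(rj) && nrow(qj_set)) {
    found <- qj_set[rj, on = c("chrom", "strand", "donor", "acceptor"),
                    which = TRUE]
    jf <- data.table(transcript_id = rj$transcript_id,
                     hit = !is.na(found))[, .(n_found = sum(hit)),
                                          by = transcript_id]
    res[jf, n_found := i.n_found, on = c(reference_id = "transcript_id")]
  }
  # chain identity
  ref_keys <- chain_keys_from_exons(reference$exons)
  query_keys <- chain_keys_from_exons(query$exons)
  qkey_set <- unique(query_keys[!is.na(query_keys)])
  correct_multi <- !is.na(ref_keys[res$reference_id]) &
    ref_keys[res$reference_id] %in% qkey_set
  # single-exon rule
  rse <- single_exon_table(reference)
  qse <- single_exon_table(query)
  se_pairs <- single_exon_pairs(rse, qse, single_exon_overlap)
  se_best <- se_pairs[order(a_id, -ovl, b_id)][, .SD[1L], by = a_id]
  correct_single <- res$reference_id %in% se_best$a_id
  res[, correctly_assembled := correct_multi | correct_single]
  res[, splice_completeness :=
        ifelse(n_junc > 0, 100 * n_found / n_junc,
               ifelse(correctly_assembled, 100, 0))]
  # best query per multi-exon reference: shared junction counts
  best <- data.table(reference_id = character(), best_query_id = character())
  if (nrow(rj) && nrow(qj)) {
    pairs <- merge(rj, qj, by = c("chrom", "strand", "donor", "acceptor"),
                   allow.cartesian = TRUE, suffixes = c(".r", ".q"))
    if (nrow(pairs)) {
      shared <- pairs[, .(shared = .N),
                      by = .(reference_id = transcript_id.r,
                             query_id = transcript_id.q)]
      top <- shared[, .SD[shared == max(shared)], by = reference_id]
      need_tie <- top[, .N, by = reference_id][N > 1L]$reference_id
      if (length(need_tie)) {
        tied <- top[reference_id %in% need_tie]
        tied[, shared_bnd := shared_boundaries(reference, query,
                                               reference_id, query_id),
             by = seq_len(nrow(tied))]
        tied_best <- tied[order(reference_id, -shared_bnd, query_id),
                          .SD[1L], by = reference_id]
        top <- rbind(top[!reference_id %in% need_tie], tied_best,
                     fill = TRUE)
      }
      best <- top[, .(reference_id, best_query_id = query_id)]
    }
  }
  # multi-exon references with no shared junction: fall back to shared exon
  # boundaries on the same chromosome and strand
  no_best <- setdiff(res$reference_id[res$n_junc > 0], best$reference_id)
  if (length(no_best)) {
    fb <- boundary_fallback(reference, query, no_best)
    best <- rbind(best, fb)
  }
  # single-exon references: best = qualifying overlap partner
  if (nrow(se_best)) {
    best <- rbind(best,
                  se_best[, .(reference_id = a_id, best_query_id = b_id)])
  }
  res[, best_query_id := NA_character_]
  if (nrow(best))
    res[best, best_query_id := i.best_query_id, on = "reference_id"]
  # exon completeness against the best query
  res[, exon_completeness := exon_completeness_vec(reference, query, res)]
  res[n_junc == 0L, exon_completeness := ifelse(correctly_assembled, 100, 0)]
  res[, n_found := NULL]
  res[, .(reference_id, exon_completeness, splice_completeness,
          correctly_assembled, best_query_id)]
}

utils::globalVariables(c("n_found", "hit", "transcript_id.r",
                         "transcript_id.q", "exon1"))

# count of shared exon boundary coordinates between one reference transcript
# and one query transcript (same chrom assumed by construction)
shared_boundaries <- function(reference, query, rid, qid) {
  re <- reference$exons[.(rid)]
  qe <- query$exons[.(qid)]
  length(intersect(c(re$start, re$end), c(qe$start, qe$end)))
}

# best query by shared boundaries for references sharing no junction
boundary_fallback <- function(reference, query, ref_ids) {
  out <- data.table(reference_id = character(), best_query_id = character())
  re <- reference$exons[transcript_id %in% ref_ids]
  if (!nrow(re) || !nrow(query$exons)) return(out)
  qb <- rbind(query$exons[, .(transcript_id, chrom, strand, bnd = start)],
              query$exons[, .(transcript_id, chrom, strand, bnd = end)])
  rb <- rbind(re[, .(transcript_id, chrom, strand, bnd = start)],
              re[, .(transcript_id, chrom, strand, bnd = end)])
  rb <- unique(rb); qb <- unique(qb)
  hits <- merge(rb, qb, by = c("chrom", "strand", "bnd"),
                allow.cartesian = TRUE, suffixes = c(".r", ".q"))
  if (!nrow(hits)) return(out)
  cnt <- hits[, .(shared_bnd = .N),
              by = .(reference_id = transcript_id.r,
                     query_id = transcript_id.q)]
  cnt[order(reference_id, -shared_bnd, query_id), .SD[1L],
      by = reference_id][, .(reference_id, best_query_id = query_id)]
}

utils::globalVariables("bnd")

# vectorized exon completeness for multi-exon references with a best query
exon_completeness_vec <- function(reference, query, res) {
  out <- numeric(nrow(res))
  has <- which(res$n_junc > 0L & !is.na(res$best_query_id))
  if (!length(has)) return(out)
  map <- res[has, .(reference_id, best_query_id)]
  re <- reference$exons[transcript_id %in% map$reference_id][order(transcript_id, start)]
  re[, `:=`(rank = seq_len(.N), ne = .N), by = transcript_id]
  re <- merge(re, map, by.x = "transcript_id", by.y = "reference_id")
  qe <- query$exons[transcript_id %in% map$best_query_id]
  pair_ok <- qe[re, on = c(transcript_id = "best_query_id", chrom = "chrom",
                           start = "start", end = "end"), which = TRUE]
  end_set <- unique(qe[, .(transcript_id, chrom, end)])
  end_ok <- end_set[re, on = c(transcript_id = "best_query_id",
                               chrom = "chrom", end = "end"), which = TRUE]
  start_set <- unique(qe[, .(transcript_id, chrom, start)])
  start_ok <- start_set[re, on = c(transcript_id = "best_query_id",
                                   chrom = "chrom", start = "start"),
                        which = TRUE]
  recovered <- ifelse(re$rank == 1L, !is.na(end_ok),
                      ifelse(re$rank == re$ne, !is.na(start_ok),
                             !is.na(pair_ok)))
  pct <- data.table(transcript_id = re$transcript_id, rec = recovered)[
    , .(pct = 100 * sum(rec) / .N), by = transcript_id]
  out[has] <- pct$pct[match(res$reference_id[has], pct$transcript_id)]
  out
}

utils::globalVariables(c("rank", "ne", "rec", "pct"))

utils::globalVariables(c("i.n_found", "i.best_query_id"))

#' Exon/splice completeness summary table
#'
#' Per coding class and feature (exon, splice), the share of reference
#' transcripts that are complete (exactly 100%), missing (exactly 0%) or
#' partial (in between). Given a list of per-replicate result sets, the mean
#' percentages are reported with standard deviations across replicates.
#'
#' @param results a [match_assembly()] result, or a list of them (replicates).
#' @param classes named character vector `reference_id -> class` (`coding` /
#'   `noncoding`); every reference id must be labeled.
#' @return data.table with columns `coding_class`, `feature`, `complete`,
#'   `missing`, `partial` (percent) and, for replicate input, `*_sd` columns.
#' @export
completeness_table <- function(results, classes) {
  if (is.data.frame(results)) results <- list(results)
  one <- function(res) {
    res <- as.data.table(res)
    cls <- classes[res$reference_id]
    if (anyNA(cls))
      stop("missing class label for reference transcript: ",
           res$reference_id[which(is.na(cls))[1L]])
    long <- rbind(
      data.table(coding_class = cls, feature = "exon",
                 value = res$exon_completeness),
      data.table(coding_class = cls, feature = "splice",
                 value = res$splice_completeness))
    long[, .(complete = 100 * mean(value >= 100 - 1e-9),
             missing = 100 * mean(value <= 1e-9),
             partial = 100 * mean(value > 1e-9 & value < 100 - 1e-9)),
         by = .(coding_class, feature)]
  }
  per_rep <- lapply(results, one)
  stacked <- rbindlist(per_rep)
  out <- stacked[, .(complete = mean(complete), missing = mean(missing),
                     partial = mean(partial)),
                 by = .(coding_class, feature)]
  if (length(per_rep) > 1L) {
    sds <- stacked[, .(complete_sd = sd(complete), missing_sd = sd(missing),
                       partial_sd = sd(partial)),
                   by = .(coding_class, feature)]
    out <- merge(out, sds, by = c("coding_class", "feature"))
  }
  setorder(out, coding_class, feature)
  out[]
}

utils::globalVariables(c("complete", "missing", "partial", "feature"))

#' Transcript-level assembly sensitivity
#'
#' Fraction of reference transcripts correctly assembled, per coding class and
#' overall. A zero denominator yields `NA` (undefined), never 0.
#'
#' @param results a [match_assembly()] result.
#' @param classes named vector `reference_id -> class`.
#' @return data.table with `coding_class` (`coding`, `noncoding`, `overall`),
#'   `n_reference`, `n_correct`, `sensitivity`.
#' @export
assembly_sensitivity <- function(results, classes) {
  res <- as.data.table(results)
  cls <- classes[res$reference_id]
  if (anyNA(cls))
    stop("missing class label for reference transcript: ",
         res$reference_id[which(is.na(cls))[1L]])
  per <- data.table(coding_class = cls,
                    ok = res$correctly_assembled)[
    , .(n_reference = .N, n_correct = sum(ok)), by = coding_class]
  all_row <- data.table(coding_class = "overall",
                        n_reference = nrow(res),
                        n_correct = sum(res$correctly_assembled))
  out <- rbind(per, all_row)
  out[, sensitivity := ifelse(n_reference > 0, n_correct / n_reference,
                              NA_real_)]
  setorder(out, coding_class)
  out[]
}

utils::globalVariables(c("ok", "n_reference", "n_correct", "sensitivity",
                         "n_query", "n_matched", "precision"))

#' Transcript-level assembly precision
#'
#' Fraction of query transcripts whose structure matches some reference
#' transcript (intron-chain identity for multi-exon queries; the reciprocal
#' single-exon overlap rule otherwise), per the query's own class labels and
#' overall. Each query transcript is counted at most once even if it matches
#' several reference transcripts. Query transcripts that match nothing are the
#' false positives. A zero denominator yields `NA`.
#'
#' @param query,reference assemblies.
#' @param single_exon_overlap reciprocal-overlap fraction.
#' @return data.table with `coding_class`, `n_query`, `n_matched`,
#'   `precision`.
#' @export
assembly_precision <- function(query, reference, single_exon_overlap = 0.9) {
  qtx <- query$transcripts
  matched_ids <- matched_query_ids(query, reference, single_exon_overlap)
  per <- data.table(coding_class = qtx$coding_class,
                    m = qtx$transcript_id %in% matched_ids)[
    , .(n_query = .N, n_matched = sum(m)), by = coding_class]
  all_row <- data.table(coding_class = "overall", n_query = nrow(qtx),
                        n_matched = length(matched_ids))
  out <- rbind(per, all_row)
  out[, precision := ifelse(n_query > 0, n_matched / n_query, NA_real_)]
  setorder(out, coding_class)
  out[]
}

utils::globalVariables("m")

# ids of query transcripts matching some reference transcript
matched_query_ids <- function(query, reference, frac) {
  qkeys <- chain_keys_from_exons(query$exons)
  rkeys <- chain_keys_from_exons(reference$exons)
  rset <- unique(rkeys[!is.na(rkeys)])
  multi_hit <- names(qkeys)[!is.na(qkeys) & qkeys %in% rset]
  qse <- single_exon_table(query)
  rse <- single_exon_table(reference)
  se <- single_exon_pairs(qse, rse, frac)
  unique(c(multi_hit, se$a_id))
}

#' Classify query transcripts against an annotation
#'
#' A query transcript is `annotated` when its structure matches an annotation
#' transcript (intron-chain identity, or the single-exon reciprocal-overlap
#' rule); `novel` when none of its exons overlaps any annotation exon on
#' either strand; `variant` otherwise (exon overlap with an annotated gene but
#' a different isoform structure).
#'
#' @param query,annotation assemblies.
#' @param single_exon_overlap reciprocal-overlap fraction for the match rule.
#' @return named character vector `transcript_id -> status`.
#' @export
classify_annotation_status <- function(query, annotation,
                                       single_exon_overlap = 0.9) {
  qtx <- query$transcripts
  status <- setNames(rep("novel", nrow(qtx)), qtx$transcript_id)
  if (!nrow(qtx)) return(status)
  ann <- matched_query_ids(query, annotation, single_exon_overlap)
  # any exonic overlap, strand-agnostic
  ae <- annotation$exons
  if (nrow(ae)) {
    aa <- copy(ae)[, end1 := end - 1]
    setkey(aa, chrom, start, end1)
    qq <- copy(query$exons)[, end1 := end - 1]
    hits <- foverlaps(qq, aa, by.x = c("chrom", "start", "end1"),
                      type = "any", nomatch = NULL)
    touching <- unique(hits$i.transcript_id)
    status[touching] <- "variant"
  }
  status[names(status) %in% ann] <- "annotated"
  status
}

#' Flag transcripts overlapping transposable elements
#'
#' A transcript is TE-containing when any exon overlaps any TE interval by at
#' least `min_overlap` nt (strand-agnostic). Overlap queries run on interval
#' trees ([GenomicRanges::findOverlaps()]); the result is independent of input
#' ordering.
#'
#' @param assembly an assembly.
#' @param te_intervals data.table/data.frame of 0-based half-open intervals
#'   with columns `chrom`, `start`, `end` (e.g. from [read_bed()]); `NULL` or
#'   empty marks every transcript `FALSE`.
#' @param min_overlap minimum exonic overlap in nt.
#' @return the assembly with `te_containing` set on every transcript.
#' @export
annotate_te_overlap <- function(assembly, te_intervals, min_overlap = 1) {
  tx <- copy(assembly$transcripts)
  tx[, te_containing := FALSE]
  te <- if (is.null(te_intervals)) NULL else as.data.table(te_intervals)
  if (!is.null(te) && nrow(te) && nrow(assembly$exons)) {
    ex <- assembly$exons
    ex_gr <- GenomicRanges::GRanges(ex$chrom,
                                    IRanges::IRanges(ex$start + 1, ex$end))
    te_gr <- GenomicRanges::GRanges(te$chrom,
                                    IRanges::IRanges(te$start + 1, te$end))
    ov <- GenomicRanges::findOverlaps(ex_gr, te_gr,
                                      minoverlap = min_overlap,
                                      ignore.strand = TRUE)
    hit_tx <- unique(ex$transcript_id[S4Vectors::queryHits(ov)])
    tx[transcript_id %in% hit_tx, te_containing := TRUE]
  }
  assembly$transcripts <- tx
  assembly
}

#' Recurrent-transcript filter across samples
#'
#' Collects the transcripts whose identical assembly occurs in at least
#' `min_samples` of the input assemblies. Multi-exon transcripts are keyed by
#' intron chain; single-exon transcripts are clustered per chromosome and
#' strand by reciprocal overlap (greedily, longest member first) with the
#' longest member as representative. Each output transcript carries its
#' recurrence count (number of distinct input assemblies containing it).
#'
#' @param assemblies list of assemblies.
#' @param min_samples minimum number of assemblies (>= 1).
#' @param single_exon_overlap reciprocal-overlap fraction for single-exon
#'   clustering.
#' @return an assembly of representative transcripts whose `transcripts`
#'   table has an extra `recurrence` column.
#' @export
recurrence_filter <- function(assemblies, min_samples,
                              single_exon_overlap = 0.9) {
  if (min_samples < 1) stop("min_samples must be >= 1")
  stopifnot(length(assemblies) >= 1)
  # multi-exon: chain tally
  cand <- rbindlist(lapply(seq_along(assemblies), function(ai) {
    a <- assemblies[[ai]]
    keys <- chain_keys_from_exons(a$exons)
    keys <- keys[!is.na(keys)]
    if (!length(keys)) return(NULL)
    tx <- a$transcripts[match(names(keys), transcript_id)]
    data.table(ai = ai, transcript_id = names(keys), chain = unname(keys),
               len = tx$length)
  }))
  rep_rows <- data.table(ai = integer(), transcript_id = character(),
                         recurrence = integer())
  if (nrow(cand)) {
    tally <- cand[, .(recurrence = data.table::uniqueN(ai)), by = chain]
    keep <- tally[recurrence >= min_samples]
    if (nrow(keep)) {
      reps <- cand[chain %in% keep$chain][
        order(chain, -len, transcript_id, ai), .SD[1L], by = chain]
      reps <- merge(reps, keep, by = "chain")
      rep_rows <- reps[, .(ai, transcript_id, recurrence)]
    }
  }
  # single-exon: greedy reciprocal-overlap clustering, longest member first
  se <- rbindlist(lapply(seq_along(assemblies), function(ai) {
    t <- single_exon_table(assemblies[[ai]])
    if (!nrow(t)) return(NULL)
    t[, ai := ai][]
  }))
  if (!is.null(se) && nrow(se)) {
    setorder(se, chrom, strand, -len, transcript_id, ai)
    se_rep <- se[, cluster_single_exons(.SD, single_exon_overlap),
                 by = .(chrom, strand)]
    se_keep <- se_rep[recurrence >= min_samples,
                      .(ai, transcript_id, recurrence)]
    rep_rows <- rbind(rep_rows, se_keep)
  }
  # assemble output from the source assemblies
  if (!nrow(rep_rows)) {
    empty <- new_assembly(data.table(transcript_id = character(),
                                     chrom = character(), start = numeric(),
                                     end = numeric(), strand = character()),
                          meta = sample_meta(sample_id = "recurrent"))
    empty$transcripts[, recurrence := integer()]
    return(empty)
  }
  pieces_ex <- list(); pieces_at <- list()
  for (i in seq_len(nrow(rep_rows))) {
    a <- assemblies[[rep_rows$ai[i]]]
    tid <- rep_rows$transcript_id[i]
    out_id <- sprintf("%s", tid)
    ex <- copy(a$exons[.(tid)])[, transcript_id := out_id]
    at <- copy(a$transcripts[.(tid)])[, transcript_id := out_id]
    pieces_ex[[i]] <- ex
    pieces_at[[i]] <- at
  }
  ex_all <- rbindlist(pieces_ex)
  at_all <- rbindlist(pieces_at)
  # disambiguate representatives that happen to share an id
  if (anyDuplicated(at_all$transcript_id)) {
    new_ids <- make.unique(at_all$transcript_id, sep = ".")
    remap <- setNames(new_ids, paste0(at_all$transcript_id, "#",
                                      seq_len(nrow(at_all))))
    for (i in seq_len(nrow(at_all))) {
      pieces_ex[[i]][, transcript_id := new_ids[i]]
      pieces_at[[i]][, transcript_id := new_ids[i]]
    }
    ex_all <- rbindlist(pieces_ex)
    at_all <- rbindlist(pieces_at)
  }
  asm <- new_assembly(ex_all[, .(transcript_id, chrom, start, end, strand)],
                      tx_attrs = at_all[, .(transcript_id, gene_id,
                                            coding_class, annotation_status,
                                            te_containing, expression)],
                      meta = sample_meta(sample_id = "recurrent"))
  asm$transcripts[, recurrence :=
                    rep_rows$recurrence[match(transcript_id,
                                              at_all$transcript_id)]]
  asm
}

utils::globalVariables(c("ai", "tally", "keep"))

# greedy clustering of one (chrom, strand) block of single-exon transcripts,
# pre-sorted by length desc then id; returns representative rows
cluster_single_exons <- function(block, frac) {
  n <- nrow(block)
  assigned <- rep(FALSE, n)
  reps <- integer(0); counts <- integer(0)
  for (i in seq_len(n)) {
    if (assigned[i]) next
    ovl <- pmin(block$end, block$end[i]) - pmax(block$start, block$start[i])
    member <- !assigned & ovl >= frac * block$len & ovl >= frac * block$len[i]
    member[i] <- TRUE
    assigned[member] <- TRUE
    reps <- c(reps, i)
    counts <- c(counts, data.table::uniqueN(block$ai[member]))
  }
  data.table(ai = block$ai[reps], transcript_id = block$transcript_id[reps],
             len = block$len[reps], recurrence = counts)
}
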