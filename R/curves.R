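#' Rank transcripts by expression and accumulate expression share
#'
#' Sorts transcripts by expression, descending (ties broken by transcript id
#' for determinism), and adds the rank percentile (`100 * rank / n`) and the
#' cumulative expression percentage. The cumulative curve is non-decreasing,
#' concave, and ends at 100.
#'
#' @param x an assembly whose transcripts carry expression values, or a
#'   data.frame with columns `transcript_id`, `expression` and optionally
#'   `coding_class`, `matched`, `annotated`.
#' @return data.table of class rows sorted by rank: `transcript_id`,
#'   `expression`, `percentile`, `cum_expr_pct`, plus any of `coding_class`,
#'   `matched`, `annotated` that were supplied.
#' @export
rank_by_expression <- function(x) {
  tab <- if (inherits(x, "assembly")) {
    x$transcripts[, .(transcript_id, expression, coding_class)]
  } else as.data.table(x)
  if (!all(c("transcript_id", "expression") %in% names(tab)))
    stop("need transcript_id and expression columns")
  if (!nrow(tab)) stop("no transcripts to rank")
  if (anyNA(tab$expression)) stop("missing expression values")
  if (all(tab$expression == 0)) stop("all expression values are zero")
  tab <- copy(tab)
  setorder(tab, -expression, transcript_id)
  n <- nrow(tab)
  tab[, percentile := 100 * seq_len(n) / n]
  tab[, cum_expr_pct := 100 * cumsum(expression) / sum(expression)]
  tab[]
}

#' Top-rank percentile needed to reach an expression share
#'
#' The smallest top-rank percentile whose cumulative expression reaches
#' `share` percent of the total (e.g. "95% of the RNA is in the top X% of
#' transcripts"). Non-decreasing in `share`.
#'
#' @param table a [rank_by_expression()] table.
#' @param share target share of total expression, in (0, 100].
#' @return the percentile (0-100].
#' @export
quantile_for_share <- function(table, share) {
  if (share <= 0 || share > 100) stop("share must be in (0, 100]")
  i <- which(table$cum_expr_pct >= share - 1e-9)[1L]
  table$percentile[i]
}

#' Cumulative assembly precision along the expression ranking
#'
#' At each rank `r`, the precision (share of matched transcripts) over the
#' top-`r` prefix of the ranking.
#'
#' @param table a ranked table with a logical `matched` column.
#' @return the table with a `cum_precision` column.
#' @export
cumulative_precision <- function(table) {
  if (!"matched" %in% names(table)) stop("table lacks a matched column")
  tab <- copy(as.data.table(table))
  tab[, cum_precision := cumsum(as.logical(matched)) / seq_len(.N)]
  tab[]
}

utils::globalVariables("cum_precision")

#' Assign expression-rank precision classes
#'
#' Partitions the ranked transcripts at the 30th and 60th rank percentiles
#' (configurable): class A is the top 30 percentile, B is (30, 60], C the
#' lowest 40. Also reports, per class, the share of annotated transcripts
#' when an `annotated` column is present.
#'
#' @param table a [rank_by_expression()] table.
#' @param boundaries two increasing percentiles in (0, 100).
#' @return list with `table` (input plus `precision_class` column) and
#'   `summary` (per class: size, share of ranked list, and share annotated if
#'   available).
#' @export
assign_precision_classes <- function(table, boundaries = c(30, 60)) {
  if (length(boundaries) != 2 || diff(boundaries) <= 0 ||
      any(boundaries <= 0) || any(boundaries >= 100))
    stop("boundaries must be two increasing percentiles inside (0, 100)")
  tab <- copy(as.data.table(table))
  tab[, precision_class := ifelse(percentile <= boundaries[1L], "A",
                                  ifelse(percentile <= boundaries[2L],
                                         "B", "C"))]
  summ <- tab[, .(n = .N, share_of_list = .N / nrow(tab)),
              by = precision_class]
  if ("annotated" %in% names(tab)) {
    ann <- tab[, .(pct_annotated = 100 * mean(as.logical(annotated))),
               by = precision_class]
    summ <- merge(summ, ann, by = "precision_class")
  }
  setorder(summ, precision_class)
  list(table = tab[], summary = summ[])
}

utils::globalVariables(c("precision_class", "share_of_list", "pct_annotated"))

#' Cumulative coding to noncoding ratio along the expression ranking
#'
#' At each rank, the coding:noncoding count ratio among the top-`r`
#' transcripts; undefined (`NA`) until the first noncoding transcript
#' appears.
#'
#' @param table a ranked table with a `coding_class` column.
#' @return the table with a `cum_ratio` column.
#' @export
cumulative_class_ratio <- function(table) {
  if (!"coding_class" %in% names(table))
    stop("table lacks a coding_class column")
  tab <- copy(as.data.table(table))
  nc <- cumsum(tab$coding_class == "noncoding")
  co <- cumsum(tab$coding_class == "coding")
  tab[, cum_ratio := ifelse(nc == 0, NA_real_, co / nc)]
  tab[]
}

utils::globalVariables("cum_ratio")

#' Build an expression-ranked evaluation table from a simulated sample
#'
#' Convenience constructor for the cumulative-curve inputs: emitted
#' transcripts with their abundance, class, matched flag (structure matches
#' the reference panel) and annotated flag (matches the annotated subset of
#' the panel).
#'
#' @param sample a [simulate_assembly()] sample (filtered or not).
#' @param panel the reference panel.
#' @param assembly optionally, a filtered version of the sample's assembly to
#'   use instead of the raw one.
#' @param single_exon_overlap reciprocal-overlap fraction for matching.
#' @return a [rank_by_expression()] table with `matched` and `annotated`.
#' @export
expression_table <- function(sample, panel, assembly = NULL,
                             single_exon_overlap = 0.9) {
  asm <- assembly %||% sample$assembly
  matched_ids <- matched_query_ids(asm, panel$assembly, single_exon_overlap)
  ann_ids <- panel$assembly$transcripts[annotation_status == "annotated",
                                        transcript_id]
  ann_asm <- subset_assembly(panel$assembly, ann_ids)
  ann_hit <- matched_query_ids(asm, ann_asm, single_exon_overlap)
  tab <- asm$transcripts[, .(transcript_id, expression, coding_class)]
  tab[, `:=`(matched = transcript_id %in% matched_ids,
             annotated = transcript_id %in% ann_hit)]
  rank_by_expression(tab)
}
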