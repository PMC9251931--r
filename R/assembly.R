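#' Assembly container
#'
#' An `assembly` bundles the transcripts of one sample: a transcript-level
#' attribute table and an exon table, plus sample metadata (the three read
#' depth levels: total, mapped, and assigned-to-transcript).
#'
#' Coordinates are 0-based half-open, so an exon's length is `end - start`.
#' Strand is `"+"`, `"-"` or `"*"` (unstranded). Exons of a transcript must be
#' sorted by start and pairwise non-overlapping, all on one chromosome.
#'
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand` (one strand value per transcript). Row order within a
#'   transcript is ignored; exons are re-sorted by start.
#' @param tx_attrs optional data.frame keyed by `transcript_id` with any of
#'   `gene_id`, `coding_class` (`"coding"`, `"noncoding"`, `"unknown"`),
#'   `annotation_status` (`"annotated"`, `"variant"`, `"novel"`, `"unknown"`),
#'   `te_containing` (logical), `expression` (non-negative numeric).
#' @param meta sample metadata, see [sample_meta()].
#' @return An object of class `assembly` with elements `meta`, `transcripts`
#'   (one row per transcript: id, gene, chrom, strand, class/status/TE/
#'   expression attributes, `n_exons`, `length`) and `exons`.
#' @seealso [read_gtf()], [filter_assembly()]
#' @export
new_assembly <- function(exons, tx_attrs = NULL, meta = sample_meta()) {
  ex <- as.data.table(exons)
  required <- c("transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(required, names(ex))
  if (length(miss)) stop("exon table lacks columns: ", paste(miss, collapse = ", "))
  ex <- ex[, required, with = FALSE]
  ex[, `:=`(transcript_id = as.character(transcript_id),
            chrom = as.character(chrom),
            start = as.numeric(start), end = as.numeric(end),
            strand = as.character(strand))]
  if (nrow(ex)) {
    if (any(!ex$strand %in% c("+", "-", "*")))
      stop("strand must be one of '+', '-', '*'")
    if (any(ex$start < 0)) stop("exon start must be >= 0")
    if (any(ex$end <= ex$start)) stop("exon end must exceed start")
    if (any(!nzchar(ex$chrom))) stop("chrom must be non-empty")
  }
  setorder(ex, transcript_id, start)
  ex[, exon_rank := seq_len(.N), by = transcript_id]
  # per-transcript invariants
  if (nrow(ex)) {
    bad <- ex[, .(multi_chrom = data.table::uniqueN(chrom) > 1L,
                  multi_strand = data.table::uniqueN(strand) > 1L,
                  overlapping = .N > 1L && any(start[-1L] < end[-.N])),
              by = transcript_id]
    if (any(bad$multi_chrom))
      stop("transcript on multiple chromosomes: ",
           bad$transcript_id[bad$multi_chrom][1L])
    if (any(bad$multi_strand))
      stop("transcript with inconsistent strand: ",
           bad$transcript_id[bad$multi_strand][1L])
    if (any(bad$overlapping))
      stop("transcript with overlapping exons: ",
           bad$transcript_id[bad$overlapping][1L])
  }
  tx <- ex[, .(chrom = chrom[1L], strand = strand[1L],
               n_exons = .N, length = sum(end - start)),
           by = transcript_id]
  tx[, `:=`(gene_id = transcript_id, coding_class = "unknown",
            annotation_status = "unknown", te_containing = NA,
            expression = NA_real_)]
  if (!is.null(tx_attrs) && nrow(as.data.frame(tx_attrs))) {
    at <- as.data.table(tx_attrs)
    if (!"transcript_id" %in% names(at))
      stop("tx_attrs must carry a transcript_id column")
    at[, transcript_id := as.character(transcript_id)]
    if (anyDuplicated(at$transcript_id))
      stop("duplicate transcript_id in tx_attrs")
    for (col in intersect(names(at),
                          c("gene_id", "coding_class", "annotation_status",
                            "te_containing", "expression"))) {
      idx <- match(tx$transcript_id, at$transcript_id)
      has <- !is.na(idx)
      data.table::set(tx, which(has), col, at[[col]][idx[has]])
    }
  }
  if (any(!tx$coding_class %in% c("coding", "noncoding", "unknown")))
    stop("coding_class must be coding/noncoding/unknown")
  if (any(!tx$annotation_status %in% c("annotated", "variant", "novel", "unknown")))
    stop("annotation_status must be annotated/variant/novel/unknown")
  if (anyDuplicated(tx$transcript_id))
    stop("duplicate transcript_id in assembly")
  setcolorder_tx(tx)
  setkey(ex, transcript_id)
  setkey(tx, transcript_id)
  structure(list(meta = validate_meta(meta), transcripts = tx[], exons = ex[]),
            class = "assembly")
}

setcolorder_tx <- function(tx) {
  data.table::setcolorder(tx, c("transcript_id", "gene_id", "chrom", "strand",
                                "coding_class", "annotation_status",
                                "te_containing", "expression", "n_exons",
                                "length"))
}

#' Sample metadata
#'
#' The three depth levels tracked per sample: total reads, reads mapped to the
#' genome, and reads assigned to a transcript. `0 <= assigned <= mapped <=
#' total` is enforced.
#'
#' @param sample_id,group_label identifiers (group = cell or tissue type).
#' @param total_reads,mapped_reads,assigned_reads read counts.
#' @return list of class `sample_meta`.
#' @export
sample_meta <- function(sample_id = "sample", group_label = "group",
                        total_reads = 0, mapped_reads = 0, assigned_reads = 0) {
  validate_meta(list(sample_id = sample_id, group_label = group_label,
                     total_reads = total_reads, mapped_reads = mapped_reads,
                     assigned_reads = assigned_reads))
}

validate_meta <- function(meta) {
  stopifnot(is.list(meta))
  defaults <- list(sample_id = "sample", group_label = "group",
                   total_reads = 0, mapped_reads = 0, assigned_reads = 0)
  for (nm in names(defaults)) if (is.null(meta[[nm]])) meta[[nm]] <- defaults[[nm]]
  if (!(meta$assigned_reads >= 0 && meta$assigned_reads <= meta$mapped_reads &&
        meta$mapped_reads <= meta$total_reads))
    stop("need 0 <= assigned_reads <= mapped_reads <= total_reads")
  class(meta) <- "sample_meta"
  meta
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %s: %d transcripts, %d exons (total reads %s)\n",
              x$meta$sample_id, nrow(x$transcripts), nrow(x$exons),
              format(x$meta$total_reads, big.mark = ",")))
  cls <- table(factor(x$transcripts$coding_class,
                      c("coding", "noncoding", "unknown")))
  cat(sprintf("  coding %d | noncoding %d | unknown %d\n",
              cls[["coding"]], cls[["noncoding"]], cls[["unknown"]]))
  invisible(x)
}

#' Number of transcripts in an assembly
#' @param assembly an [new_assembly()] object.
#' @return integer count.
#' @export
n_transcripts <- function(assembly) nrow(assembly$transcripts)

#' Extract one transcript record
#'
#' @param assembly an assembly.
#' @param id transcript id.
#' @return list with `transcript_id`, `chrom`, `strand`, attribute fields and
#'   an `exons` data.table (sorted, 0-based half-open).
#' @export
transcript_record <- function(assembly, id) {
  tx <- assembly$transcripts[.(id)]
  if (nrow(tx) != 1L || is.na(tx$chrom)) stop("unknown transcript: ", id)
  c(as.list(tx), list(exons = assembly$exons[.(id)][order(start)]))
}

#' Replace the transcript set of an assembly, keeping metadata
#' @keywords internal
subset_assembly <- function(assembly, ids) {
  keep_tx <- assembly$transcripts[transcript_id %in% ids]
  keep_ex <- assembly$exons[transcript_id %in% ids]
  structure(list(meta = assembly$meta, transcripts = keep_tx, exons = keep_ex),
            class = "assembly")
}
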