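#' Read a BED file of genomic intervals
#'
#' BED3+ reader for transposable-element (or any) interval annotations. BED is
#' already 0-based half-open, so coordinates pass through unchanged. If a
#' strand column (field 6) is present it is honored; otherwise intervals are
#' unstranded (`"*"`).
#'
#' @param path BED file path.
#' @return data.table with columns `chrom`, `start`, `end`, `strand`
#'   (plus `name` if field 4 exists).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.table(chrom = character(), start = numeric(), end = numeric(),
                      strand = character()))
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1L],
         ": non-numeric coordinates")
  if (any(end <= start))
    stop("malformed BED line ", which(end <= start)[1L], ": end <= start")
  if (any(start < 0))
    stop("malformed BED line ", which(start < 0)[1L], ": negative start")
  out <- data.table(chrom = chrom, start = start, end = end)
  if (all(nf >= 4L)) out[, name := vapply(fields, `[`, "", 4L)]
  out[, strand := if (all(nf >= 6L)) {
    s <- vapply(fields, `[`, "", 6L)
    ifelse(s %in% c("+", "-"), s, "*")
  } else "*"]
  out[]
}

utils::globalVariables("name")

#' Read a transcript coding-class table
#'
#' TSV with columns `transcript_id` and `class` (values `coding` or
#' `noncoding`), standing in for the output of a coding-potential classifier
#' such as FEELnc.
#'
#' @param path TSV path (header required).
#' @return named character vector: `transcript_id -> class`.
#' @export
read_class_table <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("transcript_id", "class") %in% names(tab)))
    stop("class table needs columns transcript_id and class")
  bad <- setdiff(unique(tab$class), c("coding", "noncoding"))
  if (length(bad))
    stop("unknown coding class value(s): ", paste(bad, collapse = ", "))
  dup <- tab[, data.table::uniqueN(class), by = transcript_id][V1 > 1L]
  if (nrow(dup))
    stop("conflicting classes for transcript(s): ",
         paste(head(dup$transcript_id, 5), collapse = ", "))
  tab <- unique(tab, by = "transcript_id")
  setNames(tab$class, tab$transcript_id)
}

utils::globalVariables("V1")

#' Join coding classes onto an assembly
#'
#' By default only transcripts whose class is `"unknown"` are updated; set
#' `overwrite = TRUE` to replace existing labels too.
#'
#' @param assembly an assembly.
#' @param classes named vector from [read_class_table()].
#' @param overwrite replace known labels as well.
#' @return the assembly with updated `coding_class`.
#' @export
assign_classes <- function(assembly, classes, overwrite = FALSE) {
  tx <- copy(assembly$transcripts)
  hit <- classes[tx$transcript_id]
  upd <- !is.na(hit) & (overwrite | tx$coding_class == "unknown")
  tx[upd, coding_class := hit[upd]]
  assembly$transcripts <- tx
  assembly
}

#' Read a cells-by-transcripts count matrix
#'
#' Accepts either a dense TSV (rows = transcripts, columns = cell barcodes,
#' first column = transcript ids) or a MatrixMarket triplet file with sidecar
#' row/column name files (`<path>.rownames`, `<path>.colnames`, one name per
#' line). Counts must be non-negative integers.
#'
#' @param path matrix file path.
#' @param format `"auto"`, `"tsv"` or `"mtx"`.
#' @return a [cell_matrix()].
#' @export
read_counts_matrix <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (nrow(m) != length(rn) || ncol(m) != length(cn))
      stop("sidecar row/column names do not match matrix dimensions")
    counts <- as.matrix(m)
    dimnames(counts) <- list(rn, cn)
  } else {
    tab <- fread(path, sep = "\t", header = TRUE)
    rn <- as.character(tab[[1L]])
    counts <- as.matrix(tab[, -1L, with = FALSE])
    rownames(counts) <- rn
  }
  cell_matrix(counts)
}

#' Cells-by-transcripts count matrix container
#'
#' @param counts numeric matrix, transcripts in rows (named), cells in
#'   columns (barcode names); non-negative integers.
#' @param classes optional named vector of coding classes for the row ids.
#' @return object of class `cell_matrix` with elements `counts`, `classes`,
#'   and `tag_total` (per-cell column sums).
#' @export
cell_matrix <- function(counts, classes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("tx", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  if (any(counts < 0)) stop("negative count in matrix")
  if (any(counts != round(counts))) stop("non-integer count in matrix")
  cls <- rep("unknown", nrow(counts))
  names(cls) <- rownames(counts)
  if (!is.null(classes)) {
    hit <- classes[rownames(counts)]
    cls[!is.na(hit)] <- hit[!is.na(hit)]
  }
  structure(list(counts = counts, classes = cls,
                 tag_total = colSums(counts)),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d transcripts x %d cells, median tag total %s\n",
              nrow(x$counts), ncol(x$counts),
              format(median(x$tag_total), big.mark = ",")))
  invisible(x)
}

#' Restrict a cell matrix to a transcript subset
#'
#' Models guiding the single-cell quantification with a smaller bulk-assembled
#' transcript set: rows outside `ids` are dropped and per-cell tag totals are
#' recomputed.
#'
#' @param cm a [cell_matrix()].
#' @param ids transcript ids to keep.
#' @return a cell_matrix.
#' @export
subset_cell_matrix <- function(cm, ids) {
  keep <- intersect(rownames(cm$counts), ids)
  cell_matrix(cm$counts[keep, , drop = FALSE], classes = cm$classes)
}
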