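#' Read a GTF file into an assembly
#'
#' Parses exon features of a GTF file (GENCODE/StringTie dialect) into an
#' [new_assembly()] object. GTF's 1-based inclusive coordinates are converted
#' to the internal 0-based half-open convention, so a GTF exon `100..200`
#' becomes the interval `[99, 200)` of length 101. Strand `"."` is kept as the
#' first-class unstranded value `"*"` (the length/strand confidence filter
#' needs to see such transcripts, not choke on them). Both quoted
#' (`key "value";`) and unquoted (`key value;`) attribute dialects are
#' accepted.
#'
#' Recognized transcript attributes: `transcript_id` (required on exon
#' features), `gene_id`, `coding_class`, `annotation_status`, `te_containing`,
#' `expression`; unknown class/status default to `"unknown"`.
#'
#' @param path GTF file path.
#' @param attribute_map optional named character vector renaming file
#'   attribute keys to the recognized ones, e.g. `c(FPKM = "expression")`.
#' @return an `assembly`.
#' @export
read_gtf <- function(path, attribute_map = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(new_assembly(data.table(transcript_id = character(),
                                   chrom = character(), start = numeric(),
                                   end = numeric(), strand = character())))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("malformed GTF line ", idx[which(nf < 9L)[1L]],
         ": expected 9 tab-separated fields, got ", nf[which(nf < 9L)[1L]])
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9L, byrow = TRUE)
  feature <- m[, 3L]
  is_exon <- feature == "exon"
  if (!any(is_exon)) {
    return(new_assembly(data.table(transcript_id = character(),
                                   chrom = character(), start = numeric(),
                                   end = numeric(), strand = character())))
  }
  start1 <- suppressWarnings(as.numeric(m[, 4L]))
  end1 <- suppressWarnings(as.numeric(m[, 5L]))
  bad <- which(is_exon & (is.na(start1) | is.na(end1)))
  if (length(bad))
    stop("malformed GTF line ", idx[bad[1L]], ": non-numeric coordinates")
  attrs <- lapply(m[, 9L], parse_gtf_attrs)
  if (!is.null(attribute_map)) {
    attrs <- lapply(attrs, function(a) {
      hit <- match(names(a), names(attribute_map))
      names(a)[!is.na(hit)] <- attribute_map[hit[!is.na(hit)]]
      a
    })
  }
  tid <- vapply(attrs, function(a) a[["transcript_id"]] %||% NA_character_,
                character(1))
  no_id <- which(is_exon & is.na(tid))
  if (length(no_id))
    stop("malformed GTF line ", idx[no_id[1L]],
         ": exon feature without transcript_id attribute")
  e <- which(is_exon)
  ex <- data.table(transcript_id = tid[e], chrom = m[e, 1L],
                   start = start1[e] - 1, end = end1[e],
                   strand = ifelse(m[e, 7L] %in% c("+", "-"), m[e, 7L], "*"))
  # transcript attributes may sit on `transcript` features rather than on the
  # exon lines: coalesce per transcript over every feature carrying its id
  all_i <- which(!is.na(tid))
  grab <- function(key) vapply(attrs[all_i],
                               function(a) a[[key]] %||% NA_character_,
                               character(1))
  at_all <- data.table(transcript_id = tid[all_i],
                       gene_id = grab("gene_id"),
                       coding_class = grab("coding_class"),
                       annotation_status = grab("annotation_status"),
                       te_containing = grab("te_containing"),
                       expression = grab("expression"))
  first_non_na <- function(x) {
    y <- x[!is.na(x)]
    if (length(y)) y[1L] else NA_character_
  }
  at <- at_all[transcript_id %in% ex$transcript_id,
               lapply(.SD, first_non_na), by = transcript_id]
  at[, expression := suppressWarnings(as.numeric(expression))]
  at[is.na(coding_class), coding_class := "unknown"]
  at[is.na(annotation_status), annotation_status := "unknown"]
  at[is.na(gene_id), gene_id := transcript_id]
  at[!coding_class %in% c("coding", "noncoding"), coding_class := "unknown"]
  at[!annotation_status %in% c("annotated", "variant", "novel"),
     annotation_status := "unknown"]
  at[, te_containing := c("TRUE" = TRUE, "FALSE" = FALSE)[toupper(te_containing)]]
  new_assembly(ex, tx_attrs = at)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# accepts GENCODE-quoted and unquoted attribute dialects
parse_gtf_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (!length(parts)) return(list())
  keys <- sub("[ \t].*$", "", parts)
  vals <- sub("^[^ \t]+[ \t]+", "", parts)
  vals <- gsub('^"|"$', "", vals)
  setNames(as.list(vals), keys)
}

#' Write an assembly to GTF
#'
#' Emits one `transcript` and per-exon `exon` features, converting internal
#' 0-based half-open coordinates back to GTF's 1-based inclusive convention.
#' Unstranded transcripts are written with `"."` strand. Attributes include
#' `gene_id`, `transcript_id`, and `coding_class` / `annotation_status` /
#' `te_containing` / `expression` whenever known. Output order is
#' deterministic: by chromosome, start, then transcript id.
#'
#' @param assembly an assembly.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_gtf <- function(assembly, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  tx <- copy(assembly$transcripts)
  if (!nrow(tx)) return(invisible(path))
  starts <- assembly$exons[, .(tx_start = min(start), tx_end = max(end)),
                           by = transcript_id]
  tx <- merge(tx, starts, by = "transcript_id")
  setorder(tx, chrom, tx_start, transcript_id)
  tx[, `:=`(ord = seq_len(.N), strand_out = ifelse(strand == "*", ".", strand))]
  src <- "depthsat"
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene_id,
                      tx$transcript_id)
  opt <- function(cur, field, value) {
    has <- !is.na(value) & value != "unknown"
    cur[has] <- paste0(cur[has], sprintf(' %s "%s";', field, value[has]))
    cur
  }
  attr_str <- opt(attr_str, "coding_class", tx$coding_class)
  attr_str <- opt(attr_str, "annotation_status", tx$annotation_status)
  attr_str <- opt(attr_str, "te_containing", as.character(tx$te_containing))
  attr_str <- opt(attr_str, "expression",
                  ifelse(is.na(tx$expression), NA_character_,
                         format(tx$expression, digits = 15, trim = TRUE)))
  tx_lines <- paste(tx$chrom, src, "transcript", tx$tx_start + 1, tx$tx_end,
                    ".", tx$strand_out, ".", attr_str, sep = "\t")
  ex <- merge(assembly$exons,
              tx[, .(transcript_id, ord, gene_id, strand_out)],
              by = "transcript_id")
  setorder(ex, ord, start)
  ex[, exon_rank := seq_len(.N), by = transcript_id]
  ex_lines <- paste(ex$chrom, src, "exon", ex$start + 1, ex$end, ".",
                    ex$strand_out, ".",
                    sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                            ex$gene_id, ex$transcript_id, ex$exon_rank),
                    sep = "\t")
  # interleave: each transcript line followed by its exon lines
  pos_tx <- tx$ord + c(0, cumsum(tabulate(ex$ord, nbins = nrow(tx))))[tx$ord]
  out <- character(length(tx_lines) + length(ex_lines))
  out[pos_tx] <- tx_lines
  out[-pos_tx] <- ex_lines
  writeLines(out, con)
  invisible(path)
}
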