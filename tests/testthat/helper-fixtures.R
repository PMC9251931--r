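# Shared fixture builders for the test suite. Everything is generated
# programmatically; nothing is read from checked-in data files.

# Compact assembly builder: spec is a named list, one element per transcript,
# each a list with `chrom` (default "chr1"), `strand` (default "+") and
# `exons`, a list of c(start, end) pairs in 0-based half-open coordinates.
toy_assembly <- function(spec, attrs = NULL, meta = sample_meta()) {
  rows <- lapply(names(spec), function(id) {
    s <- spec[[id]]
    ex <- do.call(rbind, s$exons)
    data.frame(transcript_id = id,
               chrom = if (is.null(s$chrom)) "chr1" else s$chrom,
               start = ex[, 1], end = ex[, 2],
               strand = if (is.null(s$strand)) "+" else s$strand,
               stringsAsFactors = FALSE)
  })
  new_assembly(do.call(rbind, rows), tx_attrs = attrs, meta = meta)
}

# Class vector for an assembly's transcripts (reference_id -> class).
class_vector <- function(assembly) {
  tx <- assembly$transcripts
  stats::setNames(tx$coding_class, tx$transcript_id)
}

# Random matching instance: a reference assembly of <= 25 transcripts and a
# query derived from it by a mix of exact copies, terminal-boundary trims
# (junctions intact), internal-junction jitter (chain broken), contiguous
# exon subsets, strand flips, plus unrelated noise transcripts. Also labels
# classes and annotation status randomly. Deterministic given `seed`.
random_instance <- function(seed) {
  set.seed(seed)
  n_ref <- sample(1:25, 1)
  chroms <- c("chr1", "chr2")
  cursor <- c(chr1 = 0, chr2 = 0)
  ref_rows <- vector("list", n_ref)
  ref_attr <- vector("list", n_ref)
  for (i in seq_len(n_ref)) {
    chrom <- sample(chroms, 1)
    ne <- sample(1:5, 1)
    lens <- sample(50:300, ne, replace = TRUE)
    gaps <- if (ne > 1) sample(90:500, ne - 1, replace = TRUE) else integer(0)
    start0 <- cursor[[chrom]] + sample(100:400, 1)
    starts <- start0 + cumsum(c(0, utils::head(lens, -1) + gaps))
    cursor[[chrom]] <- max(starts + lens)
    ref_rows[[i]] <- data.frame(transcript_id = sprintf("ref%03d", i),
                                chrom = chrom, start = starts,
                                end = starts + lens,
                                strand = sample(c("+", "-"), 1),
                                stringsAsFactors = FALSE)
    ref_attr[[i]] <- data.frame(transcript_id = sprintf("ref%03d", i),
                                coding_class = sample(c("coding", "noncoding"), 1),
                                annotation_status = sample(c("annotated", "novel"), 1),
                                expression = round(stats::rlnorm(1, 1, 1), 4),
                                stringsAsFactors = FALSE)
  }
  reference <- new_assembly(do.call(rbind, ref_rows),
                            tx_attrs = do.call(rbind, ref_attr))
  q_rows <- list(); q_attr <- list(); qi <- 0
  add_query <- function(ex) {
    qi <<- qi + 1
    id <- sprintf("q%03d", qi)
    ex$transcript_id <- id
    q_rows[[qi]] <<- ex
    q_attr[[qi]] <<- data.frame(transcript_id = id,
                                coding_class = sample(c("coding", "noncoding"), 1),
                                expression = round(stats::rlnorm(1, 0.5, 1), 4),
                                stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_ref)) {
    for (k in seq_len(sample(0:2, 1, prob = c(0.3, 0.5, 0.2)))) {
      ex <- ref_rows[[i]]
      mode <- sample(c("exact", "trim", "jitter", "subset", "flip"), 1)
      if (mode == "trim") {
        len1 <- ex$end[1] - ex$start[1]
        ex$start[1] <- max(0, ex$start[1] + sample(seq(-40, len1 - 10), 1))
        lenN <- ex$end[nrow(ex)] - ex$start[nrow(ex)]
        ex$end[nrow(ex)] <- ex$end[nrow(ex)] + sample(seq(-(lenN - 10), 40), 1)
      } else if (mode == "jitter" && nrow(ex) > 1) {
        j <- sample(2:nrow(ex), 1)
        lenj <- ex$end[j] - ex$start[j]
        ex$start[j] <- ex$start[j] + sample(seq_len(min(20, lenj - 10)), 1)
      } else if (mode == "subset" && nrow(ex) > 1) {
        a <- sample(nrow(ex), 1); b <- sample(nrow(ex), 1)
        ex <- ex[min(a, b):max(a, b), ]
      } else if (mode == "flip") {
        ex$strand <- ifelse(ex$strand == "+", "-", "+")
      }
      add_query(ex)
    }
  }
  for (k in seq_len(sample(0:3, 1))) {
    chrom <- sample(chroms, 1)
    ne <- sample(1:3, 1)
    lens <- sample(80:250, ne, replace = TRUE)
    gaps <- if (ne > 1) sample(100:400, ne - 1, replace = TRUE) else integer(0)
    start0 <- cursor[[chrom]] + 5000 + sample(100:2000, 1)
    starts <- start0 + cumsum(c(0, utils::head(lens, -1) + gaps))
    cursor[[chrom]] <- max(starts + lens)
    add_query(data.frame(transcript_id = "x", chrom = chrom, start = starts,
                         end = starts + lens,
                         strand = sample(c("+", "-"), 1),
                         stringsAsFactors = FALSE))
  }
  query <- if (qi > 0)
    new_assembly(do.call(rbind, q_rows), tx_attrs = do.call(rbind, q_attr))
  else
    new_assembly(data.frame(transcript_id = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            strand = character(), stringsAsFactors = FALSE))
  list(reference = reference, query = query)
}

# Small reference panel + one simulated sample, shared by several tests.
small_panel <- function(n = 300, seed = 5) {
  generate_reference(sim_config(n_transcripts = n, seed = seed))
}
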