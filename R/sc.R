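#' Median-of-ratios normalization of a cell matrix
#'
#' Size factor per cell = median, over transcripts nonzero in every cell, of
#' the ratio of the cell's count to the transcript's geometric mean across
#' cells; normalized count = count / size factor. When no transcript is
#' nonzero in all cells (the usual situation in sparse single-cell data), the
#' fallback uses transcripts nonzero in at least half the cells, with
#' geometric means over their nonzero cells; the result is flagged.
#'
#' Size factors are scale-equivariant: multiplying one cell's counts by `c`
#' multiplies its factor by `c` relative to the other cells' (all factors also
#' pick up a common constant from the geometric means), so the normalized
#' matrix changes only by one global constant.
#'
#' @param cm a [cell_matrix()] with >= 2 cells.
#' @param fallback use the sparse-data variant when needed.
#' @return list with `normalized` (matrix), `size_factors` (per cell),
#'   `fallback_used` (logical).
#' @export
normalize_median_of_ratios <- function(cm, fallback = TRUE) {
  counts <- cm$counts
  if (ncol(counts) < 2) stop("need at least 2 cells")
  all_nz <- rowSums(counts > 0) == ncol(counts)
  fallback_used <- FALSE
  if (any(all_nz)) {
    sub <- counts[all_nz, , drop = FALSE]
    gm <- exp(rowMeans(log(sub)))
    ratios <- sub / gm
  } else {
    if (!fallback)
      stop("no transcript is nonzero in all cells and fallback is disabled")
    fallback_used <- TRUE
    half_nz <- rowSums(counts > 0) >= ncol(counts) / 2 & rowSums(counts) > 0
    if (!any(half_nz))
      stop("no transcript is nonzero in at least half the cells")
    sub <- counts[half_nz, , drop = FALSE]
    gm <- exp(apply(sub, 1L, function(r) mean(log(r[r > 0]))))
    ratios <- sub / gm
    ratios[sub == 0] <- NA
  }
  sf <- apply(ratios, 2L, median, na.rm = TRUE)
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor for cell(s): ",
         paste(colnames(counts)[!is.finite(sf) | sf <= 0], collapse = ", "))
  list(normalized = sweep(counts, 2L, sf, "/"), size_factors = sf,
       fallback_used = fallback_used)
}

#' Per-transcript and per-cell detection statistics
#'
#' Detection is thresholded on raw counts (`count >= threshold`); normalized
#' expression is reported alongside. Per transcript: the percent of cells in
#' which it is detected, the mean normalized expression and the coefficient
#' of variation of normalized expression. The CV is computed over detecting
#' cells by default (zero inflation otherwise dominates the statistic); set
#' `cv_mode = "all"` for all cells. Per cell: the number of detected
#' transcripts per coding class.
#'
#' @param cm a [cell_matrix()].
#' @param normalized normalized matrix from [normalize_median_of_ratios()]
#'   (defaults to running it).
#' @param threshold minimum raw count for detection.
#' @param cv_mode `"detected"` or `"all"`.
#' @return list of class `detection_stats`: `per_transcript` (data.table:
#'   `transcript_id`, `coding_class`, `pct_cells_detected`, `mean_norm_expr`,
#'   `cv`), `per_cell` (data.table: `barcode`, `tag_total`, `n_detected`,
#'   `n_detected_coding`, `n_detected_noncoding`).
#' @export
detection_stats <- function(cm, normalized = NULL, threshold = 1,
                            cv_mode = c("detected", "all")) {
  cv_mode <- match.arg(cv_mode)
  if (is.null(normalized))
    normalized <- normalize_median_of_ratios(cm)$normalized
  det <- cm$counts >= threshold
  pct <- 100 * rowMeans(det)
  mean_norm <- rowMeans(normalized)
  cv <- vapply(seq_len(nrow(cm$counts)), function(i) {
    v <- if (cv_mode == "detected") normalized[i, det[i, ]] else normalized[i, ]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  }, numeric(1))
  per_tx <- data.table(transcript_id = rownames(cm$counts),
                       coding_class = unname(cm$classes),
                       pct_cells_detected = pct,
                       mean_norm_expr = mean_norm, cv = cv)
  cls <- cm$classes
  per_cell <- data.table(barcode = colnames(cm$counts),
                         tag_total = unname(cm$tag_total),
                         n_detected = colSums(det),
                         n_detected_coding = colSums(det[cls == "coding", ,
                                                         drop = FALSE]),
                         n_detected_noncoding =
                           colSums(det[cls == "noncoding", , drop = FALSE]))
  structure(list(per_transcript = per_tx, per_cell = per_cell,
                 threshold = threshold, cv_mode = cv_mode),
            class = "detection_stats")
}

#' @export
print.detection_stats <- function(x, ...) {
  cat(sprintf("<detection_stats> %d transcripts x %d cells (threshold %g)\n",
              nrow(x$per_transcript), nrow(x$per_cell), x$threshold))
  invisible(x)
}

#' Correlation between cell depth and detected transcript count
#'
#' Spearman rho between the per-cell tag total and the number of detected
#' transcripts, per coding class and overall.
#'
#' @param stats a [detection_stats()] result with >= 3 cells.
#' @return data.table with `coding_class` and `rho` (`NA` when the detected
#'   count is constant).
#' @export
depth_detection_correlation <- function(stats) {
  pc <- stats$per_cell
  if (nrow(pc) < 3) stop("need at least 3 cells")
  data.table(coding_class = c("coding", "noncoding", "overall"),
             rho = c(spearman_rho(pc$tag_total, pc$n_detected_coding),
                     spearman_rho(pc$tag_total, pc$n_detected_noncoding),
                     spearman_rho(pc$tag_total, pc$n_detected)))
}

#' Compare detection under two guiding transcript sets
#'
#' Pairs, per cell and coding class, the number of detected transcripts when
#' quantification is guided by assembly A versus assembly B (e.g. a
#' shallow-depth versus a deep-depth bulk assembly). Reports the fraction of
#' cells above the diagonal (more detected with B) per class.
#'
#' @param cm_a,cm_b cell matrices over the same barcodes.
#' @param threshold detection threshold on raw counts.
#' @return list with `per_cell` (data.table of paired counts) and `summary`
#'   (per class: fraction of cells above/on/below the diagonal).
#' @export
compare_guided_detection <- function(cm_a, cm_b, threshold = 1) {
  if (!identical(colnames(cm_a$counts), colnames(cm_b$counts)))
    stop("barcode mismatch between the two matrices")
  count_by_class <- function(cm) {
    det <- cm$counts >= threshold
    cls <- cm$classes
    list(coding = colSums(det[cls == "coding", , drop = FALSE]),
         noncoding = colSums(det[cls == "noncoding", , drop = FALSE]),
         overall = colSums(det))
  }
  a <- count_by_class(cm_a); b <- count_by_class(cm_b)
  per_cell <- rbindlist(lapply(c("coding", "noncoding", "overall"),
                               function(k)
    data.table(barcode = colnames(cm_a$counts), coding_class = k,
               n_detected_a = a[[k]], n_detected_b = b[[k]])))
  summary <- per_cell[, .(frac_above = mean(n_detected_b > n_detected_a),
                          frac_equal = mean(n_detected_b == n_detected_a),
                          frac_below = mean(n_detected_b < n_detected_a)),
                      by = coding_class]
  list(per_cell = per_cell, summary = summary)
}

utils::globalVariables(c("n_detected_a", "n_detected_b", "frac_above",
                         "barcode"))

#' Simulate a sparse single-cell count matrix over a reference panel
#'
#' Emulates 3'-tag single-cell quantification guided by a bulk transcript
#' set: per-cell tag totals are log-normal, tags are allocated to transcripts
#' multinomially with weight `expression x length`, and an extra
#' per-(cell, transcript) dropout is applied whose probability
#' `dropout_max * exp(-expression / dropout_scale)` decreases with
#' expression. Deterministic given `seed`.
#'
#' @param panel a [generate_reference()] panel.
#' @param n_cells number of cells (>= 1).
#' @param tag_meanlog,tag_sdlog log-normal parameters of per-cell tag totals.
#' @param dropout_max dropout probability at zero expression, in \[0, 1\].
#' @param dropout_scale expression scale of dropout decay (same units as the
#'   panel's expression).
#' @param seed integer seed.
#' @return a [cell_matrix()] with the panel's transcripts as rows.
#' @export
generate_cell_matrix <- function(panel, n_cells,
                                 tag_meanlog = log(5000), tag_sdlog = 0.5,
                                 dropout_max = 0.3, dropout_scale = 5,
                                 seed = 1) {
  stopifnot(inherits(panel, "reference_panel"), n_cells >= 1)
  tx <- panel$assembly$transcripts
  with_seed(derive_seed(seed, "cells"), {
    totals <- pmax(1, round(rlnorm(n_cells, tag_meanlog, tag_sdlog)))
    w <- tx$expression * tx$length
    counts <- vapply(totals, function(tt) rmultinom(1, tt, w)[, 1L],
                     numeric(nrow(tx)))
    counts <- matrix(counts, nrow = nrow(tx), ncol = n_cells)
    p_drop <- dropout_max * exp(-tx$expression / dropout_scale)
    if (any(p_drop > 0)) {
      dropm <- matrix(rbinom(length(counts), 1L,
                             rep(p_drop, times = n_cells)),
                      nrow = nrow(tx))
      counts <- counts * (1L - dropm)
    }
    rownames(counts) <- tx$transcript_id
    colnames(counts) <- sprintf("bc%05d", seq_len(n_cells))
    cell_matrix(counts,
                classes = setNames(tx$coding_class, tx$transcript_id))
  })
}
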