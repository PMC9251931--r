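#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average ranks).
#' A constant vector makes the coefficient undefined; `NA` is returned rather
#' than 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return coefficient in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  suppressWarnings(cor(x, y, method = "spearman"))
}

#' Local linear (loess-style) fit of counts against depth
#'
#' Degree-1 local regression with tricube weights over the span-nearest
#' neighbors, no robustness iterations: at an evaluation point `x0` the
#' `q = floor(span * n)` nearest training depths get weight
#' `(1 - (d / d_q)^3)^3` and a weighted least-squares line is solved. The same
#' weighting is used at arbitrary grid points, so the evaluator is defined
#' everywhere in the training range; outside it, predictions are clamped to
#' the boundary value (clamping is recorded in the fit's metadata).
#'
#' The pointwise standard error band is derived from the weighted residual
#' variance of the local neighborhood:
#' `se(x0)^2 = sigma_w^2 * x0' (X'WX)^{-1} x0` with
#' `sigma_w^2 = sum(w r^2) / sum(w)`.
#'
#' @param depths,counts training points (>= 5).
#' @param span neighborhood fraction in (0, 1].
#' @return object of class `depth_loess` with elements `x`, `y`, `span`,
#'   `rho` (Spearman coefficient of the training data), `range`.
#' @seealso [predict.depth_loess()], [increments()]
#' @export
loess_fit <- function(depths, counts, span = 0.75) {
  stopifnot(length(depths) == length(counts))
  if (length(depths) < 5) stop("need at least 5 points for a loess fit")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (floor(span * length(depths)) < 3)
    stop("span too small: local neighborhoods would have fewer than 3 points")
  o <- order(depths)
  structure(list(x = as.numeric(depths)[o], y = as.numeric(counts)[o],
                 span = span,
                 rho = spearman_rho(depths, counts),
                 range = range(depths)),
            class = "depth_loess")
}

# tricube local linear solve at a single point; returns c(fit, se)
local_fit_point <- function(x, y, x0, q) {
  d <- abs(x - x0)
  dq <- sort(d, partial = q)[q]
  w <- numeric(length(x))
  if (dq == 0) {
    # degenerate neighborhood (replicated depths): equal weights on the ties
    w[d == 0] <- 1
    if (sum(w > 0) < 2) return(c(mean(y[d == 0]), 0))
  } else {
    u <- d / dq
    w[u < 1] <- (1 - u[u < 1]^3)^3
  }
  xc <- x - x0
  sw <- sum(w); swx <- sum(w * xc); swx2 <- sum(w * xc^2)
  swy <- sum(w * y); swxy <- sum(w * xc * y)
  det <- sw * swx2 - swx^2
  if (det <= .Machine$double.eps * sw * max(swx2, 1)) {
    fit <- swy / sw
    res <- y - fit
    return(c(fit, sqrt(sum(w * res^2) / sw / sw)))
  }
  b <- (sw * swxy - swx * swy) / det
  a <- (swy - b * swx) / sw
  fit <- a                       # value at xc = 0
  res <- y - (a + b * xc)
  sig2 <- sum(w * res^2) / sw
  # var(a_hat) for weighted LS at the evaluation point: first diagonal entry
  # of (X'WX)^{-1} in centered coordinates
  var_a <- swx2 / det
  c(fit, sqrt(sig2 * var_a))
}

#' Evaluate a [loess_fit()] on new depths
#'
#' @param object a `depth_loess` fit.
#' @param newdata numeric vector of depths.
#' @param se also return the pointwise standard-error band.
#' @param ... unused.
#' @return numeric vector of fitted values, or (with `se = TRUE`) a
#'   data.table with `depth`, `fit`, `se`, `clamped`.
#' @export
predict.depth_loess <- function(object, newdata, se = FALSE, ...) {
  x <- object$x; y <- object$y
  q <- floor(object$span * length(x))
  x0 <- pmin(pmax(as.numeric(newdata), object$range[1]), object$range[2])
  out <- vapply(x0, function(p) local_fit_point(x, y, p, q), numeric(2))
  if (!se) return(out[1L, ])
  data.table(depth = as.numeric(newdata), fit = out[1L, ], se = out[2L, ],
             clamped = newdata < object$range[1] | newdata > object$range[2])
}

#' @export
print.depth_loess <- function(x, ...) {
  cat(sprintf("<depth_loess> %d points, span %.2f, rho = %.3f\n",
              length(x$x), x$span, x$rho))
  invisible(x)
}

#' Per-step transcript increments predicted from a loess fit
#'
#' The grid runs from 0 to `max_depth` in steps of `step` (10 million reads by
#' default); `increment_i = fit((i + 1) * step) - fit(i * step)`. Evaluation
#' outside the training range is clamped to the boundary value, so increments
#' there are 0; the `clamped` column records where this happened. Increments
#' telescope: their sum is `fit(max) - fit(0)`.
#'
#' @param fit a [loess_fit()].
#' @param max_depth upper end of the grid.
#' @param step grid step in reads.
#' @return data.table with `depth_from`, `depth_to`, `fit_from`, `fit_to`,
#'   `increment`, `clamped`.
#' @export
increments <- function(fit, max_depth, step = 1e7) {
  grid <- seq(0, max_depth, by = step)
  if (grid[length(grid)] < max_depth) grid <- c(grid, max_depth)
  v <- predict(fit, grid)
  data.table(depth_from = head(grid, -1), depth_to = tail(grid, -1),
             fit_from = head(v, -1), fit_to = tail(v, -1),
             increment = diff(v),
             clamped = head(grid, -1) < fit$range[1] |
               tail(grid, -1) > fit$range[2])
}

#' First depth at which the fitted increment falls below a threshold
#'
#' Scans an increment table for the first step whose predicted gain drops
#' below `threshold` transcripts, a simple operational definition of the
#' saturation depth.
#'
#' @param inc an [increments()] table.
#' @param threshold transcripts per step.
#' @return the `depth_to` of the first qualifying step (`NA` if none).
#' @export
saturation_depth <- function(inc, threshold) {
  i <- which(inc$increment < threshold)
  if (!length(i)) return(NA_real_)
  inc$depth_to[min(i)]
}

#' Build a depth-count series from assemblies
#'
#' One row per sample: its depth at the chosen measure (total, mapped or
#' assigned reads) and its transcript counts, overall and per coding class.
#'
#' @param assemblies list of assemblies (e.g. filtered simulated samples).
#' @param depth_measure which metadata read count to use as depth.
#' @return data.table of class rows (`sample_id`, `group_label`, `depth`,
#'   `n_all`, `n_coding`, `n_noncoding`).
#' @export
depth_series <- function(assemblies,
                         depth_measure = c("total", "mapped", "assigned")) {
  depth_measure <- match.arg(depth_measure)
  field <- paste0(switch(depth_measure, total = "total", mapped = "mapped",
                         assigned = "assigned"), "_reads")
  rbindlist(lapply(assemblies, function(a) {
    tx <- a$transcripts
    data.table(sample_id = a$meta$sample_id,
               group_label = a$meta$group_label,
               depth = as.numeric(a$meta[[field]]),
               n_all = nrow(tx),
               n_coding = sum(tx$coding_class == "coding"),
               n_noncoding = sum(tx$coding_class == "noncoding"))
  }))
}

#' Bin a depth series into fixed-width depth bins
#'
#' Half-open bins `[i * width, (i + 1) * width)`: a depth exactly at a
#' boundary belongs to the upper bin. Per bin, boxplot-style five-number
#' summaries of the transcript counts are returned.
#'
#' @param series a [depth_series()] table.
#' @param width bin width in reads.
#' @param count_col which count column to summarize.
#' @return data.table with `bin` (index), `depth_lo`, `depth_hi`, `n_samples`
#'   and `min`, `q1`, `median`, `q3`, `max`.
#' @export
bin_by_depth <- function(series, width = 1e7, count_col = "n_all") {
  s <- as.data.table(series)
  s[, bin := floor(depth / width)]
  s[, .(depth_lo = bin[1L] * width, depth_hi = (bin[1L] + 1) * width,
        n_samples = .N,
        min = min(.SD[[count_col]]),
        q1 = unname(quantile(.SD[[count_col]], 0.25)),
        median = unname(median(.SD[[count_col]])),
        q3 = unname(quantile(.SD[[count_col]], 0.75)),
        max = max(.SD[[count_col]])),
      by = bin][order(bin)]
}

#' Coding to noncoding transcript count ratio
#'
#' `n_coding / n_noncoding` per row; a zero noncoding count makes the ratio
#' undefined (`NA`), which is propagated rather than dropped.
#'
#' @param x a [depth_series()] table, or an assembly.
#' @return for a series, the series with a `ratio` column; for an assembly, a
#'   single number.
#' @export
coding_noncoding_ratio <- function(x) {
  if (inherits(x, "assembly")) {
    nc <- sum(x$transcripts$coding_class == "noncoding")
    co <- sum(x$transcripts$coding_class == "coding")
    return(if (nc == 0) NA_real_ else co / nc)
  }
  s <- copy(as.data.table(x))
  s[, ratio := ifelse(n_noncoding == 0, NA_real_, n_coding / n_noncoding)]
  s[]
}

utils::globalVariables("ratio")

#' Observed minus loess-predicted counts per sample group
#'
#' For each group (cell or tissue type) with at least `min_replicates`
#' samples, the deviations `observed - fit(depth)` of its samples from a fit
#' trained on the full series. Groups below the replicate threshold are
#' excluded.
#'
#' @param series a [depth_series()] table.
#' @param fit a [loess_fit()] trained on the full series for the chosen count.
#' @param count_col count column the fit predicts.
#' @param min_replicates minimum group size.
#' @return data.table with `group_label`, `sample_id`, `depth`, `observed`,
#'   `predicted`, `deviation`.
#' @export
observed_minus_predicted <- function(series, fit, count_col = "n_all",
                                     min_replicates = 8) {
  s <- as.data.table(series)
  sizes <- s[, .N, by = group_label]
  keep_groups <- sizes[N >= min_replicates]$group_label
  s <- s[group_label %in% keep_groups]
  if (!nrow(s))
    return(data.table(group_label = character(), sample_id = character(),
                      depth = numeric(), observed = numeric(),
                      predicted = numeric(), deviation = numeric()))
  pred <- predict(fit, s$depth)
  s[, .(group_label, sample_id, depth, observed = .SD[[count_col]],
        predicted = pred, deviation = .SD[[count_col]] - pred)]
}

utils::globalVariables(c("observed", "predicted", "deviation"))
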