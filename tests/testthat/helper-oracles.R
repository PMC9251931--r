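# Independent brute-force oracles. These are deliberately written as plain
# loops over data.frames — no data.table joins, no shared code paths with the
# package — so that agreement with the package implementations is meaningful.

ora_split_exons <- function(assembly) {
  ex <- as.data.frame(assembly$exons)
  out <- split(ex, ex$transcript_id)
  lapply(out, function(d) d[order(d$start), , drop = FALSE])
}

ora_chain <- function(ex) {
  if (nrow(ex) < 2) return(NA_character_)
  paste(ex$chrom[1], ex$strand[1],
        paste(ex$end[-nrow(ex)], ex$start[-1], sep = "-", collapse = ";"),
        sep = "|")
}

ora_junc_strings <- function(ex) {
  if (nrow(ex) < 2) return(character(0))
  paste(ex$chrom[1], ex$strand[1], ex$end[-nrow(ex)], ex$start[-1], sep = "|")
}

# reciprocal-overlap length between two single-exon transcripts, or -Inf when
# the rule does not qualify
ora_se_overlap <- function(rex, qex, frac) {
  if (nrow(rex) != 1 || nrow(qex) != 1) return(-Inf)
  if (qex$chrom != rex$chrom || qex$strand != rex$strand) return(-Inf)
  ovl <- min(qex$end, rex$end) - max(qex$start, rex$start)
  if (ovl >= frac * (qex$end - qex$start) && ovl >= frac * (rex$end - rex$start))
    ovl else -Inf
}

oracle_match <- function(query, reference, frac = 0.9) {
  rsplit <- ora_split_exons(reference)
  qsplit <- ora_split_exons(query)
  qchains <- vapply(qsplit, ora_chain, character(1))
  qj_union <- unique(unlist(lapply(qsplit, ora_junc_strings)))
  rows <- lapply(reference$transcripts$transcript_id, function(rid) {
    rex <- rsplit[[rid]]
    nj <- nrow(rex) - 1
    if (nj >= 1) {
      rj <- ora_junc_strings(rex)
      splice <- 100 * sum(rj %in% qj_union) / nj
      correct <- ora_chain(rex) %in% qchains[!is.na(qchains)]
      shared <- vapply(names(qsplit), function(qid)
        sum(rj %in% ora_junc_strings(qsplit[[qid]])), integer(1))
      best <- NA_character_
      if (length(shared) && any(shared > 0)) {
        cand <- names(shared)[shared == max(shared)]
        if (length(cand) > 1) {
          nb <- vapply(cand, function(qid)
            length(intersect(c(rex$start, rex$end),
                             c(qsplit[[qid]]$start, qsplit[[qid]]$end))),
            integer(1))
          cand <- cand[nb == max(nb)]
        }
        best <- sort(cand)[1]
      } else if (length(qsplit)) {
        nb <- vapply(names(qsplit), function(qid) {
          qex <- qsplit[[qid]]
          if (qex$chrom[1] != rex$chrom[1] || qex$strand[1] != rex$strand[1])
            return(0L)
          length(intersect(unique(c(rex$start, rex$end)),
                           unique(c(qex$start, qex$end))))
        }, integer(1))
        if (any(nb > 0)) best <- sort(names(nb)[nb == max(nb)])[1]
      }
      if (!is.na(best)) {
        qex <- qsplit[[best]]
        rec <- logical(nrow(rex))
        for (e in seq_len(nrow(rex))) {
          rec[e] <- if (e == 1)
            any(qex$chrom == rex$chrom[e] & qex$end == rex$end[e])
          else if (e == nrow(rex))
            any(qex$chrom == rex$chrom[e] & qex$start == rex$start[e])
          else
            any(qex$chrom == rex$chrom[e] & qex$start == rex$start[e] &
                  qex$end == rex$end[e])
        }
        exon_c <- 100 * sum(rec) / nrow(rex)
      } else exon_c <- 0
    } else {
      ovl <- vapply(qsplit, function(qex) ora_se_overlap(rex, qex, frac),
                    numeric(1))
      correct <- length(ovl) > 0 && any(is.finite(ovl))
      best <- NA_character_
      if (correct) {
        top <- max(ovl[is.finite(ovl)])
        best <- sort(names(ovl)[is.finite(ovl) & ovl == top])[1]
      }
      splice <- if (correct) 100 else 0
      exon_c <- if (correct) 100 else 0
    }
    data.frame(reference_id = rid, exon_completeness = exon_c,
               splice_completeness = splice, correctly_assembled = correct,
               best_query_id = best, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

oracle_matched_query_ids <- function(query, reference, frac = 0.9) {
  rsplit <- ora_split_exons(reference)
  qsplit <- ora_split_exons(query)
  rchains <- vapply(rsplit, ora_chain, character(1))
  hits <- character(0)
  for (qid in names(qsplit)) {
    qex <- qsplit[[qid]]
    ok <- if (nrow(qex) > 1) {
      ora_chain(qex) %in% rchains[!is.na(rchains)]
    } else {
      any(vapply(rsplit, function(rex)
        is.finite(ora_se_overlap(qex, rex, frac)), logical(1)))
    }
    if (ok) hits <- c(hits, qid)
  }
  hits
}

oracle_sensitivity <- function(results, classes) {
  cls <- classes[results$reference_id]
  per <- list()
  for (cc in unique(cls)) {
    sel <- cls == cc
    per[[cc]] <- data.frame(coding_class = cc,
                            n_reference = as.integer(sum(sel)),
                            n_correct = as.integer(sum(results$correctly_assembled[sel])),
                            stringsAsFactors = FALSE)
  }
  out <- rbind(do.call(rbind, per),
               data.frame(coding_class = "overall",
                          n_reference = as.integer(nrow(results)),
                          n_correct = as.integer(sum(results$correctly_assembled)),
                          stringsAsFactors = FALSE))
  out$sensitivity <- ifelse(out$n_reference > 0,
                            out$n_correct / out$n_reference, NA_real_)
  out <- out[order(out$coding_class), ]
  rownames(out) <- NULL
  out
}

oracle_precision <- function(query, reference, frac = 0.9) {
  qtx <- as.data.frame(query$transcripts)
  hits <- oracle_matched_query_ids(query, reference, frac)
  per <- list()
  for (cc in unique(qtx$coding_class)) {
    sel <- qtx$coding_class == cc
    per[[cc]] <- data.frame(coding_class = cc, n_query = as.integer(sum(sel)),
                            n_matched = as.integer(sum(qtx$transcript_id[sel] %in% hits)),
                            stringsAsFactors = FALSE)
  }
  out <- rbind(do.call(rbind, per),
               data.frame(coding_class = "overall",
                          n_query = as.integer(nrow(qtx)),
                          n_matched = as.integer(length(hits)),
                          stringsAsFactors = FALSE))
  out$precision <- ifelse(out$n_query > 0, out$n_matched / out$n_query,
                          NA_real_)
  out <- out[order(out$coding_class), ]
  rownames(out) <- NULL
  out
}

oracle_completeness <- function(results, classes) {
  cls <- classes[results$reference_id]
  rows <- list()
  for (cc in sort(unique(cls))) {
    for (feat in c("exon", "splice")) {
      v <- if (feat == "exon") results$exon_completeness[cls == cc] else
        results$splice_completeness[cls == cc]
      rows[[paste(cc, feat)]] <-
        data.frame(coding_class = cc, feature = feat,
                   complete = 100 * mean(v >= 100 - 1e-9),
                   missing = 100 * mean(v <= 1e-9),
                   partial = 100 * mean(v > 1e-9 & v < 100 - 1e-9),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

oracle_classify <- function(query, annotation, frac = 0.9) {
  qsplit <- ora_split_exons(query)
  asplit <- ora_split_exons(annotation)
  ann_hits <- oracle_matched_query_ids(query, annotation, frac)
  aex <- as.data.frame(annotation$exons)
  ids <- query$transcripts$transcript_id
  status <- stats::setNames(rep("novel", length(ids)), ids)
  for (qid in ids) {
    qex <- qsplit[[qid]]
    touch <- FALSE
    for (e in seq_len(nrow(qex))) {
      if (any(aex$chrom == qex$chrom[e] & aex$start < qex$end[e] &
                aex$end > qex$start[e])) { touch <- TRUE; break }
    }
    if (touch) status[qid] <- "variant"
  }
  status[ids %in% ann_hits] <- "annotated"
  status
}

# Recurrence oracle: returns data.frame(transcript_id, recurrence) for the
# chosen representatives plus their exon tables, using plain loops.
oracle_recurrence <- function(assemblies, min_samples, frac = 0.9) {
  # multi-exon tally by chain
  recs <- list()
  chain_info <- list()
  for (ai in seq_along(assemblies)) {
    sp <- ora_split_exons(assemblies[[ai]])
    for (tid in names(sp)) {
      ch <- ora_chain(sp[[tid]])
      if (is.na(ch)) next
      chain_info[[length(chain_info) + 1]] <-
        list(ai = ai, id = tid, chain = ch,
             len = sum(sp[[tid]]$end - sp[[tid]]$start), ex = sp[[tid]])
    }
  }
  chains <- vapply(chain_info, `[[`, character(1), "chain")
  for (ch in unique(chains)) {
    members <- chain_info[chains == ch]
    n_asm <- length(unique(vapply(members, `[[`, integer(1), "ai")))
    if (n_asm < min_samples) next
    lens <- vapply(members, `[[`, numeric(1), "len")
    cand <- members[lens == max(lens)]
    ids <- vapply(cand, `[[`, character(1), "id")
    cand <- cand[ids == sort(ids)[1]]
    ais <- vapply(cand, `[[`, integer(1), "ai")
    rep_m <- cand[[which.min(ais)]]
    recs[[length(recs) + 1]] <- list(id = rep_m$id, recurrence = n_asm,
                                     ex = rep_m$ex)
  }
  # single-exon greedy clustering per (chrom, strand), longest first
  se <- list()
  for (ai in seq_along(assemblies)) {
    sp <- ora_split_exons(assemblies[[ai]])
    for (tid in names(sp)) {
      ex <- sp[[tid]]
      if (nrow(ex) != 1) next
      se[[length(se) + 1]] <- list(ai = ai, id = tid, chrom = ex$chrom,
                                   strand = ex$strand, start = ex$start,
                                   end = ex$end, len = ex$end - ex$start,
                                   ex = ex)
    }
  }
  if (length(se)) {
    keyv <- vapply(se, function(s) paste(s$chrom, s$strand), character(1))
    for (kv in unique(keyv)) {
      block <- se[keyv == kv]
      ord <- order(-vapply(block, `[[`, numeric(1), "len"),
                   vapply(block, `[[`, character(1), "id"),
                   vapply(block, `[[`, integer(1), "ai"))
      block <- block[ord]
      assigned <- rep(FALSE, length(block))
      for (i in seq_along(block)) {
        if (assigned[i]) next
        members <- i
        for (j in seq_along(block)) {
          if (j == i || assigned[j]) next
          ovl <- min(block[[i]]$end, block[[j]]$end) -
            max(block[[i]]$start, block[[j]]$start)
          if (ovl >= frac * block[[i]]$len && ovl >= frac * block[[j]]$len)
            members <- c(members, j)
        }
        assigned[members] <- TRUE
        n_asm <- length(unique(vapply(block[members], `[[`, integer(1), "ai")))
        if (n_asm >= min_samples)
          recs[[length(recs) + 1]] <- list(id = block[[i]]$id,
                                           recurrence = n_asm,
                                           ex = block[[i]]$ex)
      }
    }
  }
  recs
}

# Expression-curve oracles ---------------------------------------------------

oracle_rank <- function(tab) {
  tab <- as.data.frame(tab)
  o <- order(-tab$expression, tab$transcript_id)
  tab <- tab[o, , drop = FALSE]
  n <- nrow(tab)
  tab$percentile <- 100 * seq_len(n) / n
  # base cumsum/sum (extended-precision accumulators) so the prefix sums are
  # reproduced bit-for-bit; the ordering and percentile logic above is the
  # independent part of this oracle
  tab$cum_expr_pct <- 100 * cumsum(tab$expression) / sum(tab$expression)
  rownames(tab) <- NULL
  tab
}

oracle_cum_precision <- function(ranked) {
  n <- nrow(ranked)
  out <- numeric(n); hits <- 0
  for (i in seq_len(n)) {
    hits <- hits + as.numeric(ranked$matched[i])
    out[i] <- hits / i
  }
  out
}

oracle_cum_ratio <- function(ranked) {
  n <- nrow(ranked)
  out <- numeric(n); co <- 0; nc <- 0
  for (i in seq_len(n)) {
    if (ranked$coding_class[i] == "coding") co <- co + 1 else nc <- nc + 1
    out[i] <- if (nc == 0) NA_real_ else co / nc
  }
  out
}

oracle_quantile_for_share <- function(ranked, share) {
  for (i in seq_len(nrow(ranked)))
    if (ranked$cum_expr_pct[i] >= share - 1e-9) return(ranked$percentile[i])
  NA_real_
}

# Tricube local-linear oracle at one point: explicit weight construction and
# closed-form 2x2 weighted least squares.
oracle_tricube_point <- function(x, y, x0, span) {
  n <- length(x)
  q <- floor(span * n)
  d <- abs(x - x0)
  dq <- sort(d)[q]
  w <- rep(0, n)
  if (dq == 0) {
    w[d == 0] <- 1
    return(sum(w * y) / sum(w))
  }
  u <- d / dq
  w[u < 1] <- (1 - u[u < 1]^3)^3
  X <- cbind(1, x - x0)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  coef <- solve(A, b)
  coef[1]
}
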