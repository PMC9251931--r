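test_that("length filter keeps 200 nt and drops 199 nt and unstranded", {
  asm <- toy_assembly(list(
    keep = list(exons = list(c(0, 200))),
    drop_len = list(exons = list(c(300, 499))),
    drop_strand = list(exons = list(c(600, 900)), strand = "*"),
    keep_split = list(exons = list(c(1000, 1100), c(1200, 1300)))))
  f <- filter_assembly(asm)
  expect_setequal(f$transcripts$transcript_id, c("keep", "keep_split"))
})

test_that("a 4-exon transcript has 3 junctions with half-open coordinates", {
  asm <- toy_assembly(list(t = list(
    exons = list(c(0, 100), c(200, 300), c(400, 500), c(600, 700)))))
  ch <- intron_chain(transcript_record(asm, "t"))
  expect_equal(nrow(ch$junctions), 3)
  expect_equal(ch$junctions$donor, c(100, 300, 500))
  expect_equal(ch$junctions$acceptor, c(200, 400, 600))
  se <- intron_chain(transcript_record(
    toy_assembly(list(s = list(exons = list(c(0, 50))))), "s"))
  expect_equal(nrow(se$junctions), 0)
})

test_that("terminal boundaries are free: trimmed copy still matches chain", {
  ref <- toy_assembly(list(r = list(
    exons = list(c(0, 100), c(200, 300), c(400, 500)))))
  qry <- toy_assembly(list(q = list(
    exons = list(c(40, 100), c(200, 300), c(400, 470)))))
  res <- match_assembly(qry, ref)
  expect_true(res$correctly_assembled)
  expect_equal(res$splice_completeness, 100)
  # internal exon complete, terminal exons' splice-side boundaries match
  expect_equal(res$exon_completeness, 100)
})

test_that("partial recovery yields the worked 2-of-3-junction case", {
  ref <- toy_assembly(list(r = list(
    exons = list(c(0, 100), c(200, 300), c(400, 500), c(600, 700)))))
  # query covers the first three exons only: junctions 1 and 2 of 3
  qry <- toy_assembly(list(q = list(
    exons = list(c(0, 100), c(200, 300), c(400, 500)))))
  res <- match_assembly(qry, ref)
  expect_false(res$correctly_assembled)
  expect_equal(res$splice_completeness, 100 * 2 / 3)
  # exons 1, 2 recovered; exon 3 is terminal in the query so its end (500)
  # exists, and ref exon 3 is internal needing both boundaries: recovered;
  # exon 4 missing -> 3 of 4
  expect_equal(res$exon_completeness, 75)
  expect_equal(res$best_query_id, "q")
})

test_that("single-exon matching uses the reciprocal 0.9 overlap rule", {
  ref <- toy_assembly(list(r = list(exons = list(c(0, 1000)))))
  hit <- toy_assembly(list(q = list(exons = list(c(50, 1000)))))   # 95%
  miss <- toy_assembly(list(q = list(exons = list(c(500, 1000))))) # 50%
  other_strand <- toy_assembly(list(q = list(exons = list(c(0, 1000)),
                                             strand = "-")))
  expect_true(match_assembly(hit, ref)$correctly_assembled)
  expect_equal(match_assembly(hit, ref)$exon_completeness, 100)
  expect_false(match_assembly(miss, ref)$correctly_assembled)
  expect_equal(match_assembly(miss, ref)$exon_completeness, 0)
  expect_false(match_assembly(other_strand, ref)$correctly_assembled)
  # non-reciprocal: query much longer than reference
  long <- toy_assembly(list(q = list(exons = list(c(0, 2000)))))
  expect_false(match_assembly(long, ref)$correctly_assembled)
})

test_that("sensitivity and precision on a constructed mixed fixture", {
  ref <- toy_assembly(list(
    r1 = list(exons = list(c(0, 100), c(200, 300))),
    r2 = list(exons = list(c(1000, 1100), c(1200, 1300))),
    r3 = list(exons = list(c(2000, 2500))),
    r4 = list(exons = list(c(3000, 3100), c(3200, 3300)), strand = "-")),
    attrs = data.frame(transcript_id = c("r1", "r2", "r3", "r4"),
                       coding_class = c("coding", "coding", "noncoding",
                                        "noncoding")))
  qry <- toy_assembly(list(
    q1 = list(exons = list(c(0, 100), c(200, 300))),      # matches r1
    q2 = list(exons = list(c(2010, 2500))),               # matches r3 (98%)
    q3 = list(exons = list(c(5000, 5100), c(5300, 5400))),# false positive
    q4 = list(exons = list(c(7000, 7400)))),              # false positive
    attrs = data.frame(transcript_id = c("q1", "q2", "q3", "q4"),
                       coding_class = c("coding", "noncoding", "coding",
                                        "noncoding")))
  cls <- class_vector(ref)
  sens <- assembly_sensitivity(match_assembly(qry, ref), cls)
  expect_equal(sens[sens$coding_class == "coding"]$sensitivity, 0.5)
  expect_equal(sens[sens$coding_class == "noncoding"]$sensitivity, 0.5)
  expect_equal(sens[sens$coding_class == "overall"]$sensitivity, 0.5)
  prec <- assembly_precision(qry, ref)
  expect_equal(prec[prec$coding_class == "overall"]$precision, 0.5)
  expect_equal(prec[prec$coding_class == "coding"]$precision, 0.5)
})

test_that("zero denominators give NA, not zero", {
  ref <- toy_assembly(list(r = list(exons = list(c(0, 100), c(200, 300)))),
                      attrs = data.frame(transcript_id = "r",
                                         coding_class = "coding"))
  qry <- toy_assembly(list(q = list(exons = list(c(0, 100), c(200, 300)))),
                      attrs = data.frame(transcript_id = "q",
                                         coding_class = "coding"))
  sens <- assembly_sensitivity(match_assembly(qry, ref), class_vector(ref))
  expect_false("noncoding" %in% sens$coding_class)
  emptyq <- new_assembly(data.frame(transcript_id = character(),
                                    chrom = character(), start = numeric(),
                                    end = numeric(), strand = character()))
  prec <- assembly_precision(emptyq, ref)
  expect_true(is.na(prec[prec$coding_class == "overall"]$precision))
})

test_that("completeness_table reproduces hand-computed strata", {
  ref <- toy_assembly(list(
    r1 = list(exons = list(c(0, 100), c(200, 300))),
    r2 = list(exons = list(c(1000, 1100), c(1200, 1300), c(1400, 1500))),
    r3 = list(exons = list(c(2000, 2400)))),
    attrs = data.frame(transcript_id = c("r1", "r2", "r3"),
                       coding_class = c("coding", "coding", "noncoding")))
  qry <- toy_assembly(list(
    q1 = list(exons = list(c(0, 100), c(200, 300))),       # r1 complete
    q2 = list(exons = list(c(1000, 1100), c(1200, 1300))))) # r2 partial
  tab <- completeness_table(match_assembly(qry, ref), class_vector(ref))
  cod_sp <- tab[tab$coding_class == "coding" & tab$feature == "splice"]
  expect_equal(cod_sp$complete, 50)
  expect_equal(cod_sp$partial, 50)
  expect_equal(cod_sp$missing, 0)
  nc_ex <- tab[tab$coding_class == "noncoding" & tab$feature == "exon"]
  expect_equal(nc_ex$missing, 100)
  # replicate input yields means and SDs
  tab2 <- completeness_table(list(match_assembly(qry, ref),
                                  match_assembly(qry, ref)),
                             class_vector(ref))
  expect_true(all(c("complete_sd", "missing_sd") %in% names(tab2)))
  expect_equal(tab2$complete_sd, rep(0, nrow(tab2)))
})

test_that("annotation status classifies annotated, variant and novel", {
  ann <- toy_assembly(list(a = list(
    exons = list(c(0, 100), c(200, 300)))))
  qry <- toy_assembly(list(
    same = list(exons = list(c(10, 100), c(200, 280))),  # same chain
    iso = list(exons = list(c(0, 100), c(250, 300))),    # overlapping isoform
    anti = list(exons = list(c(0, 100)), strand = "-"),  # overlap, other strand
    far = list(exons = list(c(9000, 9200)))))            # no overlap
  st <- classify_annotation_status(qry, ann)
  expect_equal(st[["same"]], "annotated")
  expect_equal(st[["iso"]], "variant")
  expect_equal(st[["anti"]], "variant")  # exonic overlap is strand-agnostic
  expect_equal(st[["far"]], "novel")
})

test_that("TE overlap is exonic, strand-agnostic, and >= 1 nt by default", {
  asm <- toy_assembly(list(
    hit = list(exons = list(c(0, 100), c(200, 300))),
    intronic = list(exons = list(c(1000, 1100), c(1400, 1500))),
    clean = list(exons = list(c(5000, 5200)))))
  te <- data.frame(chrom = "chr1", start = c(99, 1150), end = c(150, 1350))
  out <- annotate_te_overlap(asm, te)
  tx <- out$transcripts
  expect_true(tx[tx$transcript_id == "hit"]$te_containing)
  expect_false(tx[tx$transcript_id == "intronic"]$te_containing)  # intron only
  expect_false(tx[tx$transcript_id == "clean"]$te_containing)
  # min_overlap raises the bar: the 1 nt overlap no longer counts
  out2 <- annotate_te_overlap(asm, te, min_overlap = 2)
  expect_false(out2$transcripts[.("hit")]$te_containing)
  out3 <- annotate_te_overlap(asm, NULL)
  expect_false(any(out3$transcripts$te_containing))
})

test_that("recurrence filter tallies chains across samples", {
  a1 <- toy_assembly(list(
    x = list(exons = list(c(0, 100), c(200, 300))),
    y = list(exons = list(c(1000, 1200)))))
  a2 <- toy_assembly(list(
    x2 = list(exons = list(c(20, 100), c(200, 320))),  # same chain as x
    z = list(exons = list(c(5000, 5100), c(5200, 5300)))))
  a3 <- toy_assembly(list(
    y2 = list(exons = list(c(1010, 1210)))))           # overlaps y ~95%
  rec2 <- recurrence_filter(list(a1, a2, a3), min_samples = 2)
  # x and x2 tie at length 200, as do y and y2: the lexicographically
  # smaller ids win as representatives
  expect_setequal(rec2$transcripts$transcript_id, c("x", "y"))
  expect_equal(rec2$transcripts[.("x")]$recurrence, 2)
  expect_equal(rec2$transcripts[.("x")]$length, 200)
  # min_samples = 1 keeps every distinct structure, one representative each:
  # the x chain, the z chain, and the y/y2 single-exon cluster
  rec1 <- recurrence_filter(list(a1, a2, a3), min_samples = 1)
  expect_equal(n_transcripts(rec1), 3)
  rec3 <- recurrence_filter(list(a1, a2, a3), min_samples = 3)
  expect_equal(n_transcripts(rec3), 0)
})

test_that("match_assembly requires a non-empty reference", {
  empty <- new_assembly(data.frame(transcript_id = character(),
                                   chrom = character(), start = numeric(),
                                   end = numeric(), strand = character()))
  qry <- toy_assembly(list(q = list(exons = list(c(0, 100)))))
  expect_error(match_assembly(qry, empty), "empty reference")
})
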