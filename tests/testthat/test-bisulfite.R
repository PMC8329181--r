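test_that("bisulfite conversion applies the per-position rule", {
  r <- bisulfite_reference("ACGACA")
  expect_equal(r$cpg_sites, 1L)
  # methylated CpG C retained, non-CpG C converted
  expect_equal(bisulfite_convert(r, methylated_sites = 1)$residues, "ACGATA")
  # no methylation: zero C left on the strand
  expect_false(grepl("C", bisulfite_convert(r)$residues))
  # all CpGs methylated: C survives exactly at the CpG sites
  full <- bisulfite_convert(r, methylated_sites = r$cpg_sites)$residues
  expect_equal(as.integer(gregexpr("C", full)[[1]]) - 1L, r$cpg_sites)
  expect_error(bisulfite_convert(r, methylated_sites = 3), "subset")
})

test_that("conversion is idempotent on its own output", {
  set.seed(17)
  for (i in 1:20) {
    s <- random_seq(150)
    r <- bisulfite_reference(s)
    meth <- r$cpg_sites[stats::runif(length(r$cpg_sites)) < 0.5]
    once <- bisulfite_convert(r, meth)$residues
    r2 <- bisulfite_reference(once)
    # surviving Cs are exactly the methylated CpGs, still CpGs, so a second
    # conversion with the same sites is a no-op
    again <- bisulfite_convert(r2, intersect(meth, r2$cpg_sites))$residues
    expect_equal(again, once)
  }
})

test_that("clones align to the correct strand with converted-state identity", {
  s <- random_seq(200)
  set.seed(23)
  r <- bisulfite_reference(s)
  ot <- bisulfite_convert(r, strand = "+")
  al <- align_clone(ot, r)
  expect_equal(al$strand, "+")
  expect_equal(al$identity, 1.0)
  expect_false(grepl("-", al$clone_aligned))

  ob <- bisulfite_convert(r, strand = "-")
  al2 <- align_clone(ob, r)
  expect_equal(al2$strand, "-")
  expect_equal(al2$identity, 1.0)
})

test_that("a planted internal deletion is reproduced in the alignment", {
  set.seed(29)
  s <- random_seq(200)
  r <- bisulfite_reference(s)
  conv <- bisulfite_convert(r)$residues
  clone <- paste0(substr(conv, 1, 100), substr(conv, 103, 200))
  al <- align_clone(clone, r)
  expect_equal(al$strand, "+")
  gaps <- gregexpr("-+", al$clone_aligned)[[1]]
  expect_equal(length(gaps), 1)
  expect_equal(attr(gaps, "match.length"), 2L)
  expect_equal(sum(al$ref_map == "-"), 2)
})

test_that("methylation calls read C/T at CpG sites with gaps ambiguous", {
  set.seed(31)
  s <- paste0("TTACGTT", "AACGAA", "TTCGTT", "AACGTA", "GGCGAT",
              "TACGGT", "AACGCA", "TTCGAA")  # 8 CpGs
  r <- bisulfite_reference(s)
  expect_equal(length(r$cpg_sites), 8)
  meth <- r$cpg_sites[c(2, 5)]
  clone <- bisulfite_convert(r, meth)
  al <- align_clone(clone, r)
  calls <- call_methylation(al, r$cpg_sites)
  expect_equal(which(calls == "M"), c(2L, 5L))
  expect_equal(which(calls == "U"), setdiff(1:8, c(2, 5)))

  # fully converted clone: everything unmethylated
  expect_true(all(call_methylation(align_clone(bisulfite_convert(r), r),
                                   r$cpg_sites) == "U"))

  # deletion spanning one CpG makes only that site ambiguous; site 5 sits
  # in a GG..AT context where the gap placement is unambiguous
  conv <- bisulfite_convert(r)$residues
  site5 <- r$cpg_sites[5] + 1
  clone_del <- paste0(substr(conv, 1, site5 - 1), substr(conv, site5 + 2,
                                                         nchar(conv)))
  calls_del <- call_methylation(align_clone(clone_del, r), r$cpg_sites)
  expect_equal(calls_del[5], "A")
  expect_true(all(calls_del[-5] %in% c("U", "M")))
})

test_that("conversion QC counts non-CpG cytosines exactly", {
  # reference with 20 non-CpG Cs and one CpG
  s <- paste0(strrep("CA", 20), "CGT")
  r <- bisulfite_reference(s)
  conv <- strsplit(bisulfite_convert(r)$residues, "")[[1]]
  al <- align_clone(paste(conv, collapse = ""), r)
  qc <- conversion_qc(al, r$cpg_sites)
  expect_equal(qc$rate, 1.0)
  expect_true(qc$pass)
  expect_equal(qc$n_total, 20)

  # retain 1 of 20: rate 0.95, still passing at the default
  fail1 <- conv; fail1[1] <- "C"
  qc1 <- conversion_qc(align_clone(paste(fail1, collapse = ""), r),
                       r$cpg_sites)
  expect_equal(qc1$rate, 0.95)
  expect_true(qc1$pass)

  # retain 5 of 20: rate 0.75, fails
  fail5 <- conv; fail5[c(1, 3, 5, 7, 9)] <- "C"
  qc5 <- conversion_qc(align_clone(paste(fail5, collapse = ""), r),
                       r$cpg_sites)
  expect_equal(qc5$rate, 0.75)
  expect_false(qc5$pass)

  # no informative cytosine: undefined rate, passes with a warning
  r2 <- bisulfite_reference("GATAGATA")
  al2 <- align_clone("GATAGATA", r2)
  expect_warning(qc2 <- conversion_qc(al2, r2$cpg_sites), "undefined")
  expect_true(is.na(qc2$rate))
  expect_true(qc2$pass)
})

test_that("zero-noise pipeline reproduces the planted matrix exactly", {
  for (seed in c(1, 7, 42)) {
    loc <- make_locus(length = 600, island = list(start = 150, end = 450,
                                                  gc = 0.65, cpg_oe = 1.0),
                      seed = seed)
    sim <- make_clones(loc$record, loc$meth_prob, n_clones = 8, seed = seed,
                       strands = c("+", "-"))
    mm <- call_clones(loc$record, sim$clones)
    expect_equal(mm$calls, sim$truth)
    expect_equal(mm$strand, sim$strands)
    expect_true(all(mm$qc_pass))
    expect_true(all(mm$conversion_rate == 1, na.rm = TRUE))
  }
})

test_that("per-site fractions converge to planted probabilities", {
  loc <- make_locus(length = 400, island = list(start = 100, end = 300,
                                                gc = 0.65, cpg_oe = 1.0),
                    seed = 55)
  sim <- make_clones(loc$record, loc$meth_prob, n_clones = 200, seed = 56)
  mm <- call_clones(loc$record, sim$clones)
  sm <- methylation_summary(mm)
  p <- loc$meth_prob
  se <- sqrt(p * (1 - p) / 200)
  expect_true(all(abs(sm$per_site$fraction - p) <= pmax(3 * se, 0.02)))
})

test_that("QC-failing clones are excluded from fractions but rendered", {
  s <- paste0(strrep("CA", 20), "CGT")
  r <- bisulfite_reference(s)
  good <- bisulfite_convert(r, r$cpg_sites)$residues       # methylated CpG
  badc <- strsplit(bisulfite_convert(r)$residues, "")[[1]]
  badc[c(1, 3, 5, 7, 9)] <- "C"                            # poor conversion
  bad <- paste(badc, collapse = "")
  mm <- call_clones(r, list(seq_record("good", good), seq_record("bad", bad)))
  expect_equal(mm$qc_pass, c(TRUE, FALSE))
  sm <- methylation_summary(mm, ascii = TRUE)
  expect_equal(sm$per_site$fraction, 1.0)   # only the good clone counts
  expect_length(sm$lollipop, 2)
  expect_match(sm$lollipop[2], "x ")
})

test_that("single-clone and all-ambiguous summaries behave", {
  r <- bisulfite_reference("TTCGATTCGACT")
  meth_clone <- bisulfite_convert(r, r$cpg_sites)$residues
  mm <- call_clones(r, list(seq_record("c1", meth_clone)))
  expect_equal(methylation_summary(mm)$per_site$fraction, c(1, 1))

  mm$calls[1, 2] <- "A"
  sm <- methylation_summary(mm, ascii = TRUE)
  expect_true(is.na(sm$per_site$fraction[2]))
  expect_match(sm$lollipop[1], "\\.")
})

test_that("primer regions classify by CpG count per the two design rules", {
  # 0 CpG, 1 CpG -> bisulfite_ok; 2 -> inadmissible; 3+ -> methyl_specific
  s <- paste0("ATATATAT", "CGAT", "CGAT", "CGAT", "ATAT")
  r <- bisulfite_reference(s)
  expect_equal(check_primer(r, c(0, 8))$class, "bisulfite_ok")
  expect_equal(check_primer(r, c(8, 12))$class, "bisulfite_ok")
  expect_equal(check_primer(r, c(8, 16))$class, "inadmissible")
  pc <- check_primer(r, c(8, 20))
  expect_equal(pc$n_cpg, 3)
  expect_equal(pc$class, "methyl_specific")
  expect_error(check_primer(r, c(10, 5)), "interval")
})
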