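test_that("generators are pure functions of (spec, seed)", {
  a <- make_locus(seed = 9); b <- make_locus(seed = 9)
  expect_identical(a$record$residues, b$record$residues)
  expect_identical(a$meth_prob, b$meth_prob)
  expect_false(identical(make_locus(seed = 10)$record$residues,
                         a$record$residues))

  c1 <- make_clones(a$record, a$meth_prob, n_clones = 5, seed = 3,
                    sequencing_error_rate = 0.01)
  c2 <- make_clones(a$record, a$meth_prob, n_clones = 5, seed = 3,
                    sequencing_error_rate = 0.01)
  expect_identical(lapply(c1$clones, `[[`, "residues"),
                   lapply(c2$clones, `[[`, "residues"))

  m1 <- make_melt_curve(60, noise_sd = 0.05, seed = 4)
  m2 <- make_melt_curve(60, noise_sd = 0.05, seed = 4)
  expect_identical(m1$signal, m2$signal)
})

test_that("island synthesis hits its GC and O/E targets", {
  for (seed in 1:5) {
    loc <- make_locus(length = 800, island = list(start = 200, end = 600,
                                                  gc = 0.7, cpg_oe = 1.0),
                      seed = seed)
    expect_lte(abs(loc$truth$island$gc - 0.7), 0.02)
    expect_lte(abs(loc$truth$island$cpg_oe - 1.0), 0.1)
  }
  # infeasible target errors rather than silently approximating
  expect_error(make_locus(island = list(start = 100, end = 400, gc = 0.3,
                                        cpg_oe = 7), max_attempts = 20),
               "infeasible")
})

test_that("planted G4 instances are recovered exactly and exclusively", {
  loc <- make_locus(length = 600, island = NULL,
                    g4_insertions = list(list(position = 100, strand = "+"),
                                         list(position = 400, strand = "-")),
                    seed = 14)
  h <- find_g4_hits(loc$record)
  expect_equal(nrow(h), 2)
  expect_equal(h$start, c(100, 400))
  expect_equal(h$strand, c("+", "-"))
})

test_that("generated loci round-trip through FASTA unchanged", {
  loc <- make_locus(seed = 77)
  tf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(loc$record, tf)
  expect_identical(read_fasta(tf)[[1]]$residues, loc$record$residues)
})

test_that("clone noise rates materialize at their binomial expectations", {
  loc <- make_locus(length = 500, island = list(start = 100, end = 400,
                                                gc = 0.65, cpg_oe = 1.0),
                    seed = 3)
  sim <- make_clones(loc$record, loc$meth_prob, n_clones = 40,
                     conversion_failure_rate = 0.25, seed = 8)
  mm <- call_clones(loc$record, sim$clones, min_conversion = 0)
  p <- mean(mm$conversion_rate, na.rm = TRUE)
  # mean observed conversion ~ 0.75 within 3 SE of the binomial mean
  n_inform <- sum(strsplit(loc$record$residues, "")[[1]] == "C") -
    length(loc$cpg_sites)
  se <- sqrt(0.75 * 0.25 / (n_inform * 40))
  expect_lt(abs(p - 0.75), 3 * se + 0.01)
})

test_that("the step methylation pattern is recovered at 20 clones", {
  loc <- make_locus(length = 800, island = list(start = 250, end = 550,
                                                gc = 0.68, cpg_oe = 1.0),
                    meth_background = 0.9, meth_island = 0.05, seed = 31)
  sim <- make_clones(loc$record, loc$meth_prob, n_clones = 20, seed = 32)
  sm <- methylation_summary(call_clones(loc$record, sim$clones))
  inside <- loc$cpg_sites >= 250 & loc$cpg_sites < 550
  se_in <- sqrt(0.05 * 0.95 / 20); se_out <- sqrt(0.9 * 0.1 / 20)
  expect_true(all(abs(sm$per_site$fraction[inside] - 0.05) <= 3 * se_in))
  expect_true(all(abs(sm$per_site$fraction[!inside] - 0.9) <= 3 * se_out))
  # the island is hypomethylated relative to its flanks
  expect_lt(mean(sm$per_site$fraction[inside]),
            mean(sm$per_site$fraction[!inside]) - 0.5)
})

test_that("peak generator plants what the threshold behavior predicts", {
  set.seed(1)
  m <- position_matrix(matrix(c(0, 20, 0, 0,  0, 0, 20, 0,  20, 0, 0, 0,
                                0, 0, 20, 0,  0, 0, 0, 20,  0, 20, 0, 0),
                              4, 6, dimnames = list(c("A", "C", "G", "T"),
                                                    NULL)))
  ref <- random_seq(1600, c("A", "T"))
  # two planted mismatches: recovered at max_mismatch 2, absent at 1
  pk <- make_peaks_with_motifs(ref, m, n_peaks = 6, fidelity = 1 - 2 / 6,
                               seed = 41)
  truth_key <- paste(pk$truth$genomic_start, pk$truth$strand)
  h2 <- scan_peaks(pk$reference, pk$peaks, m, max_mismatch = 2,
                   score_min_fraction = 0)
  expect_true(all(truth_key %in% paste(h2$genomic_start, h2$strand)))
  h1 <- scan_peaks(pk$reference, pk$peaks, m, max_mismatch = 1,
                   score_min_fraction = 0)
  expect_false(any(truth_key %in% paste(h1$genomic_start, h1$strand)))

  # nothing planted, stringent threshold: zero hits
  pk0 <- make_peaks_with_motifs(ref, m, n_peaks = 6, plant_fraction = 0,
                                seed = 43)
  expect_equal(nrow(scan_peaks(pk0$reference, pk0$peaks, m,
                               score_min_fraction = 0.9)), 0)
})

test_that("qPCR generator inverts exactly at zero noise", {
  tb <- make_qpcr_table(fold_change = 3.5, noise_sd = 0, seed = 1)
  expect_equal(fold_change_ddct(tb$sample, tb$control, "RPLP0"), 3.5)
})
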