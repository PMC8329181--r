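make_test_matrix <- function(cols, name = "TEST", pseudocount = 1) {
  m <- matrix(0, 4, length(cols), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cols)) m[, j] <- cols[[j]]
  position_matrix(m, tf_name = name, pseudocount = pseudocount)
}

test_that("JASPAR parsing is label-driven and validates shape", {
  tf <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0000.1 DEMO",
               "A [ 10  0  0  5  0  2 ]",
               "C [  0 12  0  3  0  4 ]",
               "G [  2  0 12  2 12  2 ]",
               "T [  0  0  0  2  0  4 ]"), tf)
  m <- read_jaspar(tf)
  expect_s3_class(m, "PositionMatrix")
  expect_equal(m$width, 6)
  expect_equal(m$tf_name, "MA0000.1 DEMO")

  # scrambled row order gives the identical matrix
  writeLines(c(">MA0000.1 DEMO",
               "T [  0  0  0  2  0  4 ]",
               "G [  2  0 12  2 12  2 ]",
               "C [  0 12  0  3  0  4 ]",
               "A [ 10  0  0  5  0  2 ]"), tf)
  m2 <- read_jaspar(tf)
  expect_equal(m2$counts, m$counts)

  # raw unlabelled 4-row matrix assumed A,C,G,T
  writeLines(c("10 0 0 5 0 2", "0 12 0 3 0 4", "2 0 12 2 12 2",
               "0 0 0 2 0 4"), tf)
  expect_equal(read_jaspar(tf)$counts, m$counts)

  writeLines(c(">X", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 3 ]", "T [ 1 2 ]"), tf)
  expect_error(read_jaspar(tf), "unequal")
  writeLines(c(">X", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]"), tf)
  expect_error(read_jaspar(tf), "4 matrix rows")
})

test_that("consensus takes the per-column argmax with A<C<G<T tie order", {
  m <- make_test_matrix(list(c(10, 0, 0, 0), c(0, 0, 8, 0), c(4, 4, 0, 0),
                             c(0, 1, 1, 5)))
  cons <- consensus(m)
  expect_equal(as.character(cons), "AGAT")
  expect_equal(attr(cons, "ties"), c(FALSE, FALSE, TRUE, FALSE))
})

test_that("log-odds matches a hand-evaluated case and basic bounds", {
  # columns: A-only, C-only, A/C split; pseudocount 1, uniform background
  m <- make_test_matrix(list(c(8, 0, 0, 0), c(0, 8, 0, 0), c(4, 4, 0, 0)))
  hand <- log2(((8 + 0.25) / 9) / 0.25) + log2(((8 + 0.25) / 9) / 0.25) +
    log2(((4 + 0.25) / 9) / 0.25)
  expect_equal(log_odds(m, "ACA"), hand)

  # uniform matrix scores 0 everywhere
  u <- make_test_matrix(list(rep(3, 4), rep(3, 4), rep(3, 4), rep(3, 4)))
  expect_equal(log_odds(u, "ACGT"), 0)
  expect_equal(max_log_odds(u), 0)

  # near-deterministic matrix: consensus achieves the maximum
  d <- make_test_matrix(list(c(99, 0, 0, 0), c(0, 99, 0, 0), c(0, 0, 99, 0),
                             c(0, 0, 0, 99)))
  expect_lt(abs(log_odds(d, "ACGT") - max_log_odds(d)), 0.01)

  # N-containing sites are unscored
  expect_true(is.na(log_odds(m, "ANA")))
  expect_error(log_odds(m, "AC"), "width")
})

test_that("mean log-odds under the background is non-positive", {
  set.seed(77)
  for (rep in 1:3) {
    W <- sample(4:10, 1)
    m <- make_test_matrix(lapply(seq_len(W), function(j) stats::runif(4, 0, 20)))
    sites <- vapply(1:10000, function(i) random_seq(W), character(1))
    scores <- vapply(sites, function(s) log_odds(m, s), numeric(1))
    expect_lte(mean(scores), 0)
  }
})

test_that("planted sites are recovered on the correct strand and offset", {
  set.seed(88)
  m <- make_test_matrix(list(c(0, 20, 0, 0), c(0, 0, 20, 0), c(20, 0, 0, 0),
                             c(0, 0, 20, 0), c(0, 0, 0, 20), c(0, 20, 0, 0)))
  ref <- random_seq(1500, c("A", "T"))
  pk <- make_peaks_with_motifs(ref, m, n_peaks = 8, fidelity = 1, seed = 9)
  hits <- scan_peaks(pk$reference, pk$peaks, m, score_min_fraction = 0.9)
  expect_equal(nrow(hits), nrow(pk$truth))
  got <- hits[order(hits$genomic_start), ]
  want <- pk$truth[order(pk$truth$genomic_start), ]
  expect_equal(got$genomic_start, want$genomic_start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$mismatches_vs_consensus, rep(0L, nrow(want)))

  # forward and reverse-complement plantings score identically
  site <- as.character(consensus(m))
  r1 <- paste0(strrep("A", 20), site, strrep("T", 20))
  r2 <- paste0(strrep("A", 20), revcomp(site), strrep("T", 20))
  peaks <- data.frame(seq_id = "x", start = 0L, end = nchar(r1),
                      name = "p", score = NA, strand = ".")
  h1 <- scan_peaks(r1, peaks, m, score_min_fraction = 0.99)
  h2 <- scan_peaks(r2, peaks, m, score_min_fraction = 0.99)
  expect_equal(h1$strand, "+")
  expect_equal(h2$strand, "-")
  expect_equal(h1$log_score, h2$log_score)
  expect_equal(h1$genomic_start, h2$genomic_start)

  # AT-only peak against a GC-rich matrix yields nothing
  gcm <- make_test_matrix(list(c(0, 9, 0, 0), c(0, 0, 9, 0), c(0, 9, 0, 0),
                               c(0, 0, 9, 0)))
  expect_equal(nrow(scan_peaks(strrep("AT", 50), peaks = data.frame(
    seq_id = "x", start = 0L, end = 100L, name = "p", score = NA,
    strand = "."), gcm, score_min_fraction = 0.8)), 0)
})

test_that("scanning equals exhaustive window scoring on random peaks", {
  set.seed(99)
  for (i in 1:60) {
    W <- sample(4:12, 1)
    m <- make_test_matrix(lapply(seq_len(W), function(j) stats::runif(4, 0, 15)))
    L <- sample(W:200, 1)
    refseq <- random_seq(L + 20)
    st <- sample(0:20, 1)
    frac <- stats::runif(1, 0.5, 0.95)
    peaks <- data.frame(seq_id = "x", start = st, end = st + L,
                        name = "p", score = NA, strand = ".")
    got <- scan_peaks(refseq, peaks, m, score_min_fraction = frac)
    want <- oracle_scan(refseq, st, st + L, m, frac)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got <- got[order(got$offset_in_peak, got$strand), ]
      want <- want[order(want$offset_in_peak, want$strand), ]
      expect_equal(got$offset_in_peak, want$offset_in_peak)
      expect_equal(got$strand, want$strand)
      expect_equal(got$log_score, want$log_score)
    }
  }
})

test_that("raising the score threshold never adds hits", {
  set.seed(111)
  m <- make_test_matrix(lapply(1:6, function(j) stats::runif(4, 0, 10)))
  refseq <- random_seq(400)
  peaks <- data.frame(seq_id = "x", start = 0L, end = 400L, name = "p",
                      score = NA, strand = ".")
  ns <- vapply(c(0.3, 0.5, 0.7, 0.9), function(f) {
    nrow(scan_peaks(refseq, peaks, m, score_min_fraction = f))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("ranking is deterministic with leftmost-first ties and top_n = 0", {
  hits <- data.frame(
    peak_name = c("a", "a", "b"), offset_in_peak = c(5L, 1L, 3L),
    genomic_start = c(105L, 101L, 203L), strand = c("+", "+", "-"),
    log_score = c(3.5, 3.5, 7.1), mismatches_vs_consensus = 0L,
    site_sequence = "ACGT")
  shuffled <- hits[c(2, 3, 1), ]
  rr <- rank_report(shuffled, top_n = 3)
  expect_equal(rr$ranking$genomic_start, c(203L, 101L, 105L))
  expect_equal(rr$ranking$rank, 1:3)
  rr0 <- rank_report(shuffled, top_n = 0)
  expect_equal(nrow(rr0$ranking), 0)
  expect_equal(nrow(rr0$per_peak_best), 2)

  # peaks shorter than the motif are skipped with a warning
  m <- make_test_matrix(list(c(9, 0, 0, 0), c(9, 0, 0, 0), c(9, 0, 0, 0),
                             c(9, 0, 0, 0), c(9, 0, 0, 0)))
  expect_warning(
    h <- scan_peaks("ACGTACGTAC", data.frame(
      seq_id = "x", start = 0L, end = 3L, name = "tiny", score = NA,
      strand = "."), m, score_min_fraction = 0),
    "skipped")
  expect_equal(nrow(h), 0)
})
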