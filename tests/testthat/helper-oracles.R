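# Independent brute-force oracles used to check the package's vectorized /
# regex implementations, written directly from the definitions.

random_seq <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# naive per-window recount of GC, skew and O/E
oracle_window_stats <- function(s, window, step) {
  b <- strsplit(s, "")[[1]]
  starts <- seq(1, nchar(s) - window + 1, by = step)
  out <- lapply(starts, function(i) {
    w <- b[i:(i + window - 1)]
    nA <- sum(w == "A"); nC <- sum(w == "C")
    nG <- sum(w == "G"); nT <- sum(w == "T")
    ncpg <- sum(w[-length(w)] == "C" & w[-1] == "G")
    L <- nA + nC + nG + nT
    data.frame(
      gc = if (L > 0) (nG + nC) / L else NA_real_,
      skew = if (nG + nC > 0) (nG - nC) / (nG + nC) else NA_real_,
      oe = if (nC * nG > 0) ncpg * L / (nC * nG) else NA_real_)
  })
  do.call(rbind, out)
}

# first valid (run, loop) decomposition at each G-run start, exploring run
# and loop lengths smallest-first with earlier parts varying slowest --
# the canonical lazy decomposition
oracle_g4 <- function(s, min_run = 3, loop_min = 1, loop_max = 7) {
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  g_run_at <- function(p) {  # length of G run starting at p
    k <- 0
    while (p + k <= n && b[p + k] == "G") k <- k + 1
    k
  }
  try_from <- function(pos, need) {
    # need = number of remaining parts (7 = run, 6 = loop, ... 1 = last run)
    if (need == 0) return(integer(0))
    if (need %% 2 == 1) {  # G-run
      avail <- g_run_at(pos)
      if (avail < min_run) return(NULL)
      for (r in min_run:avail) {
        rest <- try_from(pos + r, need - 1)
        if (!is.null(rest)) return(c(r, rest))
      }
      NULL
    } else {               # loop
      for (l in loop_min:loop_max) {
        if (pos + l > n + 1) return(NULL)
        rest <- try_from(pos + l, need - 1)
        if (!is.null(rest)) return(c(l, rest))
      }
      NULL
    }
  }
  anchors <- which(b == "G" & c(TRUE, b[-n] != "G"))
  res <- list()
  for (a in anchors) {
    parts <- try_from(a, 7)
    if (!is.null(parts)) {
      res[[length(res) + 1]] <- data.frame(
        start = a - 1, end = a - 1 + sum(parts),
        run1 = parts[1], loop1 = parts[2], run2 = parts[3],
        loop2 = parts[4], run3 = parts[5], loop3 = parts[6],
        run4 = parts[7])
    }
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# exhaustive both-strand window scoring of one peak
oracle_scan <- function(refseq, peak_start, peak_end, matrix,
                        score_min_fraction) {
  W <- matrix$width
  thr <- score_min_fraction * max_log_odds(matrix)
  res <- list()
  for (off in 0:(peak_end - peak_start - W)) {
    win <- substr(refseq, peak_start + off + 1, peak_start + off + W)
    for (str in c("+", "-")) {
      site <- if (str == "-") revcomp(win) else win
      sc <- log_odds(matrix, site)
      if (!is.na(sc) && sc >= thr) {
        res[[length(res) + 1]] <- data.frame(
          offset_in_peak = off, strand = str, log_score = sc)
      }
    }
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# enumeration of valid promoter-frame positions between two labels
oracle_promoter_length <- function(frm, to) {
  sum(setdiff(seq(frm, to), 0) != 0)
}
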