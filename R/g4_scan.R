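# G-quadruplex consensus scanning.
#
# The consensus is four G-runs of >= min_run guanines separated by three
# loops of loop_min..loop_max arbitrary nucleotides. The canonical hit at
# each anchor (leftmost position of a G-run admitting a match) is the lazy
# (shortest-first) decomposition; purely greedy-maximal matching can skip
# valid downstream anchors.

g4_pattern <- function(min_run, loop_min, loop_max) {
  run <- sprintf("G{%d,}?", min_run)
  loop <- sprintf("[ACGTN]{%d,%d}?", loop_min, loop_max)
  # lookahead so overlapping anchors are all found; capture runs and loops
  sprintf("(?=((%s)(%s)(%s)(%s)(%s)(%s)(%s)))",
          run, loop, run, loop, run, loop, run)
}

empty_g4_hits <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             run1 = integer(0), loop1 = integer(0), run2 = integer(0),
             loop2 = integer(0), run3 = integer(0), loop3 = integer(0),
             run4 = integer(0), max_g_run = integer(0),
             matched_sequence = character(0), stringsAsFactors = FALSE)
}

# scan one strand of a plus-orientation string; returns 0-based coordinates
# in that string's own frame
g4_scan_strand <- function(s, min_run, loop_min, loop_max) {
  pat <- g4_pattern(min_run, loop_min, loop_max)
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_g4_hits())
  cs <- attr(m, "capture.start")   # one row per anchor; col 1 = whole match
  cl <- attr(m, "capture.length")
  anchors <- as.integer(m)         # 1-based anchor positions
  # keep only anchors at the start of a G-run (previous char not G)
  chars <- strsplit(s, "")[[1]]
  at_run_start <- anchors == 1L | chars[pmax(anchors - 1L, 1L)] != "G"
  keep <- which(at_run_start)
  if (!length(keep)) return(empty_g4_hits())
  part <- cl[keep, 2:8, drop = FALSE]  # run1,loop1,run2,loop2,run3,loop3,run4
  span <- rowSums(part)
  start0 <- anchors[keep] - 1L
  matched <- substr(rep(s, length(keep)), anchors[keep],
                    anchors[keep] + span - 1L)
  max_run <- vapply(matched, function(x) {
    r <- rle(strsplit(x, "")[[1]])
    max(r$lengths[r$values == "G"])
  }, integer(1), USE.NAMES = FALSE)
  data.frame(start = start0, end = start0 + as.integer(span), strand = "+",
             run1 = part[, 1], loop1 = part[, 2], run2 = part[, 3],
             loop2 = part[, 4], run3 = part[, 5], loop3 = part[, 6],
             run4 = part[, 7], max_g_run = max_run,
             matched_sequence = matched, stringsAsFactors = FALSE)
}

#' Find putative G-quadruplex-forming sequences
#'
#' Scans for the G4 consensus: four runs of at least `min_run` guanines
#' separated by three loops of `loop_min`..`loop_max` nucleotides
#' (G3+N1-7 x 4 with defaults, minimum span 15 bp). Minus-strand hits are
#' found by scanning the reverse complement and are reported in plus-strand
#' coordinates with strand `"-"`. At each anchor the canonical hit is the
#' lazy (minimal runs and loops) decomposition; `report_all = TRUE` instead
#' enumerates every valid decomposition at every anchor.
#'
#' @param seq `SequenceRecord` or character scalar.
#' @param min_run minimum G-run length (>= 2).
#' @param loop_min,loop_max loop-length bounds.
#' @param strands character vector, subset of `c("+", "-")`.
#' @param report_all enumerate all decompositions instead of the canonical
#'   one per anchor.
#' @return `data.frame` of hits: `start`, `end` (0-based half-open, plus
#'   strand frame), `strand`, run/loop lengths `run1..run4`, `loop1..loop3`,
#'   `max_g_run` (longest maximal G-run inside the hit), and
#'   `matched_sequence`.
#' @export
#' @examples
#' find_g4_hits("GGGAGGGAGGGAGGG")
find_g4_hits <- function(seq, min_run = 3L, loop_min = 1L, loop_max = 7L,
                         strands = c("+", "-"), report_all = FALSE) {
  if (min_run < 2L) stop("min_run must be >= 2")
  if (loop_min < 1L || loop_min > loop_max) {
    stop("need 1 <= loop_min <= loop_max")
  }
  s <- as_residues(seq)
  L <- nchar(s)
  if (L < 4L * min_run + 3L * loop_min) return(empty_g4_hits())
  scan1 <- if (report_all) {
    function(x) g4_enumerate_all(x, min_run, loop_min, loop_max)
  } else {
    function(x) g4_scan_strand(x, min_run, loop_min, loop_max)
  }
  res <- list()
  if ("+" %in% strands) res$plus <- scan1(s)
  if ("-" %in% strands) {
    h <- scan1(revcomp(s))
    if (nrow(h)) {
      new_start <- L - h$end
      h$end <- L - h$start
      h$start <- new_start
      h$strand <- "-"
    }
    res$minus <- h
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- empty_g4_hits()
  out <- out[order(out$strand, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force enumeration of every (run, loop) decomposition anchored at
# G-run starts. Exported for use as report_all and as a transparent
# reference for the regex scanner.
g4_enumerate_all <- function(s, min_run = 3L, loop_min = 1L, loop_max = 7L) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  isG <- chars == "G"
  # length of the G-run starting at each position (0 when not G)
  runlen <- integer(n)
  for (i in n:1) runlen[i] <- if (isG[i]) 1L + (if (i < n) runlen[i + 1L] else 0L) else 0L
  anchors <- which(isG & (seq_len(n) == 1L | !c(FALSE, isG[-n])))
  acc <- list()
  for (a in anchors) {
    recurse <- function(pos, parts) {
      k <- length(parts)
      if (k == 7L) {
        span <- pos - a
        acc[[length(acc) + 1L]] <<- c(a - 1L, span, parts)
        return(invisible())
      }
      if (k %% 2L == 0L) {            # need a G-run
        avail <- runlen[pos]
        if (is.na(avail) || pos > n || avail < min_run) return(invisible())
        for (r in min_run:avail) recurse(pos + r, c(parts, r))
      } else {                        # need a loop
        for (l in loop_min:loop_max) {
          if (pos + l > n + 1L) break
          recurse(pos + l, c(parts, l))
        }
      }
      invisible()
    }
    recurse(a, integer(0))
  }
  if (!length(acc)) return(empty_g4_hits())
  m <- do.call(rbind, acc)
  start0 <- m[, 1]
  span <- m[, 2]
  matched <- substr(rep(s, nrow(m)), start0 + 1L, start0 + span)
  max_run <- vapply(matched, function(x) {
    r <- rle(strsplit(x, "")[[1]])
    max(r$lengths[r$values == "G"])
  }, integer(1), USE.NAMES = FALSE)
  data.frame(start = start0, end = start0 + span, strand = "+",
             run1 = m[, 3], loop1 = m[, 4], run2 = m[, 5], loop2 = m[, 6],
             run3 = m[, 7], loop3 = m[, 8], run4 = m[, 9],
             max_g_run = max_run, matched_sequence = matched,
             stringsAsFactors = FALSE)
}

#' Merge overlapping G4 hits into loci
#'
#' Overlapping or near-adjacent hits on the same strand are consolidated
#' into loci (a biologist counts loci, not regex matches). The best hit of a
#' locus is the one with the largest total G-run content, ties broken by
#' leftmost start.
#'
#' @param hits data frame from [find_g4_hits()].
#' @param max_gap maximum gap (bp) between hits merged into one locus.
#' @return `data.frame`: `start`, `end`, `strand`, `n_merged_hits`, plus the
#'   best hit's run/loop signature (`best_signature`) and sequence.
#' @export
merge_g4_hits <- function(hits, max_gap = 0L) {
  if (!nrow(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), n_merged_hits = integer(0),
                      best_signature = character(0),
                      best_sequence = character(0)))
  }
  hits <- hits[order(hits$strand, hits$start, hits$end), , drop = FALSE]
  out <- list()
  for (str in unique(hits$strand)) {
    h <- hits[hits$strand == str, , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(h$start[-1] > cummax(h$end)[-nrow(h)] + max_gap)))
    for (g in unique(grp)) {
      hg <- h[grp == g, , drop = FALSE]
      gsum <- hg$run1 + hg$run2 + hg$run3 + hg$run4
      best <- hg[order(-gsum, hg$start)[1L], ]
      out[[length(out) + 1L]] <- data.frame(
        start = min(hg$start), end = max(hg$end), strand = str,
        n_merged_hits = nrow(hg),
        best_signature = sprintf("G%d-N%d-G%d-N%d-G%d-N%d-G%d",
                                 best$run1, best$loop1, best$run2, best$loop2,
                                 best$run3, best$loop3, best$run4),
        best_sequence = best$matched_sequence, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Windowed G-richness score
#'
#' A G4Hunter-style strand-resolved score: each base in a G-run of length r
#' contributes +min(r, 4), each base in a C-run contributes -min(r, 4),
#' other bases 0; the windowed mean is reported. Values lie in [-4, 4];
#' positive values favor a plus-strand G4.
#'
#' @inheritParams gc_content
#' @return A `WindowProfile` data frame.
#' @export
g4_run_score <- function(seq, window = 25L, step = 1L) {
  s <- as_residues(seq)
  chars <- strsplit(s, "")[[1]]
  r <- rle(chars)
  per_run <- ifelse(r$values == "G", pmin(r$lengths, 4L),
                    ifelse(r$values == "C", -pmin(r$lengths, 4L), 0L))
  base_score <- rep(per_run, r$lengths)
  starts <- window_starts(length(chars), window, step)
  val <- window_sums(base_score, starts, window) / window
  nN <- window_sums(chars == "N", starts, window)
  new_window_profile(starts, window, step, val, nN / window)
}
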