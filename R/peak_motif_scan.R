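# Position-frequency-matrix motif search restricted to peak intervals.
#
# Scoring is the log2 likelihood ratio (PWM log-odds) of a site under the
# motif model versus a background model; Hamming distance to the plain
# argmax consensus is kept as a secondary, more literal approximate-string
# filter. Both knobs are exposed.

BASES <- c("A", "C", "G", "T")

#' Construct a position matrix
#'
#' @param counts 4 x W nonnegative numeric matrix with rownames among
#'   A, C, G, T (any row order; rows are matched by label).
#' @param tf_name transcription-factor name.
#' @param pseudocount total pseudocount, distributed by the background.
#' @param background length-4 probability vector (A, C, G, T) summing to 1.
#' @return An object of class `PositionMatrix` with derived probability and
#'   log-odds matrices.
#' @export
position_matrix <- function(counts, tf_name = "motif", pseudocount = 1,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- BASES
  if (!setequal(rownames(counts), BASES)) {
    stop("counts must have rows labelled A, C, G, T")
  }
  counts <- counts[BASES, , drop = FALSE]
  if (ncol(counts) < 1L) stop("motif must have at least one column")
  if (any(counts < 0)) stop("negative counts")
  if (any(colSums(counts) <= 0)) stop("zero column sum")
  if (abs(sum(background) - 1) > 1e-8 || any(background <= 0)) {
    stop("background must be positive and sum to 1")
  }
  background <- setNames(as.numeric(background), BASES)
  prob <- sweep(counts + pseudocount * background, 2,
                colSums(counts) + pseudocount, "/")
  lo <- log2(prob / background)
  structure(list(tf_name = tf_name, counts = counts, pseudocount = pseudocount,
                 background = background, prob = prob, log_odds = lo,
                 width = ncol(counts)),
            class = "PositionMatrix")
}

#' @export
print.PositionMatrix <- function(x, ...) {
  cat(sprintf("PositionMatrix '%s': width %d, consensus %s\n",
              x$tf_name, x$width, consensus(x)))
  print(round(x$counts, 2))
  invisible(x)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Accepts the JASPAR text format (`>ID NAME` header followed by four
#' `A [ 1 2 3 ]`-style labelled rows, in any row order) or a raw 4-row
#' whitespace-separated matrix (assumed A, C, G, T order).
#'
#' @param path file path.
#' @inheritParams position_matrix
#' @return A `PositionMatrix`.
#' @export
read_jaspar <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  name <- "motif"
  if (length(lines) && startsWith(lines[1], ">")) {
    parts <- strsplit(sub("^>", "", lines[1]), "\\s+")[[1]]
    name <- paste(parts, collapse = " ")
    lines <- lines[-1]
  }
  if (length(lines) != 4L) stop("expected 4 matrix rows, found ", length(lines))
  rows <- lapply(lines, function(ln) {
    lab <- NA_character_
    if (grepl("^[ACGTacgt]([[:space:]]|\\[)", ln)) {
      lab <- toupper(substr(ln, 1, 1))
      ln <- sub("^[ACGTacgt]", "", ln)
    }
    ln <- gsub("\\[|\\]", " ", ln)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (anyNA(vals)) stop("unparseable matrix row: ", ln)
    list(lab = lab, vals = vals)
  })
  widths <- lengths(lapply(rows, `[[`, "vals"))
  if (length(unique(widths)) != 1L) {
    stop("unequal row widths: ", paste(widths, collapse = ", "))
  }
  labs <- vapply(rows, `[[`, character(1), "lab")
  m <- do.call(rbind, lapply(rows, `[[`, "vals"))
  if (all(!is.na(labs))) {
    if (!setequal(labs, BASES)) stop("missing row: need A, C, G, T, got ",
                                     paste(labs, collapse = ","))
    rownames(m) <- labs
  } else if (all(is.na(labs))) {
    rownames(m) <- BASES
  } else {
    stop("mix of labelled and unlabelled matrix rows")
  }
  position_matrix(m, tf_name = name, pseudocount = pseudocount,
                  background = background)
}

#' Consensus sequence of a position matrix
#'
#' Per column, the base with maximal count; ties are broken by the fixed
#' base order A < C < G < T and flagged in the `"ties"` attribute.
#'
#' @param matrix a `PositionMatrix`.
#' @return Character scalar of length W, with a logical `"ties"` attribute.
#' @export
consensus <- function(matrix) {
  stopifnot(inherits(matrix, "PositionMatrix"))
  idx <- apply(matrix$counts, 2, which.max)
  ties <- apply(matrix$counts, 2, function(col) sum(col == max(col)) > 1L)
  structure(paste(BASES[idx], collapse = ""), ties = ties)
}

#' Log-odds score of a candidate site
#'
#' Sum over positions of
#' log2[(count + pseudocount x bg) / (colsum + pseudocount) / bg], the PWM
#' log-likelihood ratio of the site under the motif versus the background.
#' Finite for every ACGT site. Sites containing N return `NA` (unscored).
#'
#' @param matrix a `PositionMatrix`.
#' @param site character scalar of length W over A, C, G, T.
#' @return Numeric score (bits).
#' @export
log_odds <- function(matrix, site) {
  stopifnot(inherits(matrix, "PositionMatrix"))
  b <- strsplit(toupper(site), "")[[1]]
  if (length(b) != matrix$width) {
    stop("site length ", length(b), " != motif width ", matrix$width)
  }
  if (any(!b %in% BASES)) return(NA_real_)
  sum(matrix$log_odds[cbind(match(b, BASES), seq_along(b))])
}

#' Maximum attainable log-odds score of a matrix
#'
#' @param matrix a `PositionMatrix`.
#' @return Numeric, the sum of per-column maxima.
#' @export
max_log_odds <- function(matrix) {
  sum(apply(matrix$log_odds, 2, max))
}

#' Scan peak intervals for motif hits
#'
#' Every width-W window of every peak, on both strands, is a candidate
#' site. A candidate is retained when its log-odds score reaches
#' `score_min_fraction` of the matrix's maximum attainable score and (when
#' `max_mismatch` is set) its Hamming distance to the consensus does not
#' exceed `max_mismatch`. Output is sorted by score descending, ties by
#' genomic start ascending, `+` before `-`. Peaks are taken verbatim (no
#' summit-centering or slop).
#'
#' @param reference `SequenceRecord` or character scalar the peaks index
#'   into.
#' @param peaks data frame as returned by [read_peaks()].
#' @param matrix a `PositionMatrix`.
#' @param max_mismatch optional integer, maximum mismatches versus the
#'   consensus; `NULL` disables the filter.
#' @param score_min_fraction number in [0, 1].
#' @return `data.frame` of hits: `peak_name`, `offset_in_peak` (0-based),
#'   `genomic_start` (0-based), `strand`, `log_score`,
#'   `mismatches_vs_consensus`, `site_sequence` (plus-strand window shown
#'   as its motif-orientation sequence for `-` hits).
#' @export
scan_peaks <- function(reference, peaks, matrix, max_mismatch = NULL,
                       score_min_fraction = 0.8) {
  stopifnot(inherits(matrix, "PositionMatrix"),
            score_min_fraction >= 0, score_min_fraction <= 1)
  s <- as_residues(reference)
  W <- matrix$width
  cons <- as.character(consensus(matrix))
  cons_b <- strsplit(cons, "")[[1]]
  # at fraction 0 the score filter is off entirely (scores can be negative)
  thr <- if (score_min_fraction > 0) score_min_fraction * max_log_odds(matrix)
         else -Inf
  res <- list()
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    if (p$start < 0L || p$end > nchar(s)) {
      stop("peak '", p$name, "' outside reference bounds")
    }
    plen <- p$end - p$start
    if (plen < W) {
      warning("peak '", p$name, "' shorter than motif width; skipped")
      next
    }
    pseq <- substr(s, p$start + 1L, p$end)
    offs <- 0:(plen - W)
    for (str in c("+", "-")) {
      sites <- substring(pseq, offs + 1L, offs + W)
      if (str == "-") sites <- vapply(sites, revcomp, character(1),
                                      USE.NAMES = FALSE)
      scores <- vapply(sites, function(x) log_odds(matrix, x), numeric(1),
                       USE.NAMES = FALSE)
      mism <- vapply(sites, function(x) {
        sum(strsplit(x, "")[[1]] != cons_b)
      }, integer(1), USE.NAMES = FALSE)
      keep <- !is.na(scores) & scores >= thr
      if (!is.null(max_mismatch)) keep <- keep & mism <= max_mismatch
      if (!any(keep)) next
      res[[length(res) + 1L]] <- data.frame(
        peak_name = p$name, offset_in_peak = offs[keep],
        genomic_start = p$start + offs[keep], strand = str,
        log_score = scores[keep], mismatches_vs_consensus = mism[keep],
        site_sequence = sites[keep], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(peak_name = character(0), offset_in_peak = integer(0),
               genomic_start = integer(0), strand = character(0),
               log_score = numeric(0), mismatches_vs_consensus = integer(0),
               site_sequence = character(0), stringsAsFactors = FALSE)
  out <- out[order(-out$log_score, out$genomic_start,
                   match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ranked motif-hit report
#'
#' @param hits data frame from [scan_peaks()].
#' @param top_n number of top-ranked hits to keep in the ranking table.
#' @return List with `ranking` (top `top_n` hits with a `rank` column) and
#'   `per_peak_best` (best hit per peak).
#' @export
rank_report <- function(hits, top_n = 10L) {
  hits <- hits[order(-hits$log_score, hits$genomic_start,
                     match(hits$strand, c("+", "-"))), , drop = FALSE]
  rownames(hits) <- NULL
  ranking <- utils::head(hits, top_n)
  if (nrow(ranking)) ranking <- cbind(rank = seq_len(nrow(ranking)), ranking)
  else ranking <- cbind(rank = integer(0), ranking)
  best <- if (nrow(hits)) {
    do.call(rbind, lapply(split(hits, hits$peak_name), function(h) h[1L, ]))
  } else hits
  rownames(best) <- NULL
  list(ranking = ranking, per_peak_best = best)
}
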