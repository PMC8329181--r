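# Sliding-window composition profiles and CpG-island detection.
#
# All window coordinates are 0-based half-open internally; the last partial
# window is dropped, never padded. N residues are excluded from every count;
# windows with > 10% N are flagged.

# 0-based window starts; last partial window dropped.
window_starts <- function(len, window, step) {
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  if (window > len) stop("window (", window, ") exceeds sequence length (", len, ")")
  seq.int(0L, len - window, by = step)
}

# Windowed sums of a per-base indicator vector via cumulative sums.
window_sums <- function(ind, starts, window) {
  cs <- c(0, cumsum(ind))
  cs[starts + window + 1L] - cs[starts + 1L]
}

new_window_profile <- function(starts, window, step, values, n_frac) {
  structure(
    data.frame(start = starts, end = starts + window, value = values,
               n_flag = n_frac > 0.10),
    window = window, step = step, class = c("WindowProfile", "data.frame")
  )
}

profile_base <- function(seq, window, step) {
  s <- as_residues(seq)
  b <- strsplit(s, "")[[1]]
  starts <- window_starts(length(b), window, step)
  list(b = b, starts = starts,
       nN = window_sums(b == "N", starts, window))
}

#' Sliding-window GC content
#'
#' Per-window fraction (G+C)/(A+C+G+T); N residues enter neither numerator
#' nor denominator. Windows consisting only of N are reported as `NA`
#' (undefined); windows with more than 10% N carry `n_flag = TRUE`.
#'
#' @param seq `SequenceRecord` or character scalar.
#' @param window,step window size and step in bp.
#' @return A `WindowProfile` data frame with columns `start`, `end`
#'   (0-based half-open), `value`, `n_flag`.
#' @export
#' @examples
#' gc_content("GCGCATAT", window = 4, step = 4)$value # 1, 0
gc_content <- function(seq, window, step = 1L) {
  p <- profile_base(seq, window, step)
  gc <- window_sums(p$b %in% c("G", "C"), p$starts, window)
  denom <- window - p$nN
  val <- ifelse(denom > 0, gc / denom, NA_real_)
  new_window_profile(p$starts, window, step, val, p$nN / window)
}

#' Sliding-window GC skew
#'
#' Per-window (G - C)/(G + C), the standard measure of strand asymmetry in
#' G versus C composition. Windows with no G or C are `NA`.
#'
#' @inheritParams gc_content
#' @param cumulative if `TRUE`, return the cumulative sum of the windowed
#'   skew instead of the windowed value.
#' @return A `WindowProfile` data frame.
#' @export
gc_skew <- function(seq, window, step = 1L, cumulative = FALSE) {
  p <- profile_base(seq, window, step)
  g <- window_sums(p$b == "G", p$starts, window)
  cc <- window_sums(p$b == "C", p$starts, window)
  val <- ifelse(g + cc > 0, (g - cc) / (g + cc), NA_real_)
  if (cumulative) val <- cumsum(ifelse(is.na(val), 0, val))
  new_window_profile(p$starts, window, step, val, p$nN / window)
}

#' Sliding-window observed/expected CpG ratio
#'
#' Per-window (N_CpG x L)/(N_C x N_G), the canonical island criterion ratio,
#' with L the number of non-N positions in the window. Undefined (`NA`) when
#' the window has no C or no G. A CpG dinucleotide is counted when wholly
#' inside the window.
#'
#' @inheritParams gc_content
#' @return A `WindowProfile` data frame.
#' @export
#' @examples
#' cpg_obs_exp("CGCGCGCG", window = 8)$value # (4*8)/(4*4) = 2
cpg_obs_exp <- function(seq, window, step = 1L) {
  p <- profile_base(seq, window, step)
  b <- p$b
  n <- length(b)
  cpg_ind <- c(b[-n] == "C" & b[-1L] == "G", FALSE)
  # a CpG starting at the last window position straddles the boundary
  ncpg <- window_sums(cpg_ind, p$starts, window) -
    cpg_ind[p$starts + window]
  nc <- window_sums(b == "C", p$starts, window)
  ng <- window_sums(b == "G", p$starts, window)
  L <- window - p$nN
  val <- ifelse(nc * ng > 0, ncpg * L / (nc * ng), NA_real_)
  new_window_profile(p$starts, window, step, val, p$nN / window)
}

#' Detect CpG islands
#'
#' Classic sliding-window island detection: windows qualifying on both the
#' GC-content and observed/expected CpG thresholds are merged into maximal
#' runs of consecutive qualifying windows; a run is reported as an island
#' when its span reaches `min_length`. Defaults are the conventional
#' Gardiner-Garden & Frommer settings (window 100, GC >= 0.5, O/E >= 0.6,
#' minimum length 200 bp).
#'
#' Islands are annotated with the mean GC and mean O/E of their qualifying
#' windows, so every stored island satisfies both thresholds. Islands longer
#' than 2000 bp are reported but flagged (`over_2kb`), since canonical CpG
#' islands are described as 200-2000 bp segments.
#'
#' @inheritParams gc_content
#' @param gc_threshold minimum windowed GC fraction.
#' @param oe_threshold minimum windowed observed/expected CpG ratio.
#' @param min_length minimum island span in bp.
#' @return `data.frame` with columns `start`, `end` (0-based half-open),
#'   `length`, `mean_gc`, `mean_obs_exp`, `n_windows`, `over_2kb`.
#' @export
detect_cgi <- function(seq, window = 100L, step = 1L, gc_threshold = 0.5,
                       oe_threshold = 0.6, min_length = 200L) {
  s <- as_residues(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), mean_gc = numeric(0),
                      mean_obs_exp = numeric(0), n_windows = integer(0),
                      over_2kb = logical(0))
  if (nchar(s) < window) {
    warning("sequence shorter than window; no islands reported")
    return(empty)
  }
  gc <- gc_content(s, window, step)
  oe <- cpg_obs_exp(s, window, step)
  ok <- !is.na(gc$value) & !is.na(oe$value) &
    gc$value >= gc_threshold & oe$value >= oe_threshold
  if (!any(ok)) return(empty)
  r <- rle(ok)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  keep <- which(r$values)
  runs <- lapply(keep, function(k) idx_start[k]:idx_end[k])
  # overlapping windows can make nearby runs cover overlapping spans;
  # merge such runs so reported islands never overlap
  merged <- list(runs[[1L]])
  if (length(runs) > 1L) {
    for (k in 2:length(runs)) {
      prev <- merged[[length(merged)]]
      prev_end <- gc$end[prev[length(prev)]]
      if (gc$start[runs[[k]][1L]] <= prev_end) {
        merged[[length(merged)]] <- c(prev, runs[[k]])
      } else {
        merged[[length(merged) + 1L]] <- runs[[k]]
      }
    }
  }
  out <- lapply(merged, function(i) {
    span_start <- gc$start[i[1L]]
    span_end <- gc$end[i[length(i)]]
    data.frame(start = span_start, end = span_end,
               length = span_end - span_start,
               mean_gc = mean(gc$value[i]),
               mean_obs_exp = mean(oe$value[i]),
               n_windows = length(i),
               over_2kb = (span_end - span_start) > 2000L)
  })
  out <- do.call(rbind, out)
  out <- out[out$length >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a window profile as a tab-separated table
#'
#' Output coordinates are 1-based inclusive; a `#` comment block records
#' the window parameters.
#'
#' @param profile a `WindowProfile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window=%d step=%d", attr(profile, "window"),
                     attr(profile, "step")), con)
  out <- data.frame(start = profile$start + 1L, end = profile$end,
                    value = profile$value, n_flag = profile$n_flag)
  utils::write.table(format(out, digits = 6), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
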