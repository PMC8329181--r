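# Seeded generators for every input the pipeline consumes, with planted
# ground truth: loci with CpG islands, G4 and TF-motif insertions, bisulfite
# clone sets, melt curves, CD spectra and qPCR tables.
#
# One integer seed drives all stochastic draws through a stage-name-salted
# substream scheme, so adding a generator never perturbs existing fixtures.

stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1000003) %% 2147483647)
}

sample_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

# cap G- and C-runs at max_run outside protected intervals (list of c(start0,
# end0) half-open) so random background cannot produce spurious G4 anchors
cap_runs <- function(chars, max_run = 2L, protected = list()) {
  inprot <- rep(FALSE, length(chars))
  for (iv in protected) {
    if (iv[2] > iv[1]) inprot[(iv[1] + 1L):iv[2]] <- TRUE
  }
  run <- 0L; prev <- ""
  for (i in seq_along(chars)) {
    if (inprot[i]) { run <- 0L; prev <- ""; next }
    if (chars[i] %in% c("G", "C") && chars[i] == prev) run <- run + 1L
    else run <- 1L
    if (chars[i] %in% c("G", "C") && run > max_run) {
      chars[i] <- sample(c("A", "T"), 1L)
      run <- 0L
    }
    prev <- chars[i]
  }
  chars
}

# first-order chain whose stationary composition approximates the target GC
# and whose C->G transition is boosted to reach the target CpG
# observed/expected ratio (IID sampling cannot reach O/E above ~1)
sample_island <- function(n, gc, oe) {
  pG <- gc / 2
  q <- min(oe * pG, 0.9)            # P(G | previous C)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = pG, T = (1 - gc) / 2)
  after_c <- base_p; after_c["G"] <- 0
  after_c <- after_c / sum(after_c) * (1 - q)
  after_c["G"] <- q
  out <- character(n)
  out[1] <- sample(names(base_p), 1L, prob = base_p)
  for (i in 2:n) {
    p <- if (out[i - 1L] == "C") after_c else base_p
    out[i] <- sample(names(p), 1L, prob = p)
  }
  out
}

measure_gc_oe <- function(chars) {
  n <- length(chars)
  nc <- sum(chars == "C"); ng <- sum(chars == "G")
  ncpg <- sum(chars[-n] == "C" & chars[-1] == "G")
  list(gc = (nc + ng) / n,
       oe = if (nc * ng > 0) ncpg * n / (nc * ng) else NA_real_)
}

#' Generate a synthetic locus with planted features
#'
#' Emulates a GC-rich regulatory locus: an AT-richer background carrying an
#' unmethylated CpG island (GC and observed/expected CpG hit their targets
#' by rejection sampling of a dinucleotide chain), optional planted G4
#' consensus instances and TF motif sites, and a per-CpG methylation
#' probability map that is high outside the island and low inside (the
#' canonical "methylated flanks, unmethylated island" promoter pattern).
#' Background G/C runs are capped at 2 outside planted features so
#' spurious G4 anchors cannot arise.
#'
#' @param length locus length, bp.
#' @param background_gc background GC fraction.
#' @param island `NULL` or list with `start`, `end` (0-based half-open),
#'   `gc`, `cpg_oe`.
#' @param g4_insertions list of lists with `position` (0-based), `runs`
#'   (4 G-run lengths), `loops` (3 loop lengths), `strand`.
#' @param motif_insertions list of lists with `position`, `site` (literal
#'   sequence to plant) and `strand`.
#' @param meth_background,meth_island per-CpG methylation probabilities
#'   outside/inside the island.
#' @param gc_tol,oe_tol acceptance half-widths for the island targets.
#' @param max_attempts rejection-sampling budget before erroring (an
#'   infeasible GC/O-E combination is reported rather than approximated).
#' @param seed integer seed.
#' @return List: `record` (`SequenceRecord`), `truth` with `island`
#'   (realized coordinates and composition), `g4` and `motifs` data frames,
#'   `cpg_sites` (0-based) and `meth_prob` (per site).
#' @export
make_locus <- function(length = 1000L, background_gc = 0.4,
                       island = list(start = 350L, end = 650L,
                                     gc = 0.7, cpg_oe = 1.0),
                       g4_insertions = list(), motif_insertions = list(),
                       meth_background = 0.9, meth_island = 0.05,
                       gc_tol = 0.02, oe_tol = 0.1,
                       max_attempts = 500L, seed = 1L) {
  set.seed(stage_seed(seed, "locus"))
  chars <- sample_bases(length, background_gc)
  island_truth <- NULL
  protected <- list()
  if (!is.null(island)) {
    ilen <- island$end - island$start
    stopifnot(ilen > 0, island$start >= 0, island$end <= length)
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      cand <- sample_island(ilen, island$gc, island$cpg_oe)
      m <- measure_gc_oe(cand)
      if (!is.na(m$oe) && abs(m$gc - island$gc) <= gc_tol &&
          abs(m$oe - island$cpg_oe) <= oe_tol) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("island spec infeasible: could not reach GC ", island$gc,
           " and O/E ", island$cpg_oe, " in ", max_attempts, " attempts")
    }
    chars[(island$start + 1L):island$end] <- cand
    protected <- c(protected, list(c(island$start, island$end)))
    island_truth <- data.frame(start = island$start, end = island$end,
                               gc = m$gc, cpg_oe = m$oe)
  }
  g4_truth <- data.frame(start = integer(0), end = integer(0),
                         strand = character(0), sequence = character(0))
  for (ins in g4_insertions) {
    runs <- ins$runs %||% c(3L, 3L, 3L, 3L)
    loops <- ins$loops %||% c(1L, 1L, 1L)
    strand <- ins$strand %||% "+"
    loopseq <- lapply(loops, function(l) sample(c("A", "T"), l, replace = TRUE))
    parts <- character(0)
    for (k in 1:4) {
      parts <- c(parts, rep("G", runs[k]))
      if (k < 4) parts <- c(parts, loopseq[[k]])
    }
    if (strand == "-") parts <- strsplit(revcomp(paste(parts, collapse = "")),
                                         "")[[1]]
    span <- length(parts)
    stopifnot(ins$position + span <= length)
    chars[(ins$position + 1L):(ins$position + span)] <- parts
    protected <- c(protected, list(c(ins$position, ins$position + span)))
    g4_truth <- rbind(g4_truth, data.frame(
      start = ins$position, end = ins$position + span, strand = strand,
      sequence = paste(parts, collapse = "")))
  }
  motif_truth <- data.frame(start = integer(0), end = integer(0),
                            strand = character(0), site = character(0))
  for (ins in motif_insertions) {
    site <- toupper(ins$site)
    strand <- ins$strand %||% "+"
    planted <- if (strand == "-") revcomp(site) else site
    w <- nchar(planted)
    stopifnot(ins$position + w <= length)
    chars[(ins$position + 1L):(ins$position + w)] <- strsplit(planted, "")[[1]]
    protected <- c(protected, list(c(ins$position, ins$position + w)))
    motif_truth <- rbind(motif_truth, data.frame(
      start = ins$position, end = ins$position + w, strand = strand,
      site = site))
  }
  chars <- cap_runs(chars, max_run = 2L, protected = protected)
  rec <- seq_record(sprintf("synthetic_locus_seed%d", seed),
                    paste(chars, collapse = ""))
  bref <- bisulfite_reference(rec)
  meth_prob <- rep(meth_background, length(bref$cpg_sites))
  if (!is.null(island)) {
    inside <- bref$cpg_sites >= island$start & bref$cpg_sites < island$end
    meth_prob[inside] <- meth_island
  }
  list(record = rec,
       truth = list(island = island_truth, g4 = g4_truth,
                    motifs = motif_truth),
       cpg_sites = bref$cpg_sites, meth_prob = meth_prob)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate bisulfite clone sequences with planted methylation
#'
#' Per clone, per-site methylation states are drawn Bernoulli from
#' `methylation_profile`, bisulfite conversion is applied on the clone's
#' strand, then conversion failures (non-CpG cytosines escaping
#' conversion), uniform substitution sequencing errors and short indels are
#' injected at the stated rates. The planted truth matrix is returned.
#'
#' @param reference `BisulfiteReference` (or sequence coercible to one).
#' @param methylation_profile per-CpG methylation probabilities.
#' @param n_clones number of clones.
#' @param conversion_failure_rate,sequencing_error_rate,indel_rate per-event
#'   probabilities in [0, 1).
#' @param strands strand pool clones are drawn from (`"+"`, `"-"` or both).
#' @param seed integer seed.
#' @return List: `clones` (list of `SequenceRecord`), `truth` (clones x
#'   sites matrix over M/U), `strands`.
#' @export
make_clones <- function(reference, methylation_profile, n_clones = 20L,
                        conversion_failure_rate = 0,
                        sequencing_error_rate = 0, indel_rate = 0,
                        strands = "+", seed = 1L) {
  set.seed(stage_seed(seed, "clones"))
  ref <- as_bisref(reference)
  sites <- ref$cpg_sites
  stopifnot(length(methylation_profile) == length(sites))
  n <- nchar(ref$region$residues)
  truth <- matrix("U", n_clones, length(sites))
  clone_strands <- sample(strands, n_clones, replace = TRUE)
  clones <- vector("list", n_clones)
  for (i in seq_len(n_clones)) {
    meth <- sites[stats::runif(length(sites)) < methylation_profile]
    truth[i, sites %in% meth] <- "M"
    strand <- clone_strands[i]
    conv <- bisulfite_convert(ref, meth, strand)
    chars <- strsplit(conv$residues, "")[[1]]
    orig <- if (strand == "+") strsplit(ref$region$residues, "")[[1]]
            else strsplit(revcomp(ref$region$residues), "")[[1]]
    # non-CpG positions eligible for conversion failure (C -> T that are
    # not the informative CpG position on this strand)
    cpg_pos <- if (strand == "+") sites + 1L else n - (sites + 1L)  # 1-based
    conv_pos <- setdiff(which(orig == "C" & chars == "T"), cpg_pos)
    if (conversion_failure_rate > 0 && length(conv_pos)) {
      fail <- conv_pos[stats::runif(length(conv_pos)) < conversion_failure_rate]
      chars[fail] <- "C"
    }
    if (sequencing_error_rate > 0) {
      err <- which(stats::runif(length(chars)) < sequencing_error_rate)
      for (j in err) {
        chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1L)
      }
    }
    if (indel_rate > 0) {
      del <- which(stats::runif(length(chars)) < indel_rate)
      if (length(del)) chars <- chars[-del]
    }
    clones[[i]] <- seq_record(sprintf("clone_%02d_%s", i, strand),
                              paste(chars, collapse = ""))
  }
  list(clones = clones, truth = truth, strands = clone_strands)
}

#' Simulate peaks carrying planted motif sites
#'
#' Places non-overlapping peaks along a reference and plants one motif
#' instance per peak (the matrix consensus at fidelity 1; `k` mismatches at
#' lower fidelity, `k = round((1 - fidelity) * W)`), overwriting the
#' reference sequence. Truth offsets and strands are recorded.
#'
#' @param reference `SequenceRecord` or character scalar.
#' @param matrix a `PositionMatrix`.
#' @param n_peaks number of peaks.
#' @param peak_width peak width, bp.
#' @param fidelity planted-site fidelity in (0, 1].
#' @param plant_fraction fraction of peaks receiving a site.
#' @param strands strand pool for planted sites.
#' @param seed integer seed.
#' @return List: `reference` (modified `SequenceRecord`), `peaks`
#'   (narrowPeak-style data frame), `truth` (peak, offset, strand, site).
#' @export
make_peaks_with_motifs <- function(reference, matrix, n_peaks = 10L,
                                   peak_width = 120L, fidelity = 1.0,
                                   plant_fraction = 1.0,
                                   strands = c("+", "-"), seed = 1L) {
  set.seed(stage_seed(seed, "peaks"))
  s <- as_residues(reference)
  W <- matrix$width
  stopifnot(W < peak_width)
  L <- nchar(s)
  gap <- 10L
  need <- n_peaks * (peak_width + gap)
  if (L < need) stop("reference too short for ", n_peaks, " peaks")
  slot <- floor(L / n_peaks)
  starts <- (seq_len(n_peaks) - 1L) * slot +
    sample.int(slot - peak_width, n_peaks, replace = TRUE) - 1L
  chars <- strsplit(s, "")[[1]]
  cons <- as.character(consensus(matrix))
  k <- round((1 - fidelity) * W)
  truth <- list()
  for (i in seq_len(n_peaks)) {
    if (stats::runif(1) > plant_fraction) next
    site <- cons
    if (k > 0) {
      b <- strsplit(site, "")[[1]]
      pos <- sample.int(W, k)
      for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
      site <- paste(b, collapse = "")
    }
    strand <- sample(strands, 1L)
    planted <- if (strand == "-") revcomp(site) else site
    off <- sample.int(peak_width - W + 1L, 1L) - 1L
    g0 <- starts[i] + off
    chars[(g0 + 1L):(g0 + W)] <- strsplit(planted, "")[[1]]
    truth[[length(truth) + 1L]] <- data.frame(
      peak_name = sprintf("peak_%02d", i), offset_in_peak = off,
      genomic_start = g0, strand = strand, site = site,
      stringsAsFactors = FALSE)
  }
  peaks <- data.frame(
    seq_id = "synthetic", start = starts, end = starts + peak_width,
    name = sprintf("peak_%02d", seq_len(n_peaks)), score = 0,
    strand = ".", signal_value = 0, p_value = -1, q_value = -1,
    summit = peak_width %/% 2L, stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(peak_name = character(0), offset_in_peak = integer(0),
               genomic_start = integer(0), strand = character(0),
               site = character(0))
  list(reference = seq_record("synthetic", paste(chars, collapse = "")),
       peaks = peaks, truth = truth)
}

#' Simulate a two-state thermal denaturation curve
#'
#' Signal model: S(T) = (1 - theta) B_f(T) + theta B_u(T) + noise, with
#' theta the two-state logistic occupancy 1 / (1 + exp((midpoint - T) /
#' width)) and linear folded/unfolded baselines. The planted midpoint is
#' carried in the `"midpoint_c"` attribute.
#'
#' @param midpoint_c transition midpoint, degrees C (15..95).
#' @param width_c transition width parameter, degrees C.
#' @param amplitude unfolded-minus-folded signal amplitude.
#' @param baseline_slopes length-2 folded/unfolded baseline slopes per
#'   degree C.
#' @param noise_sd Gaussian noise SD (signal units).
#' @param t_min,t_max,step_c temperature ramp.
#' @param wavelength_nm monitoring wavelength annotation.
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @return A `MeltCurve` with attribute `midpoint_c`.
#' @export
make_melt_curve <- function(midpoint_c, width_c = 3, amplitude = 1,
                            baseline_slopes = c(0, 0), noise_sd = 0,
                            t_min = 15, t_max = 95, step_c = 2,
                            wavelength_nm = 262, seed = 1L) {
  stopifnot(midpoint_c >= 15, midpoint_c <= 95)
  tt <- seq(t_min, t_max, by = step_c)
  theta <- 1 / (1 + exp((midpoint_c - tt) / width_c))
  s <- (1 - theta) * baseline_slopes[1] * (tt - t_min) +
    theta * (amplitude + baseline_slopes[2] * (tt - t_min))
  if (noise_sd > 0) {
    set.seed(stage_seed(seed, "melt"))
    s <- s + stats::rnorm(length(tt), 0, noise_sd)
  }
  cv <- melt_curve(tt, s, wavelength_nm)
  attr(cv, "midpoint_c") <- midpoint_c
  cv
}

#' Synthetic CD spectrum for a G-quadruplex topology
#'
#' Builds a sum-of-Gaussians spectrum carrying the characteristic bands of
#' the requested fold (parallel: +262/-241; antiparallel: +295, +240,
#' -260; hybrid: +290 with a 260 nm shoulder and -240).
#'
#' @param topology `"parallel"`, `"antiparallel"` or `"hybrid"`.
#' @param wavelengths wavelength grid, nm.
#' @param scale uniform scale factor.
#' @param noise_sd Gaussian noise SD (pre-scale units).
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @return A `Spectrum`.
#' @export
make_cd_spectrum <- function(topology = c("parallel", "antiparallel", "hybrid"),
                             wavelengths = seq(220, 320, by = 1),
                             scale = 1, noise_sd = 0, seed = 1L) {
  topology <- match.arg(topology)
  g <- function(center, amp, sd) amp * exp(-(wavelengths - center)^2 / (2 * sd^2))
  v <- switch(topology,
    parallel = g(262, 1, 8) + g(241, -0.6, 6),
    antiparallel = g(295, 1, 7) + g(240, 0.5, 6) + g(260, -0.8, 7),
    hybrid = g(290, 1, 7) + g(260, 0.35, 10) + g(240, -0.6, 6))
  if (noise_sd > 0) {
    set.seed(stage_seed(seed, "cd"))
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  }
  spectrum(wavelengths, v * scale)
}

#' Simulate a qPCR measurement table with planted fold changes
#'
#' Control-condition target Ct values sit at `ct_base`; sample-condition
#' values are shifted by -log(fold)/log(eff) so the planted fold change is
#' exactly recoverable at zero noise. The reference gene is constant across
#' conditions.
#'
#' @param fold_change planted fold change (sample vs control).
#' @param target,reference_gene gene names.
#' @param eff_target,eff_ref amplification factors.
#' @param ct_base,ct_ref_base baseline Ct of target and reference gene.
#' @param noise_sd Gaussian Ct noise SD (cycles).
#' @param n_reps technical replicates per gene and condition.
#' @param seed integer seed.
#' @return List: `sample`, `control` (measurement data frames),
#'   `fold_change` (the planted truth).
#' @export
make_qpcr_table <- function(fold_change = 1, target = "GOI",
                            reference_gene = "RPLP0", eff_target = 2,
                            eff_ref = 2, ct_base = 25, ct_ref_base = 20,
                            noise_sd = 0, n_reps = 3L, seed = 1L) {
  set.seed(stage_seed(seed, "qpcr"))
  noise <- function(n) if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else
    rep(0, n)
  ct_t_sample <- ct_base - log(fold_change) / log(eff_target)
  mk <- function(cond, gene, ct0, eff) data.frame(
    sample = cond, target = gene, replicate = seq_len(n_reps),
    ct = ct0 + noise(n_reps), efficiency = eff, stringsAsFactors = FALSE)
  list(
    sample = rbind(mk("sample", target, ct_t_sample, eff_target),
                   mk("sample", reference_gene, ct_ref_base, eff_ref)),
    control = rbind(mk("control", target, ct_base, eff_target),
                    mk("control", reference_gene, ct_ref_base, eff_ref)),
    fold_change = fold_change)
}
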