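# In-silico bisulfite conversion, clone alignment and methylation calling.
#
# Alignment uses the standard reduced-alphabet trick: for the top (OT)
# bisulfite strand both clone and reference are collapsed C -> T, for the
# bottom (OB) strand G -> A, and the collapsed strings are globally aligned
# with Biostrings::pairwiseAlignment. Methylation and conversion QC are then
# read from the ORIGINAL letters through the alignment, so the asymmetric
# converted state (reference C read as clone T) scores as a match while the
# reverse direction does not.

#' Build a bisulfite reference
#'
#' Locates every CpG dinucleotide on the plus strand (positions of the C,
#' 0-based) unless an explicit site list is given.
#'
#' @param region `SequenceRecord` or character scalar.
#' @param cpg_sites optional integer vector of 0-based C positions; each
#'   must hold "CG" in the region.
#' @return Object of class `BisulfiteReference` with fields `region`
#'   (a `SequenceRecord`) and `cpg_sites`.
#' @export
bisulfite_reference <- function(region, cpg_sites = NULL) {
  if (!inherits(region, "SequenceRecord")) region <- seq_record("region", region)
  s <- region$residues
  found <- as.integer(gregexpr("(?=CG)", s, perl = TRUE)[[1]])
  found <- if (found[1] == -1L) integer(0) else found - 1L
  if (is.null(cpg_sites)) {
    cpg_sites <- found
  } else {
    cpg_sites <- sort(unique(as.integer(cpg_sites)))
    if (!all(cpg_sites %in% found)) {
      stop("cpg_sites positions not holding CG in the reference: ",
           paste(setdiff(cpg_sites, found), collapse = ", "))
    }
  }
  structure(list(region = region, cpg_sites = cpg_sites),
            class = "BisulfiteReference")
}

as_bisref <- function(x) {
  if (inherits(x, "BisulfiteReference")) x else bisulfite_reference(x)
}

#' In-silico bisulfite conversion
#'
#' Converts every unmethylated cytosine on the chosen strand to T (uracil is
#' represented as T, the post-PCR convention); the C of each methylated CpG
#' is retained. For strand `"-"` the converted bottom strand is returned in
#' its own 5'->3' orientation.
#'
#' @param reference `BisulfiteReference`, `SequenceRecord`, or string.
#' @param methylated_sites subset of the reference's `cpg_sites` (0-based C
#'   positions on the plus strand).
#' @param strand `"+"` (OT) or `"-"` (OB).
#' @return A `SequenceRecord` of the converted strand.
#' @export
#' @examples
#' r <- bisulfite_reference("ACGACA")
#' bisulfite_convert(r, methylated_sites = 1)$residues # "ACGATA"
bisulfite_convert <- function(reference, methylated_sites = integer(0),
                              strand = c("+", "-")) {
  strand <- match.arg(strand)
  ref <- as_bisref(reference)
  methylated_sites <- as.integer(methylated_sites)
  if (!all(methylated_sites %in% ref$cpg_sites)) {
    stop("methylated_sites must be a subset of the reference CpG sites")
  }
  b <- strsplit(ref$region$residues, "")[[1]]
  if (strand == "+") {
    protect <- methylated_sites + 1L             # 1-based C positions
    conv <- which(b == "C" & !(seq_along(b) %in% protect))
    b[conv] <- "T"
    out <- paste(b, collapse = "")
    id <- paste0(ref$region$id, "_BS_OT")
  } else {
    # bottom strand: its cytosines are the complements of plus-strand Gs;
    # the CpG on the bottom strand pairs with the G at site + 1
    rc <- strsplit(revcomp(ref$region$residues), "")[[1]]
    n <- length(b)
    protect_plusG <- methylated_sites + 2L       # 1-based G of the CpG
    protect_rc <- n - protect_plusG + 1L         # position in revcomp frame
    conv <- which(rc == "C" & !(seq_along(rc) %in% protect_rc))
    rc[conv] <- "T"
    out <- paste(rc, collapse = "")
    id <- paste0(ref$region$id, "_BS_OB")
  }
  seq_record(id, out)
}

reduce_ct <- function(s) chartr("C", "T", s)
reduce_ga <- function(s) chartr("G", "A", s)

# Global alignment of two equal-alphabet strings; returns gapped strings.
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap,
    type = "global")
  list(score = Biostrings::score(pa),
       a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

#' Align a bisulfite clone to its reference
#'
#' Aligns the clone against both bisulfite strand hypotheses (OT: clone and
#' reference collapsed C->T; OB: reverse-complemented clone and reference
#' collapsed G->A) with a global linear-gap alignment (match +1, mismatch
#' -1, gap -2); the best-scoring hypothesis wins, ties to OT. Identity is
#' then computed from the original letters with the converted state
#' (reference C / clone T on OT, reference G / clone A on OB) counted as a
#' match; clones below `identity_min` are flagged unalignable.
#'
#' @param clone `SequenceRecord` or character scalar.
#' @param reference `BisulfiteReference` (or sequence coercible to one).
#' @param match,mismatch,gap alignment scores (linear gap penalty).
#' @param identity_min minimum identity for an alignable clone.
#' @return Object of class `CloneAlignment`: fields `clone_id`, `strand`
#'   (`"+"` = OT, `"-"` = OB), `score`, `identity`, `alignable`,
#'   `ref_aligned` / `clone_aligned` (gapped original-letter strings in the
#'   plus-strand reference frame), and `ref_map` (for each 0-based reference
#'   position, the aligned clone character or `"-"`).
#' @export
align_clone <- function(clone, reference, match = 1, mismatch = -1,
                        gap = -2, identity_min = 0.8) {
  ref <- as_bisref(reference)
  if (!inherits(clone, "SequenceRecord")) clone <- seq_record("clone", clone)
  if (!nzchar(clone$residues)) stop("empty clone sequence")
  refseq <- ref$region$residues

  ot <- nw_align(reduce_ct(clone$residues), reduce_ct(refseq),
                 match, mismatch, gap)
  clone_rc <- revcomp(clone$residues)
  ob <- nw_align(reduce_ga(clone_rc), reduce_ga(refseq),
                 match, mismatch, gap)
  strand <- if (ob$score > ot$score) "-" else "+"
  al <- if (strand == "+") ot else ob
  clone_orig <- if (strand == "+") clone$residues else clone_rc

  # restore original letters through the gapped reduced strings
  restore <- function(gapped, orig) {
    g <- strsplit(gapped, "")[[1]]
    o <- strsplit(orig, "")[[1]]
    g[g != "-"] <- o
    g
  }
  ca <- restore(al$a, clone_orig)
  ra <- restore(al$b, refseq)

  ref_map <- ca[ra != "-"]                 # clone char over each ref position
  rb <- strsplit(refseq, "")[[1]]
  both <- ref_map != "-"
  conv_match <- if (strand == "+") rb == "C" & ref_map == "T"
                else rb == "G" & ref_map == "A"
  ident <- sum(both & (rb == ref_map | conv_match)) / max(sum(both), 1L)

  structure(list(clone_id = clone$id, strand = strand, score = al$score,
                 identity = ident, alignable = ident >= identity_min,
                 ref_aligned = paste(ra, collapse = ""),
                 clone_aligned = paste(ca, collapse = ""),
                 ref_map = ref_map),
            class = "CloneAlignment")
}

#' @export
print.CloneAlignment <- function(x, ...) {
  cat(sprintf("CloneAlignment '%s': strand %s, identity %.3f%s\n",
              x$clone_id, x$strand, x$identity,
              if (x$alignable) "" else " (unalignable)"))
  invisible(x)
}

#' Call per-CpG methylation from a clone alignment
#'
#' At each CpG the informative position is read through the alignment: on
#' the OT strand the C of the CpG (clone C = methylated, T = unmethylated),
#' on the OB strand the G (clone G = methylated, A = unmethylated). A gap or
#' any other base gives an ambiguous call.
#'
#' @param alignment a `CloneAlignment`.
#' @param cpg_sites 0-based plus-strand C positions of the CpGs.
#' @return Character vector over `c("M", "U", "A")`, one call per site.
#' @export
call_methylation <- function(alignment, cpg_sites) {
  stopifnot(inherits(alignment, "CloneAlignment"))
  pos <- if (alignment$strand == "+") cpg_sites + 1L else cpg_sites + 2L
  obs <- alignment$ref_map[pos]
  meth_chr <- if (alignment$strand == "+") "C" else "G"
  unmeth_chr <- if (alignment$strand == "+") "T" else "A"
  ifelse(obs == meth_chr, "M", ifelse(obs == unmeth_chr, "U", "A"))
}

#' Bisulfite conversion QC for one clone
#'
#' Conversion rate = converted non-CpG cytosines / aligned non-CpG
#' cytosines (on the OB strand, the corresponding guanine positions).
#' A clone below `min_rate` is flagged for exclusion from summaries.
#'
#' @param alignment a `CloneAlignment`.
#' @param cpg_sites 0-based plus-strand C positions of the CpGs.
#' @param min_rate minimum passing conversion rate.
#' @return List with `rate` (`NA` when the reference has no informative
#'   non-CpG position, in which case the clone passes with a warning),
#'   `n_converted`, `n_total`, `pass`.
#' @export
conversion_qc <- function(alignment, cpg_sites, min_rate = 0.95) {
  stopifnot(inherits(alignment, "CloneAlignment"))
  rb <- strsplit(gsub("-", "", alignment$ref_aligned), "")[[1]]
  if (alignment$strand == "+") {
    inform <- which(rb == "C")
    inform <- setdiff(inform, cpg_sites + 1L)
    converted_chr <- "T"; retained_chr <- "C"
  } else {
    inform <- which(rb == "G")
    inform <- setdiff(inform, cpg_sites + 2L)
    converted_chr <- "A"; retained_chr <- "G"
  }
  obs <- alignment$ref_map[inform]
  aligned <- obs != "-"
  n_total <- sum(aligned)
  if (length(inform) == 0L) {
    warning("reference has no non-CpG cytosine; conversion rate undefined")
    return(list(rate = NA_real_, n_converted = NA_integer_,
                n_total = 0L, pass = TRUE))
  }
  n_conv <- sum(obs == converted_chr)
  rate <- if (n_total > 0L) n_conv / n_total else NA_real_
  list(rate = rate, n_converted = n_conv, n_total = n_total,
       pass = is.na(rate) || rate >= min_rate)
}

#' Align and call a set of bisulfite clones
#'
#' Convenience pipeline: aligns each clone, applies conversion QC, and
#' assembles the clones x CpG-sites call grid (the lollipop data model).
#' Failing clones are retained and flagged, never silently dropped.
#'
#' @param reference `BisulfiteReference` (or sequence coercible to one).
#' @param clones list of `SequenceRecord` (e.g. from [read_fasta()]).
#' @param min_conversion minimum conversion rate ([conversion_qc()]).
#' @param identity_min minimum alignment identity ([align_clone()]).
#' @return Object of class `MethylationMatrix`: `clone_ids`, `sites`,
#'   `calls` (character matrix over M/U/A), `strand`, `conversion_rate`,
#'   `qc_pass`, `alignable`.
#' @export
call_clones <- function(reference, clones, min_conversion = 0.95,
                        identity_min = 0.8) {
  ref <- as_bisref(reference)
  if (inherits(clones, "SequenceRecord")) clones <- list(clones)
  n <- length(clones)
  sites <- ref$cpg_sites
  calls <- matrix("A", n, length(sites))
  strand <- character(n); rate <- numeric(n)
  pass <- logical(n); alignable <- logical(n)
  ids <- character(n)
  for (i in seq_len(n)) {
    al <- align_clone(clones[[i]], ref, identity_min = identity_min)
    qc <- conversion_qc(al, sites, min_rate = min_conversion)
    ids[i] <- al$clone_id; strand[i] <- al$strand
    rate[i] <- if (is.na(qc$rate)) NA_real_ else qc$rate
    pass[i] <- qc$pass; alignable[i] <- al$alignable
    calls[i, ] <- call_methylation(al, sites)
  }
  structure(list(clone_ids = ids, sites = sites, calls = calls,
                 strand = strand, conversion_rate = rate,
                 qc_pass = pass, alignable = alignable),
            class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d clones x %d CpG sites (%d passing QC)\n",
              length(x$clone_ids), length(x$sites),
              sum(x$qc_pass & x$alignable)))
  invisible(x)
}

#' Summarize a methylation matrix
#'
#' Per-site methylated fractions over non-ambiguous calls of clones passing
#' QC, the region mean, and a lollipop-style text rendering (filled circle =
#' methylated, open circle = unmethylated, dot = ambiguous; clones excluded
#' by QC are rendered but marked with `x`).
#'
#' @param matrix a `MethylationMatrix`.
#' @param ascii use `*`/`o`/`.` instead of Unicode circles.
#' @return List with `per_site` data frame (`site`, `n_meth`, `n_unmeth`,
#'   `fraction`), `region_mean`, and `lollipop` (character vector of rows).
#' @export
methylation_summary <- function(matrix, ascii = FALSE) {
  stopifnot(inherits(matrix, "MethylationMatrix"))
  ok <- matrix$qc_pass & matrix$alignable
  glyph <- if (ascii) c(M = "*", U = "o", A = ".") else
    c(M = "●", U = "○", A = "·")
  lolli <- vapply(seq_along(matrix$clone_ids), function(i) {
    row <- paste(glyph[matrix$calls[i, ]], collapse = " ")
    paste0(formatC(matrix$clone_ids[i], width = 12), " ",
           if (ok[i]) "  " else "x ", row)
  }, character(1))
  if (!any(ok)) {
    warning("no clone passed QC; empty summary")
    return(list(per_site = data.frame(site = matrix$sites,
                                      n_meth = 0L, n_unmeth = 0L,
                                      fraction = NA_real_),
                region_mean = NA_real_, lollipop = lolli))
  }
  calls <- matrix$calls[ok, , drop = FALSE]
  n_m <- colSums(calls == "M")
  n_u <- colSums(calls == "U")
  frac <- ifelse(n_m + n_u > 0, n_m / (n_m + n_u), NA_real_)
  list(per_site = data.frame(site = matrix$sites, n_meth = n_m,
                             n_unmeth = n_u, fraction = frac),
       region_mean = mean(frac, na.rm = TRUE),
       lollipop = lolli)
}

#' Classify a primer region by CpG content
#'
#' Bisulfite PCR primers must avoid methylation-state-dependent positions
#' (at most one CpG conserved), while methyl-specific primers rely on them
#' (three or more CpGs). A region with exactly two CpGs satisfies neither
#' rule and is inadmissible.
#'
#' @param reference `BisulfiteReference` (or sequence coercible to one).
#' @param primer_interval length-2 integer vector, 0-based half-open.
#' @return List with `primer_region`, `n_cpg`, `class` (one of
#'   `"bisulfite_ok"`, `"methyl_specific"`, `"inadmissible"`).
#' @export
check_primer <- function(reference, primer_interval) {
  ref <- as_bisref(reference)
  iv <- as.integer(primer_interval)
  if (length(iv) != 2L || iv[1] < 0L || iv[2] > nchar(ref$region$residues) ||
      iv[1] >= iv[2]) {
    stop("primer_interval must be a valid 0-based half-open interval inside the reference")
  }
  # a CpG is in the region when both its bases are
  n_cpg <- sum(ref$cpg_sites >= iv[1] & ref$cpg_sites + 2L <= iv[2])
  cls <- if (n_cpg <= 1L) "bisulfite_ok"
         else if (n_cpg >= 3L) "methyl_specific"
         else "inadmissible"
  list(primer_region = iv, n_cpg = n_cpg, class = cls)
}
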