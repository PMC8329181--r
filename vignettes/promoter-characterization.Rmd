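---
title: "Computational characterization of a CpG-island promoter: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational characterization of a CpG-island promoter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promscan)
```

promscan bundles the in-silico analyses that recur when a GC-rich
regulatory locus is characterized: composition profiling and CpG-island
detection, G-quadruplex (G4) consensus scanning, position-weight-matrix
motif search restricted to ChIP-seq peaks, bisulfite methylation calling,
relative qPCR quantification, and the routine numerical reductions of
CD/UV/fluorescence experiments. This vignette explains each model, its
assumptions, and the design decisions that were genuinely open.

## Coordinate frames

Internally every coordinate is 0-based, half-open — unambiguous for
arithmetic. Promoter biology, however, labels positions relative to a +1
(the first base of the annotated first exon) with no position 0:
`... -2, -1, +1, +2 ...`. `promoter_to_offset()`, `offset_to_promoter()`
and `interval_length_promoter()` implement this frame as a bijection onto
internal offsets. The inclusive span −117..+103 therefore contains
`r interval_length_promoter(-117, 103)` positions, which is how a core
promoter bounded by those labels yields a 220 bp amplicon.

## Composition profiles and CpG islands

`gc_content()`, `gc_skew()` and `cpg_obs_exp()` compute sliding-window
(G+C)/(A+C+G+T), (G−C)/(G+C), and the observed/expected CpG ratio
(N~CpG~·L)/(N~C~·N~G~). Choices a user should know about:

* **N handling.** N residues are excluded from numerator and denominator
  alike; windows that are entirely N are undefined (`NA`) and windows over
  10% N carry a flag. Exclusion avoids biasing ratios in masked regions.
* **Window placement.** The last partial window is dropped, never padded;
  padding biases edge ratios.
* **Skew.** Windowed skew is the default display; cumulative skew (the
  running sum) is available via `cumulative = TRUE`.

`detect_cgi()` re-implements the classic sliding-window island rule with
the conventional Gardiner-Garden–Frommer parameters as defaults: window
100 bp, step 1, GC ≥ 0.5, O/E ≥ 0.6, minimum span 200 bp — all exposed.
Qualifying windows are grouped into maximal consecutive runs; because
windows overlap at step < window, nearby runs can cover overlapping spans,
so spans are merged until no two islands overlap. An island's `mean_gc`
and `mean_obs_exp` are the means of its qualifying windows' values — a
convex combination, so every reported island satisfies both thresholds
exactly as stored. Islands longer than 2 kb are reported but flagged,
since canonical CpG islands are 200–2000 bp. Raising the O/E threshold
never increases the *total length* of islands; note that it can increase
their *count* (a long island may split into two shorter reportable ones),
which is inherent to any min-length filter, not an implementation quirk.

## G-quadruplex consensus scanning

`find_g4_hits()` scans both strands for the consensus of four runs of at
least three guanines separated by three loops of 1–7 arbitrary
nucleotides (minimum span 15 bp); minus-strand hits are found on the
reverse complement and reported in plus-strand coordinates. Two decisions
matter:

* **Canonical hit per anchor.** At each leftmost G-run start the lazy
  (shortest runs and loops first) decomposition is the canonical hit.
  Greedy-maximal matching can swallow guanines that a downstream anchor
  needs, silently dropping valid loci. `report_all = TRUE` enumerates
  every decomposition; `max_g_run` records the longest maximal G-run
  inside each hit.
* **Loci, not matches.** `merge_g4_hits()` consolidates overlapping
  same-strand hits: a biologist counts G4-capable loci, not regex matches.

`g4_run_score()` adds an optional G4Hunter-style windowed G-richness score
(per-base ±min(run, 4), window mean in [−4, 4]); it is a convenience, not
part of the consensus definition, and is off the main path.

## Motif search in peak intervals

`scan_peaks()` scores every width-W window of every peak on both strands.
The primary score is the log~2~ likelihood ratio of the site under the
column-wise motif model versus a background model, with the total
pseudocount (default 1) distributed by the background and a uniform
background by default — the standard PWM construction, guaranteeing
finite scores. A candidate is kept when its score reaches
`score_min_fraction` of the maximum attainable score; at fraction 0 the
score filter is off entirely (scores can be negative, so 0 is not a
neutral threshold). Hamming distance to the plain argmax consensus is
kept as a secondary, more literal approximate-string filter
(`max_mismatch`), with consensus ties broken by the fixed order
A &lt; C &lt; G &lt; T and flagged. Peaks are consumed verbatim — no summit
centering, no slop. Output order is deterministic: score descending, then
leftmost, then `+` before `-`.

## Bisulfite methylation calling

Bisulfite chemistry converts unmethylated cytosine to uracil (read as T
after PCR) while 5-methylcytosine in CpG context survives.
`bisulfite_convert()` models both strands; uracil is represented as T
throughout.

Clone alignment (`align_clone()`) uses the standard reduced-alphabet
trick: for the top-strand (OT) hypothesis both clone and reference are
collapsed C→T, for the bottom strand (OB) G→A, and each collapsed pair is
globally aligned (match +1, mismatch −1, linear gap −2) via
`Biostrings::pairwiseAlignment`. The better-scoring hypothesis wins, ties
to OT. Identity is then recomputed from the original letters with the
converted state (reference C / clone T on OT) counted as a match — the
asymmetric scheme a dedicated bisulfite aligner uses — and clones below
80% identity are flagged unalignable. Calls at each CpG are C→methylated,
T→unmethylated, anything else (including gaps) ambiguous; ambiguity is a
value, never an error. Conversion QC is the fraction of non-CpG cytosines
actually converted; clones under 95% (default) are excluded from
summaries but still rendered, greyed, in the lollipop text output.
These alignment and QC defaults follow common practice for clone-based
bisulfite tools; they are all exposed and no claim is made that they
reproduce any particular published clone set.

`check_primer()` encodes the two primer-design rules: a region with at
most one CpG is usable for bisulfite PCR (primers must not depend on
methylation state), a region with three or more CpGs qualifies for
methyl-specific PCR, and a region with exactly two satisfies neither rule
and is classed inadmissible rather than guessed.

## qPCR quantification

Efficiency is the per-cycle amplification factor (2 = perfect doubling; a
"95%" dialect parses to 1.95). `ratio_dct()` implements the
efficiency-corrected relative expression E~t~^−Ct,t^ / E~r~^−Ct,r^ (the
Pfaffl form), computed in log space to avoid overflow at low efficiency;
with both efficiencies 2 it is exactly 2^−ΔCt^. `fold_change_ddct()` is
its ratio-of-ratios between conditions, reducing to 2^−ΔΔCt^, and is
invariant to plate-wide Ct shifts. Technical replicates are averaged on
the Ct scale (the scale on which noise is approximately normal).
Efficiency is a required input, never silently defaulted, because
assuming perfect doubling biases fold changes multiplicatively.
`calibrate()` rescales a set of ratios so a chosen entry (e.g. one
transcript variant set to 1) is the unit. Significance testing is routine
support, not a contribution: `compare_fold_changes()` is a thin two-tailed
unpaired `t.test` on log~2~ fold changes.

## Melt curves, fluorescence, CD topology

`estimate_tm()` follows the derivative method: min-max normalization
(making the estimate invariant to positive affine transforms), linear
resampling to a uniform grid, moving-average smoothing (default 5 points,
applied before differentiation only), central differences, and the
temperature of the extremal |dS/dT| refined by a least-squares parabola
over the peak ±2 grid points. A transition is accepted when the
derivative peak exceeds 3× the baseline derivative noise, operationalized
as the median |dS/dT|: a featureless linear ramp then has peak/baseline
ratio 1 and correctly reports no transition (a deviation-around-median
definition would diverge there).

`tht_enhancement()` is the F − F0 dye-enhancement difference (negative
values flagged, not rejected); `concentration_from_absorbance()` is
Beer–Lambert with the Thioflavin T coefficient 36,000 M⁻¹cm⁻¹ at 412 nm
as default.

`classify_g4_topology()` applies the canonical CD band rules — parallel:
+260/−240 nm; antiparallel: +295 and +240/−260 nm; hybrid: +290 nm with a
260 nm shoulder and −240 nm — with extrema accepted within ±6 nm and the
rules tried in the order antiparallel → hybrid → parallel (most to least
specific), falling back to indeterminate. "Shoulder" has no standard
operational definition, so the package states one so it is testable:
|dS/dλ| below 20% of the main peak's flank slope within 255–268 nm while
the signal stays positive and the global maximum sits at 285–295 nm. The
classification is invariant to uniform scaling.

## What the synthetic generators emulate — and what they do not

The generators (`make_locus`, `make_clones`, `make_peaks_with_motifs`,
`make_melt_curve`, `make_cd_spectrum`, `make_qpcr_table`) are first-class,
seeded, pure functions of their arguments; one integer seed feeds a
stage-name-salted substream scheme so adding a generator never perturbs
another's draws.

* **Loci.** Background is i.i.d. with a chosen GC (default 0.4); the
  island segment is sampled from a first-order dinucleotide chain whose
  C→G transition is boosted to reach the target O/E (i.i.d. sampling
  cannot exceed O/E ≈ 1), then rejection-sampled until realized GC is
  within ±2% and O/E within ±0.1 of target; an infeasible combination
  errors rather than approximates. Defaults — 1000 bp locus, 300 bp
  island at GC 0.7 and O/E 1.0, flanks at GC 0.4 — mirror the structure
  of a short CpG-island promoter inside AT-richer DNA. Background G/C
  runs are capped at 2 outside planted features so G4 anchors exist only
  where planted. Methylation probabilities default to 0.9 at flank CpGs
  and 0.05 inside the island: the step pattern of a constitutively
  unmethylated island in a methylated neighborhood.
* **Clones** carry Bernoulli per-site methylation, strand-correct
  conversion, then non-CpG conversion failures, uniform substitution
  errors and short deletions at stated rates. PCR bias and chimeras are
  not modeled.
* **Curves and tables.** Melt curves are two-state logistic transitions
  with linear baselines over 15–95 °C at 2 °C steps and Gaussian noise;
  the noise level used in recovery tests is 2% of amplitude. CD spectra
  are sums of Gaussians placed exactly on the band rules. qPCR tables
  shift target Ct by −log(fold)/log(E) so the planted fold change is
  exactly recoverable at zero noise; Ct noise is Gaussian (σ = 0.1 in
  recovery tests, n = 3 replicates).

Passing recovery tests on these inputs demonstrates the *inference code*
is correct under its stated noise models; it says nothing about
sequencing artifacts, instrument drift, or biological heterogeneity the
generators do not simulate. No real-locus value (e.g. the GC content of
any particular promoter) is asserted anywhere in the test suite.

## Problem sizes and numerical notes

Property suites run at deliberately small scale chosen for tight oracle
coverage: brute-force G4 enumeration on sequences ≤ 30 nt (10,000 seeded
cases), exhaustive motif scoring on peaks ≤ 200 bp, clone sets of 8–200,
and 100-replicate Tm/qPCR recovery; each property's oracle is an
independent direct-enumeration implementation kept in the test helpers.
Ties in the motif ranking are broken leftmost-first then `+` before `-`
to keep output deterministic; island detection on a sequence shorter than
one window warns and returns an empty frame; conversion QC with no
informative cytosine is undefined and passes with a warning rather than
failing a clone on no evidence.
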