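# promscan

In-silico characterization of CpG-island promoters and their structural
and regulatory features, for researchers studying GC-rich regulatory loci
(epigenomics / regulatory genomics). The package bundles, as one tested
toolkit, the analyses that such a characterization typically chains
together:

* **Composition profiling & CpG-island detection** — sliding-window GC
  content, GC skew (G−C)/(G+C), observed/expected CpG ratio
  (N<sub>CpG</sub>·L)/(N<sub>C</sub>·N<sub>G</sub>), and island calling
  with the conventional thresholds (window 100, GC ≥ 0.5, O/E ≥ 0.6,
  span ≥ 200 bp).
* **G-quadruplex scanning** — both-strand search for the consensus
  G<sub>≥3</sub>N<sub>1–7</sub>G<sub>≥3</sub>N<sub>1–7</sub>G<sub>≥3</sub>N<sub>1–7</sub>G<sub>≥3</sub>,
  with lazy canonical decompositions, locus merging and an optional
  G4Hunter-style windowed score.
* **Motif search in ChIP-seq peaks** — JASPAR PFM parsing, log<sub>2</sub>
  likelihood-ratio (PWM log-odds) scoring of every peak window on both
  strands, consensus-mismatch filtering, deterministic ranking.
* **Bisulfite methylation calling** — in-silico conversion (both
  strands), reduced-alphabet clone alignment with converted-state-aware
  identity, per-CpG M/U/ambiguous calls, conversion-rate QC, lollipop
  summaries, and primer admissibility rules (≤ 1 CpG bisulfite-ok, ≥ 3
  methyl-specific, exactly 2 inadmissible).
* **qPCR quantification** — efficiency-corrected relative expression
  E<sub>t</sub><sup>−Ct,t</sup>/E<sub>r</sub><sup>−Ct,r</sup> (Pfaffl
  form; exactly 2<sup>−ΔCt</sup> at efficiency 2), 2<sup>−ΔΔCt</sup> fold
  changes, calibrator scaling.
* **Biophysical curve analysis** — melting temperature by the derivative
  method, ThT fluorescence enhancement F − F0, Beer–Lambert concentration
  (ε = 36,000 M⁻¹cm⁻¹ at 412 nm default), and CD-band G-quadruplex
  topology classification (parallel / antiparallel / hybrid).
* **Promoter coordinate frame** — the signed ±positions-with-no-zero
  convention promoter biology uses, as an exact bijection onto internal
  0-based offsets.
* **Synthetic data with planted truth** — seeded generators for every
  input above (loci with islands/G4s/motifs, bisulfite clone sets, melt
  curves, CD spectra, qPCR tables), used throughout the test suite.

Internally all coordinates are 0-based half-open; report output is
1-based inclusive; the promoter frame is a third, labeled frame. See the
vignette `vignettes/promoter-characterization.Rmd` for the models,
assumptions, parameter defaults and design decisions.

## Worked example

```r
library(promscan)

# a 1 kb synthetic locus: AT-rich flanks, a planted 300 bp island
# (GC 0.7, O/E 1.0), flank CpGs methylated at 0.9, island CpGs at 0.05
loc <- make_locus(seed = 42)

detect_cgi(loc$record)
#>   start end length   mean_gc mean_obs_exp n_windows over_2kb
#> 1   299 716    417 0.6895597    0.9403385       318    FALSE
```

One island is found, overlapping the planted segment (350–650) with
boundary error below the 100 bp window, at the GC and O/E its windows
measured.

```r
find_g4_hits("TTAGGGTTAGGGTTAGGGTTAGGGTT")
#>   start end strand run1 loop1 run2 loop2 run3 loop3 run4 max_g_run
#> 1     3  24      +    3     3    3     3    3     3    3         3
#>        matched_sequence
#> 1 GGGTTAGGGTTAGGGTTAGGG
```

The human-telomere-type repeat yields one plus-strand hit: four G3 runs,
three 3 nt loops, span 21.

```r
sim <- make_clones(loc$record, loc$meth_prob, n_clones = 8, seed = 42)
sm  <- methylation_summary(call_clones(loc$record, sim$clones), ascii = TRUE)
cat(head(sm$lollipop, 2), sep = "\n")
#>   clone_01_+   * * * * * * * * * * * * o * * o * o * o o o o o ...
#>   clone_02_+   * * * * * * * * * * o * * * * o * o o o o o o o ...
sm$region_mean
#> [1] 0.419
```

Each lollipop row is one clone (`*` methylated, `o` unmethylated): dense
methylation over the flanks collapsing to near zero inside the island —
the step pattern the generator planted.

```r
interval_length_promoter(-117, 103)
#> [1] 220
tb <- make_qpcr_table(fold_change = 3.5, noise_sd = 0.1, seed = 42)
fold_change_ddct(tb$sample, tb$control, "RPLP0")
#> [1] 3.858  # planted 3.5, sigma(Ct) = 0.1, n = 3
estimate_tm(make_melt_curve(65, noise_sd = 0.02, seed = 42))
#> Tm = 65.58 degC (derivative method, peak ratio 22.5)
classify_g4_topology(make_cd_spectrum("hybrid"))
#> [1] "hybrid"
```

A command-line front end over the same functions
(`inst/cli/promscan.R`) offers subcommands `profile`, `g4`, `scanmotif`,
`bisulfite`, `qpcr`, `melt`, `cdclass` and `simulate`, e.g.:

```sh
Rscript inst/cli/promscan.R simulate locus --seed 5 --out loc
Rscript inst/cli/promscan.R profile --input loc.fa --out prof
```

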