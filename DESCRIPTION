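Package: promscan
Title: In-Silico Characterization of CpG-Island Promoters, G-Quadruplexes,
    and Associated Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for computational characterization of GC-rich regulatory
    loci: sliding-window GC content, GC skew and observed/expected CpG
    profiling with CpG-island detection; consensus-motif scanning for
    putative G-quadruplex-forming sequences on both strands; position
    frequency matrix (JASPAR) motif search restricted to ChIP-seq peak
    intervals with log-odds ranking; in-silico bisulfite conversion, clone
    alignment, per-CpG methylation calling and lollipop summaries;
    efficiency-corrected relative qPCR quantification (Pfaffl and
    delta-delta-Ct forms); melting-temperature estimation from thermal
    denaturation curves, Thioflavin T fluorescence enhancement,
    Beer-Lambert concentration, and circular-dichroism G-quadruplex
    topology classification. Includes seeded synthetic-data generators
    that plant ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
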