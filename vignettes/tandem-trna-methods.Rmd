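---
title: "Methods: conservation statistics and tandem-duplication detection for tRNA genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation statistics and tandem-duplication detection for tRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tRNAtandem)
```

# Scope and model

tRNAtandem analyses nuclear tRNA gene annotations across species. Its
two halves are

1. **descriptive conservation statistics** — gene-length and
   intron-length distributions, sliding-window GC profiles over
   length-normalised gene positions, species-by-anticodon abundance
   matrices, and a gene-count versus genome-size correlation; and
2. **tandem-duplication detection** — finding proximal gene pairs on a
   scaffold, classifying them by sequence identity, chaining pairs into
   clusters, and decomposing each cluster's ordered label string into
   its smallest exact repeat unit.

A *gene record* carries genomic coordinates (1-based, inclusive), a
strand, an isotype (three-letter amino-acid code plus `iMet`, `SeC` and
`Und`), a DNA anticodon, the genomic sequence on the gene's coding
strand, and zero or more intron spans in gene-relative coordinates. A
`trna_annotation` bundles gene tables from several species with the
assembly sizes used for the genome-size correlation and keeps genes
sorted by species, scaffold and coordinate.

## The genetic-code layer

Anticodons are written in DNA (T, not U). An anticodon decodes the
codon that is its reverse complement; `anticodon_to_amino_acid()` uses
the standard genetic code. Three anticodons pair with stop codons
(`TTA`, `CTA`, `TCA`); with `sec = TRUE` the anticodon `TCA` is
reported as SeC (selenocysteine, which decodes a recoded stop), and the
others are reported as `stop-pairing`, which annotation sources
typically label `Und` (undetermined). Because of this, a complement in
which 49 of the 64 anticodons are observed contains one stop-pairing
anticodon besides SeC; the default views of `abundance_matrix()`
exclude `Und` genes (the usual high-confidence convention), so counting
all 49 requires `include_und = TRUE`. This accounting subtlety is easy
to trip over and is why both views exist.

# Tandem-duplication detection

## Proximal pairs

Two genes form a *proximal pair* when they lie on the same scaffold and
their inter-gene gap — `start(downstream) − end(upstream) − 1`, clamped
at zero for overlaps — is strictly below `max_gap` (default 1000 bp).
Strand is ignored for pairing. A start-to-start distance is available
by flag. All qualifying pairs are reported, not only adjacent ones: in
a dense array, second neighbours within the threshold also pair, which
is what lets cluster chaining bridge small gaps.

The sweep sorts genes by coordinate and, for each gene, scans forward
until the gap bound fails; because genes are sorted by start, every
later gene is at least as far away, so the scan can stop early. The
test suite checks this sweep against a quadratic brute force on random
fixtures.

## Identity classification

A pair is *identical* when the two full genomic sequences (introns
included) are byte-equal; otherwise the percent identity of a global
alignment is recorded. Spliced (mature) comparison is available by
flag. Flags for same-anticodon and same-amino-acid (with SeC decoding)
support the *degenerate pair* report: pairs encoding the same amino
acid through different anticodons.

## The aligner

`global_align()` is a three-state affine-gap global aligner (Gotoh)
written in C++ with the parameterisation commonly used for nucleotide
global alignment: match +5, mismatch −4, gap open 10, gap extension
0.5, `N` scoring zero against anything, and **free end gaps**. A gap
run of length $k$ costs $\mathrm{open} + (k-1)\cdot\mathrm{ext}$.
Identity is identical columns divided by *all* alignment columns.
Tie-breaking is fixed (diagonal over up over left, and match state over
the two gap states) so the traceback, and hence the reported identity,
is deterministic. With free end gaps the optimum may place entire
sequences in terminal gaps (score 0 for disjoint sequences); the
end-cell search therefore includes row 0 and column 0 of the dynamic
programming matrix. The tests pin the scores to an exhaustive
enumeration over all alignments of short sequences and to an
independent aligner with an equivalent gap-cost convention.

## Clusters and repeat units

Pairs are edges of a graph on genes; clusters are connected components
(computed with igraph, and checked against a union-find oracle in the
tests). Two modes mirror two views of an array:

* `identical` — only byte-identical pairs are edges; components are
  arrays of exact copies.
* `all` — every proximal pair is an edge regardless of identity.

The mode matters for mixed-isotype arrays: in a repeating
Tyr–Tyr–Ser unit, neighbours of different isotypes are never
identical, so identical-only chaining splits the array into interleaved
per-isotype clusters, while `all` mode recovers the full array.

Each cluster's genes, ordered by coordinate, give a string of
`isotype_anticodon` labels. `unit_decomposition()` finds the smallest
$p$ such that the string is the unit of length $p$ repeated $n/p$
times, using the Knuth–Morris–Pratt border (failure) array: the
smallest period is $n - \mathrm{border}(n)$, and it is an exact unit
only when it divides $n$; otherwise the whole string is its own unit
and, as an informative extra, the maximal exactly-periodic prefix run
is reported. The tests compare this against a brute force over all
candidate period lengths for every short binary label string.

# Conservation statistics

* **GC profiles.** `gc_profile()` slides a window (default 5 bp, step
  1) along a sequence and reports the GC fraction at the window-centre
  position normalised by sequence length, so genes of different
  lengths superimpose. `aggregate_gc()` bins the pooled profiles
  (default 100 bins) and smooths the bin means with a tricube-weighted
  local linear regression (span 0.75). The smoother is written out
  explicitly rather than delegated so its output is identical across R
  versions; the tests verify it against a direct weighted
  least-squares fit. The confidence band is the bin mean ±1.96
  standard errors from within-bin variance. In tRNA genes this
  profile shows the cloverleaf signature: GC-rich stems, GC-poor
  loops, and a dip around the anticodon.
* **Abundance.** `abundance_matrix()` is species × 64 anticodons, with
  a 65-column variant that splits initiator Met (`iMet`) from elongator
  `CAT`. Present/absent sets are taken over the full 64-anticodon
  space.
* **Introns.** `intron_stats()` reports per-species I/T ratios
  (intron-containing genes as a percentage of all genes), the pooled
  intron-length histogram, mean and mode.
* **Genome size.** `genome_size_correlation()` is a Pearson
  correlation with a two-sided t test and an OLS $R^2$, delegated to
  `stats::cor.test()`/`stats::lm()`. It requires at least three
  species and returns `NA` with a note when the counts have zero
  variance; the pipeline skips it for runs with fewer species.

# The synthetic generator

`generate_fixture()` builds a multi-species annotation with a genome,
background genes and *planted tandem arrays*, plus a truth table for
validation. Design points:

* **Sequences** are cloverleaf-schematic: stem positions are drawn
  GC-rich (target ≥ 0.65) and loop positions GC-poor, with the literal
  anticodon at mature positions 34–36. This reproduces the positional
  GC signature that the statistics half measures; it does **not**
  attempt real covariance-model realism (no base-pair complementarity
  across stems, no modified-base logic, no pseudogene decay).
* **Gene lengths** are drawn from a bimodal distribution over 62–92 bp
  peaked at 72 and 82 bp; genomic spans including introns are capped at
  `max_gene_span` (default 98 bp). Real tRNA introns reach hundreds of
  base pairs; the cap deliberately trades intron-length realism for
  keeping spans inside the observed 62–98 bp range, and planted intron
  lengths are log-normal around a 12-bp mode, truncated to [3, 261]
  and to the cap.
* **Introns** are inserted immediately 3′ of the anticodon, the
  canonical position, with per-anticodon probabilities defaulting to
  high rates for `CAT` and `GTA` (the anticodons that dominate
  intron-containing tRNA genes).
* **Background genes** are separated by at least 1200 bp so they can
  never enter tandem calls; planted arrays use copy gaps far below the
  1-kb threshold. Arrays are built from one base sequence per unit
  slot; a `divergence` of $d$ applies exactly $d$ substitutions per
  later copy, never touching the anticodon.
* **Determinism.** `set.seed()` is pinned to Mersenne-Twister with
  Inversion/Rejection so a spec plus seed reproduces the fixture
  byte-for-byte; the truth table records each array's unit, copy
  count, gaps and gene ids.
* The default per-anticodon counts mark 15 anticodons (14 amino-acid
  anticodons plus one stop-pairing one) as absent, matching the
  widely observed eukaryote-wide pattern.

The generator's defaults are the package's study conditions; the
acceptance script (`scripts/acceptance.R`) only chooses the planted
array composition and takes the seed from the command line.

# Pipeline and provenance

`run_pipeline(run_config(...))` executes
`simulate → ingest → stats → tandem → cluster → report`, writing TSV,
BED6 and JSON outputs plus a manifest with per-stage status, timings,
row counts and MD5 checksums of every output file. TSV writers format
floats with fixed precision and write through a binary connection, so
re-running an identical configuration is byte-identical except for the
manifest's timings. A stage failure aborts with a partial manifest.

I/O supports the tRNAscan-SE tabular (".out") format — including
minus-strand coordinate normalisation, genome-to-gene-relative intron
conversion, pseudogene notes and `???`/`NNN` placeholders — and FASTA
via Biostrings.

# Limitations

* Identity-based clustering leaves the divergent-cluster threshold to
  the user: the package reports per-cluster identity statistics rather
  than imposing a cut-off, because how much internal divergence still
  counts as "one array" is a judgement call.
* Substitution-rate dating of duplications (Kn/Ks) and synteny-based
  segmental-duplication detection are out of scope.
* The generator is a validation instrument, not a population-genetic
  simulator: no indels within genes, no array-boundary decay, no
  transposon context.
* No claims are made here about empirical genome collections; every
  number the package documentation cites is computed by its own test
  suite from constructed or generated inputs.
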