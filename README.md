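# tRNAtandem

Conservation statistics and tandem-duplication detection for tRNA gene
annotations.

## The problem

Nuclear genomes carry tens to hundreds of tRNA genes whose anticodon
repertoire, gene lengths, intron placement and GC structure are highly
conserved across species, while their copy numbers are not. One source
of copy-number change is **tandem duplication**: arrays of near-adjacent
tRNA gene copies on one scaffold, sometimes of a single isotype
(e.g. 27 proline genes in a row) and sometimes with a periodic
multi-isotype unit (e.g. Tyr–Tyr–Ser repeated 27 times). This package
takes per-species tRNA gene annotations (tRNAscan-SE tabular output plus
genome FASTA) and computes

* descriptive conservation statistics — gene-length and intron-length
  distributions, sliding-window GC profiles over length-normalised gene
  positions, species × anticodon abundance matrices with present/absent
  accounting over the full 64-anticodon space, I/T intron ratios, and a
  gene-count versus genome-size correlation; and
* tandem-duplication calls — proximal pair detection, identity
  classification, cluster chaining and repeat-unit decomposition.

It also ships a seeded synthetic fixture generator with planted arrays
and a ground-truth table, used throughout the test suite.

## Model and algorithms

* **Proximal pairs.** Genes $a$ (upstream) and $b$ on one scaffold pair
  when the inter-gene gap $g = \mathrm{start}(b) - \mathrm{end}(a) - 1$
  (clamped at 0) satisfies $g < 1000$ (strict). Found by a sorted sweep;
  tests check it against the $O(n^2)$ brute force.
* **Identity.** A pair is *identical* iff the full genomic sequences are
  byte-equal. Otherwise percent identity comes from a three-state
  affine-gap global alignment (Gotoh) with match $+5$, mismatch $-4$,
  gap run cost $10 + (k-1)\cdot 0.5$, free end gaps, identity =
  identical columns / all alignment columns. Scores are pinned by an
  exhaustive-enumeration oracle and an independent aligner in the tests.
* **Clusters.** Pairs are graph edges; clusters are connected
  components, in two modes (`identical` edges only, or `all` proximal
  pairs). For each cluster the ordered `isotype_anticodon` label string
  $s$ of length $n$ is decomposed via the KMP border array: the smallest
  period $p = n - \mathrm{border}(n)$ is an exact repeat unit when
  $p \mid n$, giving `repeats` $= n/p$.
* **GC profiles.** Window GC (default 5 bp, step 1) at length-normalised
  window-centre positions, binned and smoothed with an explicit
  tricube-weighted local linear regression, with a ±1.96 SE band.
* **Clustering of unique sequences.** Deterministic greedy centroid
  clustering at ≥ 90 % identity and ≥ 80 % bidirectional coverage.

See the methods vignette (`vignettes/tandem-trna-methods.Rmd`) for the
full parameter rationale, generator design and limitations.

## Worked example

Plant a five-copy proline array among background genes, then detect it:

```r
library(tRNAtandem)

spec <- synthetic_spec(42L,
  species_spec("Ath", scaffold_lengths = c(3e5),
               anticodon_counts = default_anticodon_counts(0.3)),
  arrays = list(array_spec("Ath", "Ath_chr1", anchor = 5000L,
                           unit = unit_labels("Pro_TGG"),
                           copies = 5L, intra_gap = 200L)))
fix <- generate_fixture(spec)
fix$annotation
#> trna_annotation: 58 genes, 1 species, 1 scaffolds
#> assembly sizes (bp): Ath 3e+05

pairs <- classify_pairs(proximal_pairs(fix$annotation), fix$annotation)
str(pair_summary(pairs))
#> List of 5
#>  $ n_pairs                 : int 9
#>  $ n_identical             : int 9
#>  $ n_divergent             : int 0
#>  $ fraction_identical      : num 100
#>  $ divergent_identity_range: num [1:2] NA NA

clusters <- chain_clusters(pairs, fix$annotation, mode = "identical")
clusters[, c("cluster_id", "seq_id", "start", "end", "n_genes",
             "unit", "repeats")]
#>   cluster_id   seq_id start  end n_genes    unit repeats
#> 1     TC0001 Ath_chr1  5000 6214       5 Pro_TGG       5
```

(The nine pairs from five adjacent copies are the four neighbours plus
the five second- and third-neighbour pairs still inside the 1-kb bound.)

The aligner is available directly:

```r
al <- global_align("GGGCCCGTAGCTCAGT", "GGGCCCGTAGTTCAGT")
str(al[c("score", "identity_pct", "aligned_a", "aligned_b")])
#> List of 4
#>  $ score       : num 71
#>  $ identity_pct: num 93.8
#>  $ aligned_a   : chr "GGGCCCGTAGCTCAGT"
#>  $ aligned_b   : chr "GGGCCCGTAGTTCAGT"
```

An end-to-end run (`simulate → ingest → stats → tandem → cluster →
report`) with TSV/BED/JSON outputs and a checksummed manifest:

```r
m <- run_pipeline(run_config("out_dir", seed = 1L))
```

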