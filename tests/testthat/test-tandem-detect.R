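test_that("the 1-kb bound is strict: gap 999 pairs, gap 1000 does not", {
  g999 <- make_genes(c(1L, 1072L))          # gap = 1072 - 72 - 1 = 999
  expect_equal(nrow(proximal_pairs(g999)), 1L)
  expect_equal(proximal_pairs(g999)$gap_bp, 999L)
  g1000 <- make_genes(c(1L, 1073L))
  expect_equal(nrow(proximal_pairs(g1000)), 0L)
})

test_that("pairs respect scaffolds, overlap clamping and strand", {
  g <- rbind(make_genes(1L), make_genes(200L, seq_id = "chr2"))
  g$gene_id <- c("a", "b")
  expect_equal(nrow(proximal_pairs(g)), 0L)

  # overlapping genes get gap clamped to zero
  ov <- make_genes(c(1L, 40L))
  p <- proximal_pairs(ov)
  expect_equal(p$gap_bp, 0L)

  # strand is ignored for pairing
  gs <- make_genes(c(1L, 200L), strand = c("+", "-"))
  expect_equal(nrow(proximal_pairs(gs)), 1L)

  # unsorted plain tables are re-sorted with a warning
  un <- make_genes(c(500L, 1L))  # rows not in coordinate order
  expect_warning(pu <- proximal_pairs(un), "re-sort")
  expect_equal(nrow(pu), 1L)
})

test_that("sweep equals the O(n^2) brute force on random fixtures", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(5:200, 1)
    starts <- sort(sample.int(60000, n))
    lens <- sample(62:98, n, replace = TRUE)
    g <- trna_genes(gene_id = paste0("g", seq_len(n)), species = "Tst",
                    seq_id = sample(c("c1", "c2"), n, replace = TRUE),
                    start = starts, end = starts + lens - 1L,
                    strand = "+", isotype = "Pro", anticodon = "TGG",
                    genomic_seq = strrep("A", lens))
    got <- proximal_pairs(trna_annotation(g))
    want <- brute_force_pairs(trna_annotation(g)$genes)
    key <- function(d) sort(paste(d$gene_a, d$gene_b, d$gap_bp))
    expect_equal(key(got), key(want))
  }
})

test_that("raising max_gap never loses pairs", {
  set.seed(55)
  starts <- sort(sample.int(30000, 60))
  g <- make_genes(starts, lengths = 72L)
  n_by_gap <- vapply(c(100L, 500L, 1000L, 2000L), function(mg)
    nrow(proximal_pairs(g, mg)), integer(1))
  expect_true(all(diff(n_by_gap) >= 0))
})

test_that("pair classification flags identity and decoding", {
  s <- random_dna(72)
  g <- trna_genes(gene_id = c("p1", "p2", "p3"), species = "Tst",
                  seq_id = "chr1", start = c(1L, 300L, 600L),
                  end = c(72L, 371L, 671L), strand = "+",
                  isotype = "Pro", anticodon = c("TGG", "TGG", "AGG"),
                  genomic_seq = c(s, s, random_dna(72)))
  cls <- classify_pairs(proximal_pairs(g), g)
  p12 <- cls[cls$gene_a == "p1" & cls$gene_b == "p2", ]
  expect_true(p12$identical)
  expect_equal(p12$identity_pct, 100)
  p23 <- cls[cls$gene_a == "p2" & cls$gene_b == "p3", ]
  expect_false(p23$identical)
  expect_true(p23$same_amino_acid)      # Pro_TGG vs Pro_AGG
  expect_false(p23$same_anticodon)
  expect_lt(p23$identity_pct, 100)
})

test_that("cluster chaining equals union-find components", {
  set.seed(66)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    starts <- sort(sample.int(20000, n))
    g <- make_genes(starts, lengths = 72L)
    pairs <- proximal_pairs(g)
    if (nrow(pairs) == 0) next
    cls <- classify_pairs(pairs, g)
    got <- chain_clusters(cls, g, mode = "all")
    want <- uf_components(unique(c(pairs$gene_a, pairs$gene_b)),
                          pairs$gene_a, pairs$gene_b)
    want_key <- sort(unname(vapply(want, function(m)
      paste(sort(m), collapse = ","), character(1))))
    got_key <- sort(vapply(strsplit(got$gene_ids, ","), function(m)
      paste(sort(m), collapse = ","), character(1)))
    expect_equal(got_key, want_key)
    # genes appear in exactly one cluster; spans do not overlap
    all_ids <- unlist(strsplit(got$gene_ids, ","))
    expect_false(anyDuplicated(all_ids) > 0)
    bysc <- split(got, got$seq_id)
    for (d in bysc) if (nrow(d) > 1) {
      d <- d[order(d$start), ]
      expect_true(all(d$start[-1] > d$end[-nrow(d)]))
    }
  }
})

test_that("identical-mode chaining separates planted arrays", {
  # three identical arrays of 26, 18 and 14 copies, well separated
  mk_arrays <- list(
    array_spec("Cpu", "Cpu_chr1", anchor = 2000L,
               unit = unit_labels("Ile_AAT"), copies = 26L,
               intra_gap = 150L),
    array_spec("Cpu", "Cpu_chr1", anchor = 30000L,
               unit = unit_labels("Cys_GCA"), copies = 18L,
               intra_gap = 150L),
    array_spec("Cpu", "Cpu_chr1", anchor = 50000L,
               unit = unit_labels("Cys_GCA"), copies = 14L,
               intra_gap = 150L))
  spec <- synthetic_spec(41L,
    species_spec("Cpu", scaffold_lengths = c(8e4),
                 anticodon_counts = default_anticodon_counts(0)),
    arrays = mk_arrays)
  fix <- generate_fixture(spec)
  cls <- classify_pairs(proximal_pairs(fix$annotation), fix$annotation)
  clusters <- chain_clusters(cls, fix$annotation, mode = "identical")
  expect_equal(nrow(clusters), 3L)
  expect_equal(sum(clusters$n_genes), 58L)
  expect_equal(sort(clusters$n_genes), c(14L, 18L, 26L))
  expect_true(all(clusters$identity_class == "all-identical"))
})

test_that("unit decomposition finds the smallest exact repeat unit", {
  expect_equal(unit_decomposition(rep("Pro_TGG", 27))[c("unit_len",
                                                        "repeats")],
               list(unit_len = 1L, repeats = 27L))
  d <- unit_decomposition(rep(c("Tyr_GTA", "Tyr_GTA", "Ser_GCT"), 27))
  expect_equal(d$unit_len, 3L)
  expect_equal(d$repeats, 27L)
  expect_equal(d$unit, c("Tyr_GTA", "Tyr_GTA", "Ser_GCT"))
  # non-dividing period: whole string is its own unit
  expect_equal(unit_decomposition(c("A", "B", "A"))[c("unit_len",
                                                      "repeats")],
               list(unit_len = 3L, repeats = 1L))
  expect_error(unit_decomposition(character(0)), "empty")

  # every label string of length <= 8 over two symbols vs brute force
  for (n in 1:8) {
    combos <- expand.grid(rep(list(c("A", "B")), n),
                          stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      s <- as.character(combos[r, ])
      got <- unit_decomposition(s)
      want <- brute_force_unit(s)
      expect_equal(got$unit_len, want$unit_len, info = paste(s,
                                                             collapse = ""))
      expect_equal(got$repeats, want$repeats)
    }
  }
})

test_that("degenerate anticodon pairs keep same-aa different-anticodon", {
  s <- random_dna(72)
  g <- trna_genes(gene_id = paste0("d", 1:4), species = "Tst",
                  seq_id = "chr1",
                  start = c(1L, 300L, 600L, 900L),
                  end = c(72L, 371L, 671L, 971L), strand = "+",
                  isotype = c("Pro", "Pro", "Pro", "Ala"),
                  anticodon = c("TGG", "AGG", "TGG", "TGC"),
                  genomic_seq = c(s, random_dna(72), s, random_dna(72)))
  cls <- classify_pairs(proximal_pairs(g), g)
  deg <- degenerate_anticodon_pairs(cls)
  keys <- paste(deg$pairs$gene_a, deg$pairs$gene_b)
  expect_true("d1 d2" %in% keys)   # Pro TGG vs Pro AGG: kept
  expect_false("d1 d3" %in% keys)  # same anticodon: excluded
  expect_false("d3 d4" %in% keys)  # different amino acid: excluded
  expect_equal(deg$by_amino_acid$amino_acid, "Pro")
  expect_equal(deg$by_amino_acid$n_pairs, 2L)  # d1-d2 and d2-d3
})
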