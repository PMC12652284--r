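test_that("generated sequences place the anticodon at positions 34-36", {
  set.seed(5)
  for (k in 1:20) {
    ac <- sample(setdiff(ANTICODONS, c("TTA", "CTA", "TCA")), 1)
    L <- sample(62:98, 1)
    s <- generate_trna_sequence(anticodon_to_amino_acid(ac), ac, L)
    expect_equal(nchar(s), L)
    expect_equal(substr(s, 34, 36), ac)
  }
  expect_error(generate_trna_sequence("Pro", "TGG", 50), "range")
  expect_error(generate_trna_sequence("Pro", "TGG", 99), "range")
})

test_that("stems are GC-rich relative to the anticodon triplet", {
  set.seed(101)
  acs <- sample(setdiff(ANTICODONS, c("TTA", "CTA", "TCA")), 200,
                replace = TRUE)
  stem_gc <- numeric(200); ac_gc <- numeric(200)
  for (k in 1:200) {
    L <- sample(62:98, 1)
    s <- generate_trna_sequence("Und", acs[k], L)
    chars <- strsplit(s, "")[[1]]
    stems <- tRNAtandem:::.stem_mask(L)
    stem_gc[k] <- mean(chars[stems] %in% c("G", "C"))
    ac_gc[k] <- mean(chars[34:36] %in% c("G", "C"))
  }
  expect_gt(mean(stem_gc), mean(ac_gc))
  expect_gt(mean(stem_gc), 0.65)
})

test_that("planted arrays produce the promised copies and divergence", {
  spec <- small_spec(seed = 3L, scale = 0, arrays = list(
    array_spec("Tst", "Tst_chr1", anchor = 2000L,
               unit = unit_labels("Pro_TGG"), copies = 27L,
               intra_gap = 100L)))
  fix <- generate_fixture(spec)
  g <- fix$annotation$genes
  expect_equal(nrow(g), 27L)
  expect_length(unique(g$genomic_seq), 1L)  # divergence 0: identical
  gaps <- g$start[-1] - g$end[-27] - 1L
  expect_true(all(gaps == 100L))
  # 26 adjacent identical pairs
  adj <- sum(g$genomic_seq[-1] == g$genomic_seq[-27])
  expect_equal(adj, 26L)

  # multi-isotype unit: isotype string has smallest period 3
  spec2 <- small_spec(seed = 3L, scale = 0, arrays = list(
    array_spec("Tst", "Tst_chr1", anchor = 2000L,
               unit = unit_labels(c("Tyr_GTA", "Tyr_GTA", "Ser_GCT")),
               copies = 27L, intra_gap = 100L)))
  g2 <- generate_fixture(spec2)$annotation$genes
  expect_equal(nrow(g2), 81L)
  dec <- unit_decomposition(paste(g2$isotype, g2$anticodon, sep = "_"))
  expect_equal(dec$unit_len, 3L)
  expect_equal(dec$repeats, 27L)

  # degenerate single-copy array: one gene, no pairs
  spec3 <- small_spec(seed = 3L, scale = 0, arrays = list(
    array_spec("Tst", "Tst_chr1", anchor = 2000L,
               unit = unit_labels("Pro_TGG"), copies = 1L)))
  fix3 <- generate_fixture(spec3)
  expect_equal(nrow(fix3$annotation$genes), 1L)
  expect_equal(nrow(proximal_pairs(fix3$annotation)), 0L)
})

test_that("divergent copies carry exactly d substitutions outside the anticodon", {
  spec <- small_spec(seed = 9L, scale = 0, arrays = list(
    array_spec("Tst", "Tst_chr1", anchor = 2000L,
               unit = unit_labels("Ala_TGC"), copies = 6L,
               intra_gap = 150L, divergence = 3L)))
  g <- generate_fixture(spec)$annotation$genes
  base <- strsplit(g$genomic_seq[1], "")[[1]]
  for (i in 2:6) {
    v <- strsplit(g$genomic_seq[i], "")[[1]]
    expect_equal(sum(v != base), 3L)
    expect_equal(v[34:36], base[34:36])  # anticodon untouched
    expect_equal(g$anticodon[i], "TGC")
  }
})

test_that("fixtures are bit-reproducible and bookkeeping is exact", {
  spec <- small_spec(seed = 7L, scale = 0.2, arrays = list(
    array_spec("Tst", "Tst_chr1", anchor = 5000L,
               unit = unit_labels("Pro_TGG"), copies = 5L)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(generate_fixture(spec), d1)
  write_fixture(generate_fixture(spec), d2)
  for (fn in list.files(d1))
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  fix <- generate_fixture(spec)
  expect_equal(nrow(fix$truth), 1L)
  truth_ids <- strsplit(fix$truth$gene_ids, ",")[[1]]
  expect_length(truth_ids, 5L)
  expect_true(all(truth_ids %in% fix$annotation$genes$gene_id))
  # a different seed changes the fixture
  fix2 <- generate_fixture(small_spec(seed = 8L, scale = 0.2))
  expect_false(identical(fix$genome, fix2$genome))
})

test_that("gene lengths stay inside the 62-98 bp envelope", {
  fix <- generate_fixture(small_spec(seed = 13L, scale = 0.5))
  ld <- length_distribution(fix$annotation$genes, include_und = TRUE)
  expect_gte(ld$min, 62L)
  expect_lte(ld$max, 98L)
})

test_that("planted arrays are recoverable and background stays clear", {
  spec <- synthetic_spec(21L,
    species_spec("Tst", scaffold_lengths = c(3e5),
                 anticodon_counts = default_anticodon_counts(0.3)),
    arrays = list(
      array_spec("Tst", "Tst_chr1", anchor = 4000L,
                 unit = unit_labels("Pro_TGG"), copies = 8L,
                 intra_gap = 300L),
      array_spec("Tst", "Tst_chr1", anchor = 40000L,
                 unit = unit_labels(c("Tyr_GTA", "Ser_GCT")),
                 copies = 6L, intra_gap = 200L)))
  fix <- generate_fixture(spec)
  pairs <- classify_pairs(proximal_pairs(fix$annotation),
                          fix$annotation)
  clusters <- chain_clusters(pairs, fix$annotation, mode = "all")
  # every divergence-0 array is recovered with exactly its gene set;
  # "all" mode is needed because mixed-isotype units alternate
  # non-identical neighbours
  for (i in seq_len(nrow(fix$truth))) {
    truth_ids <- sort(strsplit(fix$truth$gene_ids[i], ",")[[1]])
    hit <- clusters[clusters$start == fix$truth$start[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(sort(strsplit(hit$gene_ids, ",")[[1]]), truth_ids)
    expect_equal(hit$repeats, fix$truth$copies[i])
    expect_equal(hit$unit_len, fix$truth$unit_len[i])
  }
  # no background gene participates in any pair
  array_ids <- unlist(strsplit(fix$truth$gene_ids, ","))
  expect_true(all(c(pairs$gene_a, pairs$gene_b) %in% array_ids))
})

test_that("arrays with gaps of 1 kb or more are not detected", {
  spec <- small_spec(seed = 4L, scale = 0, arrays = list(
    array_spec("Tst", "Tst_chr1", anchor = 2000L,
               unit = unit_labels("Pro_TGG"), copies = 5L,
               intra_gap = 1000L)))
  fix <- generate_fixture(spec)
  expect_equal(nrow(proximal_pairs(fix$annotation)), 0L)
})
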