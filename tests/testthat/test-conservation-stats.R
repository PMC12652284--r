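test_that("gc_profile matches a naive recount", {
  p <- gc_profile("GGGGG")
  expect_equal(nrow(p), 1L)
  expect_equal(p$gc, 1.0)
  expect_equal(p$position, 3 / 5)

  p2 <- gc_profile("ATATAT")
  expect_equal(nrow(p2), 2L)
  expect_equal(p2$gc, c(0, 0))

  expect_error(gc_profile("ACG", window = 5), "shorter")

  set.seed(31)
  for (k in 1:20) {
    s <- random_dna(80)
    w <- sample(3:9, 1); st <- sample(1:3, 1)
    expect_equal(as.data.frame(gc_profile(s, w, st)),
                 naive_gc_profile(s, w, st), ignore_attr = TRUE)
  }
})

test_that("aggregate_gc averages bins and smooths with tricube weights", {
  mk <- function(v) structure(data.frame(position = seq(0.01, 0.99,
                                                        length.out = 50),
                                         gc = v),
                              class = c("gc_profile", "data.frame"),
                              window = 5L, step = 1L, source = "x")
  agg <- aggregate_gc(list(mk(0.5), mk(0.5)), n_bins = 20)
  expect_true(all(abs(agg$gc - 0.5) < 1e-12))
  expect_true(all(abs(agg$fit - 0.5) < 1e-9))
  expect_true(all(agg$upper - agg$lower < 1e-12))  # zero-width band

  agg2 <- aggregate_gc(list(mk(0.4), mk(0.6)), n_bins = 20)
  expect_true(all(abs(agg2$gc - 0.5) < 1e-12))

  # smoother equals a direct weighted-least-squares fit at probe points
  set.seed(8)
  x <- seq(0.005, 0.995, by = 0.01)
  y <- 0.5 + 0.2 * sin(2 * pi * x) + rnorm(100, 0, 0.02)
  span <- 0.75
  got <- tRNAtandem:::.tricube_local_linear(x, y, x[c(5, 25, 50, 75, 95)],
                                            span)
  for (m in seq_along(c(5, 25, 50, 75, 95))) {
    x0 <- x[c(5, 25, 50, 75, 95)][m]
    d <- abs(x - x0)
    h <- sort(d)[ceiling(span * length(x))]
    w <- (1 - pmin(d / h, 1)^3)^3
    fit <- stats::lm(y ~ I(x - x0), weights = w)
    expect_equal(got[m], unname(coef(fit)[1]), tolerance = 1e-9)
  }
  expect_error(aggregate_gc(list()), "no profiles")
})

test_that("abundance matrix accounts for the 64-anticodon space", {
  empty <- abundance_matrix(make_genes(integer(0))[0, ])
  expect_length(empty$absent, 64L)

  # one gene for each of 49 distinct anticodons leaves 15 absent
  sense <- setdiff(ANTICODONS, c("TTA", "CTA", "TCA"))
  acs <- sense[1:49]
  g <- make_genes(seq(1, by = 5000, length.out = 49),
                  isotype = anticodon_to_amino_acid(acs),
                  anticodon = acs)
  ab <- abundance_matrix(g)
  expect_length(ab$present, 49L)
  expect_length(ab$absent, 15L)
  expect_equal(sum(ab$matrix), 49L)

  # row sums equal per-species gene counts; present + absent = 64
  fix <- generate_fixture(small_spec(seed = 2L, scale = 0.4))
  ab2 <- abundance_matrix(fix$annotation$genes, include_und = TRUE)
  gg <- filter_high_confidence(fix$annotation$genes,
                               include_und = TRUE)
  expect_equal(unname(rowSums(ab2$matrix)),
               unname(as.integer(table(gg$species))))
  expect_equal(length(ab2$present) + length(ab2$absent), 64L)
  # matrix equals the generator's per-anticodon spec counts
  want <- fix$spec$species_specs[[1]]$anticodon_counts
  expect_equal(as.integer(ab2$matrix["Tst", names(want)]),
               unname(as.integer(want)))
  # iMet split: 65-column view separates initiator Met from CAT
  expect_equal(ab2$matrix65[, "CAT"] + ab2$matrix65[, "iMet_CAT"],
               ab2$matrix[, "CAT"])
})

test_that("intron statistics compute I/T ratios, mode and mean", {
  g <- make_genes(seq(1, by = 5000, length.out = 10), lengths = 90L)
  g$introns[[1]] <- intron_spans(38L, 49L)
  expect_equal(intron_stats(g)$per_species$it_ratio, 10)

  g0 <- make_genes(seq(1, by = 5000, length.out = 4))
  st0 <- intron_stats(g0)
  expect_equal(st0$per_species$it_ratio, 0)
  expect_length(st0$lengths, 0L)

  # planted lengths {12 x5, 11 x2}: mode 12, mean 82/7
  lens <- c(rep(12L, 5), rep(11L, 2))
  g2 <- make_genes(seq(1, by = 5000, length.out = 7), lengths = 95L,
                   introns = lapply(lens, function(l)
                     intron_spans(38L, 37L + l)))
  st <- intron_stats(g2)
  expect_equal(st$mode_length, 12L)
  expect_equal(st$mean_length, 82 / 7)
  expect_equal(sum(st$histogram), 7L)
})

test_that("genome-size correlation matches the textbook formulas", {
  # suppress lm's "essentially perfect fit" note on this exact probe
  r1 <- suppressWarnings(genome_size_correlation(2 * (1:5), 1:5))
  expect_equal(r1$r, 1)
  expect_equal(r1$r_squared, 1)

  r0 <- genome_size_correlation(rep(3, 5), 1:5)
  expect_true(is.na(r0$r))

  set.seed(12)
  x <- c(120, 480, 310, 95, 700, 260)
  y <- c(210, 340, 300, 180, 420, 330)
  res <- genome_size_correlation(y, x)
  # hand-computed Pearson r and two-sided t-test p-value
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r_hand * sqrt((6 - 2) / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_stat), df = 4)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_equal(res$slope, slope_hand, tolerance = 1e-12)
  expect_equal(res$r_squared, r_hand^2, tolerance = 1e-12)
  # r is symmetric in (x, y); R^2 invariant to x-scaling
  expect_equal(genome_size_correlation(x, y)$r, res$r)
  expect_equal(genome_size_correlation(y, x * 1000)$r_squared,
               res$r_squared)
})

test_that("length distribution reports every tied mode", {
  g <- make_genes(seq(1, by = 5000, length.out = 5),
                  lengths = c(72L, 72L, 82L, 82L, 75L))
  ld <- length_distribution(g)
  expect_equal(ld$modes, c(72L, 82L))
  expect_equal(ld$min, 72L)
  expect_equal(ld$max, 82L)
  g1 <- make_genes(1L, lengths = 77L)
  ld1 <- length_distribution(g1)
  expect_equal(ld1$min, 77L)
  expect_equal(ld1$max, 77L)
  expect_equal(ld1$modes, 77L)
})

test_that("aggregate GC of fixtures is stem-high at the 5' end", {
  fix <- generate_fixture(small_spec(seed = 6L, scale = 0.4))
  prof <- gene_gc_profiles(fix$annotation$genes)
  agg <- aggregate_gc(prof, n_bins = 100)
  head_gc <- mean(agg$gc[agg$position <= 0.05])
  anticodon_gc <- mean(agg$gc[agg$position >= 0.42 &
                                agg$position <= 0.50])
  expect_gt(head_gc, anticodon_gc)
})
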