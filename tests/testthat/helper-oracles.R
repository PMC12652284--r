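# Independent oracles and small fixture builders shared across tests.

# quick gene table: n genes on one scaffold with given starts/lengths
make_genes <- function(starts, lengths = 72L, species = "Tst",
                       seq_id = "chr1", isotype = "Pro",
                       anticodon = "TGG", seqs = NULL, strand = "+",
                       introns = NULL) {
  n <- length(starts)
  lengths <- rep_len(lengths, n)
  if (is.null(seqs))
    seqs <- vapply(lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1))
  trna_genes(gene_id = sprintf("%s.g%d", species, seq_len(n)),
             species = species, seq_id = rep_len(seq_id, n),
             start = starts, end = starts + lengths - 1L,
             strand = strand, isotype = rep_len(isotype, n),
             anticodon = rep_len(anticodon, n), genomic_seq = seqs,
             introns = introns)
}

# O(n^2) scan for proximal pairs: every same-scaffold pair with
# inter-gene gap strictly below max_gap, upstream gene first
brute_force_pairs <- function(genes, max_gap = 1000L) {
  out <- list()
  n <- nrow(genes)
  ord <- order(genes$species, genes$seq_id, genes$start, genes$end,
               genes$gene_id)
  g <- genes[ord, , drop = FALSE]
  for (i in seq_len(max(n - 1L, 0L))) for (j in seq.int(i + 1L, n)) {
    if (j > n) break
    if (g$species[i] != g$species[j] || g$seq_id[i] != g$seq_id[j]) next
    gap <- g$start[j] - g$end[i] - 1L
    if (gap < max_gap)
      out[[length(out) + 1L]] <- data.frame(
        gene_a = g$gene_id[i], gene_b = g$gene_id[j],
        gap_bp = max(gap, 0L), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(gene_a = character(0), gene_b = character(0),
                  gap_bp = integer(0))
}

# union-find connected components over an edge list
uf_components <- function(ids, edges_a, edges_b) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, character(1))
  split(ids, roots)
}

# exhaustive enumeration of global alignment score with affine gaps:
# a gap run of length k costs open + (k-1) * ext; with free end gaps
# any terminal run is free (handled by free prefix skips and the
# boundary shortcut)
enum_align_score <- function(a, b, match = 5, mismatch = -4,
                             open = 10, ext = 0.5, end_free = TRUE) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  na <- length(av); nb <- length(bv)
  s <- function(x, y) {
    if (x == "N" || y == "N") return(0)
    if (x == y) match else mismatch
  }
  rec <- function(i, j, run) {
    if (i == na && j == nb) return(0)
    best <- -Inf
    if (end_free && (i == na || j == nb)) best <- 0  # free tail run
    if (i < na && j < nb)
      best <- max(best, s(av[i + 1], bv[j + 1]) + rec(i + 1, j + 1, 0L))
    if (i < na)
      best <- max(best, -(if (run == 1L) ext else open) +
                          rec(i + 1, j, 1L))
    if (j < nb)
      best <- max(best, -(if (run == 2L) ext else open) +
                          rec(i, j + 1, 2L))
    best
  }
  if (!end_free) return(rec(0L, 0L, 0L))
  best <- -Inf
  for (i0 in 0:na) best <- max(best, rec(i0, 0L, 0L))  # free head in a
  for (j0 in 0:nb) best <- max(best, rec(0L, j0, 0L))  # free head in b
  best
}

# naive windowed GC recount
naive_gc_profile <- function(seq, window = 5L, step = 1L) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  starts <- seq.int(1L, L - window + 1L, by = step)
  data.frame(position = (starts + (window - 1) / 2) / L,
             gc = vapply(starts, function(i)
               sum(chars[i:(i + window - 1L)] %in% c("G", "C")) / window,
               numeric(1)))
}

# smallest-period repeat decomposition by scanning every period length
brute_force_unit <- function(labels) {
  n <- length(labels)
  p <- n
  for (q in seq_len(n))
    if (all(labels[seq_len(n - q)] == labels[seq_len(n - q) + q])) {
      p <- q; break
    }
  if (n %% p == 0L) list(unit_len = p, repeats = n %/% p)
  else list(unit_len = n, repeats = 1L)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# minimal one-species spec used by several tests
small_spec <- function(seed = 11L, arrays = list(), scale = 0.3,
                       scaffolds = c(2e5)) {
  synthetic_spec(seed,
                 species_spec("Tst", scaffold_lengths = scaffolds,
                              anticodon_counts =
                                default_anticodon_counts(scale)),
                 arrays = arrays)
}
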