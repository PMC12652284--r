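# Tandem duplication detection: genes on the same scaffold separated by
# an inter-gene gap below a threshold (default: strictly less than
# 1 kb) are candidate tandem duplicates. Pairs are classified by exact
# sequence identity or alignment identity, chained into clusters as
# connected components, and each cluster's ordered (isotype, anticodon)
# label string is decomposed into its smallest exact repeat unit.

.pair_cols <- function() {
  data.frame(species = character(0), seq_id = character(0),
             gene_a = character(0), gene_b = character(0),
             gap_bp = integer(0), stringsAsFactors = FALSE)
}

.as_genes <- function(x) {
  if (inherits(x, "trna_annotation")) x$genes else x
}

#' Find proximal gene pairs on the same scaffold
#'
#' Emits every pair of genes sharing (species, seq_id) whose inter-gene
#' gap is strictly below \code{max_gap} bp, by a sorted sweep. All
#' qualifying pairs are emitted, not only rank-adjacent ones; strand is
#' ignored. The gap is \code{start(b) - end(a) - 1} for the downstream
#' gene b (clamped to 0 for overlapping genes); \code{distance =
#' "start"} instead measures start-to-start.
#'
#' @param annot \code{trna_annotation} or gene record data.frame (a
#'   warning is issued and the table re-sorted if unsorted).
#' @param max_gap Strict upper bound on the distance (bp).
#' @param distance \code{"gap"} (inter-gene gap, default) or
#'   \code{"start"} (start-to-start).
#' @return Data.frame with columns \code{species}, \code{seq_id},
#'   \code{gene_a} (upstream), \code{gene_b}, \code{gap_bp}.
#' @export
proximal_pairs <- function(annot, max_gap = 1000L,
                           distance = c("gap", "start")) {
  distance <- match.arg(distance)
  genes <- .as_genes(annot)
  if (nrow(genes) < 2L) return(.pair_cols())
  o <- order(genes$species, genes$seq_id, genes$start, genes$end,
             genes$gene_id)
  if (is.unsorted(o)) {
    if (!inherits(annot, "trna_annotation"))
      warning("gene table not sorted by (species, seq_id, start); ",
              "re-sorting", call. = FALSE)
    genes <- genes[o, , drop = FALSE]
  }
  res <- lapply(split(genes, paste(genes$species, genes$seq_id, sep = "\r")),
                function(g) {
    n <- nrow(g)
    if (n < 2L) return(NULL)
    out <- vector("list", n)
    for (i in seq_len(n - 1L)) {
      js <- integer(0); gaps <- integer(0)
      for (j in seq.int(i + 1L, n)) {
        d <- if (distance == "gap") g$start[j] - g$end[i] - 1L
             else g$start[j] - g$start[i]
        if (d >= max_gap) break  # starts are sorted: later j only grow
        js <- c(js, j); gaps <- c(gaps, max(d, 0L))
      }
      if (length(js))
        out[[i]] <- data.frame(species = g$species[i],
                               seq_id = g$seq_id[i],
                               gene_a = g$gene_id[i],
                               gene_b = g$gene_id[js],
                               gap_bp = gaps,
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) return(.pair_cols())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify proximal pairs by sequence identity and decoding
#'
#' Adds to each pair: \code{identical} (byte equality of the
#' coding-strand genomic sequences, introns included),
#' \code{identity_pct} (100 for identical pairs, otherwise global
#' alignment identity), \code{same_anticodon} and
#' \code{same_amino_acid} (from anticodon decoding with the SeC flag).
#' The summary fraction of identical pairs is available via
#' \code{\link{pair_summary}}.
#'
#' @param pairs Output of \code{\link{proximal_pairs}}.
#' @param annot Annotation (or gene table) supplying sequences and
#'   labels.
#' @param spliced Compare mature (intron-spliced) sequences instead of
#'   full genomic sequences.
#' @param params \code{\link{scoring_params}} for non-identical pairs.
#' @return The pair table with classification columns appended.
#' @export
classify_pairs <- function(pairs, annot, spliced = FALSE,
                           params = scoring_params()) {
  genes <- .as_genes(annot)
  m_a <- match(pairs$gene_a, genes$gene_id)
  m_b <- match(pairs$gene_b, genes$gene_id)
  if (anyNA(m_a) || anyNA(m_b))
    stop("missing gene record for a paired gene", call. = FALSE)
  seqs <- if (spliced) splice_introns(genes) else
    stats::setNames(genes$genomic_seq, genes$gene_id)
  sa <- toupper(unname(seqs[m_a])); sb <- toupper(unname(seqs[m_b]))
  if (anyNA(sa) || anyNA(sb) || any(!nzchar(sa)) || any(!nzchar(sb)))
    stop("missing sequence for a paired gene", call. = FALSE)
  pairs$identical <- sa == sb
  pairs$identity_pct <- ifelse(pairs$identical, 100, NA_real_)
  todo <- which(!pairs$identical)
  if (length(todo))
    pairs$identity_pct[todo] <- vapply(todo, function(i)
      global_align(sa[i], sb[i], params)$identity_pct, numeric(1))
  ac_a <- genes$anticodon[m_a]; ac_b <- genes$anticodon[m_b]
  pairs$anticodon_a <- ac_a; pairs$anticodon_b <- ac_b
  pairs$same_anticodon <- ac_a == ac_b
  dec <- function(ac) ifelse(ac %in% ANTICODONS,
                             anticodon_to_amino_acid(
                               ifelse(ac %in% ANTICODONS, ac, "AAA"),
                               sec = TRUE), NA_character_)
  aa_a <- dec(ac_a); aa_b <- dec(ac_b)
  pairs$amino_acid_a <- aa_a; pairs$amino_acid_b <- aa_b
  pairs$same_amino_acid <- !is.na(aa_a) & !is.na(aa_b) & aa_a == aa_b
  pairs
}

#' Summary counts of a classified pair set
#'
#' @param pairs Output of \code{\link{classify_pairs}}.
#' @return List with \code{n_pairs}, \code{n_identical},
#'   \code{n_divergent}, \code{fraction_identical} (percent) and the
#'   identity range of the divergent pairs.
#' @export
pair_summary <- function(pairs) {
  n <- nrow(pairs)
  ni <- sum(pairs$identical)
  div <- pairs$identity_pct[!pairs$identical]
  list(n_pairs = n, n_identical = ni, n_divergent = n - ni,
       fraction_identical = if (n > 0) 100 * ni / n else NA_real_,
       divergent_identity_range = if (length(div)) range(div)
                                  else c(NA_real_, NA_real_))
}

#' Chain pairs into tandem clusters
#'
#' Clusters are connected components of the pair graph, optionally
#' restricted to the identical-pair subgraph (\code{mode =
#' "identical"}); the two modes mirror the separate analyses of fully
#' identical arrays and of all proximal arrays. Each cluster records its
#' ordered (isotype, anticodon) label string and its smallest exact
#' repeat-unit decomposition.
#'
#' @param pairs Classified pairs (\code{mode = "identical"} requires the
#'   \code{identical} column).
#' @param annot Annotation or gene table.
#' @param mode \code{"all"} or \code{"identical"}.
#' @return Data.frame of class \code{tandem_clusters}; one row per
#'   cluster with columns \code{cluster_id}, \code{species},
#'   \code{seq_id}, \code{start}, \code{end}, \code{n_genes},
#'   \code{identity_class} (\code{"all-identical"} or
#'   \code{"divergent"}), \code{label_string}, \code{unit},
#'   \code{unit_len}, \code{repeats}, \code{anticodon_summary},
#'   \code{gene_ids}.
#' @export
chain_clusters <- function(pairs, annot, mode = c("all", "identical")) {
  mode <- match.arg(mode)
  genes <- .as_genes(annot)
  empty <- data.frame(cluster_id = character(0), species = character(0),
                      seq_id = character(0), start = integer(0),
                      end = integer(0), n_genes = integer(0),
                      identity_class = character(0),
                      label_string = character(0), unit = character(0),
                      unit_len = integer(0), repeats = integer(0),
                      anticodon_summary = character(0),
                      gene_ids = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("tandem_clusters", "data.frame")
  if (mode == "identical") {
    if (is.null(pairs$identical))
      stop("mode = 'identical' needs classified pairs", call. = FALSE)
    pairs <- pairs[pairs$identical, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) return(empty)
  ids <- unique(c(pairs$gene_a, pairs$gene_b))
  gr <- igraph::graph_from_data_frame(pairs[c("gene_a", "gene_b")],
                                      directed = FALSE,
                                      vertices = data.frame(name = ids))
  comp <- igraph::components(gr)$membership
  rows <- lapply(split(names(comp), comp), function(mem) {
    g <- genes[match(mem, genes$gene_id), , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    labels <- paste(g$isotype, g$anticodon, sep = "_")
    dec <- unit_decomposition(labels)
    acs <- table(g$anticodon)
    data.frame(species = g$species[1L], seq_id = g$seq_id[1L],
               start = min(g$start), end = max(g$end),
               n_genes = nrow(g),
               identity_class = if (length(unique(g$genomic_seq)) == 1L)
                 "all-identical" else "divergent",
               label_string = paste(labels, collapse = ","),
               unit = paste(dec$unit, collapse = ","),
               unit_len = dec$unit_len, repeats = dec$repeats,
               anticodon_summary = paste(names(acs), as.integer(acs),
                                         sep = ":", collapse = ","),
               gene_ids = paste(g$gene_id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$seq_id, out$start), , drop = FALSE]
  out <- data.frame(cluster_id = sprintf("TC%04d", seq_len(nrow(out))),
                    out, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("tandem_clusters", "data.frame")
  out
}

#' Smallest exact repeat unit of a label string
#'
#' Computes the smallest period p of the label vector from the KMP
#' border (failure) array. If p divides the length, the string is an
#' exact repetition of its first p labels; otherwise the whole string is
#' its own unit. The longest exactly periodic prefix under the smallest
#' period is also reported (informative for ragged arrays).
#'
#' @param labels Non-empty character vector (labels compared as whole
#'   strings, e.g. \code{"Tyr_GTA"}).
#' @return List with \code{unit} (character vector), \code{unit_len},
#'   \code{repeats}, and \code{prefix_repeats} (repeats of the smallest
#'   period within the longest periodic prefix).
#' @export
unit_decomposition <- function(labels) {
  n <- length(labels)
  if (n == 0L) stop("empty label string", call. = FALSE)
  border <- integer(n)
  k <- 0L
  for (i in seq_len(n)[-1L]) {
    while (k > 0L && labels[i] != labels[k + 1L]) k <- border[k]
    if (labels[i] == labels[k + 1L]) k <- k + 1L
    border[i] <- k
  }
  p <- n - border[n]
  prefix_ok <- n
  while (prefix_ok > 0L &&
         !identical(labels[seq_len(prefix_ok)],
                    rep_len(labels[seq_len(min(p, prefix_ok))], prefix_ok)))
    prefix_ok <- prefix_ok - 1L
  if (n %% p == 0L)
    list(unit = labels[seq_len(p)], unit_len = p, repeats = n %/% p,
         prefix_repeats = n %/% p)
  else
    list(unit = labels, unit_len = n, repeats = 1L,
         prefix_repeats = prefix_ok %/% p)
}

#' Pairs decoding the same amino acid through different anticodons
#'
#' Filters classified pairs to those whose two genes decode the same
#' amino acid but carry different (degenerate) anticodons, and
#' tabulates them by amino acid and species with per-amino-acid identity
#' ranges.
#'
#' @param pairs Output of \code{\link{classify_pairs}}.
#' @return List with \code{pairs} (the filtered table),
#'   \code{by_amino_acid} (data.frame amino_acid, n_pairs, n_species,
#'   min_identity, max_identity) and \code{by_species}.
#' @export
degenerate_anticodon_pairs <- function(pairs) {
  keep <- pairs$same_amino_acid & !pairs$same_anticodon
  sel <- pairs[keep, , drop = FALSE]
  by_aa <- if (nrow(sel)) do.call(rbind, lapply(
    split(sel, sel$amino_acid_a), function(d)
      data.frame(amino_acid = d$amino_acid_a[1L], n_pairs = nrow(d),
                 n_species = length(unique(d$species)),
                 min_identity = min(d$identity_pct),
                 max_identity = max(d$identity_pct),
                 stringsAsFactors = FALSE)))
  else data.frame(amino_acid = character(0), n_pairs = integer(0),
                  n_species = integer(0), min_identity = numeric(0),
                  max_identity = numeric(0), stringsAsFactors = FALSE)
  rownames(by_aa) <- NULL
  by_sp <- table(sel$species)
  list(pairs = sel, by_amino_acid = by_aa,
       by_species = data.frame(species = names(by_sp),
                               n_pairs = as.integer(by_sp),
                               stringsAsFactors = FALSE))
}
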