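# Seeded generator of multi-species tRNA annotation fixtures. The
# fixtures carry the statistical structure the downstream analysis
# assumes: genomic gene lengths confined to 62-98 bp with peaks at 72
# and 82 bp, intron-containing genes dominated by Met-CAT / Tyr-GTA
# with intron lengths peaked near 12 bp, cloverleaf-schematic sequences
# with GC-rich stems and GC-poor loops, per-species anticodon abundance
# over the 64-anticodon space, and planted tandem arrays (identical or
# diverged) with configurable intra-array gaps. A single RNG stream
# seeded from the synthetic_spec makes every fixture bit-reproducible.

# anticodons left absent in the default fixture: wobble-disfavoured
# A34 triplets, rarely used G34 family-box triplets, and one
# stop-pairing anticodon (14 amino acids + 1 stop)
.DEFAULT_ABSENT <- c("AAA", "ACA", "ACC", "ACT", "ATA", "ATC", "ATG",
                     "ATT", "GAT", "GCG", "GGC", "GAC", "GGT", "GGG",
                     "TTA")

#' Default per-anticodon gene counts for one synthetic species
#'
#' Deterministic counts over the 64-anticodon space: 49 anticodons are
#' present (15 absent: 14 decoding amino acids plus one stop-pairing),
#' with Asp-GTC, Gly-GCC, Met-CAT and Tyr-GTA the most abundant.
#'
#' @param scale Multiplier applied (and rounded) to the base counts.
#' @return Named integer vector over all 64 anticodons.
#' @export
default_anticodon_counts <- function(scale = 1) {
  counts <- stats::setNames(integer(64), ANTICODONS)
  if (scale <= 0) return(counts)
  present <- setdiff(ANTICODONS, .DEFAULT_ABSENT)
  counts[present] <- rep_len(c(1L, 2L, 3L), length(present))
  counts[c("GTC", "GCC", "CAT", "GTA")] <- c(8L, 6L, 6L, 5L)
  counts[present] <- pmax(1L, as.integer(round(counts[present] * scale)))
  counts
}

#' Per-species block of a synthetic fixture specification
#'
#' @param species Short species code.
#' @param scaffold_lengths Named integer vector of scaffold lengths
#'   (bp); names become seq_ids (defaults to
#'   \code{<species>_chr1..k}).
#' @param background_gc Background genomic GC fraction.
#' @param anticodon_counts Named counts over the 64-anticodon space (see
#'   \code{\link{default_anticodon_counts}}).
#' @param intron_prob Named numeric vector of per-gene intron
#'   probabilities: the \code{default} entry applies to every anticodon
#'   without its own entry. The default mirrors the dominance of
#'   Met-CAT and Tyr-GTA among intron-containing tRNA genes.
#' @param imet_fraction Fraction of CAT genes flagged as initiator Met.
#' @param gap_sampler Function(n) drawing background inter-gene gaps
#'   (bp); the default draws gaps of at least 1200 bp so background
#'   genes never enter tandem calls.
#' @return List of class \code{species_spec}.
#' @export
species_spec <- function(species,
                         scaffold_lengths = c(4e5, 4e5),
                         background_gc = 0.36,
                         anticodon_counts = default_anticodon_counts(),
                         intron_prob = c(default = 0.02, CAT = 0.5,
                                         GTA = 0.65),
                         imet_fraction = 0.3,
                         gap_sampler = function(n)
                           sample(1200:3500, n, replace = TRUE)) {
  scaffold_lengths <- as.integer(scaffold_lengths)
  if (is.null(names(scaffold_lengths)))
    names(scaffold_lengths) <- paste0(species, "_chr",
                                      seq_along(scaffold_lengths))
  stopifnot(all(anticodon_counts >= 0),
            all(names(anticodon_counts) %in% ANTICODONS),
            "default" %in% names(intron_prob))
  structure(list(species = species,
                 scaffold_lengths = scaffold_lengths,
                 background_gc = background_gc,
                 anticodon_counts = anticodon_counts,
                 intron_prob = intron_prob,
                 imet_fraction = imet_fraction,
                 gap_sampler = gap_sampler),
            class = "species_spec")
}

#' Specification of a planted tandem array
#'
#' @param species,seq_id Target scaffold.
#' @param anchor 1-based position of the first gene.
#' @param unit Data.frame with columns \code{isotype}, \code{anticodon}:
#'   the ordered repeat unit (length 1, 2, 3 or 5 unless
#'   \code{allowed_unit_len} is widened).
#' @param copies Number of unit repetitions.
#' @param intra_gap Gap (bp) between consecutive genes; must be < 1000
#'   for the array to be detectable as tandem.
#' @param divergence Number of substitutions applied to every copy after
#'   the first (never inside the anticodon triplet); 0 = identical
#'   copies.
#' @param allowed_unit_len Permitted unit lengths.
#' @return List of class \code{array_spec}.
#' @export
array_spec <- function(species, seq_id, anchor, unit, copies,
                       intra_gap = 200L, divergence = 0L,
                       allowed_unit_len = c(1L, 2L, 3L, 5L)) {
  stopifnot(is.data.frame(unit),
            all(c("isotype", "anticodon") %in% names(unit)),
            nrow(unit) %in% allowed_unit_len,
            copies >= 1L, intra_gap >= 0L, divergence >= 0L)
  structure(list(species = species, seq_id = seq_id,
                 anchor = as.integer(anchor), unit = unit,
                 copies = as.integer(copies),
                 intra_gap = as.integer(intra_gap),
                 divergence = as.integer(divergence)),
            class = "array_spec")
}

#' Repeat unit from compact labels
#'
#' @param labels Character vector like \code{c("Tyr_GTA", "Ser_GCT")}.
#' @return Data.frame with columns \code{isotype}, \code{anticodon}.
#' @export
unit_labels <- function(labels) {
  parts <- strsplit(labels, "_", fixed = TRUE)
  data.frame(isotype = vapply(parts, `[`, character(1), 1L),
             anticodon = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Full specification of a synthetic fixture
#'
#' @param seed Integer seed; fully determines the fixture.
#' @param species_specs List of \code{\link{species_spec}} blocks.
#' @param arrays List of \code{\link{array_spec}} planted arrays.
#' @param max_gene_span Cap on the annotated genomic span (bp); intron
#'   lengths are truncated so gene spans stay within the observed 62-98
#'   bp envelope. Set to \code{Inf} to allow the full 3-261 bp intron
#'   range regardless of span.
#' @return List of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(seed, species_specs, arrays = list(),
                           max_gene_span = 98L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (inherits(species_specs, "species_spec"))
    species_specs <- list(species_specs)
  if (inherits(arrays, "array_spec")) arrays <- list(arrays)
  sp <- vapply(species_specs, `[[`, character(1), "species")
  if (anyDuplicated(sp)) stop("duplicate species codes", call. = FALSE)
  for (a in arrays)
    if (!a$species %in% sp)
      stop("array for unknown species: ", a$species, call. = FALSE)
  structure(list(seed = as.integer(seed), species_specs = species_specs,
                 arrays = arrays, max_gene_span = max_gene_span),
            class = "synthetic_spec")
}

#' Default three-species fixture specification
#'
#' Three species at different gene-count scales, one identical
#' five-copy Pro array and one diverged two-isotype array.
#'
#' @param seed Integer seed.
#' @return \code{\link{synthetic_spec}}.
#' @export
default_synthetic_spec <- function(seed = 1L) {
  synthetic_spec(
    seed = seed,
    species_specs = list(
      species_spec("Ath",
                   anticodon_counts = default_anticodon_counts(2),
                   background_gc = 0.36),
      species_spec("Cpu",
                   anticodon_counts = default_anticodon_counts(1.5),
                   background_gc = 0.40),
      species_spec("Osa", scaffold_lengths = c(4e5),
                   anticodon_counts = default_anticodon_counts(1),
                   background_gc = 0.44)),
    arrays = list(
      array_spec("Ath", "Ath_chr1", anchor = 5000L,
                 unit = unit_labels("Pro_TGG"), copies = 5L,
                 intra_gap = 200L, divergence = 0L),
      array_spec("Cpu", "Cpu_chr2", anchor = 5000L,
                 unit = unit_labels(c("Ala_TGC", "Leu_CAG")),
                 copies = 4L, intra_gap = 150L, divergence = 2L)))
}

# positions drawn GC-rich in a length-L cloverleaf schematic: acceptor
# stem, D stem, anticodon stem anchored at the 5' end; T stem and the
# 3' acceptor strand anchored at the 3' end. The anticodon triplet
# (mature positions 34-36) is never part of a stem.
.stem_mask <- function(L) {
  pos <- unique(c(1:7, 10:13, 22:25, 27:31, 39:43,
                  (L - 22):(L - 18), (L - 14):(L - 10), (L - 6):L))
  setdiff(pos[pos >= 1 & pos <= L], 34:36)
}

#' Generate a cloverleaf-schematic tRNA gene sequence
#'
#' Draws a sequence whose stem segments (acceptor, D, anticodon and T
#' stems) are GC-rich and whose loops are GC-poor, with the literal
#' anticodon placed at the canonical mature positions 34-36. The result
#' is deterministic given the R RNG state.
#'
#' @param isotype Isotype label (recorded by callers; not used in the
#'   sequence draw).
#' @param anticodon DNA 3-mer placed at positions 34-36.
#' @param length Mature length in bp, between 62 and 98.
#' @param gc_stem,gc_loop Target GC fraction of stem/loop positions.
#' @return DNA string of the requested length.
#' @export
generate_trna_sequence <- function(isotype, anticodon, length,
                                   gc_stem = 0.8, gc_loop = 0.25) {
  if (length < 62L || length > 98L)
    stop("tRNA gene length out of range [62, 98]: ", length,
         call. = FALSE)
  anticodon <- toupper(anticodon)
  stopifnot(nchar(anticodon) == 3L)
  .check_alphabet(anticodon, "ACGT", "anticodon")
  stems <- .stem_mask(length)
  p <- rep(gc_loop, length)
  p[stems] <- gc_stem
  gc <- stats::runif(length) < p
  base <- ifelse(gc, sample(c("G", "C"), length, replace = TRUE),
                 sample(c("A", "T"), length, replace = TRUE))
  base[34:36] <- strsplit(anticodon, "", fixed = TRUE)[[1]]
  paste(base, collapse = "")
}

# draw a mature gene length: bimodal over 62-92 with peaks at 72/82
.sample_gene_length <- function(n) {
  lens <- 62:92
  w <- 0.25 + 3 * exp(-(lens - 72)^2 / 2) + 2.2 * exp(-(lens - 82)^2 / 2)
  sample(lens, n, replace = TRUE, prob = w)
}

# intron length: discretised lognormal, mode near 12 bp, range 3-261
.sample_intron_length <- function(n) {
  pmin(pmax(round(stats::rlnorm(n, log(12), 0.45)), 3L), 261L)
}

# insert an intron immediately 3' of the anticodon (after mature
# position 36); returns the genomic sequence and the gene-relative span
.insert_intron <- function(seq, ilen, gc = 0.25) {
  intron <- paste(ifelse(stats::runif(ilen) < gc,
                         sample(c("G", "C"), ilen, replace = TRUE),
                         sample(c("A", "T"), ilen, replace = TRUE)),
                  collapse = "")
  list(seq = paste0(substr(seq, 1L, 36L), intron,
                    substr(seq, 37L, nchar(seq))),
       span = intron_spans(37L, 36L + ilen))
}

# apply exactly d substitutions, never inside the anticodon triplet
.mutate_sequence <- function(seq, d) {
  if (d == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cand <- setdiff(seq_along(chars), 34:36)
  pos <- sample(cand, d)
  for (i in pos)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

# ---- fixture assembly ------------------------------------------------

.new_draft <- function(sp_spec) {
  scafs <- lapply(names(sp_spec$scaffold_lengths), function(id) {
    L <- sp_spec$scaffold_lengths[[id]]
    gc <- sp_spec$background_gc
    sample(c("A", "C", "G", "T"), L, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  names(scafs) <- names(sp_spec$scaffold_lengths)
  list(spec = sp_spec, scaffolds = scafs,
       occupied = stats::setNames(
         rep(list(data.frame(start = integer(0), end = integer(0))),
             length(scafs)), names(scafs)),
       genes = list())
}

.write_gene <- function(draft, seq_id, start, seq, strand) {
  chars <- strsplit(if (strand == "+") seq else reverse_complement(seq),
                    "", fixed = TRUE)[[1]]
  end <- start + length(chars) - 1L
  draft$scaffolds[[seq_id]][start:end] <- chars
  draft
}

#' Plant a tandem array into a fixture draft
#'
#' Writes \code{copies * nrow(unit)} genes at increasing coordinates
#' separated by \code{intra_gap} bp. With divergence 0 all copies of a
#' unit slot are byte-identical; with divergence d > 0 every copy after
#' the first receives exactly d substitutions, never inside the
#' anticodon triplet. Array genes are intron-free and on the plus
#' strand.
#'
#' @param draft Internal fixture draft (one species).
#' @param aspec \code{\link{array_spec}}.
#' @return Updated draft; the planted gene entries carry
#'   \code{array = TRUE}.
#' @keywords internal
.plant_array <- function(draft, aspec) {
  seq_id <- aspec$seq_id
  if (is.null(draft$scaffolds[[seq_id]]))
    stop("array scaffold not in species spec: ", seq_id, call. = FALSE)
  L_scaf <- length(draft$scaffolds[[seq_id]])
  k <- nrow(aspec$unit)
  slot_len <- .sample_gene_length(k)
  slot_seq <- vapply(seq_len(k), function(s)
    generate_trna_sequence(aspec$unit$isotype[s],
                           aspec$unit$anticodon[s], slot_len[s]),
    character(1))
  pos <- aspec$anchor
  occ <- draft$occupied[[seq_id]]
  for (cp in seq_len(aspec$copies)) {
    for (s in seq_len(k)) {
      seq <- if (cp == 1L) slot_seq[s]
             else .mutate_sequence(slot_seq[s], aspec$divergence)
      end <- pos + slot_len[s] - 1L
      if (end > L_scaf)
        stop("array exceeds scaffold capacity on ", seq_id,
             call. = FALSE)
      if (nrow(occ) && any(pos <= occ$end & end >= occ$start))
        stop("array overlaps previously placed genes on ", seq_id,
             call. = FALSE)
      draft <- .write_gene(draft, seq_id, pos, seq, "+")
      draft$genes[[length(draft$genes) + 1L]] <- list(
        seq_id = seq_id, start = pos, end = end, strand = "+",
        isotype = aspec$unit$isotype[s],
        anticodon = aspec$unit$anticodon[s],
        seq = seq, introns = empty_introns(), array = TRUE)
      occ <- rbind(occ, data.frame(start = pos, end = end))
      pos <- end + 1L + aspec$intra_gap
    }
  }
  draft$occupied[[seq_id]] <- occ[order(occ$start), , drop = FALSE]
  draft
}

.place_background <- function(draft, max_gene_span) {
  sp <- draft$spec
  counts <- sp$anticodon_counts[sp$anticodon_counts > 0L]
  queue <- sample(rep(names(counts), counts))
  if (length(queue) == 0L) return(draft)
  imet_left <- round(sum(queue == "CAT") * sp$imet_fraction)
  scaf_ids <- names(draft$scaffolds)
  si <- 1L
  cursor <- sp$gap_sampler(1L) + 1L
  for (ac in queue) {
    m <- .sample_gene_length(1L)
    iso <- anticodon_to_amino_acid(ac, sec = TRUE)
    if (iso == "stop-pairing") iso <- "Und"
    if (ac == "CAT" && imet_left > 0L) { iso <- "iMet"
                                         imet_left <- imet_left - 1L }
    seq <- generate_trna_sequence(iso, ac, m)
    introns <- empty_introns()
    p_int <- if (ac %in% names(sp$intron_prob)) sp$intron_prob[[ac]]
             else sp$intron_prob[["default"]]
    if (stats::runif(1L) < p_int) {
      ilen <- .sample_intron_length(1L)
      ilen <- min(ilen, max_gene_span - m)
      if (ilen >= 3L) {
        ins <- .insert_intron(seq, ilen)
        seq <- ins$seq; introns <- ins$span
      }
    }
    glen <- nchar(seq)
    strand <- sample(c("+", "-"), 1L)
    placed <- FALSE
    while (!placed) {
      if (si > length(scaf_ids))
        stop("scaffold capacity exhausted for species ", sp$species,
             call. = FALSE)
      seq_id <- scaf_ids[si]
      end <- cursor + glen - 1L
      occ <- draft$occupied[[seq_id]]
      hit <- if (nrow(occ))
        which(cursor < occ$end + 1001L & end > occ$start - 1001L)
      else integer(0)
      if (length(hit)) { cursor <- max(occ$end[hit]) + 1001L; next }
      if (end > length(draft$scaffolds[[seq_id]])) {
        si <- si + 1L
        cursor <- sp$gap_sampler(1L) + 1L
        next
      }
      draft <- .write_gene(draft, seq_id, cursor, seq, strand)
      draft$genes[[length(draft$genes) + 1L]] <- list(
        seq_id = seq_id, start = cursor, end = end, strand = strand,
        isotype = iso, anticodon = ac, seq = seq, introns = introns,
        array = FALSE)
      cursor <- end + 1L + sp$gap_sampler(1L)
      placed <- TRUE
    }
  }
  draft
}

#' Generate a synthetic multi-species tRNA fixture
#'
#' Builds, from a \code{\link{synthetic_spec}}, the genome scaffolds,
#' the gene annotation and a truth table of every planted array.
#' Identical seeds give byte-identical output.
#'
#' @param spec \code{\link{synthetic_spec}}.
#' @return List of class \code{trna_fixture}: \code{annotation}
#'   (\code{\link{trna_annotation}}), \code{genome} (named character
#'   vector of scaffolds), \code{truth} (data.frame of planted arrays
#'   with gene ids, spans, unit, copies, divergence) and \code{spec}.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  genome <- character(0)
  all_genes <- list()
  truth_rows <- list()
  for (sp_spec in spec$species_specs) {
    draft <- .new_draft(sp_spec)
    sp_arrays <- Filter(function(a) a$species == sp_spec$species,
                        spec$arrays)
    for (a in sp_arrays) {
      n_before <- length(draft$genes)
      draft <- .plant_array(draft, a)
      idx <- seq.int(n_before + 1L, length(draft$genes))
      truth_rows[[length(truth_rows) + 1L]] <- list(
        species = sp_spec$species, seq_id = a$seq_id,
        unit = paste(a$unit$isotype, a$unit$anticodon, sep = "_",
                     collapse = ","),
        unit_len = nrow(a$unit), copies = a$copies,
        n_genes = length(idx), intra_gap = a$intra_gap,
        divergence = a$divergence,
        start = draft$genes[[idx[1L]]]$start,
        end = draft$genes[[idx[length(idx)]]]$end,
        gene_idx = idx + length(all_genes))
    }
    draft <- .place_background(draft, spec$max_gene_span)
    genome <- c(genome,
                vapply(draft$scaffolds, paste, character(1),
                       collapse = ""))
    all_genes <- c(all_genes,
                   lapply(draft$genes, function(g)
                     c(g, list(species = sp_spec$species))))
  }
  n <- length(all_genes)
  if (n == 0L) {
    genes <- trna_genes(character(0), character(0), character(0),
                        integer(0), integer(0), character(0),
                        character(0), character(0), character(0))
  } else {
    g <- function(f, how) vapply(all_genes, function(x) x[[f]], how)
    ord <- order(g("species", character(1)), g("seq_id", character(1)),
                 g("start", integer(1)))
    rank_of <- match(seq_len(n), ord)
    key <- paste(g("species", character(1)),
                 g("seq_id", character(1)))[ord]
    num <- stats::ave(seq_len(n), key, FUN = seq_along)
    ids_sorted <- paste0(g("species", character(1))[ord], ".",
                         g("seq_id", character(1))[ord], ".trna", num)
    ids <- ids_sorted[rank_of]
    genes <- trna_genes(
      gene_id = ids,
      species = g("species", character(1)),
      seq_id = g("seq_id", character(1)),
      start = g("start", integer(1)), end = g("end", integer(1)),
      strand = g("strand", character(1)),
      isotype = g("isotype", character(1)),
      anticodon = g("anticodon", character(1)),
      genomic_seq = g("seq", character(1)),
      introns = lapply(all_genes, `[[`, "introns"),
      score = round(stats::runif(n, 40, 95), 1))
    truth_rows <- lapply(truth_rows, function(tr) {
      tr$gene_ids <- paste(ids[tr$gene_idx], collapse = ",")
      tr$gene_idx <- NULL
      tr
    })
  }
  assemblies <- do.call(rbind, lapply(spec$species_specs, function(s)
    data.frame(species = s$species, seq_id = names(s$scaffold_lengths),
               length = unname(s$scaffold_lengths),
               stringsAsFactors = FALSE)))
  truth <- if (length(truth_rows))
    do.call(rbind, lapply(truth_rows, function(tr)
      data.frame(tr, stringsAsFactors = FALSE)))
  else data.frame(species = character(0), seq_id = character(0),
                  unit = character(0), unit_len = integer(0),
                  copies = integer(0), n_genes = integer(0),
                  intra_gap = integer(0), divergence = integer(0),
                  start = integer(0), end = integer(0),
                  gene_ids = character(0), stringsAsFactors = FALSE)
  if (length(truth_rows))
    truth <- data.frame(array_id = sprintf("AR%03d",
                                           seq_len(nrow(truth))),
                        truth, stringsAsFactors = FALSE)
  structure(list(annotation = trna_annotation(
                   genes, assemblies,
                   provenance = list(source = "synthetic",
                                     seed = spec$seed)),
                 genome = genome, truth = truth, spec = spec),
            class = "trna_fixture")
}

#' @export
print.trna_fixture <- function(x, ...) {
  cat("synthetic trna_fixture (seed ", x$spec$seed, "): ",
      nrow(x$annotation$genes), " genes, ",
      nrow(x$truth), " planted arrays\n", sep = "")
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits the genome FASTA, one tRNAscan-SE style table per species, and
#' a machine-readable JSON truth table of the planted arrays.
#'
#' @param fixture \code{trna_fixture}.
#' @param dir Output directory (created if needed).
#' @return Invisible named list of written paths.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir, call. = FALSE)
  fa <- file.path(dir, "genome.fasta")
  write_fasta(fixture$genome, fa)
  genes <- fixture$annotation$genes
  tabs <- character(0)
  for (sp in sort(unique(genes$species))) {
    p <- file.path(dir, paste0(sp, ".trnascan.tsv"))
    write_trnascan_table(genes[genes$species == sp, , drop = FALSE], p)
    tabs <- c(tabs, p)
  }
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(fixture$truth, tj, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  aj <- file.path(dir, "assemblies.tsv")
  write_tsv(fixture$annotation$assemblies, aj)
  invisible(list(genome = fa, tables = tabs, truth = tj,
                 assemblies = aj))
}

#' Read a written fixture back as an annotation
#'
#' Round-trips the files produced by \code{\link{write_fixture}}
#' through the tRNAscan-SE and FASTA readers.
#'
#' @param dir Fixture directory.
#' @return \code{\link{trna_annotation}}.
#' @export
read_fixture <- function(dir) {
  genome <- read_fasta(file.path(dir, "genome.fasta"))
  asm <- utils::read.delim(file.path(dir, "assemblies.tsv"),
                           stringsAsFactors = FALSE)
  tabs <- sort(list.files(dir, pattern = "\\.trnascan\\.tsv$",
                          full.names = TRUE))
  annots <- lapply(tabs, function(p) {
    sp <- sub("\\.trnascan\\.tsv$", "", basename(p))
    read_trnascan_table(p, species = sp,
                        genome = genome[asm$seq_id[asm$species == sp]],
                        assemblies = asm[asm$species == sp, ,
                                         drop = FALSE])
  })
  genes <- do.call(rbind, lapply(annots, `[[`, "genes"))
  trna_annotation(genes, asm,
                  provenance = list(source = dir,
                                    dialect = "tRNAscan-SE v2"))
}
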