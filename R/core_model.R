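# Gene records are plain data.frames with one row per annotated tRNA
# gene and a list column of gene-relative intron spans. Coordinates are
# 1-based inclusive (tRNAscan-SE convention); minus-strand records are
# normalised so start <= end and genomic_seq is always the coding
# (gene) strand.

.GENE_COLS <- c("gene_id", "species", "seq_id", "start", "end", "strand",
                "isotype", "anticodon", "genomic_seq", "introns", "score")

#' Construct a table of tRNA gene records
#'
#' @param gene_id Unique gene identifiers.
#' @param species Short species codes (e.g. \code{"Ath"}, \code{"Cpu"}).
#' @param seq_id Chromosome/scaffold names.
#' @param start,end 1-based inclusive genomic coordinates, end >= start.
#' @param strand \code{"+"} or \code{"-"}.
#' @param isotype Amino-acid label (one of \code{\link{ISOTYPES}}).
#' @param anticodon Uppercase DNA 3-mer, or \code{"NNN"} when
#'   undetermined.
#' @param genomic_seq Coding-strand DNA including introns; length must
#'   equal \code{end - start + 1}.
#' @param introns List of two-column data.frames (\code{start},
#'   \code{end}) of gene-relative 1-based inclusive intron spans, sorted
#'   and non-overlapping. \code{NULL} spans mean no introns.
#' @param score Optional covariance-model score (bits).
#' @return A validated data.frame of gene records.
#' @export
trna_genes <- function(gene_id, species, seq_id, start, end, strand = "+",
                       isotype, anticodon, genomic_seq,
                       introns = NULL, score = NA_real_) {
  n <- length(gene_id)
  if (is.null(introns)) introns <- rep(list(empty_introns()), n)
  if (is.data.frame(introns)) introns <- list(introns)
  g <- data.frame(gene_id = as.character(gene_id),
                  species = rep_len(as.character(species), n),
                  seq_id = rep_len(as.character(seq_id), n),
                  start = as.integer(start), end = as.integer(end),
                  strand = rep_len(as.character(strand), n),
                  isotype = rep_len(as.character(isotype), n),
                  anticodon = rep_len(toupper(anticodon), n),
                  genomic_seq = as.character(genomic_seq),
                  score = rep_len(as.numeric(score), n),
                  stringsAsFactors = FALSE)
  g$genomic_seq <- toupper(g$genomic_seq)
  g$introns <- introns
  validate_genes(g[.GENE_COLS])
}

#' An empty intron span table
#' @return Zero-row data.frame with columns \code{start}, \code{end}.
#' @export
empty_introns <- function() {
  data.frame(start = integer(0), end = integer(0))
}

#' Intron spans from parallel vectors
#' @param start,end Gene-relative 1-based inclusive bounds.
#' @export
intron_spans <- function(start, end) {
  data.frame(start = as.integer(start), end = as.integer(end))
}

#' Validate a gene record table
#'
#' Checks the invariants of the gene data model: unique ids, end >=
#' start, sequence length equal to the coordinate span, anticodons in
#' the 64-anticodon space (or NNN), and intron spans sorted,
#' non-overlapping and inside the gene.
#'
#' @param genes Gene record data.frame.
#' @return The input, invisibly usable, after validation.
#' @export
validate_genes <- function(genes) {
  stopifnot(is.data.frame(genes), all(.GENE_COLS %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id values", call. = FALSE)
  if (any(genes$end < genes$start))
    stop("end < start in gene records", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  len <- genes$end - genes$start + 1L
  if (any(nchar(genes$genomic_seq) != len))
    stop("genomic_seq length must equal end - start + 1", call. = FALSE)
  ok_ac <- genes$anticodon %in% c(ANTICODONS, "NNN")
  if (!all(ok_ac))
    stop("anticodon outside the 64-anticodon space: ",
         paste(unique(genes$anticodon[!ok_ac]), collapse = ", "),
         call. = FALSE)
  if (!all(genes$isotype %in% ISOTYPES))
    stop("unknown isotype label: ",
         paste(setdiff(unique(genes$isotype), ISOTYPES), collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(genes))) {
    sp <- genes$introns[[i]]
    if (is.null(sp) || nrow(sp) == 0L) next
    if (any(sp$start > sp$end) || any(sp$start < 1L) || any(sp$end > len[i]))
      stop("intron span outside gene for ", genes$gene_id[i], call. = FALSE)
    if (is.unsorted(sp$start, strictly = TRUE) ||
        any(sp$start[-1L] <= sp$end[-nrow(sp)]))
      stop("intron spans must be sorted and non-overlapping for ",
           genes$gene_id[i], call. = FALSE)
  }
  genes
}

#' Number of introns per gene
#' @param genes Gene record data.frame.
#' @return Integer vector.
#' @export
n_introns <- function(genes) {
  vapply(genes$introns, function(sp) if (is.null(sp)) 0L else nrow(sp),
         integer(1))
}

#' Splice introns out of gene sequences
#'
#' Removes all annotated intron spans from the coding-strand genomic
#' sequence of each gene, yielding the mature (exonic) sequence. Length
#' is conservative: \code{nchar(mature) + sum(intron lengths) ==
#' nchar(genomic_seq)}.
#'
#' @param genes Gene record data.frame.
#' @return Character vector of mature sequences, named by gene_id.
#' @export
splice_introns <- function(genes) {
  out <- vapply(seq_len(nrow(genes)), function(i) {
    s <- genes$genomic_seq[i]
    sp <- genes$introns[[i]]
    if (is.null(sp) || nrow(sp) == 0L) return(s)
    if (any(sp$start < 1L) || any(sp$end > nchar(s)))
      stop("intron span outside gene for ", genes$gene_id[i],
           call. = FALSE)
    keep <- setdiff(seq_len(nchar(s)),
                    unlist(Map(seq.int, sp$start, sp$end)))
    paste(strsplit(s, "", fixed = TRUE)[[1]][keep], collapse = "")
  }, character(1))
  stats::setNames(out, genes$gene_id)
}

#' Drop undetermined/pseudogene records
#'
#' Statistics exclude \code{"Und"} isotypes and \code{"NNN"} anticodons
#' by default, mirroring analyses restricted to high-confidence gene
#' sets.
#'
#' @param genes Gene record data.frame.
#' @param include_und Keep Und/NNN records.
#' @return Filtered gene table.
#' @export
filter_high_confidence <- function(genes, include_und = FALSE) {
  if (include_und) return(genes)
  genes[genes$isotype != "Und" & genes$anticodon != "NNN", , drop = FALSE]
}

#' Bundle genes and assemblies into an annotation set
#'
#' @param genes Gene record data.frame; sorted by (species, seq_id,
#'   start, end, gene_id) on construction.
#' @param assemblies Data.frame with columns \code{species},
#'   \code{seq_id}, \code{length} giving per-scaffold assembly lengths.
#' @param provenance Optional list describing the source (file names,
#'   parser dialect).
#' @return An object of class \code{trna_annotation}.
#' @export
trna_annotation <- function(genes, assemblies = NULL, provenance = list()) {
  genes <- validate_genes(genes)
  o <- order(genes$species, genes$seq_id, genes$start, genes$end,
             genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  rownames(genes) <- NULL
  if (!is.null(assemblies)) {
    stopifnot(all(c("species", "seq_id", "length") %in% names(assemblies)))
    key <- paste(genes$species, genes$seq_id)
    akey <- paste(assemblies$species, assemblies$seq_id)
    m <- match(key, akey)
    if (anyNA(m))
      stop("gene on unknown scaffold: ",
           paste(unique(key[is.na(m)]), collapse = ", "), call. = FALSE)
    if (any(genes$end > assemblies$length[m]))
      stop("gene coordinates exceed scaffold length", call. = FALSE)
  }
  structure(list(genes = genes, assemblies = assemblies,
                 provenance = provenance),
            class = "trna_annotation")
}

#' @export
print.trna_annotation <- function(x, ...) {
  g <- x$genes
  cat("trna_annotation:", nrow(g), "genes,",
      length(unique(g$species)), "species,",
      length(unique(paste(g$species, g$seq_id))), "scaffolds\n")
  if (!is.null(x$assemblies)) {
    gs <- genome_sizes(x)
    cat("assembly sizes (bp):",
        paste(names(gs), format(gs, big.mark = ","), collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Per-species genome size of an annotation set
#' @param annot \code{trna_annotation}.
#' @return Named numeric vector (bp) or NULL when no assemblies.
#' @export
genome_sizes <- function(annot) {
  if (is.null(annot$assemblies)) return(NULL)
  gs <- tapply(annot$assemblies$length, annot$assemblies$species, sum)
  stats::setNames(as.numeric(gs), names(gs))
}
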