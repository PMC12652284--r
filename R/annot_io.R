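# Readers for tRNAscan-SE v2 tabular output and FASTA, and writers for
# the result tables (TSV, BED6, JSON). The tabular dialect is the ".out"
# format: three header lines, then columns
#   sequence name, tRNA #, begin, end, isotype, anticodon,
#   intron begin, intron end, score [, note]
# Minus-strand rows have begin > end and are normalised on input so
# start <= end and the stored sequence is the coding strand. Intron
# bounds of 0 mean no intron; multiple introns are supported as
# comma-separated bounds (tRNAscan-SE itself reports at most one).

.TRNASCAN_HEADER <- c(
  "Sequence\t\ttRNA\tBounds\t\ttRNA\tAnti\tIntron Bounds\tInf",
  "Name    \ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
  "--------\t------\t-----\t---\t----\t-----\t-----\t---\t-----")

#' Read a tRNAscan-SE v2 tabular file
#'
#' @param path Path to a tRNAscan-SE ".out" style file (3 header lines,
#'   tab-separated columns).
#' @param species Short species code attached to every record.
#' @param genome Optional named character vector of scaffold sequences
#'   (as from \code{\link{read_fasta}}); when supplied, coding-strand
#'   gene sequences are extracted (reverse-complemented for minus-strand
#'   genes). Without it, sequences must be provided later from a
#'   per-gene FASTA via \code{\link{attach_sequences}}.
#' @param assemblies Optional assembly table (species, seq_id, length);
#'   derived from \code{genome} when absent.
#' @return A \code{\link{trna_annotation}}.
#' @export
read_trnascan_table <- function(path, species, genome = NULL,
                                assemblies = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("not a tRNAscan-SE table (missing header): ", path,
         call. = FALSE)
  lines <- lines[-(1:3)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    genes <- trna_genes(character(0), character(0), character(0),
                        integer(0), integer(0), character(0),
                        character(0), character(0), character(0))
    return(trna_annotation(genes, assemblies,
                           provenance = list(file = path,
                                             dialect = "tRNAscan-SE v2")))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 9L))
    stop("malformed tRNAscan-SE row (fewer than 9 columns) in ", path,
         call. = FALSE)
  if (any(ncol > 10L))
    warning("ignoring unknown trailing columns in ", path, call. = FALSE)
  f <- function(i) trimws(vapply(fields, `[`, character(1), i))
  seq_id <- f(1); num <- f(2)
  begin <- as.integer(f(3)); end <- as.integer(f(4))
  isotype <- f(5); anticodon <- toupper(f(6))
  ib <- f(7); ie <- f(8); score <- as.numeric(f(9))
  note <- if (max(ncol) >= 10L)
    trimws(vapply(fields, function(x)
      if (length(x) >= 10L) x[10L] else "", character(1)))
  else rep("", length(fields))
  strand <- ifelse(begin <= end, "+", "-")
  start <- pmin(begin, end); stop_ <- pmax(begin, end)
  isotype[isotype == "Pseudo" | grepl("pseudo", note)] <- "Und"
  anticodon[anticodon == "???"] <- "NNN"
  n <- length(seq_id)
  introns <- vector("list", n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    ibs <- as.integer(strsplit(ib[i], ",", fixed = TRUE)[[1]])
    ies <- as.integer(strsplit(ie[i], ",", fixed = TRUE)[[1]])
    keep <- !(ibs == 0L & ies == 0L)
    ibs <- ibs[keep]; ies <- ies[keep]
    if (length(ibs)) {
      lo <- pmin(ibs, ies); hi <- pmax(ibs, ies)
      if (any(lo < start[i]) || any(hi > stop_[i]))
        stop("intron bounds outside gene at row ", i, call. = FALSE)
      # genome coordinates -> gene-relative coding-strand coordinates
      if (strand[i] == "+") { rs <- lo - start[i] + 1L
                              re <- hi - start[i] + 1L }
      else { rs <- stop_[i] - hi + 1L; re <- stop_[i] - lo + 1L }
      o <- order(rs)
      introns[[i]] <- intron_spans(rs[o], re[o])
    } else introns[[i]] <- empty_introns()
    if (!is.null(genome)) {
      gseq <- genome[[seq_id[i]]]
      if (is.null(gseq))
        stop("scaffold ", seq_id[i], " absent from genome FASTA",
             call. = FALSE)
      s <- toupper(substr(gseq, start[i], stop_[i]))
      seqs[i] <- if (strand[i] == "+") s else reverse_complement(s)
    } else seqs[i] <- strrep("N", stop_[i] - start[i] + 1L)
  }
  genes <- trna_genes(
    gene_id = paste0(species, ".", seq_id, ".trna", num),
    species = species, seq_id = seq_id, start = start, end = stop_,
    strand = strand, isotype = isotype, anticodon = anticodon,
    genomic_seq = seqs, introns = introns, score = score)
  if (is.null(assemblies) && !is.null(genome))
    assemblies <- data.frame(species = species, seq_id = names(genome),
                             length = nchar(genome),
                             stringsAsFactors = FALSE)
  trna_annotation(genes, assemblies,
                  provenance = list(file = path,
                                    dialect = "tRNAscan-SE v2",
                                    has_sequence = !is.null(genome)))
}

#' Write gene records as a tRNAscan-SE v2 style table
#'
#' Inverse of \code{\link{read_trnascan_table}}: minus-strand genes are
#' written with begin > end and intron bounds in genome coordinates.
#'
#' @param genes Gene record data.frame.
#' @param path Output path.
#' @export
write_trnascan_table <- function(genes, path) {
  rows <- vapply(seq_len(nrow(genes)), function(i) {
    plus <- genes$strand[i] == "+"
    b <- if (plus) genes$start[i] else genes$end[i]
    e <- if (plus) genes$end[i] else genes$start[i]
    sp <- genes$introns[[i]]
    if (is.null(sp) || nrow(sp) == 0L) { ib <- "0"; ie <- "0" }
    else {
      if (plus) { gb <- genes$start[i] + sp$start - 1L
                  ge <- genes$start[i] + sp$end - 1L }
      else { gb <- genes$end[i] - sp$start + 1L
             ge <- genes$end[i] - sp$end + 1L }
      ib <- paste(gb, collapse = ","); ie <- paste(ge, collapse = ",")
    }
    num <- sub(".*trna", "", genes$gene_id[i])
    paste(genes$seq_id[i], num, b, e, genes$isotype[i],
          genes$anticodon[i], ib, ie,
          formatC(genes$score[i], format = "f", digits = 1), sep = "\t")
  }, character(1))
  writeLines(c(.TRNASCAN_HEADER, rows), path)
}

#' Read a multi-FASTA file
#'
#' @param path FASTA path (gzip accepted). IDs are taken up to the first
#'   whitespace; sequences are uppercased.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) && any(!nzchar(names(x)) | is.na(names(x))))
    stop("FASTA record with empty id in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  if (any(Biostrings::width(x) == 0L))
    stop("empty FASTA record in ", path, call. = FALSE)
  stats::setNames(toupper(as.character(x)), ids)
}

#' Write a named character vector as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
}

.fmt_num <- function(x) {
  if (is.double(x)) ifelse(is.na(x), "NA",
                           formatC(x, format = "f", digits = 4))
  else as.character(x)
}

#' Write a data.frame as a reproducible TSV
#'
#' Fixed column order, floats printed with 4 decimals; byte-stable for
#' identical inputs.
#'
#' @param df Data.frame (list columns are comma-joined).
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(v)
        paste(unlist(v), collapse = ","), character(1))
    df[[j]] <- .fmt_num(df[[j]])
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}

#' Write tandem clusters as BED6
#'
#' 1-based inclusive cluster spans are converted to BED's 0-based
#' half-open convention (chromStart = start - 1, chromEnd = end), name =
#' cluster id, score = cluster size, strand ".".
#'
#' @param clusters \code{tandem_clusters} data.frame.
#' @param path Output path.
#' @export
write_clusters_bed <- function(clusters, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(clusters))
    writeLines(paste(clusters$seq_id, clusters$start - 1L, clusters$end,
                     clusters$cluster_id, clusters$n_genes, ".",
                     sep = "\t"), con)
  invisible(path)
}

#' Write a result bundle to a directory
#'
#' Emits the supplied tables as TSV (list columns comma-joined, floats
#' with 4 decimals), any \code{tandem_clusters} additionally as BED6,
#' and a JSON run summary with per-table row counts. Byte-stable given
#' identical inputs.
#'
#' @param tables Named list of data.frames/matrices.
#' @param out_dir Output directory (created if needed).
#' @param summary Optional named list merged into the JSON summary.
#' @return Invisible character vector of written paths.
#' @export
write_results <- function(tables, out_dir, summary = list()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character(0)
  counts <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.matrix(tab))
      tab <- data.frame(id = rownames(tab), as.data.frame.matrix(tab),
                        check.names = FALSE, stringsAsFactors = FALSE)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(tab, p)
    paths <- c(paths, p)
    counts[[nm]] <- nrow(tab)
    if (inherits(tables[[nm]], "tandem_clusters")) {
      pb <- file.path(out_dir, paste0(nm, ".bed"))
      write_clusters_bed(tables[[nm]], pb)
      paths <- c(paths, pb)
    }
  }
  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(c(list(row_counts = counts), summary), sj,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, sj)
  invisible(paths)
}

#' Attach per-gene sequences from a FASTA to an annotation
#'
#' @param annot \code{trna_annotation} parsed without a genome.
#' @param seqs Named character vector keyed by gene id.
#' @return Updated annotation.
#' @export
attach_sequences <- function(annot, seqs) {
  g <- annot$genes
  m <- match(g$gene_id, names(seqs))
  if (anyNA(m))
    stop("missing sequence for gene(s): ",
         paste(utils::head(g$gene_id[is.na(m)], 3L), collapse = ", "),
         call. = FALSE)
  g$genomic_seq <- toupper(unname(seqs[m]))
  trna_annotation(g, annot$assemblies, annot$provenance)
}
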