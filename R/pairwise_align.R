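#' Alignment scoring parameters
#'
#' Defaults follow the EMBOSS needle DNA parameterisation: match +5,
#' mismatch -4 (EDNAFULL style, N scores 0 against anything), gap open
#' 10, gap extension 0.5, end gaps free. A gap run of length k costs
#' \code{gap_open + (k - 1) * gap_extend}; terminal runs are free when
#' \code{end_gap_free}.
#'
#' @param match,mismatch Substitution scores for identical/different
#'   bases.
#' @param gap_open,gap_extend Affine gap penalties (positive costs);
#'   \code{gap_open >= gap_extend >= 0}.
#' @param end_gap_free Logical; do not penalise terminal gap runs.
#' @return A list of class \code{scoring_params}.
#' @export
scoring_params <- function(match = 5, mismatch = -4,
                           gap_open = 10, gap_extend = 0.5,
                           end_gap_free = TRUE) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 end_gap_free = end_gap_free),
            class = "scoring_params")
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Optimal global alignment under the Gotoh three-state recurrence with
#' affine gap costs and (by default) free end gaps, the parameterisation
#' of EMBOSS needle. Tie-breaking in the traceback is fixed (diagonal,
#' then up, then left) so output is deterministic. Identity is the
#' EMBOSS definition: identical columns over all alignment columns,
#' including gap columns. Coverage of each sequence is the fraction of
#' its residues inside the aligned core (columns between the first and
#' last column where both sequences have a residue).
#'
#' @param a,b Non-empty DNA strings over ACGTN (case-insensitive).
#' @param params \code{\link{scoring_params}}.
#' @return List of class \code{alignment_result} with elements
#'   \code{aligned_a}, \code{aligned_b}, \code{score},
#'   \code{identity_pct}, \code{coverage_a}, \code{coverage_b}.
#' @examples
#' global_align("ACGTACGTAC", "ACGAACGTAC")$identity_pct  # 90
#' @export
global_align <- function(a, b, params = scoring_params()) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("empty sequence", call. = FALSE)
  .check_alphabet(c(a, b), "ACGTN")
  al <- .gotoh_align(a, b, params$match, params$mismatch,
                     params$gap_open, params$gap_extend,
                     params$end_gap_free)
  ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  ncol_aln <- length(ca)
  ident <- sum(ca == cb & ca != "-")
  both <- which(ca != "-" & cb != "-")
  if (length(both)) {
    core <- seq(min(both), max(both))
    cov_a <- sum(ca[core] != "-") / nchar(a)
    cov_b <- sum(cb[core] != "-") / nchar(b)
  } else {
    cov_a <- cov_b <- 0
  }
  structure(list(aligned_a = al$aligned_a, aligned_b = al$aligned_b,
                 score = al$score,
                 identity_pct = 100 * ident / ncol_aln,
                 coverage_a = cov_a, coverage_b = cov_b),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %.1f, identity %.1f%%, coverage %.2f/%.2f\n",
              x$score, x$identity_pct, x$coverage_a, x$coverage_b))
  invisible(x)
}

#' Greedy centroid clustering by identity and coverage
#'
#' Deterministic greedy clustering in the style of MMseqs2/CD-HIT
#' thresholds: sequences are sorted by decreasing length then
#' lexicographically, and each sequence joins the first existing cluster
#' whose representative aligns to it with identity >= \code{min_id} and
#' bidirectional coverage >= \code{min_cov}; otherwise it founds a new
#' cluster with itself as representative. The defaults mirror
#' \code{--min-seq-id 0.9 -c 0.8}.
#'
#' @param seqs Named character vector of DNA sequences (names invented
#'   when absent).
#' @param min_id Minimum fractional identity to the representative.
#' @param min_cov Minimum of the two coverages.
#' @param params \code{\link{scoring_params}}.
#' @return Data.frame with columns \code{cluster} (integer, in founding
#'   order), \code{representative} (name), \code{name}, \code{seq},
#'   \code{identity_pct}, \code{coverage}.
#' @export
greedy_cluster <- function(seqs, min_id = 0.90, min_cov = 0.80,
                           params = scoring_params()) {
  if (length(seqs) == 0L) stop("at least one sequence required",
                               call. = FALSE)
  seqs <- toupper(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  o <- order(-nchar(seqs), seqs, names(seqs))
  seqs <- seqs[o]
  rep_idx <- integer(0)       # indices (into seqs) of representatives
  assign <- integer(length(seqs))
  id_pct <- numeric(length(seqs))
  cov <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(rep_idx)) {
      r <- rep_idx[k]
      if (seqs[i] == seqs[r]) {
        assign[i] <- k; id_pct[i] <- 100; cov[i] <- 1
        placed <- TRUE; break
      }
      # exact pruning: identical columns <= min length and alignment
      # columns >= max length bound identity by the length ratio
      la <- nchar(seqs[i]); lb <- nchar(seqs[r])
      if (min(la, lb) / max(la, lb) < min_id) next
      al <- global_align(seqs[i], seqs[r], params)
      cc <- min(al$coverage_a, al$coverage_b)
      if (al$identity_pct >= 100 * min_id && cc >= min_cov) {
        assign[i] <- k; id_pct[i] <- al$identity_pct; cov[i] <- cc
        placed <- TRUE; break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assign[i] <- length(rep_idx); id_pct[i] <- 100; cov[i] <- 1
    }
  }
  data.frame(cluster = assign,
             representative = names(seqs)[rep_idx][assign],
             name = names(seqs), seq = unname(seqs),
             identity_pct = id_pct, coverage = cov,
             stringsAsFactors = FALSE)
}

#' Deduplicate gene sequences and assign stable unique names
#'
#' Exact (case-insensitive) deduplication of coding-strand genomic
#' sequences. Each unique sequence receives a stable name
#' \code{<isotype>_<anticodon>_u<k>} with k assigned in lexicographic
#' sequence order within its label group. When identical sequences carry
#' conflicting isotype/anticodon labels, the majority label wins (ties
#' broken lexicographically) with a warning.
#'
#' @param genes Gene record data.frame.
#' @return Data.frame with columns \code{unique_name}, \code{seq},
#'   \code{isotype}, \code{anticodon}, \code{n_members},
#'   \code{member_ids} (comma-joined gene ids).
#' @export
unique_sequences <- function(genes) {
  if (nrow(genes) == 0L)
    return(data.frame(unique_name = character(0), seq = character(0),
                      isotype = character(0), anticodon = character(0),
                      n_members = integer(0), member_ids = character(0),
                      stringsAsFactors = FALSE))
  seq <- toupper(genes$genomic_seq)
  grp <- split(seq_len(nrow(genes)), seq)
  useq <- names(grp)
  lab <- vapply(grp, function(idx) {
    labs <- paste(genes$isotype[idx], genes$anticodon[idx], sep = "_")
    tl <- sort(table(labs), decreasing = TRUE)
    if (length(tl) > 1L) {
      warning("conflicting labels for an identical sequence: ",
              paste(names(tl), collapse = " vs "), call. = FALSE)
      top <- names(tl)[tl == max(tl)]
      return(sort(top)[1L])
    }
    names(tl)[1L]
  }, character(1))
  out <- data.frame(seq = useq, label = unname(lab),
                    n_members = vapply(grp, length, integer(1)),
                    member_ids = vapply(grp, function(idx)
                      paste(genes$gene_id[idx], collapse = ","),
                      character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$label, out$seq), , drop = FALSE]
  k <- stats::ave(seq_len(nrow(out)), out$label, FUN = seq_along)
  out$unique_name <- paste0(out$label, "_u", k)
  parts <- strsplit(out$label, "_", fixed = TRUE)
  out$isotype <- vapply(parts, `[`, character(1), 1L)
  out$anticodon <- vapply(parts, `[`, character(1), 2L)
  rownames(out) <- NULL
  out[c("unique_name", "seq", "isotype", "anticodon", "n_members",
        "member_ids")]
}
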