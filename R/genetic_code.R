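#' The full 64-anticodon space
#'
#' All 64 DNA anticodon triplets in lexicographic order. Anticodons are
#' written as DNA (T, not U), matching tRNAscan-SE output.
#'
#' @format Character vector of length 64.
#' @export
ANTICODONS <- sort(apply(expand.grid(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"))[, 3:1],
                         1, paste0, collapse = ""))

#' Stop codons of the standard genetic code
#' @export
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Anticodons that pair with stop codons
#'
#' Reverse complements of the three stop codons. Under the standard code
#' these decode no amino acid; TCA is reassignable to selenocysteine
#' (SeC), whose tRNA reads the recoded stop codon TGA.
#' @export
STOP_ANTICODONS <- c("TTA", "CTA", "TCA")

# single-letter -> three-letter amino-acid labels
.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
          Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
          L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
          S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

#' Valid isotype labels
#'
#' The 20 standard amino acids plus initiator methionine (iMet),
#' selenocysteine (SeC) and the undetermined/pseudogene label (Und).
#' @export
ISOTYPES <- c(unname(.AA3), "iMet", "SeC", "Und")

.check_alphabet <- function(x, allowed = "ACGT", what = "sequence") {
  bad <- grepl(sprintf("[^%s]", allowed), x)
  if (any(bad))
    stop("invalid ", what, " alphabet (allowed: ", allowed, "): ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings over the ACGTN alphabet
#'   (case-insensitive; returned uppercase). Empty strings are allowed.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("CAT")  # "ATG"
#' @export
reverse_complement <- function(x) {
  x <- toupper(x)
  .check_alphabet(x, "ACGTN")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decode an anticodon to its amino acid
#'
#' Maps a DNA anticodon triplet to the amino acid decoded by its
#' reverse-complement codon under the standard genetic code. Anticodons
#' pairing stop codons return \code{"stop-pairing"}, except that with
#' \code{sec = TRUE} the anticodon TCA is reported as SeC
#' (selenocysteine, which decodes the recoded stop codon TGA).
#' The initiator/elongator Met distinction is an annotation attribute of
#' a gene record, not derivable from the anticodon: CAT always maps to
#' Met here.
#'
#' @param anticodon Character vector of 3-mers over ACGT.
#' @param sec Logical; report TCA as \code{"SeC"} instead of
#'   \code{"stop-pairing"}.
#' @return Character vector of three-letter amino-acid labels,
#'   \code{"SeC"} or \code{"stop-pairing"}.
#' @examples
#' anticodon_to_amino_acid("GTC")              # "Asp"
#' anticodon_to_amino_acid("TCA", sec = TRUE)  # "SeC"
#' @export
anticodon_to_amino_acid <- function(anticodon, sec = FALSE) {
  anticodon <- toupper(anticodon)
  if (any(nchar(anticodon) != 3L))
    stop("anticodon must be a 3-mer", call. = FALSE)
  .check_alphabet(anticodon, "ACGT", "anticodon")
  codon <- reverse_complement(anticodon)
  aa1 <- Biostrings::GENETIC_CODE[codon]
  out <- ifelse(aa1 == "*", "stop-pairing", .AA3[aa1])
  if (sec) out[anticodon == "TCA"] <- "SeC"
  unname(out)
}

#' Codon read by an anticodon
#'
#' @param anticodon Character vector of 3-mers over ACGT.
#' @return The reverse-complement codon (a bijection over the 64-mer
#'   space).
#' @export
anticodon_to_codon <- function(anticodon) {
  anticodon <- toupper(anticodon)
  if (any(nchar(anticodon) != 3L))
    stop("anticodon must be a 3-mer", call. = FALSE)
  reverse_complement(anticodon)
}
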