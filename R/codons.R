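# Shared genetic-code tables. All sequences are stored on the DNA alphabet
# (U accepted on input, converted to T) so pileups and codon tables share
# one alphabet; helpers can render U for display.

.GENETIC_CODE <- Biostrings::GENETIC_CODE
.STOP_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE == "*"]
.SENSE_CODONS <- setdiff(names(.GENETIC_CODE), .STOP_CODONS)

#' The 61 sense codons (DNA alphabet)
#'
#' @return Character vector of the 61 sense codons of the standard genetic
#'   code, written on the DNA alphabet (T, not U).
#' @export
sense_codons <- function() .SENSE_CODONS

#' Amino acid encoded by a codon
#'
#' @param codon Character vector of codons (DNA or RNA alphabet, any case).
#' @return One-letter amino-acid codes; `"*"` for stop codons.
#' @export
codon_aa <- function(codon) {
  codon <- normalize_seq(codon)
  aa <- unname(.GENETIC_CODE[codon])
  if (anyNA(aa)) stop("not a codon: ", paste(codon[is.na(aa)], collapse = ", "))
  aa
}

#' Normalize a nucleotide string to the package's DNA convention
#'
#' Upper-cases and converts U to T.
#'
#' @param x Character vector of sequences.
#' @return Normalized character vector.
#' @export
normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Render a DNA-alphabet sequence as RNA for display
#' @param x Character vector of DNA-alphabet sequences.
#' @return The same sequences with T replaced by U.
#' @export
as_rna <- function(x) gsub("T", "U", toupper(x), fixed = TRUE)

.check_alphabet <- function(x, extra = character(), what = "sequence") {
  ok <- c("A", "C", "G", "T", extra)
  bad <- setdiff(unique(unlist(strsplit(x, "", fixed = TRUE))), ok)
  if (length(bad) > 0)
    stop("invalid ", what, " character(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Leucine and serine codon groups
#'
#' Constant codon groups used throughout the codon-bias analyses: the
#' U/A-rich leucine codons that show A-site stalling when tRNA acetylation
#' is lost, their C/G-rich counterparts, and the analogous serine split.
#' Within each amino acid the two groups are disjoint and together cover
#' the whole synonymous family.
#'
#' @format A named list of character vectors (DNA alphabet):
#'   `UA_rich_Leu`, `CG_rich_Leu`, `UA_rich_Ser`, `CG_rich_Ser`.
#' @export
codon_groups <- list(
  UA_rich_Leu = c("TTA", "TTG", "CTA", "CTT"),
  CG_rich_Leu = c("CTG", "CTC"),
  UA_rich_Ser = c("TCA", "TCT", "AGT"),
  CG_rich_Ser = c("AGC", "TCC", "TCG")
)
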