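# Wobble decoding table. An anticodon is written 5'->3' as positions
# 34-35-36; positions 35 and 36 pair Watson-Crick with codon positions 2
# and 1, and position 34 pairs the codon's third base under the wobble
# rules: Watson-Crick pairs, G:U and U:G wobble, and inosine pairing with
# U, C or A.

.WC <- c(A = "T", C = "G", G = "C", T = "A")

# anticodon-34 bases able to pair each codon-3 base
.WOBBLE34 <- list(
  A = c("T", "I"),        # WC T:A; I pairs A
  C = c("G", "I"),        # WC G:C; I pairs C
  G = c("C", "T"),        # WC C:G; U:G wobble
  T = c("A", "G", "I")    # WC A:U; G:U wobble; I pairs U
)

#' Anticodons able to decode a codon under wobble rules
#'
#' @param codon A sense codon (DNA or RNA alphabet, any case).
#' @return Character vector of anticodons 5'->3' over the alphabet
#'   A, C, G, T, I (T standing for U), sorted.
#' @export
wobble_decoders <- function(codon) {
  codon <- normalize_seq(codon)
  if (nchar(codon) != 3) stop("not a codon: ", codon)
  if (codon %in% .STOP_CODONS) stop("stop codon has no decoder: ", codon)
  if (!codon %in% .SENSE_CODONS) stop("not a codon: ", codon)
  b <- strsplit(codon, "")[[1]]
  a35 <- .WC[[b[2]]]
  a36 <- .WC[[b[1]]]
  sort(paste0(.WOBBLE34[[b[3]]], a35, a36))
}
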