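# Codon-usage-shifted coding sequences: CDS start with ATG, end with a stop
# codon, and draw interior codons from a renormalized base usage times
# per-codon multipliers — the ground truth for codon-bias recovery tests.

#' Simulate coding sequences with shifted codon usage
#'
#' @param n Number of CDS to generate.
#' @param length_codons Total CDS length in codons, including the
#'   initiator ATG and the terminal stop; must be >= 3.
#' @param base_usage Named positive weights over sense codons (stop codons
#'   are never drawn in the interior); defaults to uniform over the 61.
#' @param shifted Named multipliers applied to `base_usage` (e.g.
#'   `c(TTA = 2)` doubles the relative weight of TTA).
#' @param seed Integer seed.
#' @return A [reference_set()] of `n` CDS, each `3 * length_codons` nt,
#'   with attribute `expected_freq`: the renormalized interior codon
#'   distribution actually sampled from.
#' @export
simulate_codon_shifted_cds <- function(n, length_codons,
                                       base_usage = NULL, shifted = numeric(),
                                       seed = 1) {
  if (length_codons < 3) stop("length_codons must be >= 3")
  stopifnot(n >= 1)
  if (is.null(base_usage))
    base_usage <- stats::setNames(rep(1, length(.SENSE_CODONS)), .SENSE_CODONS)
  names(base_usage) <- normalize_seq(names(base_usage))
  if (any(names(base_usage) %in% .STOP_CODONS))
    stop("base_usage must not contain stop codons")
  bad <- setdiff(names(base_usage), .SENSE_CODONS)
  if (length(bad) > 0) stop("not a codon: ", paste(bad, collapse = ", "))
  if (any(base_usage <= 0)) stop("base_usage weights must be positive")
  w <- base_usage
  if (length(shifted) > 0) {
    names(shifted) <- normalize_seq(names(shifted))
    bad <- setdiff(names(shifted), names(w))
    if (length(bad) > 0) stop("shifted codon not in base_usage: ",
                              paste(bad, collapse = ", "))
    w[names(shifted)] <- w[names(shifted)] * shifted
  }
  p <- w / sum(w)
  set.seed(seed)
  n_int <- length_codons - 2L
  seqs <- vapply(seq_len(n), function(i) {
    interior <- sample(names(p), n_int, replace = TRUE, prob = p)
    paste0("ATG", paste(interior, collapse = ""),
           sample(.STOP_CODONS, 1))
  }, "")
  out <- reference_set(stats::setNames(seqs, paste0("cds", seq_len(n))))
  attr(out, "expected_freq") <- p
  out
}
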