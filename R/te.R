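# Translation-efficiency ratios and a simple up/down classifier.

#' Translation efficiency per transcript
#'
#' TE is the ribosome-footprint proportion of a transcript divided by its
#' mRNA proportion, with a pseudocount added to every transcript before
#' normalization.
#'
#' @param rpf_counts,rna_counts Named non-negative counts over a shared
#'   transcript universe.
#' @param pseudocount Added to each count before normalization (default 0.5).
#' @return Named numeric vector of TE values.
#' @export
translation_efficiency <- function(rpf_counts, rna_counts, pseudocount = 0.5) {
  ids <- names(rpf_counts)
  if (is.null(ids) || !setequal(ids, names(rna_counts)))
    stop("rpf and rna counts must share a transcript universe")
  rna_counts <- rna_counts[ids]
  if (sum(rpf_counts) == 0 || sum(rna_counts) == 0)
    stop("zero total counts")
  p_rpf <- (rpf_counts + pseudocount) / sum(rpf_counts + pseudocount)
  p_rna <- (rna_counts + pseudocount) / sum(rna_counts + pseudocount)
  p_rpf / p_rna
}

#' Classify transcripts by TE change between two conditions
#'
#' @param te_a,te_b Named TE vectors (e.g. wild-type and knockout) over a
#'   shared universe, as from [translation_efficiency()].
#' @param threshold `|delta log2 TE|` at or beyond which a transcript is
#'   called `up`/`down` (default 1, i.e. a 2-fold change).
#' @return data.frame with `transcript_id`, `te_A`, `te_B`,
#'   `delta_log2_te` (log2(te_B / te_A)) and `class`
#'   (`up`/`down`/`unchanged`).
#' @export
classify_te <- function(te_a, te_b, threshold = 1.0) {
  ids <- names(te_a)
  if (is.null(ids) || !setequal(ids, names(te_b)))
    stop("te_a and te_b must share a transcript universe")
  te_b <- te_b[ids]
  d <- log2(te_b / te_a)
  cls <- ifelse(d <= -threshold, "down", ifelse(d >= threshold, "up", "unchanged"))
  data.frame(transcript_id = ids, te_A = unname(te_a), te_B = unname(te_b),
             delta_log2_te = unname(d), class = unname(cls))
}
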