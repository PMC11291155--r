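# Ribosome-footprint simulator. The A-site codon of each footprint is drawn
# with probability proportional to its dwell multiplier within a transcript
# chosen proportionally to transcript length (a uniform per-codon baseline;
# expression differences can be layered via duplicate records). The 5' end
# is placed so the matching offset table recovers the drawn A site.

#' Per-codon dwell-time model
#'
#' @param multipliers Named numeric vector, codon -> positive dwell
#'   multiplier (DNA or RNA alphabet). Codons not listed default to 1.
#' @return Named numeric vector over the 61 sense codons, class
#'   `dwell_model`.
#' @export
dwell_model <- function(multipliers = numeric()) {
  m <- stats::setNames(rep(1, length(.SENSE_CODONS)), .SENSE_CODONS)
  if (length(multipliers) > 0) {
    nm <- normalize_seq(names(multipliers))
    bad <- setdiff(nm, .SENSE_CODONS)
    if (length(bad) > 0) stop("not a sense codon: ", paste(bad, collapse = ", "))
    if (any(multipliers <= 0)) stop("dwell multipliers must be > 0")
    m[nm] <- unname(multipliers)
  }
  structure(m, class = "dwell_model")
}

#' Default footprint length weights
#' @param kind `"monosome"` or `"disome"`.
#' @return Named numeric vector of equal weights over the typical footprint
#'   lengths (monosome 28-30 nt; disome 59-63 nt, two stacked ribosomes).
#' @export
default_length_weights <- function(kind = c("monosome", "disome")) {
  kind <- match.arg(kind)
  if (kind == "monosome") stats::setNames(rep(1, 3), 28:30)
  else stats::setNames(rep(1, 5), 59:63)
}

#' Simulate monosome or disome footprints under a dwell model
#'
#' @param cds A [reference_set()] of coding sequences (lengths divisible
#'   by 3).
#' @param dwell A [dwell_model()].
#' @param n_reads Number of footprints (>= 1).
#' @param kind `"monosome"` or `"disome"` (selects the default offset table
#'   used to place 5' ends).
#' @param length_weights Named weights over footprint lengths; defaults to
#'   [default_length_weights()] for `kind`.
#' @param offsets Offset table used to position 5' ends; defaults to
#'   [default_offsets()] for `kind`.
#' @param seed Integer seed.
#' @return An [alignment_set()] of footprints with attribute `truth`, a
#'   data.frame (`ref_id`, `a_codon_index`, `a_codon`, `length`) logging
#'   each footprint's drawn A-site.
#' @export
simulate_footprints <- function(cds, dwell = dwell_model(), n_reads,
                                kind = c("monosome", "disome"),
                                length_weights = NULL, offsets = NULL,
                                seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(cds, "ReferenceSet"), n_reads >= 1)
  len <- ref_lengths(cds)
  if (any(len %% 3 != 0)) stop("CDS length not divisible by 3")
  if (is.null(length_weights)) length_weights <- default_length_weights(kind)
  if (is.null(offsets)) offsets <- default_offsets(kind)
  fl <- as.integer(names(length_weights))
  if (any(!as.character(fl) %in% names(offsets$offsets)))
    stop("length_weights contains a length absent from the offset table")
  set.seed(seed)
  tid <- sample(names(cds), n_reads, replace = TRUE, prob = len)
  rlen <- fl[sample.int(length(fl), n_reads, replace = TRUE,
                        prob = length_weights)]
  # per-transcript codon vectors and dwell weights
  codvec <- lapply(cds$seq, function(s)
    substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3)))
  a_idx <- integer(n_reads)
  for (t in names(cds)) {
    nt_codons <- len[[t]] / 3
    w_all <- unname(dwell[codvec[[t]]])
    for (L in fl) {
      sel <- which(tid == t & rlen == L)
      if (length(sel) == 0) next
      off <- offsets$offsets[[as.character(L)]]
      a_min <- ceiling((off + 3) / 3)
      a_max <- floor((3 * nt_codons + off + 3 - L) / 3)
      if (a_max < a_min) stop("CDS too short for footprint length ", L)
      rng <- a_min:a_max
      a_idx[sel] <- rng[sample.int(length(rng), length(sel), replace = TRUE,
                                   prob = w_all[rng])]
    }
  }
  offmap <- unlist(offsets$offsets)
  off <- unname(offmap[as.character(rlen)])
  start <- 3L * (a_idx - 1L) + 1L - as.integer(off)
  seqs <- substr(cds$seq[tid], start, start + rlen - 1L)
  out <- alignment_set(paste0("fp", seq_len(n_reads)), tid, start, seqs)
  a_codon <- character(n_reads)
  for (t in names(cds)) {
    sel <- tid == t
    a_codon[sel] <- codvec[[t]][a_idx[sel]]
  }
  truth <- data.frame(ref_id = tid, a_codon_index = a_idx,
                      a_codon = a_codon, length = rlen)
  attr(out, "truth") <- truth
  out
}
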