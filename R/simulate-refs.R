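# Synthetic references. Acetylated tRNA families carry the 5'-CCG-3'
# consensus at positions 11-13 of the mature sequence: the modified C is
# position 12, the middle of the CCG triplet, mirroring the D-arm C12 site
# of tRNA-Leu/Ser. Non-acetylated families are constructed so position 12
# is never a C (hence never a C in CCG context).

#' Generate synthetic mature tRNA references
#'
#' @param n_families Number of distinct reference sequences.
#' @param acetylated_family_ids Character vector of ids (a subset of the
#'   generated ids `iso1..isoN`) that carry the acetylation site.
#' @param length Sequence length in nt; must be >= 20 so position 12 has
#'   context on both sides. Default 76, a typical mature tRNA length.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A [reference_set()]; acetylated families have `CCG` at positions
#'   11-13 and an annotation `ac4C` at position 12.
#' @export
make_trna_references <- function(n_families, acetylated_family_ids = character(),
                                 length = 76, seed = 1) {
  if (length < 20) stop("reference length must be >= 20")
  stopifnot(n_families >= 1)
  ids <- paste0("iso", seq_len(n_families))
  bad <- setdiff(acetylated_family_ids, ids)
  if (length(bad) > 0)
    stop("unknown acetylated family id(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_families), function(i) {
    s <- sample(bases, length, replace = TRUE)
    if (ids[i] %in% acetylated_family_ids) {
      s[11:13] <- c("C", "C", "G")
    } else {
      s[12] <- sample(c("A", "G", "T"), 1)
    }
    paste(s, collapse = "")
  }, "")
  ann <- NULL
  if (length(acetylated_family_ids) > 0)
    ann <- data.frame(ref_id = acetylated_family_ids, position = 12L,
                      label = "ac4C")
  reference_set(stats::setNames(seqs, ids), annotations = ann)
}
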