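# Simplified isodecoder-level tRNA quantification. Reads are assigned by
# ungapped Hamming distance over the best offset against every reference,
# with mismatches at known modification positions costing nothing (the
# modification-tolerant idea behind misincorporation-aware tRNA
# sequencing); ties are split fractionally. Differential abundance works
# on per-sample proportions with a two-proportion test on raw counts.

#' Read sequences from a FASTQ or FASTA file
#' @param path Input path.
#' @param format `"fastq"` or `"fasta"`.
#' @return Named character vector of read sequences (DNA alphabet).
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::readBStringSet(path, format = format)
  stats::setNames(normalize_seq(as.character(x)),
                  sub("\\s.*$", "", names(x)))
}

#' Assign reads to isodecoder references
#'
#' Each read is scored against every reference by Hamming distance over
#' its best ungapped offset; mismatches at masked modification positions
#' cost 0. A read is assigned to the unique minimum-distance reference if
#' that distance is at most `max_mismatch`; ties split the read's weight
#' equally among co-minimal references; reads above the threshold are
#' discarded.
#'
#' @param reads Character vector of read sequences (each no longer than
#'   the references it can match).
#' @param refs A [reference_set()] of mature isodecoder sequences.
#' @param max_mismatch Maximum (mask-discounted) distance (default 2).
#' @param mod_mask Optional data.frame (`ref_id`, `position`) of known
#'   modification positions whose mismatches are free.
#' @param sample_id Label stored in the result.
#' @return An `isodecoder_counts` list: `counts` (named, fractional
#'   weights allowed), `assigned_total`, `discarded_total`, `sample_id`.
#' @export
assign_reads <- function(reads, refs, max_mismatch = 2, mod_mask = NULL,
                         sample_id = "sample") {
  stopifnot(inherits(refs, "ReferenceSet"))
  if (length(refs) == 0) stop("empty reference set")
  reads <- normalize_seq(reads)
  ref_raw <- lapply(refs$seq, charToRaw)
  masks <- lapply(names(refs), function(r) {
    if (is.null(mod_mask)) integer(0)
    else mod_mask$position[mod_mask$ref_id == r]
  })
  names(masks) <- names(refs)
  counts <- stats::setNames(numeric(length(refs)), names(refs))
  # score unique sequences once, then weight by multiplicity
  tab <- table(reads)
  useq <- names(tab)
  mult <- as.integer(tab)
  discarded <- 0L
  for (k in seq_along(useq)) {
    rd <- charToRaw(useq[k])
    n <- length(rd)
    best <- Inf
    best_refs <- character(0)
    for (r in names(refs)) {
      rr <- ref_raw[[r]]
      L <- length(rr)
      if (n > L) next
      dmin <- Inf
      for (o in 0:(L - n)) {
        mm <- which(rd != rr[(o + 1):(o + n)])
        if (length(masks[[r]]) > 0)
          mm <- mm[!((mm + o) %in% masks[[r]])]
        dmin <- min(dmin, length(mm))
        if (dmin == 0) break
      }
      if (dmin < best) {
        best <- dmin; best_refs <- r
      } else if (dmin == best && is.finite(best)) {
        best_refs <- c(best_refs, r)
      }
    }
    if (is.finite(best) && best <= max_mismatch) {
      counts[best_refs] <- counts[best_refs] + mult[k] / length(best_refs)
    } else {
      discarded <- discarded + mult[k]
    }
  }
  structure(list(sample_id = sample_id, counts = counts,
                 assigned_total = length(reads) - discarded,
                 discarded_total = discarded),
            class = "isodecoder_counts")
}

#' Simulate isodecoder reads at known relative abundances
#'
#' Full-length reads are drawn from the references in proportion to
#' `weights`, with optional uniform per-base errors; the drawn source
#' counts are attached as attribute `truth`.
#'
#' @param refs A [reference_set()].
#' @param weights Named positive weights over the references.
#' @param n_reads Number of reads.
#' @param error_rate Uniform per-base error probability.
#' @param seed Integer seed.
#' @return Character vector of reads with attribute `truth`.
#' @export
simulate_isodecoder_reads <- function(refs, weights, n_reads,
                                      error_rate = 0, seed = 1) {
  stopifnot(inherits(refs, "ReferenceSet"), all(weights > 0))
  weights <- weights[names(refs)]
  if (anyNA(weights)) stop("weights must cover all references")
  set.seed(seed)
  src <- sample(names(refs), n_reads, replace = TRUE, prob = weights)
  reads <- refs$seq[src]
  if (error_rate > 0) {
    # per-reference groups so equal-length vectorized error application works
    for (r in unique(src)) {
      sel <- src == r
      reads[sel] <- .apply_errors(reads[sel], error_rate)
    }
  }
  names(reads) <- paste0("r", seq_len(n_reads))
  structure(reads, truth = table(src))
}

#' Differential isodecoder abundance between two samples
#'
#' Proportions are computed from pseudocounted counts per sample (the
#' pseudocount affects fold changes only, never the test); the p-value
#' comes from a two-proportion test on raw counts, with BH q-values
#' across isodecoders.
#'
#' @param a,b `isodecoder_counts` for the two samples (shared universe).
#' @param pseudocount Added to each count for proportions/fold change
#'   (default 0.5).
#' @return data.frame: `isodecoder_id`, `proportion_A`, `proportion_B`,
#'   `log2fc` (B over A), `p_value`, `q_value`.
#' @export
differential_abundance <- function(a, b, pseudocount = 0.5) {
  stopifnot(inherits(a, "isodecoder_counts"), inherits(b, "isodecoder_counts"))
  if (!setequal(names(a$counts), names(b$counts)))
    stop("samples must share an isodecoder universe")
  ids <- names(a$counts)
  ca <- a$counts[ids]; cb <- b$counts[ids]
  ta <- sum(ca); tb <- sum(cb)
  if (ta == 0 || tb == 0) stop("zero total counts")
  pa <- (ca + pseudocount) / sum(ca + pseudocount)
  pb <- (cb + pseudocount) / sum(cb + pseudocount)
  lfc <- log2(pb / pa)
  p <- vapply(seq_along(ids), function(i) {
    xa <- round(ca[i]); xb <- round(cb[i])
    if (xa + xb == 0) return(1)
    suppressWarnings(stats::prop.test(c(xa, xb), c(round(ta), round(tb)))$p.value)
  }, 0)
  p[is.na(p)] <- 1
  data.frame(isodecoder_id = ids,
             proportion_A = unname(pa), proportion_B = unname(pb),
             log2fc = unname(lfc), p_value = unname(p),
             q_value = stats::p.adjust(p, method = "BH"))
}

#' Roll isodecoder counts up to anticodon families
#'
#' Reporting aggregation: sums isodecoder counts whose ids share an
#' anticodon label of the form `<family>-<n>` (everything before the last
#' `-`), e.g. `Leu-TAA-2` -> `Leu-TAA`. Ids without a `-` map to
#' themselves.
#'
#' @param x An `isodecoder_counts`.
#' @return Named numeric vector of family counts.
#' @export
anticodon_rollup <- function(x) {
  stopifnot(inherits(x, "isodecoder_counts"))
  fam <- sub("-[^-]*$", "", names(x$counts))
  fam[!grepl("-", names(x$counts))] <- names(x$counts)[!grepl("-", names(x$counts))]
  tapply(x$counts, fam, sum)
}
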