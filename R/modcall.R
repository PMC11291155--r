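# Acetylation-site calling from treated/control pileups: the computational
# half of the chemical probing assay. The misincorporation-rate denominator
# is total base-presenting coverage (robust to stray non-T errors); the
# treated-vs-control significance test is a two-sided Fisher exact test on
# the T/non-T 2x2 table; multiple testing is Benjamini-Hochberg across all
# tested C positions.

#' Build per-position pileups from alignments
#'
#' @param alignments An [alignment_set()].
#' @param refs A [reference_set()].
#' @return A `pileup_table`: data.frame with one row per reference position
#'   (complete 1..length grid per reference) and columns `ref_id`,
#'   `position`, `A`, `C`, `G`, `T`, `del`, `coverage` (reads presenting a
#'   base; deletions excluded), `start_count` (reads whose leftmost
#'   position is there) and `ref_base`; attribute `library_depth` is the
#'   total number of aligned reads.
#' @export
pileup <- function(alignments, refs) {
  stopifnot(inherits(refs, "ReferenceSet"))
  aln <- as.data.frame(alignments)
  if (nrow(aln) > 0 && any(!aln$ref_id %in% names(refs)))
    stop("alignment refers to a reference absent from the ReferenceSet")
  depth <- nrow(aln)
  len <- ref_lengths(refs)
  # aggregate identical reads first; sequencing data is highly redundant
  key <- paste(aln$ref_id, aln$start, aln$aligned, sep = "\r")
  agg <- table(key)
  u <- match(names(agg), key)
  w <- as.integer(agg)
  ref_u <- aln$ref_id[u]; start_u <- aln$start[u]; seq_u <- aln$aligned[u]
  wid <- nchar(seq_u)
  # expand to (ref, pos, base, weight)
  reps <- rep.int(seq_along(seq_u), wid)
  pos <- unlist(lapply(seq_along(seq_u),
                       function(i) seq.int(start_u[i], start_u[i] + wid[i] - 1L)),
                use.names = FALSE)
  base <- unlist(strsplit(seq_u, "", fixed = TRUE), use.names = FALSE)
  rid <- ref_u[reps]
  wt <- w[reps]
  offs <- c(0L, cumsum(len))[seq_along(len)]
  names(offs) <- names(len)
  gidx <- offs[rid] + pos
  total <- sum(len)
  counts <- sapply(c("A", "C", "G", "T", "-"), function(b) {
    sel <- base == b
    v <- numeric(total)
    if (any(sel)) {
      s <- rowsum(wt[sel], gidx[sel])
      v[as.integer(rownames(s))] <- s[, 1]
    }
    v
  })
  starts <- numeric(total)
  if (length(start_u) > 0) {
    s <- rowsum(w, offs[ref_u] + start_u)
    starts[as.integer(rownames(s))] <- s[, 1]
  }
  out <- data.frame(
    ref_id = rep(names(len), len),
    position = unlist(lapply(len, seq_len), use.names = FALSE),
    A = as.integer(counts[, "A"]), C = as.integer(counts[, "C"]),
    G = as.integer(counts[, "G"]), T = as.integer(counts[, "T"]),
    del = as.integer(counts[, "-"]),
    start_count = as.integer(starts))
  out$coverage <- out$A + out$C + out$G + out$T
  out$ref_base <- unlist(strsplit(unname(refs$seq), "", fixed = TRUE),
                         use.names = FALSE)
  structure(out, class = c("pileup_table", "data.frame"),
            library_depth = depth)
}

#' Extract one site's pileup
#'
#' @param pt A `pileup_table` from [pileup()].
#' @param ref_id,position Site coordinates (1-based).
#' @return A `site_pileup` list: `ref_id`, `position`, `coverage`,
#'   `base_counts` (A/C/G/T/del), `start_count`, `library_depth`,
#'   `ref_base`.
#' @export
pileup_at <- function(pt, ref_id, position) {
  i <- which(pt$ref_id == ref_id & pt$position == position)
  if (length(i) != 1) stop("no pileup at ", ref_id, ":", position)
  site_pileup(ref_id, position,
              base_counts = c(A = pt$A[i], C = pt$C[i], G = pt$G[i],
                              T = pt$T[i], del = pt$del[i]),
              start_count = pt$start_count[i],
              library_depth = attr(pt, "library_depth"),
              ref_base = pt$ref_base[i])
}

#' Construct a site pileup directly
#'
#' @param ref_id,position Site coordinates.
#' @param base_counts Named counts over `A`, `C`, `G`, `T` (and optionally
#'   `del`).
#' @param start_count Reads whose leftmost aligned position equals
#'   `position`.
#' @param library_depth Total aligned reads in the library.
#' @param ref_base Reference base at the position (optional).
#' @return A `site_pileup` list.
#' @export
site_pileup <- function(ref_id, position, base_counts = c(A = 0, C = 0, G = 0, T = 0),
                        start_count = 0, library_depth = 0, ref_base = NA_character_) {
  bc <- c(A = 0, C = 0, G = 0, T = 0, del = 0)
  bc[names(base_counts)] <- base_counts
  if (start_count > library_depth)
    stop("start_count cannot exceed library_depth")
  structure(list(ref_id = ref_id, position = as.integer(position),
                 coverage = sum(bc[c("A", "C", "G", "T")]),
                 base_counts = bc, start_count = start_count,
                 library_depth = library_depth, ref_base = ref_base),
            class = "site_pileup")
}

#' C->T misincorporation rate at a reference-C site
#'
#' @param p A `site_pileup` whose reference base is C.
#' @return `base_counts[T] / coverage` — the fraction of base-presenting
#'   reads showing T.
#' @export
misincorporation_rate <- function(p) {
  stopifnot(inherits(p, "site_pileup"))
  if (!is.na(p$ref_base) && p$ref_base != "C")
    stop("reference base at ", p$ref_id, ":", p$position, " is not C")
  if (p$coverage == 0)
    stop("undefined site: zero coverage at ", p$ref_id, ":", p$position)
  unname(p$base_counts["T"] / p$coverage)
}

#' Treated-vs-control Fisher exact test at a site
#'
#' Two-sided Fisher exact p-value on the 2x2 table of T vs non-T counts in
#' the treated and control pileups.
#'
#' @param treated,control `site_pileup`s with coverage > 0.
#' @return The p-value.
#' @export
site_test <- function(treated, control) {
  stopifnot(inherits(treated, "site_pileup"), inherits(control, "site_pileup"))
  if (treated$coverage == 0 || control$coverage == 0)
    stop("zero coverage in treated or control library")
  tt <- unname(treated$base_counts["T"]); tc <- unname(control$base_counts["T"])
  m <- matrix(c(tt, treated$coverage - tt, tc, control$coverage - tc),
              nrow = 2, byrow = TRUE)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Fold RT stop at the position 5' of a modified site
#'
#' Ratio of depth-normalized read-start counts, treated over control,
#' evaluated at position `site - 1`. When the control has zero starts but
#' the treated library does not, the ratio is set to the sentinel value
#' 100; when both have zero starts the ratio is 1 (no evidence either
#' way).
#'
#' @param treated,control `site_pileup`s at position `site - 1` with
#'   `library_depth > 0`.
#' @return A positive real (or the sentinel 100).
#' @export
fold_rt_stop <- function(treated, control) {
  stopifnot(inherits(treated, "site_pileup"), inherits(control, "site_pileup"))
  if (treated$library_depth == 0 || control$library_depth == 0)
    stop("library_depth must be > 0")
  st <- treated$start_count; sc <- control$start_count
  if (sc == 0 && st == 0) return(1)
  if (sc == 0) return(100)
  (st / treated$library_depth) / (sc / control$library_depth)
}

#' Is a position the middle C of a 5'-CCG-3' triplet?
#'
#' @param refs A [reference_set()].
#' @param ref_id,position Site coordinates.
#' @return `TRUE` iff bases at positions (position-1, position, position+1)
#'   are (C, C, G). Sequence edges return `FALSE` (never an error).
#' @export
annotate_context <- function(refs, ref_id, position) {
  stopifnot(inherits(refs, "ReferenceSet"))
  s <- refs$seq[[ref_id]]
  if (is.null(s)) stop("unknown reference: ", ref_id)
  if (position < 1 || position > nchar(s)) stop("position out of range")
  if (position == 1 || position == nchar(s)) return(FALSE)
  substr(s, position - 1, position + 1) == "CCG"
}

#' Call acetylation-like sites from treated and control pileups
#'
#' Tests every reference-C position whose coverage exceeds `min_coverage`
#' in both libraries: misincorporation rates, Fisher p-value, BH q-value
#' over all tested positions, fold RT stop at `position - 1`, CCG context,
#' and the pass/fail filter
#' `mrd_treated >= min_mrd & q <= q_max & mrd_treated > mrd_control`.
#' p-values of zero are floored at the smallest representable positive
#' value.
#'
#' @param treated,control `pileup_table`s from [pileup()].
#' @param refs A [reference_set()].
#' @param min_coverage Coverage both libraries must exceed for a position
#'   to be tested (default 100, i.e. ">100 reads").
#' @param min_mrd Minimum treated misincorporation rate (default 0.02).
#' @param q_max BH q-value cutoff (default 0.05).
#' @return data.frame of class `site_calls`: `ref_id`, `position`,
#'   `mrd_treated`, `mrd_control`, `p_value`, `q_value`, `fold_rt_stop`,
#'   `ccg_context`, `passes_filters`. Empty (with a warning) when no
#'   position is testable.
#' @export
call_sites <- function(treated, control, refs, min_coverage = 100,
                       min_mrd = 0.02, q_max = 0.05) {
  stopifnot(inherits(treated, "pileup_table"), inherits(control, "pileup_table"),
            inherits(refs, "ReferenceSet"),
            min_coverage > 0, min_mrd > 0, q_max > 0)
  key_t <- paste(treated$ref_id, treated$position)
  key_c <- paste(control$ref_id, control$position)
  ci <- match(key_t, key_c)
  ok <- treated$ref_base == "C" & !is.na(ci) &
    treated$coverage > min_coverage & control$coverage[ci] > min_coverage
  idx <- which(ok)
  if (length(idx) == 0) {
    warning("no testable C positions")
    return(structure(data.frame(ref_id = character(), position = integer(),
                                mrd_treated = numeric(), mrd_control = numeric(),
                                p_value = numeric(), q_value = numeric(),
                                fold_rt_stop = numeric(), ccg_context = logical(),
                                passes_filters = logical()),
                     class = c("site_calls", "data.frame")))
  }
  depth_t <- attr(treated, "library_depth")
  depth_c <- attr(control, "library_depth")
  res <- lapply(idx, function(i) {
    j <- ci[i]
    mrd_t <- treated$T[i] / treated$coverage[i]
    mrd_c <- control$T[j] / control$coverage[j]
    m <- matrix(c(treated$T[i], treated$coverage[i] - treated$T[i],
                  control$T[j], control$coverage[j] - control$T[j]),
                nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(m)$p.value
    pos <- treated$position[i]
    if (pos > 1) {
      iu <- which(treated$ref_id == treated$ref_id[i] & treated$position == pos - 1L)
      ju <- which(control$ref_id == treated$ref_id[i] & control$position == pos - 1L)
      st <- treated$start_count[iu]; sc <- control$start_count[ju]
      frs <- if (sc == 0 && st == 0) 1
             else if (sc == 0) 100
             else (st / depth_t) / (sc / depth_c)
    } else frs <- 1
    c(mrd_t = mrd_t, mrd_c = mrd_c, p = p, frs = frs)
  })
  res <- do.call(rbind, res)
  p <- pmax(res[, "p"], .Machine$double.xmin)
  q <- stats::p.adjust(p, method = "BH")
  ccg <- vapply(idx, function(i)
    annotate_context(refs, treated$ref_id[i], treated$position[i]), logical(1))
  out <- data.frame(ref_id = treated$ref_id[idx],
                    position = treated$position[idx],
                    mrd_treated = res[, "mrd_t"], mrd_control = res[, "mrd_c"],
                    p_value = p, q_value = q,
                    fold_rt_stop = res[, "frs"],
                    ccg_context = ccg)
  out$passes_filters <- out$mrd_treated >= min_mrd & out$q_value <= q_max &
    out$mrd_treated > out$mrd_control
  structure(out, class = c("site_calls", "data.frame"))
}

#' Write site calls using the supplementary-table column schema
#'
#' Columns are named `C2T.MRD`, `pval.CT2`, `fold.RT.stop`, `ccg.context`
#' and `pass` to mirror the assay's published table schema.
#'
#' @param calls A `site_calls` data.frame from [call_sites()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calls <- function(calls, path) {
  df <- data.frame(ref_id = calls$ref_id, position = calls$position,
                   C2T.MRD = calls$mrd_treated, C2T.MRD.control = calls$mrd_control,
                   pval.CT2 = calls$p_value, qval.CT2 = calls$q_value,
                   fold.RT.stop = calls$fold_rt_stop,
                   ccg.context = calls$ccg_context, pass = calls$passes_filters,
                   check.names = FALSE)
  write_table(df, path)
}
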