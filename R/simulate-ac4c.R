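# Simulator for the chemical-probing (ac4C-seq) read chemistry. A reduced
# ac4C site, encountered by reverse transcription in a treated library,
# either truncates the cDNA (an RT stop, measured as a read whose leftmost
# aligned position is site - 1) or is read through with a C->T
# misincorporation; untreated controls carry only uniform sequencing error.

#' Describe the ground truth of one modified site
#'
#' @param ref_id Reference id.
#' @param position 1-based site position.
#' @param stoichiometry Fraction of molecules carrying the modification.
#' @param p_mis_given_mod Probability a modified, non-stopped encounter
#'   yields a T misincorporation at the site.
#' @param p_stop_given_mod Probability a modified encounter truncates the
#'   cDNA. `p_mis_given_mod + p_stop_given_mod` must be <= 1.
#' @return One-row data.frame of class `site_truth`.
#' @export
site_truth <- function(ref_id, position, stoichiometry,
                       p_mis_given_mod = 0.5, p_stop_given_mod = 0.2) {
  stopifnot(stoichiometry >= 0, stoichiometry <= 1,
            p_mis_given_mod >= 0, p_stop_given_mod >= 0)
  if (p_mis_given_mod + p_stop_given_mod > 1)
    stop("p_mis_given_mod + p_stop_given_mod must be <= 1")
  structure(data.frame(ref_id = ref_id, position = as.integer(position),
                       stoichiometry = stoichiometry,
                       p_mis_given_mod = p_mis_given_mod,
                       p_stop_given_mod = p_stop_given_mod),
            class = c("site_truth", "data.frame"))
}

# apply uniform per-base errors to a character vector of equal-length reads
.apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  L <- nchar(seqs[1])
  n_cells <- length(seqs) * L
  n_err <- stats::rbinom(1, n_cells, error_rate)
  if (n_err == 0) return(seqs)
  cell <- sample.int(n_cells, n_err)
  ri <- ((cell - 1L) %/% L) + 1L
  pi <- ((cell - 1L) %% L) + 1L
  for (k in seq_len(n_err)) {
    old <- substr(seqs[ri[k]], pi[k], pi[k])
    substr(seqs[ri[k]], pi[k], pi[k]) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  seqs
}

#' Simulate treated/control probing reads over a reference set
#'
#' Each reference yields `coverage` full-length molecules. In a treated
#' library a molecule is modified at a truth site with probability
#' `stoichiometry`; RT walks 3'->5', so the 3'-most stop event wins: the
#' emitted read's leftmost aligned position is `site - 1` and sites 5' of
#' the stop are never reached. Non-stopped modified encounters
#' misincorporate T at the site with `p_mis_given_mod`. Untreated
#' libraries apply only the uniform per-base `error_rate` (applied to both
#' library types). A ground-truth event log is attached as attribute
#' `truth`.
#'
#' @param refs A [reference_set()].
#' @param truths A `site_truth` (rows may cover several sites/references).
#' @param coverage Molecules per reference (>= 1).
#' @param error_rate Uniform per-base error probability.
#' @param treated Logical; if `FALSE` the modification channels are off.
#' @param seed Integer seed.
#' @return An [alignment_set()] with attribute `truth`: a data.frame with
#'   per-site columns `n_molecules` (molecules whose cDNA reached the
#'   site), `n_mod`, `n_stop`, `n_mis`.
#' @export
simulate_ac4cseq_reads <- function(refs, truths, coverage, error_rate = 0.001,
                                   treated = TRUE, seed = 1) {
  stopifnot(inherits(refs, "ReferenceSet"), coverage >= 1)
  truths <- as.data.frame(truths)
  if (nrow(truths) > 0) {
    if (any(!truths$ref_id %in% names(refs)))
      stop("truth site on unknown reference")
    len <- ref_lengths(refs)[truths$ref_id]
    if (any(truths$position < 2 | truths$position > len))
      stop("truth position outside reference (or at position 1)")
  }
  set.seed(seed)
  all_ids <- character(0); all_ref <- character(0)
  all_start <- integer(0); all_seq <- character(0)
  tlog <- truths[, c("ref_id", "position"), drop = FALSE]
  tlog$n_molecules <- 0L; tlog$n_mod <- 0L; tlog$n_stop <- 0L; tlog$n_mis <- 0L
  for (rid in names(refs)) {
    rseq <- refs$seq[[rid]]
    L <- nchar(rseq)
    n <- as.integer(coverage)
    start <- rep(1L, n)
    seqs <- rep(rseq, n)
    tr <- truths[truths$ref_id == rid, , drop = FALSE]
    if (treated && nrow(tr) > 0) {
      tr <- tr[order(-tr$position), , drop = FALSE]  # 3'-most first: RT order
      stopped <- rep(FALSE, n)
      for (j in seq_len(nrow(tr))) {
        s <- tr$position[j]
        reached <- !stopped  # a prior (3'-ward) stop masks this site
        mod <- reached & stats::runif(n) < tr$stoichiometry[j]
        stp <- mod & stats::runif(n) < tr$p_stop_given_mod[j]
        # conditional branch: mis given modified and not stopped
        p_mis_cond <- if (tr$p_stop_given_mod[j] < 1)
          tr$p_mis_given_mod[j] / (1 - tr$p_stop_given_mod[j]) else 0
        mis <- mod & !stp & stats::runif(n) < p_mis_cond
        k <- match(paste(rid, s), paste(tlog$ref_id, tlog$position))
        tlog$n_molecules[k] <- tlog$n_molecules[k] + sum(reached)
        tlog$n_mod[k] <- tlog$n_mod[k] + sum(mod)
        tlog$n_stop[k] <- tlog$n_stop[k] + sum(stp)
        tlog$n_mis[k] <- tlog$n_mis[k] + sum(mis)
        if (any(mis)) substr(seqs[mis], s, s) <- "T"
        start[stp] <- s - 1L
        stopped <- stopped | stp
      }
    } else if (nrow(tr) > 0) {
      k <- match(paste(rid, tr$position), paste(tlog$ref_id, tlog$position))
      tlog$n_molecules[k] <- tlog$n_molecules[k] + n
    }
    seqs <- .apply_errors(seqs, error_rate)
    seqs <- substr(seqs, start, nchar(seqs))
    all_ids <- c(all_ids, paste0(rid, "_m", seq_len(n)))
    all_ref <- c(all_ref, rep(rid, n))
    all_start <- c(all_start, start)
    all_seq <- c(all_seq, seqs)
  }
  out <- alignment_set(all_ids, all_ref, all_start, all_seq)
  attr(out, "truth") <- tlog
  out
}
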