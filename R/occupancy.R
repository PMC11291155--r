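# E/P/A-site codon occupancy from ribosome footprints.
#
# A footprint's A-site codon index is floor((start - 1 + offset(length))/3)
# + 1 in 1-based codons; P = A - 1, E = A - 2. Per included transcript the
# density at codon i is the read count at i divided by the mean count over
# included codons (so each transcript's mean density is exactly 1), and a
# codon's occupancy is the unweighted mean of density over all included
# occurrences of that codon across transcripts.

#' Footprint-length to A-site-offset table
#'
#' The offset is the distance in nt from the footprint 5' end to the first
#' nt of the A-site codon (for disomes, the A site of the leading — i.e.
#' stalled — ribosome). Footprint lengths absent from the table are
#' rejected. Defaults follow common ribosome-profiling practice:
#' monosome \{28: 12, 29: 12, 30: 13\}, disome \{59..63: 45\}.
#'
#' @param kind `"monosome"` or `"disome"`.
#' @param offsets Optional named list/vector, footprint length -> offset
#'   (nt), overriding the defaults.
#' @return An object of class `offset_table`.
#' @export
default_offsets <- function(kind = c("monosome", "disome"), offsets = NULL) {
  kind <- match.arg(kind)
  if (is.null(offsets))
    offsets <- if (kind == "monosome") list(`28` = 12, `29` = 12, `30` = 13)
               else stats::setNames(as.list(rep(45, 5)), 59:63)
  offsets <- as.list(offsets)
  if (is.null(names(offsets)) || any(names(offsets) == ""))
    stop("offsets must be named by footprint length")
  structure(list(kind = kind, offsets = offsets), class = "offset_table")
}

#' Assign E/P/A-site codon indices to footprints
#'
#' @param start Integer vector of footprint 5' positions (1-based).
#' @param length Integer vector of footprint lengths (nt).
#' @param offsets An [default_offsets()] table.
#' @param cds_codons CDS length in codons (scalar or per-footprint vector).
#' @return data.frame with columns `A`, `P`, `E` (NA where the footprint is
#'   rejected: unlisted length, E index < 1, or A index beyond the CDS) and
#'   attribute `n_rejected`.
#' @export
assign_sites <- function(start, length, offsets, cds_codons) {
  stopifnot(inherits(offsets, "offset_table"))
  offmap <- unlist(offsets$offsets)
  off <- unname(offmap[as.character(length)])
  a <- ((start - 1 + off) %/% 3) + 1
  p <- a - 1; e <- a - 2
  bad <- is.na(off) | e < 1 | a > cds_codons
  a[bad] <- NA_integer_; p[bad] <- NA_integer_; e[bad] <- NA_integer_
  structure(data.frame(A = a, P = p, E = e), n_rejected = sum(bad))
}

# Internal: per-transcript read counts at the chosen site over included
# codons. Returns list(counts = list of per-transcript count vectors over
# included indices, included = list of included codon index ranges,
# codons = list of codon vectors, n_rejected).
.site_counts <- function(footprints, cds, offsets, site,
                         exclude_start, exclude_end) {
  stopifnot(inherits(cds, "ReferenceSet"))
  site <- match.arg(site, c("A", "P", "E"))
  len <- ref_lengths(cds)
  if (any(len %% 3 != 0)) stop("CDS length not divisible by 3")
  ncod <- len %/% 3
  fp <- as.data.frame(footprints)
  fp$width <- nchar(fp$aligned)
  idx <- assign_sites(fp$start, fp$width, offsets,
                      ncod[fp$ref_id])[[site]]
  n_rej <- sum(is.na(idx))
  keep <- !is.na(idx)
  fp <- fp[keep, , drop = FALSE]; idx <- idx[keep]
  out_counts <- list(); out_inc <- list(); out_cod <- list()
  for (t in names(cds)) {
    n <- ncod[[t]]
    inc <- seq.int(exclude_start + 1L, n - exclude_end)
    if (length(inc) < 1) stop("exclusion windows leave no codons for ", t)
    cnt <- tabulate(idx[fp$ref_id == t], nbins = n)[inc]
    out_counts[[t]] <- cnt
    out_inc[[t]] <- inc
    s <- cds$seq[[t]]
    out_cod[[t]] <- substring(s, 3 * inc - 2, 3 * inc)
  }
  list(counts = out_counts, included = out_inc, codons = out_cod,
       n_rejected = n_rej)
}

#' Per-codon site occupancy from footprints
#'
#' @param footprints An [alignment_set()] of footprints.
#' @param cds A [reference_set()] of coding sequences.
#' @param offsets An [default_offsets()] table matching the library kind.
#' @param site `"A"`, `"P"` or `"E"`.
#' @param exclude_start,exclude_end Codons trimmed from the CDS start/end
#'   to remove initiation/termination artifacts (defaults 15 and 5).
#' @param min_reads_per_transcript Transcripts with fewer site-assigned
#'   reads in the included region are excluded (default 64).
#' @return data.frame of class `occupancy_table` with columns `codon`,
#'   `amino_acid`, `occupancy` (mean normalized density) and `n`
#'   (occurrences averaged over); attributes `site`, `n_transcripts`,
#'   `n_rejected`.
#' @export
codon_occupancy <- function(footprints, cds, offsets, site = "A",
                            exclude_start = 15, exclude_end = 5,
                            min_reads_per_transcript = 64) {
  sc <- .site_counts(footprints, cds, offsets, site, exclude_start, exclude_end)
  dens <- list(); cods <- list()
  for (t in names(sc$counts)) {
    cnt <- sc$counts[[t]]
    if (sum(cnt) < min_reads_per_transcript) next
    dens[[t]] <- cnt / mean(cnt)
    cods[[t]] <- sc$codons[[t]]
  }
  if (length(dens) == 0) stop("no transcript passes min_reads_per_transcript")
  d <- unlist(dens, use.names = FALSE)
  cc <- unlist(cods, use.names = FALSE)
  occ <- tapply(d, factor(cc, levels = .SENSE_CODONS), mean)
  n <- tapply(rep(1L, length(cc)), factor(cc, levels = .SENSE_CODONS), sum)
  out <- data.frame(codon = .SENSE_CODONS,
                    amino_acid = codon_aa(.SENSE_CODONS),
                    occupancy = as.numeric(occ),
                    n = ifelse(is.na(n), 0L, as.integer(n)))
  structure(out, class = c("occupancy_table", "data.frame"),
            site = site, n_transcripts = length(dens),
            n_rejected = sc$n_rejected)
}

#' Per-codon occupancy ratio between two conditions
#'
#' @param ko,wt `occupancy_table`s computed with the same site and
#'   exclusion settings.
#' @param min_occurrences Codons with fewer occurrences in either table are
#'   omitted (default 100).
#' @return Named numeric vector, codon -> ko/wt occupancy ratio. Codons
#'   with zero wt occupancy are omitted with a warning.
#' @export
occupancy_ratio <- function(ko, wt, min_occurrences = 100) {
  stopifnot(inherits(ko, "occupancy_table"), inherits(wt, "occupancy_table"))
  m <- merge(as.data.frame(ko), as.data.frame(wt), by = "codon",
             suffixes = c("_ko", "_wt"))
  m <- m[m$n_ko >= min_occurrences & m$n_wt >= min_occurrences, , drop = FALSE]
  zero <- !is.na(m$occupancy_wt) & m$occupancy_wt == 0
  if (any(zero)) {
    warning("omitting codon(s) with zero wt occupancy: ",
            paste(m$codon[zero], collapse = ", "))
    m <- m[!zero, , drop = FALSE]
  }
  m <- m[!is.na(m$occupancy_ko) & !is.na(m$occupancy_wt), , drop = FALSE]
  stats::setNames(m$occupancy_ko / m$occupancy_wt, m$codon)
}

#' Meta-codon density profile around a codon of interest
#'
#' Averages per-transcript normalized density vectors across all
#' occurrences of `center_codon` whose full window lies inside the
#' included region.
#'
#' @inheritParams codon_occupancy
#' @param center_codon Codon to center on (DNA or RNA alphabet).
#' @param window Half-window in codons (default 30).
#' @param min_local_coverage Minimum total reads in a window for the
#'   occurrence to contribute (default 1).
#' @return Numeric vector of length `2 * window + 1`, named by codon
#'   offset (-window .. window); attribute `n_occurrences`.
#' @export
metacodon_profile <- function(footprints, cds, offsets, center_codon,
                              window = 30, min_local_coverage = 1,
                              site = "A", exclude_start = 15, exclude_end = 5,
                              min_reads_per_transcript = 64) {
  if (window < 1) stop("window must be >= 1")
  center_codon <- normalize_seq(center_codon)
  sc <- .site_counts(footprints, cds, offsets, site, exclude_start, exclude_end)
  acc <- numeric(2 * window + 1)
  n_occ <- 0L
  for (t in names(sc$counts)) {
    cnt <- sc$counts[[t]]
    if (sum(cnt) < min_reads_per_transcript) next
    dens <- cnt / mean(cnt)
    hits <- which(sc$codons[[t]] == center_codon)
    hits <- hits[hits - window >= 1 & hits + window <= length(dens)]
    for (h in hits) {
      sl <- (h - window):(h + window)
      if (sum(cnt[sl]) < min_local_coverage) next
      acc <- acc + dens[sl]
      n_occ <- n_occ + 1L
    }
  }
  if (n_occ == 0) stop("no qualifying occurrence of ", center_codon)
  structure(stats::setNames(acc / n_occ, -window:window),
            n_occurrences = n_occ)
}
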