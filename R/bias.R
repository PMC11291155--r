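# Codon-composition statistics over transcript sets: per-codon fractions,
# amino-acid-family-relative fractions, group contents (U/A- vs C/G-rich
# Leu/Ser), group comparisons by Student's t, set-vs-background bias, and
# overlapping dipeptide enrichment.

#' Codon profile of one coding sequence
#'
#' @param cds A coding sequence (DNA or RNA alphabet, any case), length
#'   divisible by 3, no internal stop codons; a terminal stop is recorded
#'   but excluded from sense totals.
#' @param transcript_id Optional id stored in the profile.
#' @return A `codon_profile` list: `transcript_id`, `counts` (61 sense
#'   codons), `fractions` (of sense codons), `family_fractions` (within
#'   the codon's synonymous family; 0 when the family does not occur),
#'   `stop_codon` (terminal stop or NA), `n_sense`.
#' @export
codon_counts <- function(cds, transcript_id = NA_character_) {
  s <- normalize_seq(cds)
  if (nchar(s) %% 3 != 0) stop("CDS length not divisible by 3")
  .check_alphabet(s)
  cod <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  n <- length(cod)
  stop_codon <- NA_character_
  if (n > 0 && cod[n] %in% .STOP_CODONS) {
    stop_codon <- cod[n]
    cod <- cod[-n]
  }
  internal <- which(cod %in% .STOP_CODONS)
  if (length(internal) > 0)
    stop("internal stop codon at codon index ", internal[1])
  counts <- table(factor(cod, levels = .SENSE_CODONS))
  counts <- stats::setNames(as.integer(counts), .SENSE_CODONS)
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else counts * 0
  aa <- codon_aa(.SENSE_CODONS)
  fam_tot <- tapply(counts, aa, sum)[aa]
  family_fractions <- ifelse(fam_tot > 0, counts / fam_tot, 0)
  structure(list(transcript_id = transcript_id,
                 counts = counts,
                 fractions = fractions,
                 family_fractions = stats::setNames(family_fractions, .SENSE_CODONS),
                 stop_codon = stop_codon, n_sense = total),
            class = "codon_profile")
}

#' Codon profiles for every sequence of a ReferenceSet
#' @param refs A [reference_set()] of coding sequences.
#' @return List of [codon_counts()] profiles, named by reference id.
#' @export
codon_profiles <- function(refs) {
  stopifnot(inherits(refs, "ReferenceSet"))
  stats::setNames(lapply(names(refs), function(i)
    codon_counts(refs$seq[[i]], transcript_id = i)), names(refs))
}

#' Combined content of a codon group in one transcript
#'
#' @param profile A `codon_profile`.
#' @param group Non-empty character vector of codons (e.g. an entry of
#'   [codon_groups]).
#' @param denominator `"all_sense"` (fraction of all sense codons) or
#'   `"family"` (fraction of the group's amino-acid family); both are
#'   exposed because published "combined codon content" figures use both
#'   normalizations.
#' @return A fraction, or `NA` when the family denominator is zero (the
#'   transcript lacks the family).
#' @export
group_content <- function(profile, group, denominator = c("all_sense", "family")) {
  stopifnot(inherits(profile, "codon_profile"), length(group) > 0)
  denominator <- match.arg(denominator)
  group <- normalize_seq(group)
  bad <- setdiff(group, .SENSE_CODONS)
  if (length(bad) > 0) stop("not a sense codon: ", paste(bad, collapse = ", "))
  num <- sum(profile$counts[group])
  if (denominator == "all_sense") {
    if (profile$n_sense == 0) return(NA_real_)
    return(num / profile$n_sense)
  }
  aa <- unique(codon_aa(group))
  if (length(aa) > 1) stop("family denominator requires a single-family group")
  fam <- .SENSE_CODONS[codon_aa(.SENSE_CODONS) == aa]
  den <- sum(profile$counts[fam])
  if (den == 0) return(NA_real_)
  num / den
}

#' Two-sample Student's t comparison of group contents
#'
#' Classic two-tailed pooled-variance Student's t test, with the usual
#' significance-star convention (* p<0.05, ** p<0.01, *** p<0.001, ns).
#'
#' @param values_a,values_b Numeric vectors (length >= 2, finite).
#' @return list(`t_statistic`, `df`, `p_value`, `stars`).
#' @export
compare_groups <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]; values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 finite values")
  if (any(!is.finite(values_a)) || any(!is.finite(values_b)))
    stop("non-finite values")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    eq <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(list(t_statistic = if (eq) 0 else Inf,
                df = length(values_a) + length(values_b) - 2,
                p_value = if (eq) 1 else 0,
                stars = if (eq) "ns" else "***"))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = p, stars = stars)
}

#' Per-codon bias of a transcript set against a background
#'
#' @param set_profiles,background_profiles Non-empty lists of
#'   `codon_profile`s.
#' @param mode `"absolute"`: difference of mean per-transcript codon
#'   fractions. `"family_relative"`: the same difference on
#'   family-relative fractions, with transcripts lacking the family
#'   excluded from that codon's mean.
#' @param average `"per_transcript"` (default): each transcript
#'   contributes one fraction vector and transcripts are averaged
#'   unweighted. `"pooled"` (absolute mode only): counts are summed over
#'   the concatenated coding sequence before taking fractions, weighting
#'   long transcripts more.
#' @return Named numeric vector over the 61 sense codons (set minus
#'   background; positive = over-represented in the set).
#' @export
bias_vs_background <- function(set_profiles, background_profiles,
                               mode = c("absolute", "family_relative"),
                               average = c("per_transcript", "pooled")) {
  mode <- match.arg(mode)
  average <- match.arg(average)
  if (average == "pooled" && mode != "absolute")
    stop("pooled averaging is defined for absolute mode only")
  stopifnot(length(set_profiles) > 0, length(background_profiles) > 0)
  mean_frac <- function(profiles) {
    if (mode == "absolute") {
      if (average == "pooled") {
        tot <- rowSums(sapply(profiles, function(p) p$counts))
        return(tot / sum(tot))
      }
      m <- sapply(profiles, function(p) p$fractions)
      rowMeans(m)
    } else {
      aa <- codon_aa(.SENSE_CODONS)
      m <- sapply(profiles, function(p) p$family_fractions)
      has <- sapply(profiles, function(p) {
        fam_tot <- tapply(p$counts, aa, sum)[aa]
        fam_tot > 0
      })
      num <- rowSums(m * has)
      den <- rowSums(has)
      out <- ifelse(den > 0, num / den, NA_real_)
      stats::setNames(out, .SENSE_CODONS)
    }
  }
  mean_frac(set_profiles) - mean_frac(background_profiles)
}

#' Overlapping dipeptide enrichment of a set against a background
#'
#' Amino-acid pairs are counted with overlap (positions i, i+1 for all i)
#' over each transcript's translation; pair frequencies are pooled within
#' each set. Fold = (set frequency + pc) / (background frequency + pc)
#' with pc = 0.5 / total pairs; p-values from a two-proportion test; BH
#' q-values over the 400 pairs.
#'
#' @param set_cds,background_cds [reference_set()]s of the coding
#'   sequences in the two groups.
#' @return data.frame: `pair`, `fold`, `p_value`, `q_value`, plus the raw
#'   pooled counts `n_set`, `n_background`.
#' @export
dipeptide_enrichment <- function(set_cds, background_cds) {
  pair_counts <- function(x) {
    seqs <- if (inherits(x, "ReferenceSet")) unname(x$seq)
            else stop("dipeptide_enrichment expects ReferenceSets of CDS")
    aa_levels <- sort(unique(unname(.GENETIC_CODE[.SENSE_CODONS])))
    pairs <- as.vector(outer(aa_levels, aa_levels, paste0))
    acc <- stats::setNames(integer(length(pairs)), pairs)
    for (s in seqs) {
      aa <- strsplit(suppressWarnings(
        as.character(Biostrings::translate(Biostrings::DNAString(normalize_seq(s)),
                                           no.init.codon = TRUE))), "")[[1]]
      aa <- aa[aa != "*"]
      if (length(aa) < 2) {
        warning("transcript too short to contribute dipeptides; skipped")
        next
      }
      pp <- paste0(aa[-length(aa)], aa[-1])
      t <- table(pp)
      acc[names(t)] <- acc[names(t)] + as.integer(t)
    }
    acc
  }
  cs <- pair_counts(set_cds)
  cb <- pair_counts(background_cds)
  ts <- sum(cs); tb <- sum(cb)
  if (ts == 0 || tb == 0) stop("no dipeptides counted")
  pc <- 0.5 / (ts + tb)  # one shared pseudocount so absent pairs give fold 1
  fold <- (cs / ts + pc) / (cb / tb + pc)
  p <- vapply(seq_along(cs), function(i) {
    if (cs[i] + cb[i] == 0) return(1)
    suppressWarnings(stats::prop.test(c(cs[i], cb[i]), c(ts, tb))$p.value)
  }, 0)
  p[is.na(p)] <- 1
  data.frame(pair = names(cs), fold = unname(fold), p_value = p,
             q_value = stats::p.adjust(p, method = "BH"),
             n_set = unname(cs), n_background = unname(cb))
}
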