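# Mendelian expectations and segregation statistics for breeding data over
# independent biallelic loci (independent assortment assumed; the loci of
# interest lie on different chromosomes).

#' Expected Mendelian genotype fractions for a cross
#'
#' Product over loci of per-locus transmission probabilities: a
#' heterozygote transmits each allele with probability 1/2, a homozygote
#' its allele with probability 1.
#'
#' @param parent1,parent2 Character vectors of per-locus genotypes
#'   (`"+/+"`, `"+/-"`, `"-/-"`), optionally named by locus.
#' @return data.frame with one column per locus plus `expected`
#'   (fractions summing to 1).
#' @export
expected_mendelian <- function(parent1, parent2) {
  stopifnot(length(parent1) == length(parent2))
  parent1 <- .norm_genotype(parent1); parent2 <- .norm_genotype(parent2)
  loci <- names(parent1)
  if (is.null(loci)) loci <- paste0("locus", seq_along(parent1))
  per_locus <- lapply(seq_along(loci), function(j) {
    p1 <- .gamete_probs(parent1[j]); p2 <- .gamete_probs(parent2[j])
    probs <- c("+/+" = 0, "+/-" = 0, "-/-" = 0)
    for (x in names(p1)) for (y in names(p2)) {
      g <- if (x == "+" && y == "+") "+/+"
           else if (x == "-" && y == "-") "-/-" else "+/-"
      probs[g] <- probs[g] + p1[[x]] * p2[[y]]
    }
    probs[probs > 0]
  })
  grid <- expand.grid(lapply(per_locus, names), stringsAsFactors = FALSE)
  names(grid) <- loci
  p <- Reduce(`*`, lapply(seq_along(loci), function(j)
    per_locus[[j]][grid[[j]]]))
  grid$expected <- unname(p)
  grid
}

#' Chi-square goodness of fit of observed genotype counts
#'
#' Pearson chi-square over categories with positive expectation; an
#' observed count in a zero-expectation category is an impossible outcome
#' and errors. A warning recommends an exact test when any expected count
#' is below 1.
#'
#' @param observed A `genotype_counts` data.frame (locus columns +
#'   `count`).
#' @param expected data.frame from [expected_mendelian()] (locus columns
#'   + `expected`), covering the observed categories.
#' @return list(`chi2`, `df`, `p_value`, `expected_counts`).
#' @export
goodness_of_fit <- function(observed, expected) {
  loci <- setdiff(names(expected), "expected")
  stopifnot(all(loci %in% names(observed)), "count" %in% names(observed))
  key_o <- do.call(paste, c(observed[loci], sep = ";"))
  key_e <- do.call(paste, c(expected[loci], sep = ";"))
  total <- sum(observed$count)
  if (total <= 0) stop("no observations")
  obs <- stats::setNames(rep(0, length(key_e)), key_e)
  hit <- match(key_o, key_e)
  if (any(is.na(hit) & observed$count > 0))
    stop("observed genotype with expected fraction 0: ",
         paste(key_o[is.na(hit) & observed$count > 0], collapse = ", "))
  obs[key_e[hit[!is.na(hit)]]] <- observed$count[!is.na(hit)]
  e <- expected$expected * total
  if (any(e < 1))
    warning("expected count below 1 in some category; consider an exact test")
  chi2 <- sum((obs - e)^2 / e)
  df <- sum(expected$expected > 0) - 1
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       expected_counts = stats::setNames(e, key_e))
}

#' Compare a target-genotype frequency across genetic backgrounds
#'
#' 2 x k contingency test of target vs other counts across backgrounds:
#' Fisher's exact test for two backgrounds (or whenever an expected cell
#' is below 5), Pearson chi-square otherwise.
#'
#' @param counts_by_background Named list, background -> numeric vector
#'   `c(target, other)`; backgrounds with zero total are excluded with a
#'   warning.
#' @return list(`method`, `statistic` (NA for the exact test),
#'   `p_value`, `table`).
#' @export
compare_backgrounds <- function(counts_by_background) {
  m <- do.call(cbind, lapply(counts_by_background, function(x) x[1:2]))
  rownames(m) <- c("target", "other")
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning("excluding background(s) with zero total: ",
            paste(colnames(m)[tot == 0], collapse = ", "))
    m <- m[, tot > 0, drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least 2 backgrounds with observations")
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  if (ncol(m) == 2 || any(e < 5)) {
    list(method = "fisher", statistic = NA_real_,
         p_value = stats::fisher.test(m)$p.value, table = m)
  } else {
    ct <- stats::chisq.test(m, correct = FALSE)
    list(method = "chisq", statistic = unname(ct$statistic),
         p_value = ct$p.value, table = m)
  }
}
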