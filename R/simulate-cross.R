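# Offspring simulator for genetic crosses over independent biallelic loci,
# with per-genotype viability — the ground truth behind sub-Mendelian
# segregation analyses.

#' Per-genotype viability map
#'
#' @param ... Named survival fractions in `[0, 1]`; names are genotype
#'   tuples as produced by [genotype_label()] (per-locus genotypes joined
#'   by `";"`). Genotypes not listed survive with probability 1.
#' @return Named numeric vector of class `viability_map`.
#' @export
viability_map <- function(...) {
  v <- c(...)
  if (length(v) > 0 && (any(v < 0) || any(v > 1)))
    stop("viability must be in [0, 1]")
  structure(v, class = "viability_map")
}

.norm_genotype <- function(g) {
  ok <- grepl("^[+-]/[+-]$", g)
  if (any(!ok)) stop("malformed genotype string: ", paste(g[!ok], collapse = ", "))
  # canonical order: "+" allele first
  ifelse(g == "-/+", "+/-", g)
}

#' Label for a multi-locus genotype tuple
#' @param ... Per-locus genotype strings (`"+/+"`, `"+/-"`, `"-/-"`).
#' @return Single string with loci joined by `";"`.
#' @export
genotype_label <- function(...) paste(.norm_genotype(c(...)), collapse = ";")

.gamete_probs <- function(g) {
  switch(g,
         "+/+" = c("+" = 1),
         "+/-" = c("+" = 0.5, "-" = 0.5),
         "-/-" = c("-" = 1),
         stop("malformed genotype string: ", g))
}

#' Simulate a cross with per-genotype viability
#'
#' Gametes are drawn independently per locus from each parent;
#' `n_offspring` conceptions are generated and each survives with
#' probability `viability[genotype]` (default 1). Counts of surviving
#' offspring are returned; ground-truth conception counts are attached as
#' attribute `conceived`.
#'
#' @param parent1,parent2 Character vectors of per-locus genotypes
#'   (`"+/+"`, `"+/-"`, `"-/-"`), optionally named by locus.
#' @param n_offspring Number of conceptions.
#' @param viability A [viability_map()] (or NULL for full viability).
#' @param seed Integer seed.
#' @return A `genotype_counts` data.frame: one column per locus plus
#'   `count`, with attributes `total` (surviving) and `conceived`.
#' @export
simulate_cross <- function(parent1, parent2, n_offspring,
                           viability = NULL, seed = 1) {
  stopifnot(length(parent1) == length(parent2), n_offspring >= 1)
  if (!is.null(viability) && !inherits(viability, "viability_map"))
    viability <- viability_map(viability)
  parent1 <- .norm_genotype(parent1); parent2 <- .norm_genotype(parent2)
  loci <- names(parent1)
  if (is.null(loci)) loci <- paste0("locus", seq_along(parent1))
  set.seed(seed)
  geno <- matrix("", nrow = n_offspring, ncol = length(loci))
  for (j in seq_along(loci)) {
    p1 <- .gamete_probs(parent1[j]); p2 <- .gamete_probs(parent2[j])
    a1 <- sample(names(p1), n_offspring, replace = TRUE, prob = p1)
    a2 <- sample(names(p2), n_offspring, replace = TRUE, prob = p2)
    geno[, j] <- ifelse(a1 == "+" & a2 == "+", "+/+",
                 ifelse(a1 == "-" & a2 == "-", "-/-", "+/-"))
  }
  label <- apply(geno, 1, paste, collapse = ";")
  surv_p <- rep(1, n_offspring)
  if (!is.null(viability) && length(viability) > 0) {
    hit <- match(label, names(viability))
    surv_p[!is.na(hit)] <- unclass(viability)[hit[!is.na(hit)]]
  }
  alive <- stats::runif(n_offspring) < surv_p
  tab_all <- table(label)
  tab_liv <- table(label[alive])
  out <- genotype_counts_from_labels(names(tab_all), as.integer(tab_liv[names(tab_all)]),
                                     loci)
  out$count[is.na(out$count)] <- 0L
  attr(out, "conceived") <- stats::setNames(as.integer(tab_all), names(tab_all))
  attr(out, "total") <- sum(out$count)
  out
}

# build a genotype_counts data.frame from ";"-joined labels
genotype_counts_from_labels <- function(labels, counts, loci) {
  parts <- do.call(rbind, strsplit(labels, ";", fixed = TRUE))
  df <- stats::setNames(as.data.frame(parts, stringsAsFactors = FALSE), loci)
  df$count <- as.integer(counts)
  structure(df, class = c("genotype_counts", "data.frame"),
            total = sum(counts, na.rm = TRUE))
}

#' Construct a genotype-count table
#'
#' @param counts Named integer vector: genotype tuple label (per-locus
#'   genotypes joined by `";"`, see [genotype_label()]) -> offspring count.
#' @param loci Character vector of locus names (one per `";"` field).
#' @return A `genotype_counts` data.frame with attribute `total`.
#' @export
genotype_counts <- function(counts, loci) {
  if (any(counts < 0)) stop("counts must be non-negative")
  genotype_counts_from_labels(names(counts), counts, loci)
}
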