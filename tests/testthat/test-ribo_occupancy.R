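test_that("site assignment arithmetic and rejections", {
  off <- default_offsets("monosome")
  idx <- assign_sites(1L, 28L, off, 100)
  expect_equal(idx$A, 5L)  # floor(12 / 3) + 1
  expect_equal(idx$P, 4L)
  expect_equal(idx$E, 3L)

  # A-site beyond the last codon
  far <- assign_sites(3L * 99L + 1L - 12L + 30L, 28L, off, 100)
  expect_true(is.na(far$A))
  # unlisted footprint length
  odd <- assign_sites(c(1L, 1L), c(28L, 31L), off, 100)
  expect_true(is.na(odd$A[2]))
  expect_equal(attr(odd, "n_rejected"), 1L)
})

# build footprints that put exactly `counts[i]` reads with their A site on
# codon i of a single transcript (length-28 monosome geometry)
fp_at_codons <- function(cds_id, counts) {
  idx <- rep(seq_along(counts), counts)
  start <- 3L * (idx - 1L) + 1L - 12L
  alignment_set(paste0("r", seq_along(idx)), rep(cds_id, length(idx)),
                start, rep(strrep("A", 28), length(idx)))
}

test_that("uniform reads give occupancy exactly 1 everywhere", {
  cds <- uniform_cds(1, 60, seed = 7)
  counts <- integer(60); counts[16:55] <- 3L
  fp <- fp_at_codons("cds1", counts)
  occ <- codon_occupancy(fp, cds, default_offsets("monosome"))
  present <- occ[occ$n > 0, ]
  expect_true(all(abs(present$occupancy - 1) < 1e-12))
})

test_that("occupancy matches a hand-computed toy exactly", {
  # 40 codons; included region is 16..35 (20 codons) under default trims
  interior <- rep(c("TTA", "GCA", "GAA", "CCA"), 10)[1:38]
  cds <- reference_set(c(t = paste0("ATG", paste(interior, collapse = ""), "TAA")))
  counts <- integer(40)
  codv <- c("ATG", interior, "TAA")
  counts[16:35] <- ifelse(codv[16:35] == "TTA", 8L, 4L)
  fp <- fp_at_codons("t", counts)
  occ <- codon_occupancy(fp, cds, default_offsets("monosome"),
                         min_reads_per_transcript = 1)
  # hand oracle: 5 TTA occurrences at 8 reads, 15 others at 4 reads
  mean_reads <- (5 * 8 + 15 * 4) / 20
  expect_equal(occ$occupancy[occ$codon == "TTA"], 8 / mean_reads)
  expect_equal(occ$occupancy[occ$codon == "GCA"], 4 / mean_reads)
  expect_equal(occ$n[occ$codon == "TTA"], 5L)
})

test_that("transcripts under the read floor are excluded", {
  cds <- uniform_cds(2, 60, seed = 8)
  counts_hi <- integer(60); counts_hi[16:55] <- 2L  # 80 reads
  counts_lo <- integer(60); counts_lo[20] <- 10L    # 10 reads < 64
  fp <- alignment_set(
    c(paste0("a", 1:80), paste0("b", 1:10)),
    c(rep("cds1", 80), rep("cds2", 10)),
    c(rep(3L * (rep(16:55, each = 2) - 1L) + 1L - 12L, 1),
      rep(3L * (20L - 1L) + 1L - 12L, 10)),
    rep(strrep("A", 28), 90))
  occ <- codon_occupancy(fp, cds, default_offsets("monosome"))
  expect_equal(attr(occ, "n_transcripts"), 1L)

  expect_error(codon_occupancy(fp, cds, default_offsets("monosome"),
                               min_reads_per_transcript = 1000),
               "no transcript")
})

test_that("per-transcript mean density is 1 to numerical precision", {
  cds <- uniform_cds(4, 100, seed = 9)
  fp <- simulate_footprints(cds, dwell_model(c(CTT = 2)), 40000, "monosome",
                            seed = 10)
  sc <- ac4ctools:::.site_counts(fp, cds, default_offsets("monosome"), "A",
                                 15, 5)
  for (t in names(sc$counts)) {
    d <- sc$counts[[t]] / mean(sc$counts[[t]])
    expect_lt(abs(mean(d) - 1), 1e-9)
  }
})

test_that("occupancy ratios filter on occurrences and flag zero denominators", {
  tab <- function(occ, n) {
    structure(data.frame(codon = c("TTA", "GCA"), amino_acid = c("L", "A"),
                         occupancy = occ, n = n),
              class = c("occupancy_table", "data.frame"), site = "A")
  }
  r <- occupancy_ratio(tab(c(2, 1), c(200, 200)), tab(c(1, 1), c(200, 200)),
                       min_occurrences = 100)
  expect_equal(unname(r["TTA"]), 2)
  expect_equal(unname(r["GCA"]), 1)

  r2 <- occupancy_ratio(tab(c(2, 1), c(200, 50)), tab(c(1, 1), c(200, 200)),
                        min_occurrences = 100)
  expect_false("GCA" %in% names(r2))

  expect_warning(r3 <- occupancy_ratio(tab(c(2, 1), c(200, 200)),
                                       tab(c(0, 1), c(200, 200)),
                                       min_occurrences = 100),
                 "zero wt occupancy")
  expect_false("TTA" %in% names(r3))
})

test_that("meta-codon profiles are flat under uniform reads and peak on dwell", {
  cds <- uniform_cds(1, 120, seed = 11)
  counts <- integer(120); counts[16:115] <- 4L
  fp <- fp_at_codons("cds1", counts)
  prof <- metacodon_profile(fp, cds, default_offsets("monosome"),
                            center_codon = "GCA", window = 5,
                            min_reads_per_transcript = 1)
  expect_true(all(abs(prof - 1) < 1e-12))
  expect_equal(names(prof)[1], "-5")

  cds2 <- uniform_cds(6, 150, seed = 12)
  fp2 <- simulate_footprints(cds2, dwell_model(c(TTG = 3)), 120000,
                             "monosome", seed = 13)
  prof2 <- metacodon_profile(fp2, cds2, default_offsets("monosome"),
                             center_codon = "TTG", window = 10)
  expect_gt(prof2[["0"]], 2 * stats::median(prof2))

  # occurrences too close to the CDS end are excluded; none left -> error
  cds3 <- reference_set(c(z = paste0("ATG", strrep("GCA", 30),
                                     "TTG", strrep("GAA", 4), "TAA")))
  fp3 <- fp_at_codons("z", { x <- integer(37); x[16:32] <- 4L; x })
  expect_error(metacodon_profile(fp3, cds3, default_offsets("monosome"),
                                 center_codon = "TTG", window = 30,
                                 min_reads_per_transcript = 1),
               "no qualifying occurrence")
})

test_that("translation-efficiency ratios and classification", {
  rpf <- c(g1 = 100, g2 = 200, g3 = 300)
  rna <- c(g1 = 1000, g2 = 2000, g3 = 3000)
  te <- translation_efficiency(rpf, rna, pseudocount = 0)
  expect_equal(unname(te), rep(1, 3))
  cls <- classify_te(te, te)
  expect_true(all(cls$class == "unchanged"))

  rpf_b <- rpf; rpf_b["g2"] <- 50
  te_b <- translation_efficiency(rpf_b, rna, pseudocount = 0)
  d <- classify_te(te, te_b)
  g2 <- d[d$transcript_id == "g2", ]
  # halving g2's footprint share also lifts the others' shares slightly
  expect_lt(g2$delta_log2_te, -1)
  expect_equal(g2$class, "down")

  expect_error(translation_efficiency(c(a = 0), c(a = 0)), "zero total")
})

test_that("injected TE shifts are classified correctly at deep counts", {
  set.seed(14)
  n <- 60
  ids <- paste0("g", seq_len(n))
  rna_p <- rep(1 / n, n)
  shift <- rep(1, n); shift[1:10] <- 4; shift[11:20] <- 0.25
  rpf_p <- rna_p * shift; rpf_p <- rpf_p / sum(rpf_p)
  rna_a <- stats::setNames(as.integer(rmultinom(1, 10000 * n, rna_p)), ids)
  rpf_a <- stats::setNames(as.integer(rmultinom(1, 10000 * n, rna_p)), ids)
  rpf_b <- stats::setNames(as.integer(rmultinom(1, 10000 * n, rpf_p)), ids)
  te_a <- translation_efficiency(rpf_a, rna_a)
  te_b <- translation_efficiency(rpf_b, rna_a)
  cls <- classify_te(te_a, te_b)
  truth <- ifelse(shift == 4, "up", ifelse(shift == 0.25, "down", "unchanged"))
  expect_gte(mean(cls$class == truth), 0.95)
})
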