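test_that("synthetic tRNA references carry the CCG consensus where asked", {
  refs <- make_trna_references(4, c("iso2", "iso3"), length = 76, seed = 11)
  expect_equal(substr(refs$seq[["iso2"]], 11, 13), "CCG")
  expect_equal(substr(refs$seq[["iso3"]], 11, 13), "CCG")
  ann <- refs$annotations
  expect_setequal(ann$ref_id, c("iso2", "iso3"))
  expect_true(all(ann$position == 12))
  # non-acetylated families never present a C at 12 (so never CCG context)
  expect_false(substr(refs$seq[["iso1"]], 12, 12) == "C")
  expect_false(annotate_context(refs, "iso1", 12))

  refs2 <- make_trna_references(4, c("iso2", "iso3"), length = 76, seed = 11)
  expect_identical(refs2$seq, refs$seq)
  expect_error(make_trna_references(2, length = 19), ">= 20")
  expect_error(make_trna_references(2, "iso9"), "unknown")
})

test_that("probing-read simulator honours the site chemistry", {
  refs <- make_trna_references(1, "iso1", seed = 3)
  # stoichiometry 0, no error: clean reference signal
  t0 <- site_truth("iso1", 12, 0)
  aln <- simulate_ac4cseq_reads(refs, t0, coverage = 200, error_rate = 0,
                                seed = 5)
  pt <- pileup(aln, refs)
  expect_equal(pt$T[pt$position == 12], 0L)
  expect_equal(pt$start_count[pt$position == 11], 0L)

  # stoichiometry 1, p_stop 1: every molecule truncates to start at site - 1
  t1 <- site_truth("iso1", 12, 1, p_mis_given_mod = 0, p_stop_given_mod = 1)
  aln1 <- simulate_ac4cseq_reads(refs, t1, coverage = 100, error_rate = 0,
                                 seed = 5)
  expect_true(all(aln1$start == 11L))

  expect_error(simulate_ac4cseq_reads(refs, site_truth("iso1", 200, 0.5),
                                      coverage = 10),
               "outside")
})

test_that("misincorporation fraction tracks the simulator's own event log", {
  refs <- make_trna_references(1, "iso1", seed = 3)
  tr <- site_truth("iso1", 12, 0.5, p_mis_given_mod = 0.8, p_stop_given_mod = 0)
  aln <- simulate_ac4cseq_reads(refs, tr, coverage = 10000, error_rate = 0,
                                seed = 7)
  truth <- attr(aln, "truth")
  pt <- pileup(aln, refs)
  obs_t <- pt$T[pt$position == 12]
  # observed Ts are exactly the logged misincorporation events
  expect_equal(obs_t, truth$n_mis)
  se <- sqrt(0.4 * 0.6 / 10000)
  expect_lt(abs(obs_t / 10000 - 0.4), 3 * se)
})

test_that("untreated controls carry only sequencing error", {
  refs <- make_trna_references(1, "iso1", seed = 3)
  tr <- site_truth("iso1", 12, 1, p_mis_given_mod = 1, p_stop_given_mod = 0)
  ctl <- simulate_ac4cseq_reads(refs, tr, coverage = 5000, error_rate = 0.01,
                                treated = FALSE, seed = 9)
  pt <- pileup(ctl, refs)
  # T rate at the site is error-level (error splits over 3 alternatives)
  rate <- pt$T[pt$position == 12] / pt$coverage[pt$position == 12]
  expect_lt(rate, 0.02)
  expect_equal(attr(ctl, "truth")$n_mis, 0L)
})

test_that("footprint simulator is seed-deterministic and placement-correct", {
  cds <- uniform_cds(3, 60)
  fp1 <- simulate_footprints(cds, dwell_model(), 2000, "monosome", seed = 21)
  fp2 <- simulate_footprints(cds, dwell_model(), 2000, "monosome", seed = 21)
  expect_identical(as.data.frame(fp1), as.data.frame(fp2))
  # the offset table recovers exactly the drawn A-site codon
  truth <- attr(fp1, "truth")
  idx <- assign_sites(fp1$start, nchar(fp1$aligned),
                      default_offsets("monosome"),
                      ref_lengths(cds)[fp1$ref_id] / 3)
  expect_equal(idx$A, truth$a_codon_index)

  bad <- reference_set(c(x = "ACGTA"))
  expect_error(simulate_footprints(bad, dwell_model(), 10), "divisible")
})

test_that("uniform dwell gives uniform A-site counts within one transcript", {
  cds <- uniform_cds(1, 200, seed = 5)
  fp <- simulate_footprints(cds, dwell_model(), 30000, "monosome",
                            length_weights = c(`28` = 1), seed = 13)
  truth <- attr(fp, "truth")
  # eligible A-site range for length 28, offset 12, on a 200-codon CDS
  cnt <- tabulate(truth$a_codon_index, nbins = 195)[5:195]
  gof <- chisq.test(cnt, p = rep(1 / length(cnt), length(cnt)))
  expect_gt(gof$p.value, 0.001)
})

test_that("an elevated dwell codon is drawn at its closed-form probability", {
  cds <- uniform_cds(2, 150, seed = 31)
  dm <- dwell_model(c(TTA = 3))
  n <- 50000
  fp <- simulate_footprints(cds, dm, n, "monosome",
                            length_weights = c(`28` = 1), seed = 17)
  truth <- attr(fp, "truth")
  # closed-form oracle: per transcript, P(TTA) = 3 nTTA / sum(weights) over
  # the eligible A-site range for length 28 (offset 12): codons 5..n-5
  len <- ref_lengths(cds)
  p_tta <- vapply(names(cds), function(t) {
    ncod <- len[[t]] / 3
    cod <- substring(cds$seq[[t]], seq(1, len[[t]] - 2, 3), seq(3, len[[t]], 3))
    rng <- 5:(ncod - 5)
    w <- ifelse(cod[rng] == "TTA", 3, 1)
    sum(w[cod[rng] == "TTA"]) / sum(w)
  }, 0)
  p_t <- len / sum(len)
  expected <- sum(p_t * p_tta)
  obs <- mean(truth$a_codon == "TTA")
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("codon-shifted CDS sets match their renormalized weights", {
  cds <- simulate_codon_shifted_cds(20, 100, seed = 41)
  expect_true(all(ref_lengths(cds) == 300))
  expect_true(all(substr(cds$seq, 1, 3) == "ATG"))
  expect_true(all(substr(cds$seq, 298, 300) %in% c("TAA", "TAG", "TGA")))

  sh <- simulate_codon_shifted_cds(50, 200, shifted = c(TTA = 2), seed = 43)
  p_exp <- attr(sh, "expected_freq")
  expect_equal(unname(p_exp["TTA"]), 2 / 62)  # 2 w / (60 w + 2 w), uniform base
  interior <- substring(sh$seq, 4, nchar(sh$seq) - 3)
  cod <- unlist(lapply(interior, function(s)
    substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))))
  n <- length(cod)
  obs <- mean(cod == "TTA")
  expect_lt(abs(obs - 2 / 62), 3 * sqrt((2 / 62) * (60 / 62) / n))

  expect_error(simulate_codon_shifted_cds(1, 2), ">= 3")
})

test_that("cross simulator reproduces Mendelian and viability ground truth", {
  x <- simulate_cross("+/-", "+/-", 20000, seed = 51)
  f <- x$count[x$locus1 == "-/-"] / attr(x, "total")
  expect_lt(abs(f - 0.25), 3 * sqrt(0.25 * 0.75 / 20000))

  xv <- simulate_cross("+/-", "+/-", 5000,
                       viability = viability_map("-/-" = 0), seed = 52)
  expect_false("-/-" %in% xv$locus1[xv$count > 0])
  expect_true("-/-" %in% names(attr(xv, "conceived")))

  # dihybrid double knockout at 1/16: oracle = exhaustive gamete enumeration
  gam <- expand.grid(a1 = c("+", "-"), a2 = c("+", "-"),
                     b1 = c("+", "-"), b2 = c("+", "-"),
                     stringsAsFactors = FALSE)
  p_dko <- mean(gam$a1 == "-" & gam$a2 == "-" & gam$b1 == "-" & gam$b2 == "-")
  expect_equal(p_dko, 1 / 16)
  xd <- simulate_cross(c(A = "+/-", B = "+/-"), c(A = "+/-", B = "+/-"),
                       32000, seed = 53)
  f_dko <- sum(xd$count[xd$A == "-/-" & xd$B == "-/-"]) / attr(xd, "total")
  expect_lt(abs(f_dko - 1 / 16), 3 * sqrt((1 / 16) * (15 / 16) / 32000))

  expect_error(viability_map("-/-" = 1.2), "\\[0, 1\\]")
})
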