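---
title: "Methods and conventions of the ac4ctools pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and conventions of the ac4ctools pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ac4ctools` re-implements, as a tested pipeline over synthetic data, the
computational analyses used to connect loss of Thumpd1/NAT10-dependent
N4-acetylcytidine (ac4C) in tRNA to its downstream consequences: calling
modification sites from chemical-probing sequencing, quantifying tRNA
isodecoders, measuring codon-resolved ribosome occupancy from monosome and
disome footprints, characterising codon-usage bias in translationally
affected transcript sets, and testing Mendelian segregation in crosses.
Every stage accepts standard formats (FASTA, a text SAM subset or an
equivalent TSV, headed TSV tables) and every stage has a matching
generator in the synthetic-data module that emits ground truth alongside
its reads, so the whole pipeline is exercisable without any external
download.

# Conventions

**Coordinates.** All positions are 1-based and inclusive on the mature
reference sequence: "C12" is the 12th nucleotide. Canonical (Sprinzl)
tRNA numbering is deliberately not implemented: the analyses quote
positions on mature sequences, and synthetic references are constructed
to match, with the acetylation consensus 5'-CCG-3' at positions 11--13
(the modified C is position 12, the middle of the triplet).

**Alphabet.** Sequences are stored as DNA (U converted to T on input) so
pileups, codon tables and references share one alphabet; `as_rna()`
renders U for display. Comparisons are always on DNA.

**Alignments.** The SAM reader handles the subset this pipeline needs:
single-end, forward-strand records with M/=/X/I/D/S/H CIGAR operations.
Insertions consume no reference position, deletions are carried as `-` in
the per-position base string, and soft clips are ignored for pileup
purposes. Reads mapped to unknown references are excluded and counted.
Paired-end logic, BAM indexing and genome-coordinate (pre-tRNA) handling
are out of scope.

# Modification calling (modcall)

The probing chemistry reduces ac4C so that reverse transcription either
misincorporates (read as C-to-T mutations in cDNA) or stops at the
modified base. The caller therefore measures, per reference-C position:

* **Misincorporation rate** `mrd = T / coverage`, where the denominator
  is total base-presenting coverage rather than C+T only. This is the
  mismatch-rate reading of a "C to T misincorporation rate" and is robust
  to stray non-T errors.
* **Significance**: a two-sided Fisher exact test on the 2x2 table of
  T vs non-T counts in treated and control libraries. Counts at tRNA
  scale are small enough that the exact test is both appropriate and
  cheap, and it admits a direct hypergeometric-enumeration oracle in the
  tests. The treated-vs-control formulation (rather than
  treated-vs-background-error) is used and documented here because it is
  the comparison the mock-treated control exists to support.
* **Multiple testing**: Benjamini--Hochberg across all tested C positions
  in the run, the field default.
* **Fold RT stop** at the position immediately 5' of a site: the ratio of
  depth-normalised read-start counts, treated over control. Start counts
  are normalised by total library depth (not local coverage) so that the
  statistic is invariant to scaling either library. Two special cases are
  fixed by convention: if the control has zero starts but the treated
  library does not, the ratio is the sentinel value 100; if both are
  zero, the ratio is 1 (no evidence either way).
* **Context**: whether the queried C is the middle of a CCG triplet, the
  consensus the acetyltransferase favours. Sequence edges return `FALSE`.

Default filters: a position is tested only when coverage exceeds 100
reads in both libraries; it passes when `mrd_treated >= 0.02` (sites
below 2% misincorporation are treated as noise or off-consensus signals),
`q <= 0.05`, and the treated rate exceeds the control rate. Zero
p-values are floored at the smallest representable positive double
rather than reported as 0.

The probing simulator models the chemistry with three parameters per
site: stoichiometry (fraction of molecules modified), a misincorporation
penetrance and a stop probability, constrained to sum to at most 1.
Reverse transcription walks 3' to 5', so when several sites could stop
the same molecule the 3'-most stop wins and masks sites 5' of it. A stop
is emitted as a read whose leftmost aligned position is `site - 1` —
the physical RT geometry is ambiguous, but this measured coordinate is
not. The untreated control carries the same uniform per-base error rate
with the modification channels switched off, since sequencing error is
library-independent to first order. The defaults used in tests
(penetrance 0.5, stop probability 0.2) are placeholders for exercising
the code, not biological claims.

# tRNA quantification (trna_quant)

Reads are assigned to isodecoders (distinct mature sequences) by Hamming
distance over the best ungapped offset against every reference, with
mismatches at known modification positions costing nothing — the
modification-tolerant idea behind misincorporation-aware tRNA
sequencing, simplified. Ungapped alignment is a deliberate choice:
mature tRNA references are short, near-full-length reads dominate, and
the restriction keeps an exhaustive brute-force oracle feasible in the
tests. A read is assigned to the unique minimum-distance reference when
that distance is at most 2 mismatches; ties split the read's weight
equally among co-minimal references, and everything else is discarded.
The published EM-based remapping and stop-aware modelling of the full
method are intentionally out of scope.

Differential abundance works on per-sample proportions (so results are
relative by construction): a pseudocount of 0.5 enters the proportions
and fold changes only, never the test statistic, which is a
two-proportion test on raw counts followed by BH correction. An
anticodon-family rollup is provided as a reporting aggregation.

# Ribosome occupancy (ribo_occupancy)

Footprints are mapped to codon-level E/P/A sites via a per-length offset
table: the A-site codon index is `floor((start - 1 + offset) / 3) + 1`.
Default offsets are monosome `{28: 12, 29: 12, 30: 13}` nt and disome
`{59..63: 45}` nt (targeting the A site of the leading — stalled —
ribosome of a collided pair). These follow common ribosome-profiling
practice and are config-overridable; periodicity-based offset learning
is out of scope. The first 15 and last 5 codons of each CDS are excluded
to remove initiation/termination artifacts, and transcripts contributing
fewer than 64 site-assigned reads are dropped.

Per included transcript, the density at codon i is the read count at i
divided by the mean count over included codons, making every
transcript's mean density exactly 1; a codon's occupancy is the
unweighted mean of density over all included occurrences of that codon
across transcripts (not read-weighted — chosen so the small hand-computed
oracle in the tests is unambiguous). Occupancy ratios between conditions
require at least 100 occurrences of a codon in both tables. Meta-codon
profiles average the density vectors around every qualifying occurrence
of a centre codon, reported in codon units over a +/-30-codon window
(occurrence windows must lie fully inside the included region).

Occupancies are pure footprint densities, not normalised against RNA-seq;
translation efficiency is handled separately as the ratio of footprint to
mRNA proportions (pseudocount 0.5), with transcripts classified up or
down at |delta log2 TE| >= 1. That 2-fold threshold is a package default
for the classifier, exposed as an argument.

The footprint simulator draws a transcript proportionally to its length
(a uniform per-codon baseline; expression can be layered via duplicate
records), a length from the library's length weights, and then an A-site
codon with probability proportional to its dwell multiplier among the
codons compatible with that length; the 5' end is placed so the matching
offset table recovers exactly the drawn A site.

# Codon bias (codon_bias)

Codon profiles count frame-0 triplets (terminal stop excluded from sense
totals, internal stops rejected), with per-codon fractions of all sense
codons and fractions within the synonymous amino-acid family. The
U/A-rich versus C/G-rich leucine and serine groups are fixed constants
(`codon_groups`); within each amino acid they are disjoint and cover the
family, so their family-relative contents always sum to 1.

Group contents are exposed under both denominators (all sense codons, or
the group's family) because published "combined codon content" panels
use both normalisations. Group comparisons use the classic two-tailed
pooled-variance Student's t test — the stricter reading of "Student's t"
— with the usual star convention. Set-versus-background bias is the
difference of mean codon fractions, per-transcript-averaged by default
(each transcript one vote) with a pooled option that concatenates coding
sequence; the family-relative variant excludes transcripts lacking the
family from that codon's mean. Dipeptides are counted with overlap
(positions i, i+1 for all i), the standard convention, and enrichment
uses a single shared pseudocount so pairs absent everywhere report a
fold of exactly 1. The background is the unweighted set of supplied
coding sequences.

The wobble table writes anticodons 5' to 3' (positions 34-35-36):
positions 35 and 36 must be Watson--Crick to codon positions 2 and 1,
and position 34 pairs the codon's third base under Watson--Crick pairs,
G:U and U:G wobble, and inosine pairing with U, C or A. Under these
rules each of the four stalling-prone Leu codons (UUA, UUG, CUU, CUA) is
decodable by the UAA or IAG anticodon. Note that purely combinatorial
pairing is broader than the decoding observed in vivo: AUG, for example,
is matched by both CAU and UAU under U:G wobble, while real methionine
decoding is restricted to CAU anticodons by tRNA modification and
identity constraints the table does not model.

# Cross statistics (cross_stats)

Mendelian expectations multiply per-locus transmission probabilities
over independent biallelic loci; independent assortment is assumed (the
loci of interest lie on different chromosomes, and the published ratios
presuppose independence). Goodness of fit is the Pearson chi-square over
categories with positive expectation, with an impossible-outcome error
when an observed genotype has zero expectation and a warning
recommending an exact test when any expected count falls below 1.
Cross-background comparisons of a target-genotype frequency use Fisher's
exact test for two backgrounds or whenever an expected cell is below 5,
and Pearson chi-square otherwise.

The cross simulator draws gametes independently per locus; `n_offspring`
counts conceptions, each of which survives with its genotype's
viability, and conception counts are retained as ground truth. With full
viability the two readings coincide, which is the regime used for
type-I-error calibration.

# Problem sizes and numerical checks

The test suite validates each stage against independent oracles (closed
forms, exhaustive enumeration, hand arithmetic) on small instances, and
against the simulators' own event logs at scale. The larger
property checks use: 10,000-read coverage for stoichiometry recovery
(binomial error well inside the +/-0.02 band); 20 replicate null runs of
~1,040 unmodified C positions for Fisher/BH calibration; 200,000
footprints per condition (40 transcripts x 300 codons) for dwell-ratio
recovery in both monosome and disome geometries, and 1,000,000
footprints for the flat-null check (all 61 occupancies within 1 +/-
0.05); 50,000 reads per sample for recovery of a 4-fold isodecoder
depletion (expected log2 fold change -1.89 once proportions are
renormalised); and 1,000 replicates of a 262-conception cross for
chi-square type-I calibration. These sizes were chosen so that sampling
error sits several standard errors inside each acceptance band.

# What the synthetic data does and does not show

The generators emulate the features the statistics consume: probing
chemistry with known stoichiometry and stop/misincorporation split,
isodecoder abundance shifts, per-codon dwell multipliers, codon-usage
shifts, and per-genotype viability. They do not emulate
sequencing-quality profiles, adapter/UMI artifacts, ligation bias, RNA
secondary-structure effects on reverse transcription, expression-weighted
transcript sampling, or linkage between loci. Passing tests therefore
demonstrate that the statistics recover known truth under the stated
models — not that those models capture every bias of real libraries.
Known confounders of the probing chemistry (e.g. 5-formylcytidine
cross-reactivity at C35 of tRNA-Leu-CAA) are likewise not modelled and
must be handled by annotation when the caller is applied to real data.
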