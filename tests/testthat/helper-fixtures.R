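# Shared fixture builders: everything is generated in code at test time.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal SAM record line
sam_line <- function(qname, rname, pos, cigar, seq) {
  paste(qname, "0", rname, pos, "255", cigar, "*", "0", "0", seq, "*",
        sep = "\t")
}

toy_refs <- function() {
  reference_set(c(t1 = "ACGTACGTAC", t2 = "GGGGCCCCGG"))
}

# a uniform-usage CDS set for footprint work
uniform_cds <- function(n = 10, codons = 120, seed = 99) {
  simulate_codon_shifted_cds(n, codons, seed = seed)
}
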