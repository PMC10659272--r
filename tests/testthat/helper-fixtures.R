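# small deterministic fixtures shared across test files

# a tiny single-chromosome reference with a known sequence
tinyGenome <- function(seq = "ACGTTCCAGGTACCATGGATCCA") {
  Biostrings::DNAStringSet(stats::setNames(seq, "chrT"))
}

# a fast generator config for tests that do not need the full corpus
smallConfig <- function(seed = 1L, ...) {
  generatorConfig(seed = seed, genome_length = 200000L, n_genes = 120L,
                  cells_per_type_per_donor = 6L, ...)
}

# write a VCF with arbitrary body lines for reader tests
writeTestVCF <- function(body, path) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               body), path)
  path
}

expect_slope_within <- function(fit, target, tol_frac) {
  expect_lt(abs(fit$slope - target), abs(target) * tol_frac)
}
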