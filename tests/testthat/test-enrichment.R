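# a hand-built genome with one '+' gene at 5-10 and one '-' gene at 15-20
annotFixture <- function() {
  g <- tinyGenome("ACGTTCCAGGTACCATGGATCCAT")
  genes <- GenomicRanges::GRanges("chrT",
                                  IRanges::IRanges(c(5L, 15L), c(10L, 20L)),
                                  strand = c("+", "-"))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = c("gPlus", "gMinus"), gene_length = c(6L, 6L))
  list(genome = g, genes = genes)
}

test_that("transcriptional strand follows the pyrimidine/template convention", {
  fx <- annotFixture()
  # position 6 is a C (pyrimidine on '+') inside the '+' gene: coding strand
  cat <- MutationCatalog("chrT", c(6L, 17L, 12L), c("C", "G", "A"),
                         c("T", "A", "C"), "c1", "d1")
  ann <- annotateMutations(cat, fx$genes, fx$genome)
  expect_equal(ann$region, c("genic", "genic", "intergenic"))
  expect_equal(ann$tx_strand[1], "untranscribed")
  expect_equal(ann$gene_id[1], "gPlus")
  # position 17: G on '+', pyrimidine on '-', gene on '-' whose template is '+'
  expect_equal(ann$tx_strand[2], "untranscribed")
  expect_equal(ann$tx_strand[3], "not_applicable")
  expect_true(is.na(ann$gene_id[3]))

  # same genic position, opposite gene strand flips the call
  genes2 <- fx$genes
  GenomicRanges::strand(genes2) <- c("-", "+")
  ann2 <- annotateMutations(cat, genes2, fx$genome)
  expect_equal(ann2$tx_strand[1], "transcribed")
  expect_equal(ann2$tx_strand[2], "transcribed")
})

test_that("matched controls preserve the 96-spectrum exactly", {
  cfg <- smallConfig(seed = 21)
  sim <- simulateGenome(cfg)
  mut <- simulateMutations(cfg, sim)
  ann <- annotateMutations(mut$catalog, sim$genes, sim$genome)
  for (m in c(1L, 3L)) {
    ctrl <- sampleMatchedControls(ann, sim$mask, sim$genome, multiplier = m,
                                  seed = 99)
    so <- buildSpectrum(ann, sim$genome)$spectrum
    sc <- buildSpectrum(ctrl, sim$genome)$spectrum
    expect_identical(unname(sc), unname(m * so))   # exact, not approximate
  }
  expect_length(sampleMatchedControls(annotateMutations(MutationCatalog(),
                                                        sim$genes, sim$genome),
                                      sim$mask, sim$genome), 0L)
})

test_that("controls restricted to a genic mask stay genic", {
  cfg <- smallConfig(seed = 22)
  sim <- simulateGenome(cfg)
  mut <- simulateMutations(cfg, sim)
  ann <- annotateMutations(mut$catalog, sim$genes, sim$genome)
  genic_mask <- GenomicRanges::granges(sim$genes)
  ctrl <- sampleMatchedControls(ann[1:200], genic_mask, sim$genome,
                                multiplier = 2, seed = 7)
  ctrl_ann <- annotateMutations(ctrl, sim$genes, sim$genome)
  expect_true(all(ctrl_ann$region == "genic"))
})

test_that("enrichment ratios have their closed form and null calibration", {
  mkann <- function(regions) {
    n <- length(regions)
    cat <- MutationCatalog(rep("chrT", n), seq_len(n) + 1L, "C", "T", "c", "d")
    S4Vectors::mcols(cat)$region <- regions
    S4Vectors::mcols(cat)$gene_id <- NA_character_
    S4Vectors::mcols(cat)$context_idx <- rep(1L, n)
    cat
  }
  obs <- mkann(rep("genic", 100))
  ctrl <- mkann(rep(c("genic", "intergenic"), each = 500))
  enr <- mutationEnrichment(obs, ctrl, "genic_vs_intergenic", n_boot = 50)
  expect_equal(enr$ratio[enr$partition_label == "genic"], 2)

  # observed drawn from the same law as controls: CIs cover 1
  set.seed(5)
  obs2 <- mkann(sample(c("genic", "intergenic"), 400, replace = TRUE))
  enr2 <- mutationEnrichment(obs2, ctrl, "genic_vs_intergenic",
                             n_boot = 500, seed = 5)
  expect_true(all(enr2$ci_low <= 1 & 1 <= enr2$ci_high))
  expect_error(mutationEnrichment(obs, mkann(rep("genic", 10)),
                                  "genic_vs_intergenic"), "empty partition")
})

test_that("expression quintiles split ranks evenly and deterministically", {
  q <- expressionQuintiles(c(10, 3, 5, 8, 1, 2, 9, 7, 4, 6),
                           sprintf("g%02d", 1:10))
  expect_equal(unname(table(q)), rep(2L, 5), ignore_attr = TRUE)
  expect_equal(unname(q[c("g05", "g01")]), c(1L, 5L))
  # heavy ties: assignment still total, deterministic, id-ordered
  q2 <- expressionQuintiles(rep(1, 10), sprintf("g%02d", 1:10))
  q3 <- expressionQuintiles(rep(1, 10), sprintf("g%02d", 1:10))
  expect_identical(q2, q3)
  expect_equal(unname(table(q2)), rep(2L, 5), ignore_attr = TRUE)
  expect_equal(unname(q2["g01"]), 1L)
  expect_error(expressionQuintiles(1:4, letters[1:4]), "at least 5")
})

test_that("strand bias is null-calibrated and recovers planted asymmetry", {
  # strand-agnostic synthetic labels: fraction near 0.5 at n >= 1000
  n <- 2000
  cat <- MutationCatalog(rep("chrT", n), seq_len(n), "C", "T", "c", "d")
  set.seed(31)
  S4Vectors::mcols(cat)$region <- "genic"
  S4Vectors::mcols(cat)$gene_id <- "g1"
  S4Vectors::mcols(cat)$sub_class <- sample(c("C>T", "T>C"), n, replace = TRUE)
  S4Vectors::mcols(cat)$tx_strand <- sample(c("transcribed", "untranscribed"),
                                            n, replace = TRUE)
  sb <- strandBias(cat)
  tc <- sb[sb$sub_class == "T>C", ]
  nn <- tc$n_transcribed + tc$n_untranscribed
  expect_lt(abs(tc$fraction_transcribed - 0.5), 3 * sqrt(0.25 / nn))
  # empty cells report NA fraction with n = 0
  cg <- sb[sb$sub_class == "C>G", ]
  expect_equal(cg$n_transcribed + cg$n_untranscribed, 0L)
  expect_true(is.na(cg$fraction_transcribed))

  # generator recovery of the configured asymmetry parameter
  cfg <- smallConfig(seed = 23, strand_asymmetry = 0.8)
  sim <- simulateGenome(cfg)
  mut <- simulateMutations(cfg, sim)
  ann <- annotateMutations(mut$catalog, sim$genes, sim$genome)
  sb2 <- strandBias(ann)
  tc2 <- sb2[sb2$sub_class == "T>C", ]
  n2 <- tc2$n_transcribed + tc2$n_untranscribed
  expect_gt(n2, 500)
  expect_lt(abs(tc2$fraction_transcribed - 0.8), 4 * sqrt(0.8 * 0.2 / n2))
})

test_that("length-decile sSNV rates are flat under uniform placement", {
  set.seed(41)
  lens <- sort(round(stats::rlnorm(60, log(500), 0.5)))
  starts <- cumsum(c(10, lens[-60] + 10))
  genes <- GenomicRanges::GRanges("chrT", IRanges::IRanges(starts, width = lens))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = sprintf("g%03d", 1:60), gene_length = lens)
  # uniform placement over gene bp
  pos <- sort(sample(unlist(mapply(function(s, l) s:(s + l - 1), starts, lens)),
                     3000, replace = TRUE))
  cat <- MutationCatalog(rep("chrT", 3000), pos, "C", "T", "c", "d")
  hit <- GenomicRanges::findOverlaps(GenomicRanges::granges(cat), genes,
                                     select = "first")
  S4Vectors::mcols(cat)$region <- "genic"
  S4Vectors::mcols(cat)$gene_id <- genes$gene_id[hit]
  res <- snvRateByLength(cat, genes)
  overall <- 3000 / sum(lens)
  expect_true(all(abs(res$table$rate - overall) < 5 * sqrt(overall / res$table$total_bp)))
  expect_gt(res$fit$p_value, 0.01)
  # single mutation: no crash, rates mostly zero
  res1 <- snvRateByLength(cat[1], genes)
  expect_equal(sum(res1$table$n_mutations), 1L)
  expect_error(snvRateByLength(cat, genes[1:5]), "at least 10")
})

test_that("class spectrum test matches an exhaustive binomial oracle", {
  mkcls <- function(classes) {
    n <- length(classes)
    cat <- MutationCatalog(rep("chrT", n), seq_len(n), "C", "T", "c", "d")
    S4Vectors::mcols(cat)$sub_class <- classes
    cat
  }
  A <- mkcls(c(rep("C>G", 30), rep("T>A", 70)))
  B <- mkcls(c(rep("C>G", 10), rep("T>A", 90)))
  res <- classSpectrumTest(A, B)
  # brute-force two-sided exact binomial p at p0 = 1/2
  oracle <- function(x, n, p0) {
    d <- stats::dbinom(0:n, n, p0)
    sum(d[d <= d[x + 1] * (1 + 1e-7)])
  }
  row <- res[res$sub_class == "C>G", ]
  expect_equal(row$p_value, oracle(30, 40, 0.5), tolerance = 1e-9)
  expect_true(row$enriched_in_A)
  # identical compositions with symmetric totals: p = 1 everywhere testable
  res0 <- classSpectrumTest(A, mkcls(c(rep("C>G", 30), rep("T>A", 70))))
  expect_true(all(res0$p_value[!is.na(res0$p_value)] == 1))
  # empty category is untestable, not an error
  expect_true(is.na(res0$p_value[res0$sub_class == "C>A"]))
  expect_error(classSpectrumTest(A, MutationCatalog()), "nonempty")
})

test_that("a planted C>G excess in housekeeping-like mutations is detected", {
  set.seed(51)
  draw <- function(n, pcg) {
    cls <- sample(c("C>G", "C>T", "T>C"), n, replace = TRUE,
                  prob = c(pcg, 0.4, 0.6 - pcg))
    cat <- MutationCatalog(rep("chrT", n), seq_len(n), "C", "T", "c", "d")
    S4Vectors::mcols(cat)$sub_class <- cls
    cat
  }
  res <- classSpectrumTest(draw(800, 0.15), draw(800, 0.05))
  row <- res[res$sub_class == "C>G", ]
  expect_true(row$enriched_in_A)
  expect_lt(row$p_value, 0.05)
  # sign agrees in the frequency-difference view
  expect_gt(row$prop_A, row$null_prop)
})

test_that("stop codons are AT-rich and C>T/C>A dominate cytosine stopgains", {
  sg <- stopgainProfile()
  expect_equal(sg$stop_au_bases, 7L)
  # among the C-centered classes, C>A and C>T carry the most stopgain events;
  # T>C can never create a stop (stops have no C)
  cn <- sg$per_class[c("C>A", "C>G", "C>T")]
  expect_setequal(names(sort(cn, decreasing = TRUE))[1:2], c("C>T", "C>A"))
  expect_equal(unname(sg$per_class["T>C"]), 0)

  # independent oracle through the standard genetic code
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  oracle <- stats::setNames(numeric(6), c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  for (cod in names(gc)) {
    if (gc[[cod]] == "*") next
    for (pos in 1:3) for (alt in setdiff(bases, substr(cod, pos, pos))) {
      mut <- cod; substr(mut, pos, pos) <- alt
      if (gc[[mut]] == "*") {
        cls <- canonicalContext(substr(cod, pos, pos), alt, "A", "A")$sub_class
        oracle[cls] <- oracle[cls] + 1
      }
    }
  }
  expect_equal(sg$per_class, oracle)
  # CAA -> TAA is one of the counted C>T events
  expect_gte(sg$per_class[["C>T"]], 1)
})

test_that("per-signature enrichment recovers the generator's placement biases", {
  cfg <- generatorConfig(seed = 25, genome_length = 500000L, n_genes = 250L)
  sim <- simulateGenome(cfg)
  mut <- simulateMutations(cfg, sim)
  ann <- annotateMutations(mut$catalog, sim$genes, sim$genome)
  ctrl <- sampleMatchedControls(ann, sim$mask, sim$genome, multiplier = 5,
                                seed = 25)
  ctrl_ann <- annotateMutations(ctrl, sim$genes, sim$genome)
  qmap <- setNames(sim$genes$expr_quintile, sim$genes$gene_id)
  S <- cbind(A1 = cfg$sig_a1, A2 = cfg$sig_a2)

  # expression-dependent placement of the T>C-dominant component: its
  # enrichment ratio rises monotonically across expression quintiles
  enr <- mutationEnrichment(ann, ctrl_ann, "expression_quintiles",
                            quintile_map = qmap, n_boot = 100, seed = 25,
                            signatures = S, sig_weights = c(0.85, 0.15))
  expect_true(all(diff(enr$ratio_A1) > 0))
  expect_gt(enr$ratio_A1[5], 1)
  expect_lt(enr$ratio_A1[1], 1)

  # the C>T-dominant component's intergenic preference survives hard
  # responsibility attribution (soft attribution dilutes the minor
  # component below detectability)
  gi <- mutationEnrichment(ann, ctrl_ann, "genic_vs_intergenic",
                           n_boot = 100, seed = 25, signatures = S,
                           sig_weights = c(0.85, 0.15), attribution = "hard")
  expect_gt(gi$ratio_A2[gi$partition_label == "intergenic"], 1)
  # and the truth labels confirm the planted bias is stronger than attributed
  a2 <- ann[mut$truth$mutation_signature == "A2"]
  expect_gt(mean(a2$region == "intergenic") / mean(ctrl_ann$region == "intergenic"),
            gi$ratio_A2[gi$partition_label == "intergenic"])
})
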