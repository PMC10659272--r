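test_that("log normalization has its closed forms and guards", {
  counts <- matrix(c(0L, 5L, 0L, 0L, 3L, 1L), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("cA", "cB")))
  norm <- logNormalize(counts)
  expect_equal(norm["g1", "cA"], 0)
  expect_equal(norm["g2", "cA"], log(1 + 10000))   # single expressed gene
  # scale invariance within a cell
  expect_equal(logNormalize(counts * 2L)[, "cB"], norm[, "cB"])
  bad <- cbind(counts, cZero = c(0L, 0L, 0L))
  expect_error(logNormalize(bad), "cZero")
})

test_that("differential expression is null under identical groups and antisymmetric", {
  set.seed(61)
  norm <- logNormalize(matrix(rpois(100 * 12, 5), 100, 12,
                              dimnames = list(sprintf("g%03d", 1:100),
                                              sprintf("c%02d", 1:12))))
  de0 <- differentialExpression(norm, sprintf("c%02d", 1:6), sprintf("c%02d", 1:6))
  expect_equal(sum(de0$significant), 0L)
  expect_true(all(abs(de0$log2_fc) < 1e-12))

  deAB <- differentialExpression(norm, sprintf("c%02d", 1:6), sprintf("c%02d", 7:12))
  deBA <- differentialExpression(norm, sprintf("c%02d", 7:12), sprintf("c%02d", 1:6))
  expect_equal(deAB$log2_fc, -deBA$log2_fc)
  expect_equal(deAB$p_value, deBA$p_value)
  expect_error(differentialExpression(norm, sprintf("c%02d", 1:2),
                                      sprintf("c%02d", 7:12)), "at least 3")
})

test_that("planted two-fold declines are detected with high sensitivity", {
  set.seed(62)
  ng <- 200; nc <- 60
  mu <- runif(ng, 3, 8)                 # well-expressed genes
  planted <- 1:20
  mkmat <- function(mu) matrix(rnbinom(ng * nc, mu = mu, size = 2), ng, nc)
  adult <- mkmat(mu)
  mu_e <- mu; mu_e[planted] <- mu_e[planted] / 2
  elderly <- mkmat(mu_e)
  counts <- cbind(adult, elderly)
  dimnames(counts) <- list(sprintf("g%03d", 1:ng), sprintf("c%03d", 1:(2 * nc)))
  norm <- logNormalize(counts)
  de <- differentialExpression(norm, sprintf("c%03d", nc + 1:nc),
                               sprintf("c%03d", 1:nc))
  hits <- de$gene_id[de$significant & de$direction == "down"]
  expect_gte(mean(sprintf("g%03d", planted) %in% hits), 0.9)
  # false-call rate among unplanted genes stays low
  expect_lt(mean(setdiff(de$gene_id, sprintf("g%03d", planted)) %in% hits), 0.05)
})

test_that("type-I error of the rank-sum stage is close to nominal on null data", {
  set.seed(63)
  ng <- 2000; nc <- 40
  counts <- matrix(rnbinom(ng * 2 * nc, mu = 5, size = 2), ng, 2 * nc,
                   dimnames = list(sprintf("g%04d", 1:ng),
                                   sprintf("c%03d", 1:(2 * nc))))
  norm <- logNormalize(counts)
  de <- differentialExpression(norm, sprintf("c%03d", 1:nc),
                               sprintf("c%03d", nc + 1:nc))
  frac <- mean(de$p_value < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("gene program classification applies its strict thresholds", {
  means <- rbind(c(0.50, 0.52, 0.48, 0.49),   # housekeeping
                 c(0.30, 0.30, 0.05, 0.05),   # neuron-specific
                 c(0.50, 0.50, 0.50, 0.60),   # spread exactly 0.1: other
                 c(0.15, 0.15, 0.15, 0.09))   # one mean below floor: other
  colnames(means) <- c("excitatory", "inhibitory", "microglia", "endothelia")
  cls <- classifyGenePrograms(means, sprintf("g%d", 1:4))
  expect_equal(cls$class, c("housekeeping", "neuron_specific", "other", "other"))
  # shifting all four means never changes the spread criterion
  cls2 <- classifyGenePrograms(means + 0.7, sprintf("g%d", 1:4))
  expect_equal(cls2$class[3], "other")
  expect_equal(cls2$class[1], "housekeeping")
  expect_error(classifyGenePrograms(means[, 1:3]), "must have columns")
})

test_that("shared-downregulation permutation matches a closed-form null", {
  cats <- c(ex = "excitatory", inh = "inhibitory", g1 = "glial", g2 = "glial")
  genes <- sprintf("g%02d", 1:10)
  expressed <- list(ex = genes, inh = genes, g1 = genes, g2 = genes)
  # empty down sets: observed 0, p 1
  empty <- lapply(expressed, function(x) character())
  r0 <- sharedDownPermutation(empty, expressed, cats, n_perm = 100, seed = 1)
  expect_equal(r0$observed, 0L)
  expect_equal(r0$p_value, 1)

  # closed-form null mean: per gene, P(down in all four sets) = (2/10)^4
  down <- lapply(expressed, function(x) x[1:2])
  r <- sharedDownPermutation(down, expressed, cats, n_perm = 2000, seed = 2)
  expect_equal(r$observed, 2L)   # the same two genes planted everywhere
  null_mean <- 10 * (2 / 10)^4
  expect_lt(abs(mean(r$perm_counts) - null_mean), 0.012)
  # p always within [1/(n+1), 1]
  expect_gte(r$p_value, 1 / 2001)
  expect_lte(r$p_value, 1)
  expect_error(sharedDownPermutation(down, expressed,
                                     c(ex = "glial", inh = "glial",
                                       g1 = "glial", g2 = "glial")),
               "excitatory")
  bad <- down; bad$ex <- c("gXX")
  expect_error(sharedDownPermutation(bad, expressed, cats), "subset")
})

test_that("gene-set enrichment agrees with the hypergeometric oracle", {
  # closed 2x2 case: (8,2; 10, 80)
  bg <- sprintf("g%03d", 1:100)
  gs <- bg[1:10]
  down <- bg[c(1:8, 11:20)]
  res <- geneSetEnrichment(down, gs, bg)
  hyper_oracle <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    d <- stats::dhyper(0:min(m, k), m, n, k)
    sum(d[d <= d[tab[1, 1] + 1] * (1 + 1e-7)])
  }
  expect_equal(res$p_value, hyper_oracle(res$table), tolerance = 1e-9)

  # random small tables against the oracle
  set.seed(64)
  for (i in 1:25) {
    tot <- sample(10:60, 1)
    bg2 <- sprintf("x%03d", seq_len(tot))
    gs2 <- sample(bg2, sample(2:(tot - 2), 1))
    dn2 <- sample(bg2, sample(1:(tot - 1), 1))
    r <- geneSetEnrichment(dn2, gs2, bg2)
    expect_equal(r$p_value, hyper_oracle(r$table), tolerance = 1e-9)
  }
  # a set with the background's own down-fraction is unremarkable
  res0 <- geneSetEnrichment(bg[seq(1, 100, 10)], bg[1:50], bg)
  expect_gt(res0$p_value, 0.5)
  expect_error(geneSetEnrichment(down, c(gs, "not_bg"), bg), "subset")
})

test_that("composition trend reproduces the exact rank-sum tail", {
  # extreme 2-vs-11 split: two-sided exact p = 2 / choose(13, 2)
  frac <- c(0.30, 0.28, runif(11, 0.05, 0.2))
  grp <- c("infant", "infant", rep("older", 11))
  r <- compositionTrend(frac, grp)
  expect_true(r$exact)
  expect_equal(r$p_value, 2 / choose(13, 2), tolerance = 1e-12)
  # label swap leaves the two-sided p unchanged
  r2 <- compositionTrend(frac, ifelse(grp == "infant", "older", "infant"))
  expect_equal(r2$p_value, r$p_value)
  # identical fractions: p = 1 under the tie convention
  r3 <- compositionTrend(rep(0.1, 8), rep(c("a", "b"), 4))
  expect_equal(r3$p_value, 1)
  expect_error(compositionTrend(frac, rep("one", 13)), "two levels")
})

test_that("length-decile fold changes recover planted gradients", {
  set.seed(65)
  n <- 300
  lens <- sort(round(rlnorm(n, log(600), 0.6)))
  ids <- sprintf("g%03d", 1:n)
  # null: fold changes independent of length
  r0 <- lengthDecileFoldChange(rnorm(n, 0, 0.3), lens, ids)
  expect_gt(r0$fit$p_value, 0.01)
  # planted linear decile gradient, -1 at the shortest to 0 at the longest
  dec <- scSomaAging:::.decileByLength(lens, ids, 10)
  lfc <- -1 * (10 - dec) / 9 + rnorm(n, 0, 0.05)
  r1 <- lengthDecileFoldChange(lfc, lens, ids)
  expect_lt(abs(r1$fit$slope - 1 / 9), 0.15 * (1 / 9))
  expect_gt(r1$fit$slope, 0)
  expect_error(lengthDecileFoldChange(lfc[1:5], lens[1:5], ids[1:5]), "at least 10")
})

test_that("Fisher's r-to-z comparison is null for identical fits", {
  r <- fisherRtoZ(0.64, 300, 0.64, 300)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
  r2 <- fisherRtoZ(0.64, 300, 0.30, 300)
  expect_gt(r2$z, 0)
  expect_lt(r2$p_value, 0.001)
  expect_error(fisherRtoZ(0.5, 3, 0.5, 300), "n > 3")
})
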