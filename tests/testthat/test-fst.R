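# Weir-Cockerham differentiation and gene diversity.

test_that("allele frequencies match direct tallies", {
  g <- toy_genotypes(list(A = list(c(1, 2), c(1, 1)),
                          B = list(c(2, 2), c(2, 2))))
  fA <- allele_frequencies(g, "A")
  expect_equal(fA[[1]]$freq, c(`1` = 0.75, `2` = 0.25))
  expect_equal(fA[[1]]$n, 4L)
  fB <- allele_frequencies(g, "B")
  expect_equal(fB[[1]]$freq, c(`2` = 1.0))

  # brute-force tally on simulated multi-allelic data
  d <- study_design(n_pops = c(one = 2L), families_per_pop = c(10L, 10L))
  gs <- simulate_genotypes(d, seed = 9, individuals = 25)
  fr <- allele_frequencies(gs, "ON01")
  idx <- gs$population == "ON01"
  for (l in names(fr)) {
    alleles <- c(gs$allele1[idx, l], gs$allele2[idx, l])
    alleles <- alleles[!is.na(alleles)]
    tally <- table(alleles) / length(alleles)
    expect_equal(unname(fr[[l]]$freq), as.numeric(tally), tolerance = 1e-12)
    expect_equal(sum(fr[[l]]$freq), 1, tolerance = 1e-12)
  }
})

test_that("Weir-Cockerham components match an independent evaluation", {
  # frozen values from a hand-tallied two-population biallelic toy,
  # evaluated independently with the published component formulas
  g <- toy_genotypes(list(
    A = list(c(1, 1), c(1, 2), c(2, 2), c(1, 1), c(1, 2)),
    B = list(c(2, 2), c(2, 2), c(1, 2), c(2, 2), c(1, 1))))
  est <- wc_fst(g)
  pl <- est$per_locus[est$per_locus$informative, ]
  expect_equal(pl$a, 0.015, tolerance = 1e-12)
  expect_equal(pl$b, 0.225, tolerance = 1e-12)
  expect_equal(pl$c, 0.300, tolerance = 1e-12)
  expect_equal(est$theta, 1 / 36, tolerance = 1e-12)
})

test_that("complete fixation gives theta = 1 and identical populations <= 0", {
  fixed <- toy_genotypes(list(A = rep(list(c(1, 1)), 8),
                              B = rep(list(c(2, 2)), 8)))
  expect_equal(wc_fst(fixed)$theta, 1)

  set.seed(31)
  calls <- lapply(1:10, function(i) sample(1:4, 2, replace = TRUE))
  same <- toy_genotypes(list(A = calls, B = calls))
  expect_lte(wc_fst(same)$theta, 0)
})

test_that("theta is invariant to allele relabeling, locus order and monomorphic loci", {
  d <- study_design(n_pops = c(x = 4L), n_loci = 6L)
  g <- simulate_genotypes(d, seed = 12, individuals = 15)
  base <- wc_fst(g)$theta

  # relabel alleles locus-wise (reverse the code space)
  g2 <- g
  g2$allele1 <- 99L - g$allele1
  g2$allele2 <- 99L - g$allele2
  expect_equal(wc_fst(g2)$theta, base, tolerance = 1e-12)

  # shuffle locus order
  ord <- c(4, 2, 6, 1, 5, 3)
  g3 <- genotype_table(g$allele1[, ord], g$allele2[, ord], g$population,
                       g$individuals, g$loci[ord])
  expect_equal(wc_fst(g3)$theta, base, tolerance = 1e-12)

  # append a monomorphic locus: theta unchanged
  g4 <- genotype_table(cbind(g$allele1, mono = 1L),
                       cbind(g$allele2, mono = 1L),
                       g$population, g$individuals, c(g$loci, "mono"))
  expect_equal(wc_fst(g4)$theta, base, tolerance = 1e-12)

  # all loci monomorphic is undefined
  gm <- toy_genotypes(list(A = rep(list(c(1, 1)), 3),
                           B = rep(list(c(1, 1)), 3)))
  expect_error(wc_fst(gm), "monomorphic")
})

test_that("pairwise matrix equals per-pair recomputation, symmetric with zero diagonal", {
  d <- study_design(n_pops = c(x = 4L), n_loci = 8L)
  g <- simulate_genotypes(d, seed = 21, individuals = 12)
  pw <- pairwise_fst(g)
  pops <- levels(g$population)
  for (i in 1:3) for (j in (i + 1):4) {
    direct <- wc_fst(subset_populations(g, c(pops[i], pops[j])))$theta
    expect_equal(pw[pops[i], pops[j]], direct, tolerance = 1e-12)
  }
  expect_equal(unclass(pw), t(unclass(pw)))
  expect_equal(unname(diag(pw)), rep(0, 4))

  # a fixed-for-alternatives pair hits 1
  fixed <- toy_genotypes(list(A = rep(list(c(1, 1)), 6),
                              B = rep(list(c(2, 2)), 6),
                              C = rep(list(c(1, 2)), 6)))
  expect_equal(pairwise_fst(fixed)["A", "B"], 1)
})

test_that("permutation p-values are deterministic, in (0, 1], and tiny under fixation", {
  fixed <- toy_genotypes(list(A = rep(list(c(1, 1)), 12),
                              B = rep(list(c(2, 2)), 12)))
  est <- fst_permutation_pvalue(fixed, n_perm = 199, seed = 4)
  # no random relabeling recreates the perfect split at these sizes
  expect_equal(est$p_value, 1 / 200)
  est2 <- fst_permutation_pvalue(fixed, n_perm = 199, seed = 4)
  expect_equal(est2$p_value, est$p_value)

  # permutation-invariant composition: p well inside (0, 1]
  calls <- lapply(1:10, function(i) c(1L + (i %% 2), 2L))
  same <- toy_genotypes(list(A = calls, B = calls))
  p <- fst_permutation_pvalue(same, n_perm = 99, seed = 1)$p_value
  expect_gt(p, 0)
  expect_lte(p, 1)
})

test_that("gene diversity equals the brute-force two-draw difference probability", {
  # fixed locus
  fixed <- toy_genotypes(list(A = rep(list(c(1, 1)), 4)))
  expect_equal(unname(gene_diversity(fixed)), 0)

  # 6-genotype single-population toy: enumerate all ordered pairs of
  # distinct allele copies and count differing pairs
  calls <- list(c(1, 2), c(1, 1), c(2, 3), c(3, 3), c(1, 3), c(2, 2))
  g <- toy_genotypes(list(A = calls))
  alleles <- unlist(calls)
  n <- length(alleles)
  diff_pairs <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && alleles[i] != alleles[j]) diff_pairs <- diff_pairs + 1
  }
  expect_equal(unname(gene_diversity(g)), diff_pairs / (n * (n - 1)),
               tolerance = 1e-12)
})
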