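# REML variance components, heritability, Q_ST and the bootstrap.

test_that("REML equals the nested-ANOVA method of moments on balanced data", {
  for (s in c(11, 23)) {
    set.seed(s)
    p <- balanced_phenotypes(npop = 6, nfam = 8, ns = 4,
                             v_b = 1, v_w = 0.8, v_res = 1)
    vc <- fit_variance_components(p, "y", random = c("population", "family"))
    df <- as.data.frame(p)
    an <- anova(lm(y ~ population + population:family, data = df))
    ms <- an[["Mean Sq"]]
    mom_res <- ms[3]
    mom_w <- (ms[2] - ms[3]) / 4
    mom_b <- (ms[1] - ms[2]) / (8 * 4)
    expect_equal(vc$V_res, mom_res, tolerance = 1e-6)
    expect_equal(vc$V_w, mom_w, tolerance = 1e-6)
    expect_equal(vc$V_b, mom_b, tolerance = 1e-6)
  }
})

test_that("variance components are translation-invariant and scale as c^2", {
  set.seed(7)
  p <- balanced_phenotypes(npop = 5, nfam = 6, ns = 2, n_blocks = 10,
                           v_block = 0.3)
  vc <- fit_variance_components(p, "y")

  p_shift <- p; p_shift$y <- p$y + 1000
  vc_s <- fit_variance_components(p_shift, "y")
  expect_equal(vc_s$V_b, vc$V_b, tolerance = 1e-5)
  expect_equal(vc_s$V_w, vc$V_w, tolerance = 1e-5)
  expect_equal(vc_s$V_res, vc$V_res, tolerance = 1e-5)

  cc <- 3.7
  p_sc <- p; p_sc$y <- p$y * cc
  vc_c <- fit_variance_components(p_sc, "y")
  tot <- vc$V_b + vc$V_w + vc$V_block + vc$V_res
  expect_equal(vc_c$V_b, cc^2 * vc$V_b, tolerance = 1e-5 * tot)
  expect_equal(vc_c$V_res, cc^2 * vc$V_res, tolerance = 1e-5 * tot)
  # h2 and Q_ST are dimensionless
  expect_equal(heritability_fullsib(vc_c)$h2, heritability_fullsib(vc)$h2,
               tolerance = 1e-6)
  expect_equal(qst_point(vc_c)$qst, qst_point(vc)$qst, tolerance = 1e-6)
})

test_that("a true-zero population variance lands on the boundary in most fits", {
  set.seed(99)
  hits <- 0L
  for (r in 1:30) {
    p <- balanced_phenotypes(npop = 6, nfam = 6, ns = 2,
                             v_b = 0, v_w = 0.5, v_res = 1)
    vc <- fit_variance_components(p, "y", random = c("population", "family"))
    if (vc$V_b <= 1e-10) hits <- hits + 1L
  }
  expect_gte(hits, 15L)
})

test_that("boundary LRT follows the half-chi-square mixture and detects family variance", {
  set.seed(3)
  p <- balanced_phenotypes(npop = 5, nfam = 20, ns = 2,
                           v_b = 0.5, v_w = 1, v_res = 1)
  tst <- test_variance_component(p, "y", "family")
  expect_gte(tst$lrt, 0)
  if (tst$lrt > 0)
    expect_equal(tst$p_value, 0.5 * pchisq(tst$lrt, 1, lower.tail = FALSE),
                 tolerance = 1e-12)

  # a term absent from the design is trivially null
  tst0 <- test_variance_component(p, "y", "block")
  expect_equal(tst0$lrt, 0)
  expect_equal(tst0$p_value, 1)
  expect_true(tst0$zeroed)

  # power: strong family variance (V_w = V_res) at study scale
  set.seed(17)
  sig <- 0L
  for (r in 1:15) {
    ps <- balanced_phenotypes(npop = 8, nfam = 25, ns = 2,
                              v_b = 0.3, v_w = 1, v_res = 1)
    if (test_variance_component(ps, "y", "family")$p_value < 0.05)
      sig <- sig + 1L
  }
  expect_gte(sig, 14L)
})

test_that("heritability and Q_ST formulas evaluate literally and agree algebraically", {
  mk_vc <- function(vb, vw, vres) {
    structure(list(V_b = vb, V_w = vw, V_block = 0, V_res = vres,
                   trait = "y", n_pops = 5L), class = "variance_components")
  }
  expect_equal(heritability_fullsib(mk_vc(1, 0, 2))$h2, 0)
  expect_equal(heritability_fullsib(mk_vc(1, 2, 2))$h2, 1)
  expect_equal(heritability_fullsib(mk_vc(1, 1, 3))$h2, 0.5)
  expect_warning(heritability_fullsib(mk_vc(1, 3, 1)), "exceeds 1")
  expect_error(heritability_fullsib(mk_vc(1, 0, 0)), "undefined")

  expect_equal(qst_point(mk_vc(0, 1, 1))$qst, 0)
  # V_b = 2 h2 (V_w + V_res) is the symmetry point
  vc <- mk_vc(2 * 0.5 * 4, 1, 3)
  expect_equal(qst_point(vc)$qst, 0.5)
  # reduced form V_b / (V_b + 4 V_w): V_b = 4, V_w = 1 -> 0.5
  vc2 <- mk_vc(4, 1, 7)
  h2 <- heritability_fullsib(vc2)
  expect_equal(qst_point(vc2, h2)$qst, vc2$V_b / (vc2$V_b + 4 * vc2$V_w),
               tolerance = 1e-12)
  expect_error(qst_point(mk_vc(0, 0, 0)), "undefined")
})

test_that("the parametric bootstrap is seeded and yields sane Q_ST intervals", {
  set.seed(5)
  p <- balanced_phenotypes(npop = 6, nfam = 10, ns = 2,
                           v_b = 1, v_w = 0.5, v_res = 1)
  ci1 <- parametric_bootstrap_ci(p, "y", "qst", n_boot = 200, seed = 42)
  ci2 <- parametric_bootstrap_ci(p, "y", "qst", n_boot = 200, seed = 42)
  expect_identical(ci1$low, ci2$low)
  expect_identical(ci1$high, ci2$high)
  expect_lte(ci1$low, ci1$high)
  expect_gte(ci1$low, 0)
  expect_lte(ci1$high, 1)
  expect_lt(abs(ci1$estimate - qst_point(fit_variance_components(p, "y"))$qst),
            1e-10)
})

test_that("pairwise Q_ST is symmetric, zero for a duplicated population, near zero under equality", {
  set.seed(8)
  # three populations, two of them carrying literally identical data
  base <- balanced_phenotypes(npop = 2, nfam = 12, ns = 2,
                              v_b = 0.5, v_w = 0.5, v_res = 1)
  df <- as.data.frame(base)
  dup <- df[df$population == "p01", ]
  dup$population <- "p03"
  dup$individual <- paste0(dup$individual, "_d")
  p <- phenotype_table(rbind(df, dup), traits = "y")
  q <- suppressWarnings(pairwise_qst(p, "y", sqrt_transform = FALSE))
  expect_equal(unclass(q), t(unclass(q)))
  expect_equal(unname(diag(q)), rep(0, 3))
  expect_equal(q["p01", "p03"], 0)

  # populations simulated with identical means: median pairwise Q_ST small
  set.seed(13)
  meds <- replicate(5, {
    p0 <- balanced_phenotypes(npop = 4, nfam = 10, ns = 2,
                              v_b = 0, v_w = 0.5, v_res = 1)
    q0 <- suppressWarnings(pairwise_qst(p0, "y", sqrt_transform = FALSE))
    median(q0[upper.tri(q0)], na.rm = TRUE)
  })
  expect_lt(median(meds), 0.05)
})
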