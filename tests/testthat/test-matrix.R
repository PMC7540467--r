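# Distance matrices, linearization and Mantel inference.

meta_from <- function(lat, lon, alt, labels = sprintf("p%d", seq_along(lat))) {
  population_metadata(data.frame(
    population = labels, subspecies = "s", latitude = lat, longitude = lon,
    altitude = alt, stringsAsFactors = FALSE))
}

test_that("great-circle distances match spherical geometry", {
  m <- meta_from(c(43, 43, 0, -43), c(1, 1, 10, -179), c(0, 0, 0, 0))
  d <- geo_distance_matrix(m)
  expect_equal(d["p1", "p2"], 0)                      # identical coordinates
  # antipodal points: half the great circle
  anti <- meta_from(c(10, -10), c(20, -160), c(0, 0))
  expect_equal(geo_distance_matrix(anti)["p1", "p2"], pi * 6371,
               tolerance = 1e-6)
  # spherical law of cosines as an independent oracle + triangle inequality
  set.seed(6)
  for (r in 1:20) {
    lat <- runif(3, -80, 80); lon <- runif(3, -179, 179)
    dm <- geo_distance_matrix(meta_from(lat, lon, c(0, 0, 0)))
    slc <- function(i, j) {
      phi <- lat * pi / 180; lam <- lon * pi / 180
      6371 * acos(pmin(1, pmax(-1, sin(phi[i]) * sin(phi[j]) +
        cos(phi[i]) * cos(phi[j]) * cos(lam[i] - lam[j]))))
    }
    expect_equal(dm["p1", "p2"], slc(1, 2), tolerance = 1e-6)
    expect_lte(dm["p1", "p3"], dm["p1", "p2"] + dm["p2", "p3"] + 1e-9)
  }
  # missing coordinates are rejected by name
  bad <- meta_from(c(43, NA), c(1, 2), c(0, 0))
  expect_error(geo_distance_matrix(bad), "p2")
})

test_that("altitude differences are absolute and symmetric", {
  m <- meta_from(c(42.5, 42.6), c(1, 2), c(61, 1564), c("BAN", "MON"))
  a <- altitude_diff_matrix(m)
  expect_equal(a["BAN", "MON"], 1503)
  expect_equal(a["MON", "BAN"], 1503)
  expect_equal(unname(diag(a)), c(0, 0))
})

test_that("F_ST linearization and log-distance behave entry-wise", {
  f <- pairwise_matrix(matrix(c(0, 0, 0.5, 0, 0, 0.109, 0.5, 0.109, 0), 3),
                       c("a", "b", "c"))
  lf <- linearize_fst(f)
  expect_equal(lf["a", "c"], 1.0)
  expect_equal(lf["b", "c"], 0.109 / 0.891, tolerance = 1e-12)
  expect_equal(lf["a", "b"], 0)

  f1 <- pairwise_matrix(matrix(c(0, 1, 1, 0), 2), c("a", "b"))
  expect_error(linearize_fst(f1), "1")
  fneg <- pairwise_matrix(matrix(c(0, -0.02, -0.02, 0), 2), c("a", "b"))
  expect_warning(lneg <- linearize_fst(fneg), "clamped")
  expect_equal(lneg["a", "b"], 0)

  dz <- pairwise_matrix(matrix(c(0, 0, 0, 0), 2), c("a", "b"))
  expect_error(log_distance_matrix(dz), "zero")
  dd <- pairwise_matrix(matrix(c(0, 4, 4, 0), 2), c("a", "b"))
  expect_equal(log_distance_matrix(dd)["a", "b"], log(4))
})

test_that("Mantel self-correlation and affine invariance hold exactly", {
  set.seed(10)
  A <- toy_pairwise(5)
  res <- mantel_test(A, A)
  expect_equal(res$r, 1)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_perm, 120L)
  # exact proportion of relabelings attaining r = 1 (identity at least)
  expect_gte(res$p, 1 / 120)
  expect_equal(res$p, 1 / 120)   # distinct entries: only identity-like maps

  # positive affine transform of the off-diagonals: r stays exactly 1
  B <- pairwise_matrix(2.5 * unclass(A) + 3 - diag(3, 5), rownames(A))
  expect_equal(mantel_test(A, B)$r, 1)

  # label mismatch and constant input are rejected
  C <- toy_pairwise(5, labels = sprintf("q%d", 1:5))
  expect_error(mantel_test(A, C), "labels")
  const <- pairwise_matrix(matrix(1, 5, 5) - diag(5), rownames(A))
  expect_error(mantel_test(A, const), "degenerate")
  expect_error(mantel_test(toy_pairwise(3), toy_pairwise(3)), "at least 4")
})

test_that("sampled Mantel p-values agree with exhaustive enumeration at n = 4", {
  set.seed(20)
  A <- toy_pairwise(4); B <- toy_pairwise(4)
  ex <- mantel_test(A, B, method = "exhaustive")
  expect_equal(ex$n_perm, 24L)
  # independent oracle: direct enumeration with a separate permutation
  # generator and plain correlation arithmetic
  perms <- oracle_permutations(4)
  ua <- A[upper.tri(A)]
  r_all <- apply(perms, 1, function(pm) {
    bp <- unclass(B)[pm, pm]
    cor(ua, bp[upper.tri(bp)])
  })
  r_obs <- cor(ua, B[upper.tri(B)])
  expect_equal(ex$r, r_obs, tolerance = 1e-12)
  expect_equal(ex$p, mean(r_all >= r_obs - 1e-12), tolerance = 1e-12)

  sam <- mantel_test(A, B, n_perm = 10000, seed = 3, method = "sampled")
  expect_lt(abs(sam$p - ex$p), 0.02)
})

test_that("Mantel r matches vegan and p agrees within Monte-Carlo error", {
  skip_if_not_installed("vegan")
  set.seed(14)
  n <- 8
  A <- toy_pairwise(n); B <- toy_pairwise(n)
  ours <- mantel_test(A, B, n_perm = 9999, seed = 2)
  veg <- vegan::mantel(as.dist(unclass(A)), as.dist(unclass(B)),
                       permutations = 9999)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - veg$signif), 0.03)
})

test_that("partial Mantel reduces to the plain test and matches brute force", {
  set.seed(30)
  A <- toy_pairwise(5); B <- toy_pairwise(5); C <- toy_pairwise(5)
  # formula identity against direct arithmetic
  r_ab <- cor(A[upper.tri(A)], B[upper.tri(B)])
  r_ac <- cor(A[upper.tri(A)], C[upper.tri(C)])
  r_bc <- cor(B[upper.tri(B)], C[upper.tri(C)])
  res <- partial_mantel_test(A, B, C)
  expect_equal(res$r, (r_ab - r_ac * r_bc) /
                 sqrt((1 - r_ac^2) * (1 - r_bc^2)), tolerance = 1e-12)

  # A = B gives r = 1 whenever defined
  res_ab <- partial_mantel_test(A, A, C)
  expect_equal(res_ab$r, 1, tolerance = 1e-9)

  # brute-force exhaustive null with the independent permutation oracle
  perms <- oracle_permutations(5)
  stat <- apply(perms, 1, function(pm) {
    ap <- unclass(A)[pm, pm]
    ua <- ap[upper.tri(ap)]
    rab <- cor(ua, B[upper.tri(B)]); rac <- cor(ua, C[upper.tri(C)])
    (rab - rac * r_bc) / sqrt((1 - rac^2) * (1 - r_bc^2))
  })
  expect_equal(res$p, mean(stat >= res$r - 1e-12), tolerance = 1e-12)

  skip_if_not_installed("vegan")
  veg <- vegan::mantel.partial(as.dist(unclass(A)), as.dist(unclass(B)),
                               as.dist(unclass(C)), permutations = 999)
  expect_equal(res$r, unname(veg$statistic), tolerance = 1e-12)
})
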