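# Distance matrices and Mantel / partial Mantel permutation inference.
# The Mantel null permutes rows and columns of one matrix jointly; with
# n <= 7 populations the full n! permutation set is enumerated and the
# p-value is the exact proportion of permutations at least as extreme
# (identity included), so the minimal one-tailed p at n = 5 is 1/120.

#' Great-circle distance matrix between populations
#'
#' Haversine distances (Earth radius 6,371 km) between population
#' coordinates, in kilometres.
#'
#' @param m a [population_metadata()].
#' @return a [pairwise_matrix()] in km.
#' @export
geo_distance_matrix <- function(m) {
  stopifnot(inherits(m, "population_metadata"))
  bad <- is.na(m$latitude) | is.na(m$longitude)
  if (any(bad))
    stop("missing coordinates for population(s): ",
         paste(m$population[bad], collapse = ", "), call. = FALSE)
  xy <- cbind(m$longitude, m$latitude)
  d <- geosphere::distm(xy, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371000)) / 1000
  pairwise_matrix(d, m$population)
}

#' Absolute altitude-difference matrix
#'
#' Entry (i, j) is \eqn{|alt_i - alt_j|} in metres.
#'
#' @param m a [population_metadata()].
#' @return a [pairwise_matrix()] in metres.
#' @export
altitude_diff_matrix <- function(m) {
  stopifnot(inherits(m, "population_metadata"))
  d <- abs(outer(m$altitude, m$altitude, "-"))
  pairwise_matrix(d, m$population)
}

#' Linearize an F_ST matrix for isolation-by-distance analysis
#'
#' Entry-wise \eqn{F/(1-F)}.  Entries equal to 1 are an error; negative
#' entries are clamped to 0 with a warning (sampling noise below the
#' parameter space).
#'
#' @param f a [pairwise_matrix()] of \eqn{F_{ST}} values.
#' @return a [pairwise_matrix()].
#' @export
linearize_fst <- function(f) {
  v <- unclass(f)
  if (any(v >= 1, na.rm = TRUE))
    stop("cannot linearize: F_ST entry equal to or above 1", call. = FALSE)
  if (any(v < 0, na.rm = TRUE)) {
    warning("negative F_ST entries clamped to 0 before linearization",
            call. = FALSE)
    v[v < 0] <- 0
  }
  pairwise_matrix(v / (1 - v), rownames(f))
}

#' Log-transform a distance matrix
#'
#' Companion transform for the isolation-by-distance regression of
#' \eqn{F/(1-F)} on log distance.  Zero off-diagonal distances are
#' rejected; the diagonal is kept at 0 by convention.
#'
#' @param d a [pairwise_matrix()] of positive distances.
#' @return a [pairwise_matrix()] of log distances.
#' @export
log_distance_matrix <- function(d) {
  v <- unclass(d)
  off <- upper_entries(v)
  if (any(off <= 0, na.rm = TRUE))
    stop("log transform undefined: zero or negative off-diagonal distance",
         call. = FALSE)
  out <- log(v)
  diag(out) <- 0
  pairwise_matrix(out, rownames(d))
}

# Shared validation for Mantel-type tests.
check_mantel_inputs <- function(...) {
  mats <- list(...)
  labels <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(rownames(m), labels))
      stop("matrix labels do not match", call. = FALSE)
    off <- upper_entries(unclass(m))
    if (anyNA(off))
      stop("Mantel test requires complete matrices", call. = FALSE)
    if (isTRUE(all.equal(var(off), 0)) || var(off) == 0)
      stop("degenerate input: constant off-diagonal entries", call. = FALSE)
  }
  if (length(labels) < 4)
    stop("Mantel test needs at least 4 populations", call. = FALSE)
  labels
}

#' Mantel permutation test
#'
#' Pearson correlation of the upper-triangle entries of two conformable
#' distance matrices.  The null distribution permutes the rows and columns
#' of `B` jointly while `A` stays fixed.  With `n <= 7` populations all
#' `n!` relabelings are enumerated and the p-value is the exact proportion
#' of permutations at least as extreme as the observed correlation;
#' otherwise `n_perm` random permutations are drawn and the add-one
#' p-value reported.
#'
#' @param A,B [pairwise_matrix()] objects with identical labels.
#' @param n_perm permutations in sampled mode.
#' @param seed optional RNG seed (sampled mode only).
#' @param tail `"greater"` (default, positive association), `"less"` or
#'   `"two-sided"`.
#' @param method `"auto"` (exhaustive for `n <= 7`, sampled otherwise) or
#'   an explicit override.
#' @return object of class `"mantel_result"`: `r`, `p`, `n_perm`, `tail`,
#'   `method` (`"exhaustive"` or `"sampled"`).
#' @export
mantel_test <- function(A, B, n_perm = 9999, seed = NULL,
                        tail = c("greater", "less", "two-sided"),
                        method = c("auto", "exhaustive", "sampled")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  labels <- check_mantel_inputs(A, B)
  n <- length(labels)
  a <- unclass(A); b <- unclass(B)
  r_obs <- cor(upper_entries(a), upper_entries(b))
  ua <- upper_entries(a)
  stat <- function(perm) cor(ua, upper_entries(b[perm, perm]))
  if (method == "exhaustive" || (method == "auto" && n <= 7)) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, stat)
    p <- switch(tail,
      greater = mean(r_perm >= r_obs - 1e-12),
      less = mean(r_perm <= r_obs + 1e-12),
      `two-sided` = mean(abs(r_perm) >= abs(r_obs) - 1e-12))
    method <- "exhaustive"; n_used <- nrow(perms)
  } else {
    r_perm <- with_seed(seed,
      vapply(seq_len(n_perm), function(k) stat(sample.int(n)), numeric(1)))
    p <- perm_pvalue(r_obs, r_perm, tail)
    method <- "sampled"; n_used <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = n_used, tail = tail,
                 method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, digits = 3, ...) {
  lbl <- if (!is.null(x$controlled)) "Partial Mantel" else "Mantel"
  cat(sprintf("%s test: r = %.3f, p = %.4g (%s, %d permutations, tail = %s)\n",
              lbl, x$r, x$p, x$method, x$n_perm, x$tail))
  invisible(x)
}

# First-order partial correlation from three pairwise correlations.
partial_r <- function(r_ab, r_ac, r_bc) {
  (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
}

#' Partial Mantel permutation test
#'
#' Correlation between matrices `A` and `B` controlling for `C`, computed
#' as the first-order partial correlation of the three pairwise Mantel
#' correlations.  The null permutes `A`'s rows and columns jointly and
#' recomputes the partial statistic (`r_BC` stays fixed).  Exhaustive for
#' `n <= 7` as in [mantel_test()].
#'
#' @param A,B,C conformable [pairwise_matrix()] objects.
#' @param n_perm permutations in sampled mode.
#' @param seed optional RNG seed.
#' @param tail,method as in [mantel_test()].
#' @return a `"mantel_result"` with `controlled = TRUE`.
#' @export
partial_mantel_test <- function(A, B, C, n_perm = 9999, seed = NULL,
                                tail = c("greater", "less", "two-sided"),
                                method = c("auto", "exhaustive", "sampled")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  labels <- check_mantel_inputs(A, B, C)
  n <- length(labels)
  a <- unclass(A); ub <- upper_entries(unclass(B)); uc <- upper_entries(unclass(C))
  r_bc <- cor(ub, uc)
  stat <- function(perm) {
    ua <- upper_entries(a[perm, perm])
    r_ab <- cor(ua, ub); r_ac <- cor(ua, uc)
    if (abs(r_ac) >= 1 || abs(r_bc) >= 1) return(NA_real_)
    partial_r(r_ab, r_ac, r_bc)
  }
  r_obs <- stat(seq_len(n))
  if (!is.finite(r_obs))
    stop("degenerate partial correlation: a controlling correlation is +/-1",
         call. = FALSE)
  if (method == "exhaustive" || (method == "auto" && n <= 7)) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, stat)
    r_perm <- r_perm[is.finite(r_perm)]
    p <- switch(tail,
      greater = mean(r_perm >= r_obs - 1e-12),
      less = mean(r_perm <= r_obs + 1e-12),
      `two-sided` = mean(abs(r_perm) >= abs(r_obs) - 1e-12))
    method <- "exhaustive"; n_used <- nrow(perms)
  } else {
    r_perm <- with_seed(seed,
      vapply(seq_len(n_perm), function(k) stat(sample.int(n)), numeric(1)))
    r_perm <- r_perm[is.finite(r_perm)]
    p <- perm_pvalue(r_obs, r_perm, tail)
    method <- "sampled"; n_used <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = n_used, tail = tail,
                 method = method, controlled = TRUE),
            class = "mantel_result")
}
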