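# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards.  seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a master seed, kept inside 32-bit range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103 + as.numeric(stage) * 12347) %%
               2147483587)
}

#' Construct a symmetric population-by-population matrix
#'
#' Container used throughout the pipeline for pairwise \eqn{F_{ST}},
#' pairwise \eqn{Q_{ST}}, geographic distances and altitude differences:
#' a symmetric numeric matrix with zero diagonal and stable population
#' labels.  Off-diagonal entries may be `NA` where an estimate failed.
#'
#' @param values square numeric matrix, or a single number to fill all
#'   off-diagonals.
#' @param labels character vector of population labels; defaults to the
#'   dimnames of `values`.
#' @return a matrix of class `"pairwise_matrix"`.
#' @export
pairwise_matrix <- function(values, labels = NULL) {
  if (is.null(dim(values)) && length(values) == 1L && !is.null(labels)) {
    n <- length(labels)
    values <- matrix(values, n, n)
    diag(values) <- 0
  }
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("pairwise matrix must be square", call. = FALSE)
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("pop", seq_len(nrow(values)))
  if (length(labels) != nrow(values))
    stop("label length does not match matrix dimension", call. = FALSE)
  dimnames(values) <- list(labels, labels)
  if (any(abs(diag(values)) > 1e-12, na.rm = TRUE))
    stop("pairwise matrix diagonal must be zero", call. = FALSE)
  diag(values) <- 0
  off <- !is.na(values) & !is.na(t(values))
  if (any(abs(values[off] - t(values)[off]) > 1e-8))
    stop("pairwise matrix must be symmetric", call. = FALSE)
  values[lower.tri(values)] <- t(values)[lower.tri(values)]
  class(values) <- c("pairwise_matrix", class(values))
  values
}

#' @export
print.pairwise_matrix <- function(x, digits = 4, ...) {
  cat("Pairwise matrix (", nrow(x), " populations)\n", sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

# Upper-triangle (i < j) entries in a fixed column-major order.
upper_entries <- function(m) m[upper.tri(m)]

# All permutations of 1..n as an (n! x n) integer matrix, lexicographic.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    idx <- seq.int(row, row + nrow(sub) - 1L)
    out[idx, 1L] <- k
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

# Add-one permutation p-value: share of permuted statistics at least as
# extreme as the observed one, counting the identity.
perm_pvalue <- function(stat_obs, stat_perm, tail = "greater") {
  switch(tail,
    greater = (1 + sum(stat_perm >= stat_obs)) / (length(stat_perm) + 1),
    less    = (1 + sum(stat_perm <= stat_obs)) / (length(stat_perm) + 1),
    `two-sided` = (1 + sum(abs(stat_perm) >= abs(stat_obs))) /
      (length(stat_perm) + 1),
    stop("unknown tail: ", tail, call. = FALSE))
}
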