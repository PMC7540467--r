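# Neutral differentiation from multi-allelic co-dominant markers:
# Weir & Cockerham (1984) theta as a ratio of sums of the among-population
# (a), between-individual-within-population (b) and within-individual (c)
# variance components, accumulated over loci and alleles.

#' Allele frequencies in one population
#'
#' Tallies allele frequencies per locus for one population, excluding
#' missing calls locus-wise.  Loci with no non-missing call in the
#' population are dropped with a warning.
#'
#' @param g a [genotype_table()].
#' @param population population label.
#' @return named list, one element per retained locus:
#'   `freq` (named frequency vector summing to 1) and `n` (allele count).
#' @export
allele_frequencies <- function(g, population) {
  stopifnot(inherits(g, "genotype_table"))
  if (!population %in% levels(g$population))
    stop("unknown population: ", population, call. = FALSE)
  idx <- g$population == population
  out <- list()
  dropped <- character()
  for (l in g$loci) {
    alleles <- c(g$allele1[idx, l], g$allele2[idx, l])
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) { dropped <- c(dropped, l); next }
    tab <- table(alleles)
    out[[l]] <- list(freq = as.numeric(tab) / length(alleles), n = length(alleles))
    names(out[[l]]$freq) <- names(tab)
  }
  if (length(dropped))
    warning("locus with all-missing calls excluded in ", population, ": ",
            paste(dropped, collapse = ", "), call. = FALSE)
  out
}

# Per-locus Weir-Cockerham components for a set of populations.
# Returns a data.frame with one row per locus: a, b, c summed over alleles,
# n_pops used, and a monomorphic flag.  Loci with < 2 populations carrying
# data, or monomorphic loci, carry zero components and are flagged.
wc_components <- function(g) {
  loci <- g$loci
  pops <- levels(g$population)
  res <- data.frame(locus = loci, a = 0, b = 0, c = 0,
                    n_pops = 0L, informative = FALSE,
                    stringsAsFactors = FALSE)
  for (li in seq_along(loci)) {
    l <- loci[li]
    x1 <- g$allele1[, l]; x2 <- g$allele2[, l]
    ok <- !is.na(x1)
    if (!any(ok)) next
    pop <- g$population[ok]; y1 <- x1[ok]; y2 <- x2[ok]
    n_i <- tapply(rep(1, length(pop)), pop, sum, default = 0)
    keep_pops <- names(n_i)[n_i > 0]
    if (length(keep_pops) < 2) next
    sel <- pop %in% keep_pops
    pop <- droplevels(pop[sel]); y1 <- y1[sel]; y2 <- y2[sel]
    alleles <- sort(unique(c(y1, y2)))
    res$n_pops[li] <- nlevels(pop)
    if (length(alleles) < 2) next          # monomorphic: 0/0, skipped
    r <- nlevels(pop)
    n_i <- as.numeric(table(pop))           # diploid individuals per pop
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    A <- B <- C <- 0
    for (al in alleles) {
      cnt <- (y1 == al) + (y2 == al)
      p_i <- tapply(cnt, pop, mean) / 2
      h_i <- tapply(cnt == 1L, pop, mean)   # heterozygotes carrying allele
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
    res$a[li] <- A; res$b[li] <- B; res$c[li] <- C
    res$informative[li] <- TRUE
  }
  res
}

#' Weir-Cockerham theta (overall F_ST)
#'
#' Multi-allelic Weir & Cockerham (1984) estimator: for every locus and
#' allele the among-population (a), between-individual (b) and
#' within-individual (c) components are computed from allele frequencies,
#' observed heterozygosities and per-locus sample sizes; theta is the ratio
#' of sums \eqn{\sum a / \sum (a+b+c)} across loci and alleles.
#' Monomorphic loci contribute 0/0 and are skipped.  Negative estimates are
#' reported as computed.
#'
#' @param g a [genotype_table()].
#' @param populations optional subset of population labels.
#' @return object of class `"fst_estimate"`: `theta`, `per_locus`
#'   (data.frame of locus components), `n_populations`, `p_value`
#'   (`NA` until [fst_permutation_pvalue()] is run).
#' @export
wc_fst <- function(g, populations = NULL) {
  stopifnot(inherits(g, "genotype_table"))
  if (!is.null(populations)) g <- subset_populations(g, populations)
  if (nlevels(g$population) < 2)
    stop("F_ST requires at least two populations", call. = FALSE)
  comp <- wc_components(g)
  if (!any(comp$informative))
    stop("undefined estimate: all loci are monomorphic", call. = FALSE)
  used <- comp[comp$informative, ]
  theta <- sum(used$a) / sum(used$a + used$b + used$c)
  structure(
    list(theta = theta, per_locus = comp,
         n_populations = nlevels(g$population),
         n_individuals = length(g$individuals),
         p_value = NA_real_, n_perm = NA_integer_),
    class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, digits = 4, ...) {
  cat("Weir-Cockerham F_ST over ", sum(x$per_locus$informative),
      " informative loci, ", x$n_populations, " populations\n", sep = "")
  cat("  theta =", format(round(x$theta, digits)), "\n")
  if (!is.na(x$p_value))
    cat("  permutation p =", format(x$p_value), "(", x$n_perm,
        "permutations )\n")
  invisible(x)
}

#' Pairwise F_ST matrix
#'
#' Entry (i, j) is [wc_fst()] recomputed on the two-population subset.
#' Negative point estimates are retained; pairs where the estimate is
#' undefined (all loci monomorphic) become `NA` with a warning.
#'
#' @param g a [genotype_table()].
#' @return a [pairwise_matrix()].
#' @export
pairwise_fst <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  pops <- levels(g$population)
  if (length(pops) < 2)
    stop("pairwise F_ST requires at least two populations", call. = FALSE)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in seq.int(i + 1L, length(pops))) {
      est <- tryCatch(wc_fst(g, populations = c(pops[i], pops[j]))$theta,
                      error = function(e) {
                        warning("pairwise F_ST undefined for ", pops[i], "-",
                                pops[j], ": ", conditionMessage(e),
                                call. = FALSE)
                        NA_real_
                      })
      m[i, j] <- m[j, i] <- est
    }
  }
  pairwise_matrix(m, pops)
}

#' Permutation test of overall F_ST
#'
#' Individuals (both alleles together) are permuted among populations with
#' population sizes held fixed; theta is recomputed for each permutation and
#' the add-one p-value \eqn{(1 + \#\{\theta^* \ge \theta\})/(n_{perm}+1)}
#' returned.
#'
#' @param g a [genotype_table()].
#' @param n_perm number of permutations (>= 99).
#' @param seed optional RNG seed for reproducibility.
#' @return the input's [wc_fst()] estimate with `p_value` and `n_perm`
#'   filled in.
#' @export
fst_permutation_pvalue <- function(g, n_perm = 999, seed = NULL) {
  stopifnot(inherits(g, "genotype_table"))
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  obs <- wc_fst(g)
  theta_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      gp <- g
      gp$population <- sample(g$population)
      wc_fst(gp)$theta
    }, numeric(1))
  })
  obs$p_value <- perm_pvalue(obs$theta, theta_perm, "greater")
  obs$n_perm <- as.integer(n_perm)
  obs
}

#' Per-locus gene diversity (expected heterozygosity)
#'
#' Unbiased within-population gene diversity
#' \eqn{H_s = \frac{n}{n-1}(1 - \sum_k p_k^2)} with \eqn{n} the allele
#' count, computed per population and averaged over populations weighted by
#' allele sample size.  Monomorphic loci return 0.
#'
#' @param g a [genotype_table()].
#' @return named numeric vector, one entry per locus with data.
#' @export
gene_diversity <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  pops <- levels(g$population)
  freqs <- lapply(pops, function(p)
    suppressWarnings(allele_frequencies(g, p)))
  names(freqs) <- pops
  out <- numeric(0)
  for (l in g$loci) {
    hs <- ns <- numeric(0)
    for (p in pops) {
      fl <- freqs[[p]][[l]]
      if (is.null(fl)) next
      n <- fl$n
      h <- if (n > 1) (n / (n - 1)) * (1 - sum(fl$freq^2)) else 0
      hs <- c(hs, h); ns <- c(ns, n)
    }
    if (length(hs)) out[l] <- sum(hs * ns) / sum(ns)
  }
  out
}
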