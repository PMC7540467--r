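# Shared builders for small in-code fixtures.

# Genotype table from a list of populations, each a list of c(a1, a2)
# calls per individual at a single locus -- or a list of per-locus lists.
toy_genotypes <- function(pops, loci = NULL) {
  flat <- lapply(pops, function(p) do.call(rbind, p))
  n_loci <- ncol(flat[[1]]) / 2
  a1 <- do.call(rbind, lapply(flat, function(m) m[, seq(1, 2 * n_loci, 2),
                                                  drop = FALSE]))
  a2 <- do.call(rbind, lapply(flat, function(m) m[, seq(2, 2 * n_loci, 2),
                                                  drop = FALSE]))
  genotype_table(a1, a2,
                 rep(names(pops), vapply(pops, length, integer(1))),
                 loci = loci)
}

# Balanced phenotype table: npop populations x nfam families x ns sibs,
# with explicit variance components and an optional block design.
balanced_phenotypes <- function(npop = 6, nfam = 8, ns = 2,
                                v_b = 1, v_w = 0.5, v_block = 0, v_res = 1,
                                mu = 10, n_blocks = 0, subspecies = "sub_a") {
  n <- npop * nfam * ns
  pop <- rep(sprintf("p%02d", seq_len(npop)), each = nfam * ns)
  fam <- rep(sprintf("f%02d", seq_len(nfam)), times = npop, each = ns)
  blk <- if (n_blocks > 0) sample(rep(sprintf("b%02d", seq_len(n_blocks)),
                                      length.out = n)) else "b01"
  key <- paste(pop, fam)
  y <- mu +
    rnorm(npop, sd = sqrt(v_b))[match(pop, unique(pop))] +
    rnorm(npop * nfam, sd = sqrt(v_w))[match(key, unique(key))] +
    (if (n_blocks > 0) rnorm(n_blocks, sd = sqrt(v_block))[
      match(blk, sprintf("b%02d", seq_len(n_blocks)))] else 0) +
    rnorm(n, sd = sqrt(v_res))
  phenotype_table(data.frame(
    individual = sprintf("i%04d", seq_len(n)), subspecies = subspecies,
    population = pop, family = fam, block = blk, y = y,
    stringsAsFactors = FALSE), traits = "y")
}

# Random symmetric distance-like matrix with labelled populations.
toy_pairwise <- function(n, labels = sprintf("p%d", seq_len(n))) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  pairwise_matrix(m, labels)
}

# Independent permutation enumerator (iterative heap-style, deliberately
# distinct from the package's recursive generator) used as an oracle.
oracle_permutations <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (k in 2:n) {
    grown <- vector("list", nrow(out) * k)
    idx <- 1L
    for (r in seq_len(nrow(out))) {
      row <- out[r, ]
      for (pos in seq_len(k)) {
        grown[[idx]] <- append(row, k, after = pos - 1L)
        idx <- idx + 1L
      }
    }
    out <- do.call(rbind, grown)
  }
  out
}
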