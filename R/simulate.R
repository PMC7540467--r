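# Synthetic study generator.  Emulates the snapdragon common-garden design:
# 13 populations in two subspecies (8 + 5), 9-42 full-sib families per
# population, 2 sibs per family, a randomized block design of 40 containers
# holding 24 plants each, 23 multi-allelic neutral loci at among-population
# F_ST ~ 0.10, and populations spread over a 61-1,564 m altitude range.

default_trait_specs <- function() {
  # Variance components in trait units^2.  Chosen to span the study's
  # reported ranges: full-sib h2 from ~0.3 to ~0.9 and Q_ST regimes from
  # stabilizing (germination date) through neutral to strongly divergent
  # (plant height, internode length), plus altitudinal clines on node and
  # branch counts matching the printed regression slopes.
  data.frame(
    trait = c("germination_date", "diameter", "nodes", "branches",
              "plant_height", "internode_length", "sla"),
    mean = c(30, 5, 12, 18, 80, 4, 200),
    V_b = c(0.2, 0.05, 0.8, 1.0, 120, 0.9, 150),
    V_w = c(2, 0.1, 0.8, 1.2, 12, 0.12, 250),
    V_block = c(0.5, 0.02, 0.3, 0.4, 5, 0.03, 60),
    V_res = c(4, 0.3, 2.2, 3.0, 30, 0.17, 300),
    altitude_slope = c(0, 0, 0.00125, -0.00048, 0, 0, 0),
    stringsAsFactors = FALSE)
}

#' Define a synthetic study design
#'
#' Defaults reproduce the common-garden design the analysis assumes:
#' two subspecies with 8 and 5 populations, 9-42 full-sib families per
#' population, 2 sibs per family, 40 blocks of capacity 24, 23 loci with
#' 3-12 alleles at target \eqn{F_{ST}} 0.10, and altitudes of origin
#' between 61 and 1,564 m.
#'
#' @param n_pops named integer vector: populations per subspecies.
#' @param families_per_pop length-2 range from which family counts are
#'   drawn per population.
#' @param sibs_per_family full sibs grown per family.
#' @param n_blocks,block_capacity randomized block design dimensions.
#' @param n_loci,alleles_per_locus marker panel size and allele-count range.
#' @param target_fst among-population differentiation of the marker panel.
#' @param altitude_range altitude-of-origin range in metres.
#' @param trait_specs data.frame with columns `trait`, `mean`, `V_b`,
#'   `V_w`, `V_block`, `V_res`, `altitude_slope`.
#' @return object of class `"study_design"`.
#' @export
study_design <- function(n_pops = c(pseudomajus = 8L, striatum = 5L),
                         families_per_pop = c(9L, 42L),
                         sibs_per_family = 2L,
                         n_blocks = 40L, block_capacity = 24L,
                         n_loci = 23L, alleles_per_locus = c(3L, 12L),
                         target_fst = 0.10,
                         altitude_range = c(61, 1564),
                         trait_specs = default_trait_specs()) {
  stopifnot(all(n_pops >= 1), length(families_per_pop) == 2,
            sibs_per_family >= 1, n_loci >= 1,
            target_fst > 0, target_fst < 1)
  if (is.null(names(n_pops)))
    names(n_pops) <- paste0("subsp", seq_along(n_pops))
  need <- c("trait", "mean", "V_b", "V_w", "V_block", "V_res",
            "altitude_slope")
  if (!all(need %in% names(trait_specs)))
    stop("trait_specs must carry columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(trait_specs[c("V_b", "V_w", "V_block", "V_res")] < 0))
    stop("variance components must be non-negative", call. = FALSE)
  # feasibility on the expected family draw; the realized draw is checked
  # again when plants are assigned to blocks
  exp_plants <- sum(n_pops) * mean(families_per_pop) * sibs_per_family
  if (exp_plants > n_blocks * block_capacity)
    stop("infeasible design: ~", round(exp_plants), " plants exceed block ",
         "capacity ", n_blocks * block_capacity, call. = FALSE)
  structure(list(n_pops = n_pops, families_per_pop = families_per_pop,
                 sibs_per_family = sibs_per_family, n_blocks = n_blocks,
                 block_capacity = block_capacity, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus,
                 target_fst = target_fst, altitude_range = altitude_range,
                 trait_specs = trait_specs),
            class = "study_design")
}

# Population labels and subspecies assignment implied by a design.
design_populations <- function(d) {
  subsp <- rep(names(d$n_pops), d$n_pops)
  pop <- unlist(lapply(names(d$n_pops), function(s)
    sprintf("%s%02d", toupper(substr(s, 1, 2)), seq_len(d$n_pops[[s]]))))
  data.frame(population = pop, subspecies = subsp, stringsAsFactors = FALSE)
}

# Family counts per population, drawn uniformly on the design range.
draw_family_counts <- function(d) {
  pops <- design_populations(d)
  rng <- d$families_per_pop
  counts <- if (rng[1] == rng[2]) rep(rng[1], nrow(pops)) else
    sample(seq.int(rng[1], rng[2]), nrow(pops), replace = TRUE)
  setNames(as.integer(counts), pops$population)
}

# k Dirichlet(alpha) draws via gamma normalization.
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[sample.int(length(x), 1)] <- 1
  x / sum(x)
}

#' Simulate neutral multi-allelic genotypes (Balding-Nichols model)
#'
#' Ancestral allele frequencies per locus are Dirichlet(1, ..., 1);
#' population frequencies are Dirichlet with concentration
#' \eqn{p_{anc}(1-F)/F}, so their expected among-population
#' differentiation equals the design's `target_fst`; diploid genotypes are
#' independent draws from the population frequencies.
#'
#' @param d a [study_design()].
#' @param seed RNG seed.
#' @param individuals either `NULL` (family counts drawn from the design,
#'   sibs genotyped), a single count per population, or a data.frame with
#'   columns `id`, `population`.
#' @param missing_rate proportion of calls set to missing.
#' @return a [genotype_table()].
#' @export
simulate_genotypes <- function(d, seed = NULL, individuals = NULL,
                               missing_rate = 0) {
  stopifnot(inherits(d, "study_design"))
  with_seed(seed, {
    pops <- design_populations(d)
    if (is.null(individuals)) {
      fam <- draw_family_counts(d)
      n_i <- fam * d$sibs_per_family
      individuals <- data.frame(
        id = unlist(lapply(pops$population, function(p)
          paste0(p, "_i", seq_len(n_i[[p]])))),
        population = rep(pops$population, n_i),
        stringsAsFactors = FALSE)
    } else if (is.numeric(individuals) && length(individuals) == 1L) {
      individuals <- data.frame(
        id = unlist(lapply(pops$population, function(p)
          paste0(p, "_i", seq_len(individuals)))),
        population = rep(pops$population, each = individuals),
        stringsAsFactors = FALSE)
    }
    n <- nrow(individuals)
    a1 <- a2 <- matrix(NA_integer_, n, d$n_loci)
    loci <- sprintf("loc%02d", seq_len(d$n_loci))
    F <- d$target_fst
    for (l in seq_len(d$n_loci)) {
      k <- if (d$alleles_per_locus[1] == d$alleles_per_locus[2])
        d$alleles_per_locus[1] else
        sample(seq.int(d$alleles_per_locus[1], d$alleles_per_locus[2]), 1L)
      p_anc <- rdirichlet1(rep(1, k))
      for (p in pops$population) {
        p_pop <- rdirichlet1(p_anc * (1 - F) / F)
        rows <- which(individuals$population == p)
        a1[rows, l] <- sample.int(k, length(rows), replace = TRUE,
                                  prob = p_pop)
        a2[rows, l] <- sample.int(k, length(rows), replace = TRUE,
                                  prob = p_pop)
      }
    }
    if (missing_rate > 0) {
      drop <- matrix(runif(n * d$n_loci) < missing_rate, n, d$n_loci)
      a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
    }
    genotype_table(a1, a2, individuals$population, individuals$id, loci)
  })
}

#' Simulate phenotypes, metadata and truth for a study design
#'
#' Altitudes of origin are uniform on the design range; each trait value is
#' \deqn{y = \mu + slope \cdot alt + b_{pop} + f_{family} + c_{block} + e}
#' with independent zero-mean Gaussian effects at the design's variances.
#' Plants are assigned to blocks by randomized fill respecting capacity.
#'
#' @param d a [study_design()].
#' @param seed RNG seed.
#' @return list with `phenotypes` ([phenotype_table()]), `metadata`
#'   ([population_metadata()]) and `truth` (generating parameters:
#'   family counts, altitudes, per-trait variance components and slopes).
#' @export
simulate_phenotypes <- function(d, seed = NULL) {
  stopifnot(inherits(d, "study_design"))
  with_seed(seed, {
    pops <- design_populations(d)
    np <- nrow(pops)
    fam_counts <- draw_family_counts(d)
    altitude <- runif(np, d$altitude_range[1], d$altitude_range[2])
    latitude <- runif(np, 42.2, 43.2)     # Pyrenean band
    longitude <- runif(np, 0.0, 3.0)
    meta <- population_metadata(data.frame(
      population = pops$population, subspecies = pops$subspecies,
      latitude = round(latitude, 5), longitude = round(longitude, 5),
      altitude = round(altitude, 1), stringsAsFactors = FALSE))

    pop_of <- rep(pops$population, fam_counts[pops$population] *
                    d$sibs_per_family)
    fam_of <- unlist(lapply(pops$population, function(p)
      rep(sprintf("f%03d", seq_len(fam_counts[[p]])),
          each = d$sibs_per_family)))
    n <- length(pop_of)
    ids <- unlist(lapply(pops$population, function(p)
      paste0(p, "_i", seq_len(fam_counts[[p]] * d$sibs_per_family))))
    if (n > d$n_blocks * d$block_capacity)
      stop("infeasible block assignment: ", n, " plants for ",
           d$n_blocks * d$block_capacity, " container slots", call. = FALSE)
    slots <- sample(rep(seq_len(d$n_blocks), d$block_capacity))[seq_len(n)]
    block_of <- sprintf("b%02d", slots)

    df <- data.frame(individual = ids,
                     subspecies = rep(pops$subspecies,
                                      fam_counts[pops$population] *
                                        d$sibs_per_family),
                     population = pop_of, family = fam_of,
                     block = block_of, stringsAsFactors = FALSE)
    truth <- list(family_counts = as.list(fam_counts),
                  altitude = setNames(as.list(round(altitude, 1)),
                                      pops$population),
                  traits = list())
    alt_of_pop <- setNames(altitude, pops$population)
    fam_key <- paste(df$population, df$family, sep = ":")
    ufam <- unique(fam_key)
    ublk <- unique(df$block)
    for (i in seq_len(nrow(d$trait_specs))) {
      sp <- d$trait_specs[i, ]
      b <- rnorm(np, sd = sqrt(sp$V_b))[match(df$population, pops$population)]
      f <- rnorm(length(ufam), sd = sqrt(sp$V_w))[match(fam_key, ufam)]
      cbl <- rnorm(length(ublk), sd = sqrt(sp$V_block))[match(df$block, ublk)]
      e <- rnorm(n, sd = sqrt(sp$V_res))
      df[[sp$trait]] <- sp$mean + sp$altitude_slope * alt_of_pop[df$population] +
        b + f + cbl + e
      truth$traits[[sp$trait]] <- as.list(sp[c("mean", "V_b", "V_w",
                                               "V_block", "V_res",
                                               "altitude_slope")])
    }
    list(phenotypes = phenotype_table(df, traits = d$trait_specs$trait),
         metadata = meta, truth = truth)
  })
}

#' Write a complete miniature synthetic study to disk
#'
#' Generates a small study that exercises every pipeline stage quickly:
#' four traits -- one neutral (population variance drawn from the neutral
#' expectation \eqn{2F/(1-F) \cdot V_A}), one divergent (true
#' \eqn{Q_{ST} \gg F_{ST}}), one uniform (true \eqn{Q_{ST} \ll F_{ST}})
#' and one with an altitudinal cline -- plus a matching marker panel.
#' Writes `genotypes.gen`, `phenotypes.csv`, `metadata.csv` and
#' `truth.yaml`; regeneration with the same seed is byte-identical.
#'
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @param families_per_pop family-count range of the miniature design.
#' @return invisible list of the written paths plus the in-memory objects.
#' @export
generate_fixture_study <- function(seed = 1, dir = tempfile("study"),
                                   families_per_pop = c(12L, 12L)) {
  F <- 0.10
  v_w <- 0.5                    # with V_res = 1.5: true full-sib h2 = 0.5
  v_a <- 2 * v_w
  specs <- data.frame(
    trait = c("neutral_trait", "divergent_trait", "uniform_trait",
              "cline_trait"),
    mean = c(10, 10, 10, 12),
    V_b = c(2 * F / (1 - F) * v_a, 4 * v_w * 0.7 / (1 - 0.7), 0.001,
            2 * F / (1 - F) * v_a),
    V_w = v_w, V_block = 0.25, V_res = 1.5,
    altitude_slope = c(0, 0, 0, 0.00125),
    stringsAsFactors = FALSE)
  d <- study_design(families_per_pop = families_per_pop,
                    trait_specs = specs)
  sim <- simulate_phenotypes(d, seed = derive_seed(seed, 1L))
  g <- simulate_genotypes(d, seed = derive_seed(seed, 2L),
                          individuals = data.frame(
                            id = sim$phenotypes$individual,
                            population = sim$phenotypes$population,
                            stringsAsFactors = FALSE))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genotypes = file.path(dir, "genotypes.gen"),
                phenotypes = file.path(dir, "phenotypes.csv"),
                metadata = file.path(dir, "metadata.csv"),
                truth = file.path(dir, "truth.yaml"))
  write_genepop(g, paths$genotypes, title = "synthetic study")
  write_phenotype_csv(sim$phenotypes, paths$phenotypes)
  write_population_metadata(sim$metadata, paths$metadata)
  truth <- sim$truth
  truth$design <- list(target_fst = F, n_pops = as.list(d$n_pops),
                       sibs_per_family = d$sibs_per_family,
                       n_blocks = d$n_blocks,
                       block_capacity = d$block_capacity,
                       n_loci = d$n_loci, seed = seed)
  yaml::write_yaml(truth, paths$truth)
  invisible(list(paths = paths, design = d, phenotypes = sim$phenotypes,
                 metadata = sim$metadata, genotypes = g, truth = truth))
}
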