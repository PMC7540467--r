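# Population- and subspecies-level phenotypic divergence models: ML
# likelihood-ratio tests of the population effect, block-adjusted marginal
# means, altitudinal regressions, and the sequential variance-explained
# partition of subspecies vs populations-in-subspecies.

#' Likelihood-ratio test of the population effect
#'
#' Maximum-likelihood (not REML) fits of
#' `y ~ population + (1 | block)` against `y ~ 1 + (1 | block)`; the
#' statistic is referred to \eqn{\chi^2} with `n_pops - 1` degrees of
#' freedom.
#'
#' @param p a [phenotype_table()].
#' @param trait trait name.
#' @param populations optional scope.
#' @return list with `trait`, `lrt`, `df`, `p_value`.
#' @export
population_effect_lrt <- function(p, trait, populations = NULL) {
  df <- vc_frame(p, trait, populations)
  if (nlevels(df$population) < 2)
    stop("population LRT needs >= 2 populations", call. = FALSE)
  ctl <- vc_engine_control()
  full <- lme4::lmer(y ~ population + (1 | block), data = df, REML = FALSE,
                     control = ctl)
  null <- lme4::lmer(y ~ 1 + (1 | block), data = df, REML = FALSE,
                     control = ctl)
  lrt <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  k <- nlevels(df$population) - 1L
  list(trait = trait, lrt = lrt, df = k,
       p_value = pchisq(lrt, df = k, lower.tail = FALSE))
}

#' Block-adjusted marginal means per population
#'
#' Fits `y ~ 0 + population + (1 | block)` so the fixed-effect coefficients
#' are reference-free per-population means averaged over the block
#' (container) distribution, with model-based standard errors.
#'
#' @param p a [phenotype_table()].
#' @param trait trait name.
#' @param populations optional scope.
#' @return data.frame of class `"marginal_means"`: `population`, `mean`,
#'   `se`, `n`, `flagged` (TRUE when a population has < 2 observations).
#' @export
marginal_means <- function(p, trait, populations = NULL) {
  df <- vc_frame(p, trait, populations)
  fit <- lme4::lmer(y ~ 0 + population + (1 | block), data = df,
                    REML = TRUE, control = vc_engine_control())
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  pops <- sub("^population", "", names(est))
  n <- as.integer(table(df$population)[pops])
  out <- data.frame(population = pops, mean = unname(est), se = unname(se),
                    n = n, flagged = n < 2, stringsAsFactors = FALSE)
  structure(out, trait = trait,
            class = c("marginal_means", "data.frame"))
}

#' Linear regression of population marginal means on altitude
#'
#' Ordinary least squares of the block-adjusted population means on
#' altitude of origin (metres), with the two-sided slope p-value.
#'
#' @param mm a [marginal_means()] table.
#' @param m a [population_metadata()] giving altitudes.
#' @return list with `slope`, `intercept`, `p_value`, `r_squared`, `n` and
#'   the underlying `lm` fit.
#' @export
altitude_regression <- function(mm, m) {
  stopifnot(inherits(mm, "marginal_means"), inherits(m, "population_metadata"))
  dat <- merge(as.data.frame(mm), as.data.frame(m)[c("population", "altitude")],
               by = "population")
  if (nrow(dat) < 3)
    stop("altitude regression needs >= 3 populations", call. = FALSE)
  fit <- lm(mean ~ altitude, data = dat)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p_value = sm$coefficients["altitude", "Pr(>|t|)"],
       r_squared = sm$r.squared, n = nrow(dat), fit = fit)
}

#' Variance explained by subspecies and by populations within subspecies
#'
#' Sequential (type-I) linear-model decomposition
#' `y ~ subspecies + population-in-subspecies`: the incremental
#' \eqn{R^2} of each term relative to the total sum of squares, with
#' F-test p-values.
#'
#' @param p a [phenotype_table()].
#' @param trait trait name.
#' @return list with `r2_subspecies`, `p_subspecies`,
#'   `r2_pops_in_subspecies`, `p_pops`, `r2_residual`.
#' @export
subspecies_partition_r2 <- function(p, trait) {
  stopifnot(inherits(p, "phenotype_table"))
  df <- as.data.frame(p)
  df <- df[!is.na(df[[trait]]), ]
  df$subspecies <- factor(df$subspecies)
  df$population <- factor(df$population)
  if (nlevels(df$subspecies) < 2)
    stop("both subspecies must be present", call. = FALSE)
  df$y <- df[[trait]]
  fit <- lm(y ~ subspecies + subspecies:population, data = df)
  an <- anova(fit)
  ss <- an[["Sum Sq"]]
  sst <- sum(ss)
  list(r2_subspecies = ss[1] / sst,
       p_subspecies = an[["Pr(>F)"]][1],
       r2_pops_in_subspecies = ss[2] / sst,
       p_pops = an[["Pr(>F)"]][2],
       r2_residual = ss[3] / sst)
}
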