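# Deciding divergent / stabilizing / neutral per trait, by (a) overlap of
# the Q_ST confidence interval with the mean F_ST and (b) the simulated
# neutral distribution of the Q_ST - F_ST difference (Whitlock-Guillaume
# framework): under neutrality the among-deme additive variance is
# 2 F/(1-F) * V_A with chi-square deme-sampling noise, which makes the
# expected Q_ST equal to F_ST.

comparison_result <- function(trait, qst_obs, fst_mean, p_value, verdict,
                              method, null_diffs = NULL) {
  structure(list(trait = trait, qst_obs = qst_obs, fst_mean = fst_mean,
                 diff_obs = qst_obs - fst_mean, null_diffs = null_diffs,
                 p_value = p_value, verdict = verdict, method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, digits = 3, ...) {
  cat("Q_ST-F_ST comparison (", x$method, ") for '", x$trait, "'\n", sep = "")
  cat(sprintf("  Q_ST = %.3f, mean F_ST = %.3f, difference = %+.3f\n",
              x$qst_obs, x$fst_mean, x$diff_obs))
  if (!is.na(x$p_value)) cat("  p =", format(round(x$p_value, 4)), "\n")
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Verdict by confidence-interval overlap
#'
#' A trait is called neutral when the \eqn{Q_{ST}} confidence interval
#' contains the mean \eqn{F_{ST}}; divergent when the whole interval lies
#' above it; stabilizing when it lies below.
#'
#' @param q a [qst_point()] estimate carrying bootstrap CI bounds.
#' @param fst_mean the overall \eqn{F_{ST}} (mean neutral differentiation).
#' @return a `"comparison_result"`.
#' @export
ci_overlap_verdict <- function(q, fst_mean) {
  stopifnot(inherits(q, "qst_estimate"))
  if (is.na(q$ci_low) || is.na(q$ci_high))
    stop("Q_ST estimate carries no confidence interval; run ",
         "parametric_bootstrap_ci first", call. = FALSE)
  verdict <- if (fst_mean < q$ci_low) "divergent"
             else if (fst_mean > q$ci_high) "stabilizing"
             else "neutral"
  comparison_result(q$trait, q$qst, fst_mean, NA_real_, verdict, "ci_overlap")
}

#' Simulate the neutral null of the Q_ST - F_ST difference
#'
#' Builds a cache of neutral-world replicates and resamples it to the
#' requested size.  Per cache entry: (i) loci are resampled with
#' replacement and the ratio-of-sums theta recomputed (`F_sim`; values at
#' or below 0 are clamped to 1e-6, values at or above 1 redrawn); (ii) a
#' trait dataset is simulated on the observed design with the neutral
#' among-population variance
#' \eqn{V_b^{neutral} = \frac{2F_{sim}}{1-F_{sim}} V_A} (the realized
#' among-deme variance then carries the \eqn{\chi^2_{d}} deme-sampling
#' noise, \eqn{d = n_{pops} - 1}) and the fitted within-population
#' components, where \eqn{V_A = 2 V_w} is the full-sib additive variance;
#' (iii) the variance components of the simulated values are re-estimated
#' by the same REML machinery and
#' \eqn{Q_{sim} = V_b^*/(V_b^* + 4 V_w^*)} recomputed from them, so the
#' null carries the same estimation noise as the observed \eqn{Q_{ST}};
#' (iv) the recorded value is \eqn{Q_{sim} - F_{sim}}.  Replicates where
#' both re-estimated components hit the zero boundary are redrawn and
#' counted.
#'
#' @param p a [phenotype_table()].
#' @param trait trait name.
#' @param per_locus_fst an [wc_fst()] estimate carrying per-locus
#'   components.
#' @param n_rep number of null replicates (>= 1000), resampled from the
#'   cache.
#' @param seed optional RNG seed.
#' @param populations optional scope (populations entering the trait fit).
#' @param cache_size number of simulate-and-refit replicates behind the
#'   null (the costly part; the `n_rep` sample resamples these).
#' @return numeric vector of `n_rep` null differences, with attributes
#'   `n_redrawn`, `f_sim_mean`, `d`.
#' @export
simulate_neutral_diff <- function(p, trait, per_locus_fst, n_rep = 10000,
                                  seed = NULL, populations = NULL,
                                  cache_size = 1000) {
  stopifnot(inherits(per_locus_fst, "fst_estimate"))
  if (n_rep < 1000) stop("n_rep must be at least 1000", call. = FALSE)
  cache_size <- max(cache_size, 100)
  vc <- fit_variance_components(p, trait, populations)
  v_a <- 2 * vc$V_w
  if (v_a <= 0)
    stop("fitted additive variance is zero; the neutral null is undefined ",
         "for trait '", trait, "'", call. = FALSE)
  comp <- per_locus_fst$per_locus
  comp <- comp[comp$informative, ]
  n_loci <- nrow(comp)
  tot <- comp$a + comp$b + comp$c
  d <- vc$n_pops - 1
  eng <- vc_engine(vc$frame, random = vc$random, REML = TRUE)
  with_seed(derive_seed(seed, 2L), {
    f_cache <- diff_cache <- numeric(cache_size)
    n_redrawn <- 0L
    j <- 1L
    while (j <= cache_size) {
      idx <- sample.int(n_loci, n_loci, replace = TRUE)
      f_sim <- sum(comp$a[idx]) / sum(tot[idx])
      if (!is.finite(f_sim) || f_sim >= 1) { n_redrawn <- n_redrawn + 1L; next }
      f_sim <- max(f_sim, 1e-6)
      gen <- c(population = (2 * f_sim / (1 - f_sim)) * v_a,
               family = vc$V_w, block = vc$V_block)
      ystar <- engine_simulate(eng, vc$mu, gen, vc$V_res)
      fit <- tryCatch(engine_fit(eng, ystar,
                                 start = engine_start(eng, gen, vc$V_res)),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { n_redrawn <- n_redrawn + 1L; next }
      vb <- unname(fit$vc["population"]); vw <- unname(fit$vc["family"])
      if (vb + 4 * vw <= 0) { n_redrawn <- n_redrawn + 1L; next }
      f_cache[j] <- f_sim
      diff_cache[j] <- vb / (vb + 4 * vw) - f_sim
      j <- j + 1L
    }
    pick <- sample.int(cache_size, n_rep, replace = TRUE)
    diffs <- diff_cache[pick]
    attr(diffs, "n_redrawn") <- n_redrawn
    attr(diffs, "f_sim_mean") <- mean(f_cache[pick])
    attr(diffs, "d") <- d
    diffs
  })
}

#' Verdict from the simulated neutral null
#'
#' Two-tailed add-one permutation-style p-value of the observed
#' \eqn{Q_{ST} - F_{ST}} difference against its simulated neutral
#' distribution:
#' \eqn{p = 2\min[(1 + \#\{null \ge d\})/(n+1), (1 + \#\{null \le d\})/(n+1)]},
#' capped at 1.
#'
#' @param diff_obs observed difference \eqn{Q_{ST} - F_{ST}}.
#' @param null_diffs simulated null sample ([simulate_neutral_diff()]).
#' @param alpha significance level for the verdict.
#' @param trait trait label carried into the result.
#' @param fst_mean observed mean \eqn{F_{ST}} (for reporting; the observed
#'   \eqn{Q_{ST}} is reconstructed as `diff_obs + fst_mean`).
#' @return a `"comparison_result"`.
#' @export
bootstrap_null_pvalue <- function(diff_obs, null_diffs, alpha = 0.05,
                                  trait = NA_character_, fst_mean = NA_real_) {
  if (!length(null_diffs)) stop("empty null sample", call. = FALSE)
  n <- length(null_diffs)
  p_hi <- (1 + sum(null_diffs >= diff_obs)) / (n + 1)
  p_lo <- (1 + sum(null_diffs <= diff_obs)) / (n + 1)
  p <- min(1, 2 * min(p_hi, p_lo))
  verdict <- if (p < alpha) {
    if (diff_obs > 0) "divergent" else "stabilizing"
  } else "neutral"
  comparison_result(trait, diff_obs + fst_mean, fst_mean, p, verdict,
                    "bootstrap_null", null_diffs = null_diffs)
}

#' Full Q_ST-F_ST analysis for one subspecies
#'
#' Orchestrates the pipeline for a set of traits: overall Weir-Cockerham
#' \eqn{F_{ST}} (with permutation p), per-trait REML variance components,
#' full-sib heritability and Spitze \eqn{Q_{ST}} with parametric-bootstrap
#' confidence intervals, and both comparison methods (CI overlap and the
#' simulated neutral null).
#'
#' @param phenotypes a [phenotype_table()].
#' @param genotypes a [genotype_table()] (populations must cover the
#'   phenotype populations).
#' @param traits traits to analyse; defaults to all trait columns.
#' @param n_boot bootstrap replicates for confidence intervals.
#' @param n_rep neutral-null replicates.
#' @param n_perm permutations for the \eqn{F_{ST}} significance test.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param alpha significance level.
#' @return object of class `"qstfst"` with elements `fst`, and per-trait
#'   entries carrying components, `h2`, `qst` and the two comparisons.
#' @export
qst_fst <- function(phenotypes, genotypes, traits = NULL,
                    n_boot = 1000, n_rep = 10000, n_perm = 999,
                    seed = NULL, alpha = 0.05) {
  stopifnot(inherits(phenotypes, "phenotype_table"),
            inherits(genotypes, "genotype_table"))
  if (is.null(traits)) traits <- attr(phenotypes, "traits")
  pops <- unique(phenotypes$population)
  g <- subset_populations(genotypes, pops)
  fst <- fst_permutation_pvalue(g, n_perm = n_perm,
                                seed = derive_seed(seed, 10L))
  per_trait <- list()
  for (k in seq_along(traits)) {
    tr <- traits[k]
    vc <- fit_variance_components(phenotypes, tr)
    h2 <- heritability_fullsib(vc)
    qst <- qst_point(vc, h2)
    boot <- parametric_bootstrap_ci(phenotypes, tr, "qst", n_boot = n_boot,
                                    seed = derive_seed(seed, 100L + k))
    qst$ci_low <- boot$low; qst$ci_high <- boot$high
    qst$n_boot <- n_boot - boot$n_fail
    h2b <- 2 * boot$samples[, "V_w"] /
      (boot$samples[, "V_w"] + boot$samples[, "V_res"])
    h2$ci_low <- quantile(h2b, 0.025, names = FALSE)
    h2$ci_high <- quantile(h2b, 0.975, names = FALSE)
    h2$n_boot <- qst$n_boot
    ci_cmp <- ci_overlap_verdict(qst, fst$theta)
    nulls <- simulate_neutral_diff(phenotypes, tr, fst, n_rep = n_rep,
                                   seed = derive_seed(seed, 200L + k),
                                   cache_size = min(n_boot, 1000))
    boot_cmp <- bootstrap_null_pvalue(qst$qst - fst$theta, nulls,
                                      alpha = alpha, trait = tr,
                                      fst_mean = fst$theta)
    per_trait[[tr]] <- list(components = vc, h2 = h2, qst = qst,
                            ci_overlap = ci_cmp, bootstrap_null = boot_cmp)
  }
  structure(list(fst = fst, traits = per_trait, alpha = alpha),
            class = "qstfst")
}

#' @export
print.qstfst <- function(x, ...) {
  cat("Q_ST-F_ST analysis:", length(x$traits), "trait(s),",
      x$fst$n_populations, "populations\n")
  cat(sprintf("Overall F_ST (Weir-Cockerham theta): %.3f", x$fst$theta))
  if (!is.na(x$fst$p_value)) cat(sprintf(" (p = %.3g)", x$fst$p_value))
  cat("\n\n")
  print(summary(x))
  invisible(x)
}

#' @export
summary.qstfst <- function(object, ...) {
  rows <- lapply(names(object$traits), function(tr) {
    e <- object$traits[[tr]]
    data.frame(trait = tr, h2 = e$h2$h2, qst = e$qst$qst,
               qst_low = e$qst$ci_low, qst_high = e$qst$ci_high,
               fst = object$fst$theta,
               diff = e$bootstrap_null$diff_obs,
               p_boot = e$bootstrap_null$p_value,
               verdict_ci = e$ci_overlap$verdict,
               verdict_boot = e$bootstrap_null$verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot Q_ST estimates with confidence intervals against mean F_ST
#'
#' One point per trait (overall \eqn{Q_{ST}} with its bootstrap interval)
#' and a dashed horizontal line at the mean \eqn{F_{ST}}.
#'
#' @param x a [qst_fst()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.qstfst <- function(x, ...) {
  s <- summary(x)
  n <- nrow(s)
  ylim <- range(0, s$qst_high, s$qst_low, x$fst$theta, 1, na.rm = TRUE)
  graphics::plot(seq_len(n), s$qst, ylim = ylim, xaxt = "n", pch = 19,
                 xlab = "", ylab = expression(Q[ST]), ...)
  graphics::axis(1, at = seq_len(n), labels = s$trait, las = 2,
                 cex.axis = 0.8)
  graphics::arrows(seq_len(n), s$qst_low, seq_len(n), s$qst_high,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = x$fst$theta, lty = 2)
  invisible(x)
}
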