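# Variance-component quantitative genetics for the full-sib common-garden
# design: REML fits of y = mu + population + family(population) + block + e,
# full-sib heritability h2 = 2 Vw / (Vw + Vres), and Spitze's
# Q_ST = Vb / (Vb + 2 h2 (Vw + Vres)).

# Prepare the model frame for one trait: listwise deletion, family labels
# nested explicitly inside population, factors dropped to the scope.
vc_frame <- function(p, trait, populations = NULL) {
  stopifnot(inherits(p, "phenotype_table"))
  if (!trait %in% attr(p, "traits"))
    stop("unknown trait: ", trait, call. = FALSE)
  df <- as.data.frame(p)
  if (!is.null(populations)) df <- df[df$population %in% populations, ]
  df <- df[!is.na(df[[trait]]), ]
  if (nrow(df) < 10)
    stop("trait '", trait, "' has fewer than 10 non-missing values in scope",
         call. = FALSE)
  data.frame(y = df[[trait]],
             population = factor(df$population),
             family = factor(paste(df$population, df$family, sep = ":")),
             block = factor(df$block))
}

#' REML variance components for one trait
#'
#' Fits the random-effects model
#' \deqn{y = \mu + population + family(population) + block + \varepsilon}
#' by REML (all effects independent, zero-mean, homogeneous variances;
#' non-negativity enforced at the boundary) and returns the four variance
#' components.
#'
#' @param p a [phenotype_table()].
#' @param trait trait column name.
#' @param populations optional subset of population labels (e.g. one
#'   subspecies, or a population pair).
#' @param random which random terms to include; the default is the full
#'   design.  Terms whose factor has a single level in scope are dropped
#'   (their variance is reported as 0).
#' @return object of class `"variance_components"`: `V_b`, `V_w`,
#'   `V_block`, `V_res`, `log_likelihood` (REML), counts, convergence flag,
#'   and the model frame used (for bootstrap resimulation).
#' @export
fit_variance_components <- function(p, trait,
                                    populations = NULL,
                                    random = c("population", "family", "block")) {
  df <- vc_frame(p, trait, populations)
  if ("population" %in% random && nlevels(df$population) < 2)
    stop("variance-component fit needs >= 2 populations in scope",
         call. = FALSE)
  fam_per_pop <- tapply(df$family, df$population,
                        function(f) length(unique(f)))
  if (all(fam_per_pop < 2, na.rm = TRUE))
    stop("singular design: no population carries >= 2 families", call. = FALSE)
  eng <- vc_engine(df, random = random, REML = TRUE)
  fit <- engine_fit(eng)
  if (!fit$converged)
    stop("REML fit failed to converge for trait '", trait, "'", call. = FALSE)
  structure(
    list(V_b = unname(fit$vc["population"]),
         V_w = unname(fit$vc["family"]),
         V_block = unname(fit$vc["block"]),
         V_res = fit$sigma2,
         mu = fit$mu,
         log_likelihood = -fit$criterion / 2,
         criterion = fit$criterion,
         n_obs = nrow(df),
         n_pops = nlevels(df$population),
         n_families = nlevels(df$family),
         trait = trait, random = random, converged = fit$converged,
         frame = df),
    class = "variance_components")
}

#' @export
print.variance_components <- function(x, digits = 4, ...) {
  cat("REML variance components for trait '", x$trait, "' (",
      x$n_obs, " plants, ", x$n_pops, " populations, ", x$n_families,
      " families)\n", sep = "")
  v <- c(`V_b (population)` = x$V_b, `V_w (family)` = x$V_w,
         `V_block (container)` = x$V_block, `V_res` = x$V_res)
  print(round(v, digits))
  invisible(x)
}

#' Boundary likelihood-ratio test of one variance component
#'
#' Compares the full REML fit with the fit dropping one random term.
#' The LRT statistic is referred to the boundary mixture
#' \eqn{\frac{1}{2}\chi^2_0 + \frac{1}{2}\chi^2_1}; a component whose
#' p-value is at or above `alpha` is flagged `zeroed` (treated as null in
#' downstream calculations).
#'
#' @param p a [phenotype_table()].
#' @param trait trait name.
#' @param component one of `"population"`, `"family"`, `"block"`.
#' @param populations optional scope.
#' @param alpha significance level for the zeroing flag.
#' @return list with `lrt`, `p_value`, `zeroed`, `component`.
#' @export
test_variance_component <- function(p, trait, component,
                                    populations = NULL, alpha = 0.05) {
  component <- match.arg(component, c("population", "family", "block"))
  full <- fit_variance_components(p, trait, populations)
  present <- full$random[vapply(full$random, function(f)
    nlevels(full$frame[[f]]) > 1, logical(1))]
  if (!component %in% present) {     # term absent: trivially null
    return(list(lrt = 0, p_value = 1, zeroed = TRUE, component = component))
  }
  reduced <- setdiff(present, component)
  if (!length(reduced))
    stop("cannot drop the only random term", call. = FALSE)
  eng_red <- vc_engine(full$frame, random = reduced, REML = TRUE)
  fit_red <- engine_fit(eng_red)
  lrt <- fit_red$criterion - full$criterion
  if (lrt < 0) {
    if (lrt < -0.01)
      stop("numerical error: negative LRT (", format(lrt), ")", call. = FALSE)
    lrt <- 0
  }
  p_val <- if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  list(lrt = lrt, p_value = p_val, zeroed = p_val >= alpha,
       component = component)
}

# Apply the zeroing rule to a fitted set of components: each random term is
# boundary-tested and nonsignificant components are set to 0.
zero_nonsignificant <- function(p, trait, populations = NULL, alpha = 0.05,
                                vc = NULL) {
  if (is.null(vc)) vc <- fit_variance_components(p, trait, populations)
  map <- c(population = "V_b", family = "V_w", block = "V_block")
  zeroed <- character(0)
  for (comp in intersect(vc$random, names(map))) {
    tst <- test_variance_component(p, trait, comp, populations, alpha)
    if (tst$zeroed) {
      vc[[map[[comp]]]] <- 0
      zeroed <- c(zeroed, comp)
    }
  }
  vc$zeroed <- zeroed
  vc
}

#' Full-sib narrow-sense heritability
#'
#' In a full-sib design the family variance estimates half the additive
#' variance, so \eqn{h^2 = 2 V_w / (V_w + V_{res})}.  Estimates above 1 are
#' reported with a warning, not clamped.
#'
#' @param vc a [fit_variance_components()] result (conventionally the
#'   all-populations fit for one subspecies).
#' @return object of class `"heritability_estimate"`: `h2`, `ci_low`,
#'   `ci_high` (`NA` until bootstrapped), `n_boot`.
#' @export
heritability_fullsib <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  denom <- vc$V_w + vc$V_res
  if (denom <= 0)
    stop("undefined heritability: V_w + V_res = 0", call. = FALSE)
  h2 <- 2 * vc$V_w / denom
  if (h2 > 1)
    warning("full-sib heritability estimate exceeds 1 (", format(round(h2, 3)),
            "); reported as computed", call. = FALSE)
  structure(list(h2 = h2, ci_low = NA_real_, ci_high = NA_real_,
                 n_boot = 0L, trait = vc$trait),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, digits = 3, ...) {
  cat("Full-sib h2 for '", x$trait, "': ", round(x$h2, digits), sep = "")
  if (x$n_boot > 0)
    cat(sprintf("  [%.*f, %.*f] (%d bootstrap replicates)",
                digits, x$ci_low, digits, x$ci_high, x$n_boot))
  cat("\n")
  invisible(x)
}

#' Spitze's Q_ST from variance components
#'
#' \deqn{Q_{ST} = V_b / (V_b + 2 h^2 (V_w + V_{res}))}
#' With the full-sib \eqn{h^2 = 2V_w/(V_w+V_{res})} from the same fit this
#' reduces algebraically to \eqn{V_b/(V_b + 4V_w)}.
#'
#' @param vc a [fit_variance_components()] result.
#' @param h2 a [heritability_fullsib()] estimate (possibly from a wider
#'   scope than `vc`, e.g. the whole subspecies for a pairwise fit).
#' @return object of class `"qst_estimate"`: `qst`, `ci_low`, `ci_high`,
#'   `trait`, `scope`.
#' @export
qst_point <- function(vc, h2 = heritability_fullsib(vc)) {
  stopifnot(inherits(vc, "variance_components"))
  h2v <- if (inherits(h2, "heritability_estimate")) h2$h2 else as.numeric(h2)
  denom <- vc$V_b + 2 * h2v * (vc$V_w + vc$V_res)
  if (denom <= 0)
    stop("undefined Q_ST: V_b and 2 h2 (V_w + V_res) are both 0",
         call. = FALSE)
  structure(list(qst = vc$V_b / denom,
                 ci_low = NA_real_, ci_high = NA_real_, n_boot = 0L,
                 trait = vc$trait,
                 scope = if (vc$n_pops == 2) "pair" else "overall"),
            class = "qst_estimate")
}

#' @export
print.qst_estimate <- function(x, digits = 3, ...) {
  cat("Q_ST (", x$scope, ") for '", x$trait, "': ",
      round(x$qst, digits), sep = "")
  if (x$n_boot > 0)
    cat(sprintf("  [%.*f, %.*f] (%d bootstrap replicates)",
                digits, x$ci_low, digits, x$ci_high, x$n_boot))
  cat("\n")
  invisible(x)
}

# Sign-preserving square-root normalization: the trait minimum is shifted
# to 0 first when negatives exist (the shift is otherwise omitted).
sqrt_normalize <- function(x) {
  mn <- min(x, na.rm = TRUE)
  if (mn < 0) x <- x - mn
  sqrt(x)
}

#' Pairwise Q_ST matrix
#'
#' For each population pair the trait is square-root normalized, the
#' random-effects model refitted on the pair's data alone, the zeroing rule
#' applied, and \eqn{Q_{ST}} computed with the subspecies-level heritability.
#' Pairs whose fit fails yield `NA` with a warning.
#'
#' @param p a [phenotype_table()].
#' @param trait trait name.
#' @param h2 heritability shared across the table's populations; computed
#'   from the all-populations fit of the normalized trait when omitted.
#' @param alpha zeroing-rule significance level.
#' @param sqrt_transform normalize the trait by a square-root transform
#'   (the convention for pairwise fits)?
#' @return a [pairwise_matrix()] of pairwise \eqn{Q_{ST}}.
#' @export
pairwise_qst <- function(p, trait, h2 = NULL, alpha = 0.05,
                         sqrt_transform = TRUE) {
  stopifnot(inherits(p, "phenotype_table"))
  pt <- p
  if (sqrt_transform) pt[[trait]] <- sqrt_normalize(pt[[trait]])
  if (is.null(h2))
    h2 <- heritability_fullsib(fit_variance_components(pt, trait))
  pops <- sort(unique(pt$population))
  if (length(pops) < 2) stop("pairwise Q_ST needs >= 2 populations",
                             call. = FALSE)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in seq.int(i + 1L, length(pops))) {
      q <- tryCatch({
        vc <- zero_nonsignificant(pt, trait, populations = c(pops[i], pops[j]),
                                  alpha = alpha)
        if (vc$V_b <= 0) 0 else qst_point(vc, h2)$qst
      }, error = function(e) {
        warning("pairwise Q_ST failed for ", pops[i], "-", pops[j], ": ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
      m[i, j] <- m[j, i] <- q
    }
  }
  pairwise_matrix(m, pops)
}

#' Parametric bootstrap confidence interval for h2 or Q_ST
#'
#' Following the O'Hara-Merila parametric bootstrap: datasets are simulated
#' from the fitted model (independent zero-mean Gaussian population, family,
#' block effects and residuals with the estimated variances, on the observed
#' design), each replicate refitted by the same REML machinery, the
#' statistic recomputed, and percentile 2.5/97.5 bounds returned.
#' Non-converged replicates are dropped and counted (a warning is attached
#' when more than 10% fail).
#'
#' @param p a [phenotype_table()].
#' @param trait trait name.
#' @param statistic `"h2"` or `"qst"`.
#' @param n_boot number of bootstrap replicates (>= 200).
#' @param seed optional RNG seed.
#' @param populations optional scope.
#' @param level confidence level.
#' @return list with `low`, `high`, `estimate`, `samples` (matrix of
#'   replicate components, columns `V_b`, `V_w`, `V_block`, `V_res`,
#'   `statistic`), `n_fail`.
#' @export
parametric_bootstrap_ci <- function(p, trait, statistic = c("h2", "qst"),
                                    n_boot = 1000, seed = NULL,
                                    populations = NULL, level = 0.95) {
  statistic <- match.arg(statistic)
  if (n_boot < 200) stop("n_boot must be at least 200", call. = FALSE)
  vc <- fit_variance_components(p, trait, populations)
  boot <- bootstrap_components(vc, n_boot = n_boot, seed = seed)
  stat <- switch(statistic,
    h2 = 2 * boot[, "V_w"] / (boot[, "V_w"] + boot[, "V_res"]),
    qst = boot[, "V_b"] / (boot[, "V_b"] + 4 * boot[, "V_w"]))
  est <- switch(statistic,
    h2 = heritability_fullsib(vc)$h2,
    qst = qst_point(vc)$qst)
  a <- (1 - level) / 2
  ci <- quantile(stat, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  n_fail <- attr(boot, "n_fail")
  if (n_fail > 0.1 * n_boot)
    warning(sprintf("%d of %d bootstrap replicates failed to converge",
                    n_fail, n_boot), call. = FALSE)
  list(low = ci[1], high = ci[2], estimate = est,
       samples = cbind(boot, statistic = stat), n_fail = n_fail)
}

# Core resimulate-and-refit loop; returns an (n_kept x 4) matrix of
# components with an n_fail attribute.  Reused by the neutral-null module
# as the additive-variance cache.
bootstrap_components <- function(vc, n_boot, seed = NULL) {
  stopifnot(inherits(vc, "variance_components"))
  eng <- vc_engine(vc$frame, random = vc$random, REML = TRUE)
  comp <- c(population = vc$V_b, family = vc$V_w, block = vc$V_block)
  start <- engine_start(eng, comp, vc$V_res)
  with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 4,
                  dimnames = list(NULL, c("V_b", "V_w", "V_block", "V_res")))
    n_fail <- 0L
    for (b in seq_len(n_boot)) {
      ystar <- engine_simulate(eng, vc$mu, comp, vc$V_res)
      fit <- tryCatch(engine_fit(eng, ystar, start = start),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { n_fail <- n_fail + 1L; next }
      out[b, ] <- c(fit$vc["population"], fit$vc["family"],
                    fit$vc["block"], fit$sigma2)
    }
    out <- out[!is.na(out[, 1]), , drop = FALSE]
    attr(out, "n_fail") <- n_fail
    out
  })
}
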