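# Thin layer over lme4's modular interface.  A "vc engine" is built once per
# design (response ~ 1 + (1|population) + (1|family) + (1|block)); bootstrap
# replicates then swap the response in place and re-optimize the profiled
# REML deviance, avoiding per-fit formula/model-frame overhead.

vc_engine_control <- function() {
  lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = "ignore",
    check.nlev.gtreq.5 = "ignore",
    check.nobs.vs.nlev = "ignore",
    check.nobs.vs.rankZ = "ignore",
    check.nobs.vs.nRE = "ignore")
}

# df: data.frame with column y and the grouping factors in `random`.
# Returns an engine: devfun + environment + bookkeeping.
vc_engine <- function(df, random = c("population", "family", "block"),
                      REML = TRUE) {
  stopifnot(all(random %in% names(df)), "y" %in% names(df))
  for (f in random) df[[f]] <- factor(df[[f]])
  random <- random[vapply(random, function(f) nlevels(df[[f]]) > 1, logical(1))]
  if (!length(random)) stop("no random term with >= 2 levels", call. = FALSE)
  form <- as.formula(paste("y ~ 1 +",
                           paste(sprintf("(1 | %s)", random), collapse = " + ")))
  lmod <- lme4::lFormula(form, data = df, REML = REML,
                         control = vc_engine_control())
  devfun <- do.call(lme4::mkLmerDevfun, lmod)
  list(devfun = devfun, rho = environment(devfun), lmod = lmod,
       random = random, n = nrow(df), p = ncol(lmod$X), REML = REML,
       theta0 = lmod$reTrms$theta, data = df)
}

# Relative-sd starting values for the optimizer from named variance
# components; a fixed start keeps repeated refits independent of each
# other (the predictor module otherwise carries the previous optimum, so
# one boundary fit would anchor all later refits at the boundary).
engine_start <- function(eng, vc_named, v_res) {
  th <- sqrt(pmax(vc_named[names(eng$lmod$reTrms$cnms)], 0) / v_res)
  th[!is.finite(th)] <- 1
  unname(th)
}

# (Re)fit the engine for response y; returns variance components named
# population/family/block (absent terms = 0), residual variance, the REML/ML
# criterion (-2 log lik) and a convergence flag.
engine_fit <- function(eng, y = NULL, start = NULL) {
  if (!is.null(y)) eng$rho$resp$setResp(y)
  if (is.null(start)) start <- eng$theta0
  # tight tolerances so balanced-design fits agree with closed forms;
  # maxeval bounds NLopt if roundoff prevents the tolerances being met
  opt <- lme4::optimizeLmer(eng$devfun, start = start,
                            calc.derivs = FALSE,
                            control = list(xtol_abs = 1e-12,
                                           ftol_abs = 1e-14,
                                           xtol_rel = 1e-12,
                                           ftol_rel = 1e-14,
                                           maxeval = 3000))
  eng$devfun(opt$par)   # leave the predictor state at the optimum
  pwrss <- eng$rho$resp$wrss() + eng$rho$pp$sqrL(1)
  denom <- if (eng$REML) eng$n - eng$p else eng$n
  sigma2 <- pwrss / denom
  vc <- sigma2 * opt$par^2
  names(vc) <- names(eng$lmod$reTrms$cnms)
  full <- c(population = 0, family = 0, block = 0)
  full[names(vc)] <- vc
  list(vc = full, sigma2 = sigma2, criterion = opt$fval,
       converged = is.finite(opt$fval) &&
         (is.null(opt$conv) || opt$conv %in% c(0, 5)),
       mu = unname(eng$rho$pp$beta(1)[1]))
}

# Simulate a response from fitted components on the engine's design.
engine_simulate <- function(eng, mu, vc, sigma2) {
  y <- rep(mu, eng$n)
  for (f in eng$random) {
    fac <- eng$data[[f]]
    y <- y + rnorm(nlevels(fac), sd = sqrt(vc[[f]]))[as.integer(fac)]
  }
  y + rnorm(eng$n, sd = sqrt(sigma2))
}
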