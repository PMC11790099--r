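## Average treatment-effect estimators.  Each internal estimator returns the
## two counterfactual arm means (where the estimator defines them) and the
## risk difference; risk ratio and odds ratio are derived transforms.

.ate_naive <- function(arm, outcome) {
  list(ey1 = mean(outcome[arm == 1]), ey0 = mean(outcome[arm == 0]))
}

## Hajek (self-normalized) IPW: bounded on [-1, 1] unlike Horvitz-Thompson.
.ate_ipw <- function(e, arm, outcome) {
  if (any(e <= 0 | e >= 1))
    .stopf("positivity error: propensity estimates outside (0,1); clip them")
  w1 <- arm / e
  w0 <- (1 - arm) / (1 - e)
  list(ey1 = sum(w1 * outcome) / sum(w1), ey0 = sum(w0 * outcome) / sum(w0))
}

.ate_gformula <- function(mu1, mu0) {
  list(ey1 = mean(mu1), ey0 = mean(mu0))
}

## AIPW influence-function pseudo-outcome; psi is retained per patient for
## the DR-learner in the heterogeneity analysis.
.ate_aipw <- function(e, mu1, mu0, arm, outcome) {
  if (any(e <= 0 | e >= 1))
    .stopf("positivity error: propensity estimates outside (0,1); clip them")
  dr1 <- mu1 + arm * (outcome - mu1) / e
  dr0 <- mu0 + (1 - arm) * (outcome - mu0) / (1 - e)
  list(ey1 = mean(dr1), ey0 = mean(dr0), psi = dr1 - dr0)
}

## DML in the partially linear model: residual-on-residual slope, reported as
## the constant-effect risk-difference analogue (no arm means are defined).
.ate_dml <- function(e, m, arm, outcome) {
  ra <- arm - e
  if (stats::var(ra) < 1e-8)
    .stopf("ill-posed DML problem: treatment residuals have near-zero variance (no effective overlap)")
  list(ey1 = NA_real_, ey0 = NA_real_, rd = sum(ra * (outcome - m)) / sum(ra^2))
}

.point_estimate <- function(estimator, np, arm, outcome) {
  est <- switch(estimator,
    naive = .ate_naive(arm, outcome),
    ipw = .ate_ipw(np$e, arm, outcome),
    gformula = .ate_gformula(np$mu1, np$mu0),
    aipw = .ate_aipw(np$e, np$mu1, np$mu0, arm, outcome),
    dml = .ate_dml(np$e, np$m, arm, outcome))
  if (is.null(est$rd)) est$rd <- est$ey1 - est$ey0
  est
}

#' Transform counterfactual arm means into the three estimands
#'
#' Given estimates of the two potential-outcome means E\[Y(1)\] and E\[Y(0)\],
#' returns the risk difference, risk ratio and odds ratio that contrast them.
#'
#' @param ey1,ey0 estimated counterfactual means, each in (0, 1).
#' @return named numeric vector `risk_difference`, `risk_ratio`, `odds_ratio`.
#' @export
#' @examples
#' transform_estimand(0.2, 0.4)   # RD -0.2, RR 0.5, OR 0.375
transform_estimand <- function(ey1, ey0) {
  if (!is.finite(ey1) || !is.finite(ey0) ||
      ey1 <= 0 || ey1 >= 1 || ey0 <= 0 || ey0 >= 1)
    .stopf("undefined risk/odds ratio: arm means must lie strictly inside (0,1), got (%s, %s)",
           format(ey1), format(ey0))
  c(risk_difference = ey1 - ey0,
    risk_ratio = ey1 / ey0,
    odds_ratio = (ey1 / (1 - ey1)) / (ey0 / (1 - ey0)))
}

## Safe variant for internal use: RD always defined, ratios NA off-boundary.
.estimands_safe <- function(ey1, ey0, rd) {
  out <- c(risk_difference = rd, risk_ratio = NA_real_, odds_ratio = NA_real_)
  if (is.finite(ey1) && is.finite(ey0) &&
      ey1 > 0 && ey1 < 1 && ey0 > 0 && ey0 < 1)
    out <- transform_estimand(ey1, ey0)
  out
}

#' Nonparametric bootstrap confidence interval
#'
#' Patient-level resampling with the full estimation pipeline re-run on every
#' resample; percentile interval at the requested level.  The default of 50
#' repetitions keeps heavy pipelines tractable but is small for a stable 95%
#' interval; 200 or more is recommended when runtime allows.
#'
#' @param statistic function taking an integer vector of resampled row
#'   indices and returning a numeric scalar (or vector) estimate; it may
#'   throw an error (e.g. single-arm resample), in which case the replicate
#'   is dropped and counted.
#' @param n number of patients (rows) to resample from.
#' @param B number of bootstrap repetitions (>= 2).
#' @param level confidence level in (0, 1).
#' @param seed optional seed for the resampling.
#' @return list with `lower`, `upper` (named as the statistic's elements),
#'   `level`, `estimates` (matrix of kept replicates) and `dropped`.
#' @export
bootstrap_ci <- function(statistic, n, B = 50, level = 0.95, seed = NULL) {
  if (B < 2) .stopf("'B' must be >= 2")
  if (level <= 0 || level >= 1) .stopf("'level' must be in (0,1)")
  run <- function() {
    reps <- vector("list", B)
    dropped <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      r <- tryCatch(statistic(idx), error = function(err) NULL)
      if (is.null(r) || anyNA(r[1])) dropped <- dropped + 1L else reps[[b]] <- r
    }
    if (dropped > 0.2 * B)
      .stopf("bootstrap failed: %d of %d replicates dropped (single-arm or degenerate resamples)",
             dropped, B)
    est <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
    alpha <- (1 - level) / 2
    ## (B+1) order-statistic convention (quantile type 6), the canonical
    ## percentile-interval definition for bootstrap replicates
    q <- function(p) apply(est, 2, function(col) {
      col <- col[!is.na(col)]
      if (!length(col)) NA_real_
      else unname(stats::quantile(col, probs = p, type = 6))
    })
    list(lower = q(alpha), upper = q(1 - alpha),
         level = level, estimates = est, dropped = dropped)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Estimate treatment effects from supplied nuisance predictions
#'
#' Applies any of the estimators to an existing set of per-patient nuisance
#' predictions rather than refitting them -- the route for oracle analyses
#' (injecting true propensities or outcome probabilities on simulated data)
#' and for deliberate-misspecification experiments (e.g. replacing the
#' outcome model by a constant to probe double robustness).
#'
#' @param predictions a [fit_nuisances()] result, or a list with any of the
#'   elements `e` (propensity), `mu1`, `mu0` (arm-wise outcome regressions)
#'   and `m` (marginal outcome regression), each a numeric vector over
#'   patients.
#' @param arm,outcome binary vectors.
#' @param estimator one of `"ipw"`, `"gformula"`, `"aipw"`, `"dml"`,
#'   `"naive"`.
#' @return a `causal_ate` object (no confidence interval).
#' @export
ate_from_predictions <- function(predictions, arm, outcome,
                                 estimator = c("aipw", "ipw", "gformula",
                                               "dml", "naive")) {
  estimator <- match.arg(estimator)
  arm <- as.integer(arm)
  outcome <- as.integer(outcome)
  need <- switch(estimator, naive = character(), ipw = "e",
                 gformula = c("mu1", "mu0"), aipw = c("e", "mu1", "mu0"),
                 dml = c("e", "m"))
  for (nm in need) {
    v <- predictions[[nm]]
    if (is.null(v) || length(v) != length(arm) || anyNA(v))
      .stopf("'predictions$%s' must be a complete numeric vector over patients", nm)
  }
  pt <- .point_estimate(estimator, predictions, arm, outcome)
  point <- .estimands_safe(pt$ey1, pt$ey0, pt$rd)
  structure(list(
    estimator = estimator,
    estimand = data.frame(estimand = names(point), estimate = unname(point),
                          lower = NA_real_, upper = NA_real_),
    arm_means = c(ey1 = pt$ey1, ey0 = pt$ey0),
    psi = pt$psi, predictions = NULL, overlap = NULL, boot = NULL,
    n = length(arm), n_treated = sum(arm),
    nuisance = NULL, k_folds = NA, clip = NA, conf_level = NA, B = 0,
    provenance = list(source = "supplied predictions"), call = match.call()
  ), class = "causal_ate")
}
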