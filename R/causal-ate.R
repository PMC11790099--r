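#' Estimate the average treatment effect of a binary intervention
#'
#' The central fitting function of the package.  Given a patient-level
#' feature matrix, a binary treatment arm and a binary outcome, estimates the
#' average treatment effect on the risk-difference scale (with risk-ratio and
#' odds-ratio transforms where the estimator defines counterfactual arm
#' means) using one of five estimators:
#'
#' * `naive` -- unadjusted contrast of arm means (the bias reference);
#' * `ipw` -- Hajek (self-normalized) inverse propensity weighting;
#' * `gformula` -- outcome regression with a T-learner (one model per arm),
#'   averaging counterfactual predictions over the whole cohort;
#' * `aipw` -- augmented IPW, the doubly robust influence-function estimator;
#'   per-patient pseudo-outcomes are retained for heterogeneity analysis;
#' * `dml` -- double machine learning: cross-fitted residual-on-residual
#'   regression in the partially linear model (risk-difference analogue only).
#'
#' Nuisance models (propensity and outcome regressions) are fit with K-fold
#' cross-fitting so that no patient is predicted by a model trained on their
#' own fold.  Confidence intervals are percentile bootstrap with the full
#' pipeline (nuisance refits included) re-run on every patient-level
#' resample; searched hyperparameters are reused across resamples unless
#' `strict_bootstrap = TRUE`.
#'
#' @param features numeric `feature_matrix` (see [impute_encode()]), data
#'   frame or matrix of confounders; an `id` column is ignored.
#' @param treatment binary treatment indicator (0/1) per row.
#' @param outcome binary outcome indicator (0/1) per row.
#' @param estimator one of `"aipw"`, `"ipw"`, `"gformula"`, `"dml"`,
#'   `"naive"`.
#' @param nuisance a [nuisance_spec()].
#' @param k_folds cross-fitting folds (>= 2).
#' @param clip propensity clipping bounds.
#' @param B bootstrap repetitions for the confidence interval; `0` skips the
#'   interval.
#' @param conf_level confidence level.
#' @param seed optional integer; fixes nuisance folds, fits and bootstrap.
#' @param strict_bootstrap if `TRUE`, re-run the hyperparameter search inside
#'   every bootstrap replicate (slow); default reuses the searched values.
#' @param raw_features optional pre-imputation `feature_matrix` (same rows
#'   and columns as `features` but with missing values).  When supplied,
#'   every bootstrap replicate re-fits the median imputation on its own
#'   resample instead of reusing the analysis-matrix medians -- the
#'   statistically stricter convention; the default mirrors the common
#'   impute-once practice.
#' @param provenance optional named list recording design choices (window,
#'   aggregation, confounder set, ...) carried into the result.
#' @return an object of class `causal_ate` with components `estimand` (data
#'   frame of estimate/lower/upper per scale), `arm_means`, `psi` (AIPW
#'   pseudo-outcomes, when applicable), `predictions`, `overlap`, `boot`,
#'   `provenance`.  Methods: `print`, `summary`, `coef`, `confint`, `plot`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_ehr(sim_config(n_patients = 1500, seed = 7))
#' built <- build_cohort(sim$tables, cohort_spec())
#' fm <- impute_encode(aggregate_features(built$cohort, sim$tables$measurements,
#'                                        interventions = sim$tables$interventions))
#' fit <- causal_ate(fm, built$cohort$arm, built$cohort$death,
#'                   estimator = "aipw",
#'                   nuisance = nuisance_spec("ridge_logistic", search_budget = 0),
#'                   B = 50, seed = 1)
#' fit
#' }
causal_ate <- function(features, treatment, outcome,
                       estimator = c("aipw", "ipw", "gformula", "dml", "naive"),
                       nuisance = nuisance_spec(),
                       k_folds = 5, clip = c(0.01, 0.99),
                       B = 50, conf_level = 0.95, seed = NULL,
                       strict_bootstrap = FALSE, raw_features = NULL,
                       provenance = list()) {
  estimator <- match.arg(estimator)
  X <- .as_feature_df(features)
  arm <- as.integer(treatment)
  y <- as.integer(outcome)
  run <- function() .causal_ate_impl(X, arm, y, estimator, nuisance, k_folds,
                                     clip, B, conf_level, strict_bootstrap,
                                     raw_features, provenance, match.call())
  if (is.null(seed)) run() else .with_seed(seed, run())
}

.needed_predictions <- function(estimator) {
  switch(estimator, naive = character(), ipw = "e", gformula = "mu",
         aipw = c("e", "mu"), dml = c("e", "m"))
}

.causal_ate_impl <- function(X, arm, y, estimator, nuisance, k_folds, clip,
                             B, conf_level, strict, raw_features,
                             provenance, call) {
  what <- .needed_predictions(estimator)
  np <- NULL
  overlap <- NULL
  if (length(what)) {
    np <- fit_nuisances(X, arm, y, nuisance, k_folds, clip, what)
    if ("e" %in% what) overlap <- overlap_diagnostic(np, arm)
  }
  pt <- .point_estimate(estimator, np, arm, y)
  point <- .estimands_safe(pt$ey1, pt$ey0, pt$rd)

  boot <- NULL
  if (B > 0) {
    boot_spec <- nuisance
    if (!strict) {
      boot_spec$search_budget <- 0
      if (!is.null(np)) boot_spec$params <- np$hyperparams
    }
    stat <- function(idx) {
      a <- arm[idx]
      if (all(a == 1L) || all(a == 0L)) .stopf("single-arm resample")
      Xb <- if (is.null(raw_features)) X[idx, , drop = FALSE]
      else {
        rf <- raw_features[idx, , drop = FALSE]
        for (at in c("roles", "strategy", "cutoff"))
          attr(rf, at) <- attr(raw_features, at)
        .as_feature_df(impute_encode(rf))
      }
      yb <- y[idx]
      npb <- if (length(what))
        suppressWarnings(fit_nuisances(Xb, a, yb, boot_spec, k_folds, clip, what))
      pb <- .point_estimate(estimator, npb, a, yb)
      .estimands_safe(pb$ey1, pb$ey0, pb$rd)
    }
    boot <- bootstrap_ci(stat, n = length(arm), B = B, level = conf_level)
  }

  estimand <- data.frame(
    estimand = names(point),
    estimate = unname(point),
    lower = if (is.null(boot)) NA_real_ else unname(boot$lower[names(point)]),
    upper = if (is.null(boot)) NA_real_ else unname(boot$upper[names(point)])
  )
  structure(list(
    estimator = estimator, estimand = estimand,
    arm_means = c(ey1 = pt$ey1, ey0 = pt$ey0),
    psi = pt$psi, predictions = np, overlap = overlap,
    boot = boot, n = length(arm), n_treated = sum(arm),
    nuisance = nuisance, k_folds = k_folds, clip = clip,
    conf_level = conf_level, B = B,
    provenance = provenance, call = call
  ), class = "causal_ate")
}

#' @export
print.causal_ate <- function(x, digits = 4, ...) {
  cat(sprintf("Average treatment effect (%s%s)\n", toupper(x$estimator),
              if (!is.null(x$predictions))
                paste0(", ", x$predictions$family, " nuisances, ",
                       x$k_folds, "-fold cross-fitting") else ""))
  cat(sprintf("  n = %d (%d treated, %d control)\n",
              x$n, x$n_treated, x$n - x$n_treated))
  ed <- x$estimand
  for (i in seq_len(nrow(ed))) {
    ci <- if (is.na(ed$lower[i])) "" else
      sprintf("  [%s, %s] (%d%% bootstrap, B=%d)",
              format(round(ed$lower[i], digits)),
              format(round(ed$upper[i], digits)),
              round(100 * x$conf_level), x$B)
    if (!is.na(ed$estimate[i]))
      cat(sprintf("  %-16s %s%s\n", ed$estimand[i],
                  format(round(ed$estimate[i], digits)), ci))
  }
  if (!is.null(x$overlap) && x$overlap$flag)
    cat("  ** positivity flag: substantial propensity mass beyond clipping bounds **\n")
  invisible(x)
}

#' @export
summary.causal_ate <- function(object, ...) {
  structure(list(fit = object), class = "summary.causal_ate")
}

#' @export
print.summary.causal_ate <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (!is.null(f$overlap)) print(f$overlap)
  if (!is.null(f$boot))
    cat(sprintf("Bootstrap: %d replicates kept, %d dropped\n",
                nrow(f$boot$estimates), f$boot$dropped))
  if (length(f$provenance)) {
    cat("Design provenance:\n")
    for (nm in names(f$provenance))
      cat(sprintf("  %s: %s\n", nm, paste(f$provenance[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.causal_ate <- function(object, ...) {
  stats::setNames(object$estimand$estimate, object$estimand$estimand)
}

#' @export
confint.causal_ate <- function(object, parm, level, ...) {
  m <- as.matrix(object$estimand[, c("lower", "upper")])
  rownames(m) <- object$estimand$estimand
  colnames(m) <- sprintf("%g %%", c((1 - object$conf_level) / 2,
                                    1 - (1 - object$conf_level) / 2) * 100)
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
plot.causal_ate <- function(x, ...) {
  if (is.null(x$predictions) || is.null(x$overlap)) {
    graphics::barplot(x$arm_means, names.arg = c("E[Y(1)]", "E[Y(0)]"),
                      ylab = "outcome probability", ...)
    return(invisible(x))
  }
  e <- x$predictions$e_raw
  ## mirrored propensity histograms: treated above, control below
  h1 <- x$overlap$per_arm$treated$hist
  h0 <- x$overlap$per_arm$control$hist
  brk <- x$overlap$breaks
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  ylim <- c(-max(h0), max(h1))
  graphics::plot(NULL, xlim = c(0, 1), ylim = ylim,
                 xlab = "estimated propensity e(X)", ylab = "count",
                 main = "Propensity overlap (treated up, control down)", ...)
  graphics::rect(brk[-length(brk)], 0, brk[-1], h1, col = "indianred")
  graphics::rect(brk[-length(brk)], -h0, brk[-1], 0, col = "steelblue")
  graphics::abline(v = x$clip, lty = 2)
  invisible(x)
}
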