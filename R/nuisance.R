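#' Nuisance-model specification
#'
#' Describes the statistical learner used for the treatment (propensity) and
#' outcome models: either ridge-penalized logistic regression or a
#' probability random forest, with an optional random-search procedure over
#' hyperparameters run inside each training fold.
#'
#' @param family `"random_forest"` or `"ridge_logistic"`.
#' @param search_budget number of random-search draws per model and training
#'   fold; `0` disables the search and uses the fixed hyperparameters below.
#' @param cv_folds internal cross-validation folds for the random search.
#' @param num_trees,mtry,min_node_size,max_depth forest hyperparameters used
#'   when `search_budget = 0` (`mtry = NULL` means `floor(sqrt(p))`).
#' @param lambda ridge penalty used when `search_budget = 0`.
#' @return an object of class `nuisance_spec`.
#' @export
nuisance_spec <- function(family = c("random_forest", "ridge_logistic"),
                          search_budget = 10, cv_folds = 3,
                          num_trees = 100, mtry = NULL,
                          min_node_size = 25, max_depth = 8,
                          lambda = 0.01) {
  family <- match.arg(family)
  if (search_budget < 0) .stopf("'search_budget' must be >= 0")
  if (search_budget > 0 && cv_folds < 2) .stopf("'cv_folds' must be >= 2")
  structure(list(family = family, search_budget = search_budget,
                 cv_folds = cv_folds,
                 params = list(num_trees = num_trees, mtry = mtry,
                               min_node_size = min_node_size,
                               max_depth = max_depth, lambda = lambda)),
            class = "nuisance_spec")
}

## ---- single binary learners ------------------------------------------------

.fit_binary <- function(X, y, family, params) {
  ## degenerate or near-degenerate training sets fall back to the base rate
  if (length(unique(y)) < 2L || min(table(y)) < 2L || length(y) < 8L)
    return(structure(list(p = mean(y)), class = "constant_model"))
  if (family == "ridge_logistic") {
    Xm <- as.matrix(X)
    if (ncol(Xm) < 2L) Xm <- cbind(Xm, .zero_pad = 0)
    fit <- glmnet::glmnet(Xm, factor(y, levels = c(0, 1)), family = "binomial",
                          alpha = 0, lambda = params$lambda, standardize = TRUE)
    structure(list(fit = fit, lambda = params$lambda), class = "ridge_model")
  } else {
    d <- as.data.frame(X)
    d$.y <- factor(y, levels = c(0, 1))
    fit <- ranger::ranger(
      .y ~ ., data = d, probability = TRUE,
      num.trees = params$num_trees,
      mtry = min(params$mtry %||% max(1L, floor(sqrt(ncol(X)))), ncol(X)),
      min.node.size = params$min_node_size,
      max.depth = params$max_depth,
      num.threads = 1, verbose = FALSE)
    structure(list(fit = fit), class = "forest_model")
  }
}

.pred_binary <- function(model, X) {
  if (inherits(model, "constant_model")) return(rep(model$p, nrow(X)))
  if (inherits(model, "ridge_model")) {
    Xm <- as.matrix(X)
    if (ncol(Xm) < 2L) Xm <- cbind(Xm, .zero_pad = 0)
    as.numeric(stats::predict(model$fit, Xm, s = model$lambda, type = "response"))
  } else {
    stats::predict(model$fit, data = as.data.frame(X),
                   num.threads = 1, verbose = FALSE)$predictions[, "1"]
  }
}

.log_loss <- function(y, p) {
  p <- .clip(p, 1e-6, 1 - 1e-6)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## Random search over hyperparameters, scored by cross-validated log-loss.
.search_hyperparams <- function(X, y, spec) {
  if (spec$search_budget == 0 || length(unique(y)) < 2L) return(spec$params)
  p <- ncol(X)
  cand <- lapply(seq_len(spec$search_budget), function(i) {
    if (spec$family == "random_forest")
      list(num_trees = sample(c(100L, 200L, 300L, 400L), 1),
           mtry = sample(seq_len(max(2L, p)), 1),
           min_node_size = sample(5:50, 1),
           max_depth = sample(4:12, 1),
           lambda = spec$params$lambda)
    else
      utils::modifyList(spec$params, list(lambda = 10^stats::runif(1, -4, 1)))
  })
  folds <- .stratified_folds(y, spec$cv_folds)
  score <- vapply(cand, function(par) {
    losses <- vapply(seq_len(spec$cv_folds), function(k) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      m <- .fit_binary(X[tr, , drop = FALSE], y[tr], spec$family, par)
      .log_loss(y[!tr], .pred_binary(m, X[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(losses, na.rm = TRUE)
  }, numeric(1))
  cand[[which.min(score)]]
}

## Fold labels stratified on a binary variable so both arms appear in every
## fold whenever the minority arm has at least k members.
.stratified_folds <- function(strata, k) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-fitted nuisance predictions
#'
#' Fits the propensity model e(X) = P(A = 1 | X), the per-arm outcome models
#' mu1(X), mu0(X) (T-learner split: mu1 on treated, mu0 on controls) and the
#' marginal outcome model m(X) = E(Y | X), all with K-fold cross-fitting:
#' every patient's prediction comes from models never trained on that
#' patient's fold.  Folds are stratified on the treatment arm.  When the
#' specification's `search_budget > 0`, hyperparameters are chosen by random
#' search within each training fold.
#'
#' @param features a fully numeric `feature_matrix` (see [impute_encode()]),
#'   data frame or matrix; an `id` column is ignored.
#' @param arm binary treatment indicator (0/1).
#' @param outcome binary outcome indicator (0/1).
#' @param spec a [nuisance_spec()].
#' @param k_folds number of cross-fitting folds (>= 2).
#' @param clip propensity predictions are clipped to this interval, guarding
#'   the inverse weights against positivity violations.
#' @param what which predictions to produce, a subset of `c("e", "mu", "m")`.
#' @return an object of class `nuisance_predictions`: out-of-fold `e`
#'   (clipped), `e_raw`, `mu1`, `mu0`, `m`, the fold assignment, the clipped
#'   fraction and the hyperparameters used.
#' @export
fit_nuisances <- function(features, arm, outcome, spec = nuisance_spec(),
                          k_folds = 5, clip = c(0.01, 0.99),
                          what = c("e", "mu", "m")) {
  X <- .as_feature_df(features)
  n <- nrow(X)
  if (k_folds < 2)
    .stopf("cross-fitting requires k_folds >= 2 (got %d)", k_folds)
  if (length(arm) != n || length(outcome) != n)
    .stopf("'arm' and 'outcome' must match the number of feature rows")
  if (!.is_binary01(arm) || !.is_binary01(outcome))
    .stopf("'arm' and 'outcome' must be binary 0/1")
  if (anyNA(X))
    .stopf("features contain missing values; run impute_encode() first")

  if (("e" %in% what || "mu" %in% what) &&
      (sum(arm == 1) < k_folds || sum(arm == 0) < k_folds))
    .stopf(paste("fewer %s patients (%d) than folds (%d): cross-fitting",
                 "cannot stratify; use fewer folds or a larger cohort"),
           if (sum(arm == 1) < k_folds) "treated" else "control",
           min(sum(arm == 1), sum(arm == 0)), k_folds)

  fold <- .stratified_folds(arm, k_folds)
  e_raw <- mu1 <- mu0 <- m <- rep(NA_real_, n)
  chosen <- NULL
  for (k in seq_len(k_folds)) {
    tr <- fold != k
    te <- !tr
    if ("e" %in% what || "mu" %in% what) {
      n1 <- sum(arm[tr] == 1); n0 <- sum(arm[tr] == 0)
      if (n1 == 0L || n0 == 0L)
        .stopf(paste("fold %d has no %s patients in its training split;",
                     "use fewer folds or a larger cohort"),
               k, if (n1 == 0L) "treated" else "control")
    }
    Xtr <- X[tr, , drop = FALSE]
    if ("e" %in% what) {
      hp <- .search_hyperparams(Xtr, arm[tr], spec)
      if (k == 1L) chosen <- hp
      e_raw[te] <- .pred_binary(.fit_binary(Xtr, arm[tr], spec$family, hp),
                                X[te, , drop = FALSE])
    }
    if ("mu" %in% what) {
      t1 <- tr & arm == 1; t0 <- tr & arm == 0
      hp1 <- .search_hyperparams(X[t1, , drop = FALSE], outcome[t1], spec)
      hp0 <- .search_hyperparams(X[t0, , drop = FALSE], outcome[t0], spec)
      mu1[te] <- .pred_binary(.fit_binary(X[t1, , drop = FALSE], outcome[t1],
                                          spec$family, hp1), X[te, , drop = FALSE])
      mu0[te] <- .pred_binary(.fit_binary(X[t0, , drop = FALSE], outcome[t0],
                                          spec$family, hp0), X[te, , drop = FALSE])
    }
    if ("m" %in% what) {
      hpm <- .search_hyperparams(Xtr, outcome[tr], spec)
      m[te] <- .pred_binary(.fit_binary(Xtr, outcome[tr], spec$family, hpm),
                            X[te, , drop = FALSE])
    }
  }

  e <- .clip(e_raw, clip[1], clip[2])
  clipped_frac <- if ("e" %in% what) mean(e_raw < clip[1] | e_raw > clip[2]) else NA
  if (!is.na(clipped_frac) && clipped_frac > 0.02)
    .warnf(paste("positivity warning: %.1f%% of propensity predictions were",
                 "clipped to [%g, %g]; overlap between arms is questionable"),
           100 * clipped_frac, clip[1], clip[2])

  structure(list(e = e, e_raw = e_raw, mu1 = mu1, mu0 = mu0, m = m,
                 fold = fold, clip = clip, clipped_frac = clipped_frac,
                 family = spec$family, hyperparams = chosen %||% spec$params,
                 k_folds = k_folds),
            class = "nuisance_predictions")
}

.as_feature_df <- function(features) {
  X <- as.data.frame(features)
  X$id <- NULL
  nonnum <- names(X)[!vapply(X, is.numeric, logical(1))]
  if (length(nonnum))
    .stopf("non-numeric feature columns (%s); run impute_encode() first",
           paste(nonnum, collapse = ", "))
  X
}

#' Propensity overlap diagnostic
#'
#' Summarizes the estimated propensity distribution per arm: range, histogram
#' and the amount of probability mass clipped at the positivity bounds.
#' Overlap is the only causal assumption testable from data, so this report
#' should be inspected before any effect estimate is trusted.
#'
#' @param predictions a [fit_nuisances()] result.
#' @param arm binary treatment indicator.
#' @return an object of class `overlap_report` with per-arm summaries, the
#'   clipped fraction, and a `flag` raised when more than 2% of predictions
#'   fall beyond the clipping bounds.
#' @export
overlap_diagnostic <- function(predictions, arm) {
  e <- predictions$e_raw
  brk <- seq(0, 1, by = 0.05)
  per_arm <- lapply(c(control = 0, treated = 1), function(a) {
    ea <- e[arm == a]
    list(n = length(ea), min = min(ea), max = max(ea),
         clipped = mean(ea < predictions$clip[1] | ea > predictions$clip[2]),
         hist = graphics::hist(ea, breaks = brk, plot = FALSE)$counts)
  })
  structure(list(per_arm = per_arm, breaks = brk,
                 clip = predictions$clip,
                 clipped_frac = predictions$clipped_frac,
                 flag = isTRUE(predictions$clipped_frac > 0.02)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Propensity overlap diagnostic\n")
  for (nm in names(x$per_arm)) {
    a <- x$per_arm[[nm]]
    cat(sprintf("  %-8s n=%6d  e-hat range [%.3f, %.3f]  clipped %.2f%%\n",
                nm, a$n, a$min, a$max, 100 * a$clipped))
  }
  cat(sprintf("  overall clipped at [%g, %g]: %.2f%%%s\n",
              x$clip[1], x$clip[2], 100 * x$clipped_frac,
              if (x$flag) "  ** POSITIVITY FLAG **" else ""))
  invisible(x)
}
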