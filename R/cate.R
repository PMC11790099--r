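#' Build the standard effect-modifier table from a cohort
#'
#' Derives the four binary patient characteristics along which treatment
#' heterogeneity is explored: age dichotomized at 60 years, male sex, septic
#' shock, and white race (reported as white vs non-white).
#'
#' @param cohort an `ehr_cohort` data frame.
#' @param age_cut age threshold in years (default 60).
#' @return data frame of binary modifier columns, one row per cohort patient.
#' @export
make_modifiers <- function(cohort, age_cut = 60) {
  data.frame(
    age_ge_60 = as.integer(cohort$age >= age_cut),
    male = as.integer(cohort$sex == "male"),
    septic_shock = as.integer(cohort$septic_shock),
    white = as.integer(cohort$race == "white")
  )
}

#' Estimate conditional average treatment effects (DR-learner)
#'
#' Regresses a per-patient causal effect signal on candidate effect
#' modifiers.  The preferred signal is the AIPW pseudo-outcome psi (making
#' this a DR-learner, valid whenever the average-effect pipeline is); the
#' T-learner difference mu1(X) - mu0(X) is accepted as an alternative.  The
#' fitted values are the per-patient effect predictions tau-hat on the
#' risk-difference scale.
#'
#' @param fit a `causal_ate` fit with pseudo-outcomes (estimator `"aipw"`),
#'   or a numeric vector of per-patient effect signals.
#' @param modifiers data frame of pre-treatment modifier columns (see
#'   [make_modifiers()]).  Columns tagged `post_treatment` in a
#'   `feature_matrix`'s roles are refused.
#' @param final_model `"ridge"` (linear ridge regression, the default) or
#'   `"forest"` (random forest regression).
#' @param lambda ridge penalty for the final model.  The default `1e-3` is a
#'   near-unpenalized fit, appropriate for a handful of binary modifiers;
#'   raise it when many modifiers are supplied.
#' @return an object of class `cate_result`: `tau` (per-patient predictions),
#'   `coefficients` (ridge final model), and `subgroups` (box summaries per
#'   binary modifier level: n, median, quartiles, 1.5 IQR whiskers clipped to
#'   observed values).
#' @export
estimate_cate <- function(fit, modifiers, final_model = c("ridge", "forest"),
                          lambda = 1e-3) {
  final_model <- match.arg(final_model)
  psi <- if (inherits(fit, "causal_ate")) {
    if (is.null(fit$psi))
      .stopf("fit has no per-patient effect signal; use estimator = \"aipw\" (pseudo-outcomes) or pass a numeric signal")
    fit$psi
  } else as.numeric(fit)

  roles <- attr(modifiers, "roles")
  if (!is.null(roles)) {
    bad <- roles$feature[roles$role == "post_treatment" &
                           roles$feature %in% names(modifiers)]
    if (length(bad))
      .stopf("leakage error: modifier(s) tagged post_treatment: %s",
             paste(bad, collapse = ", "))
  }
  M <- .as_feature_df(modifiers)
  if (nrow(M) != length(psi))
    .stopf("modifiers (%d rows) do not match the effect signal (%d values)",
           nrow(M), length(psi))

  if (stats::sd(psi) == 0) {
    ## degenerate signal: every prediction is that constant
    tau <- rep(psi[1], length(psi))
    return(structure(list(tau = tau,
                          coefficients = c("(Intercept)" = psi[1]),
                          final_model = final_model, modifiers = M,
                          subgroups = .box_summaries(tau, M),
                          n = length(tau), mean_tau = psi[1]),
                     class = "cate_result"))
  }
  if (final_model == "ridge") {
    Xm <- as.matrix(M)
    if (ncol(Xm) < 2L) Xm <- cbind(Xm, .zero_pad = 0)
    gfit <- glmnet::glmnet(Xm, psi, family = "gaussian", alpha = 0,
                           lambda = lambda, standardize = TRUE)
    tau <- as.numeric(stats::predict(gfit, Xm, s = lambda))
    coefs <- stats::setNames(as.numeric(stats::coef(gfit, s = lambda)),
                             rownames(stats::coef(gfit, s = lambda)))
    coefs <- coefs[names(coefs) != ".zero_pad"]
  } else {
    d <- M; d$.psi <- psi
    rfit <- ranger::ranger(.psi ~ ., data = d, num.trees = 200,
                           min.node.size = 50, num.threads = 1, verbose = FALSE)
    tau <- rfit$predictions      # out-of-bag predictions
    coefs <- NULL
  }

  structure(list(tau = tau, coefficients = coefs, final_model = final_model,
                 modifiers = M, subgroups = .box_summaries(tau, M),
                 n = length(tau), mean_tau = mean(tau)),
            class = "cate_result")
}

## Box summaries per binary modifier level: quartiles by linear interpolation
## (stats::quantile type 7), whiskers at 1.5 IQR clipped to observed values.
.box_summaries <- function(tau, M) {
  rows <- list()
  for (col in names(M)) {
    x <- M[[col]]
    if (!all(x %in% c(0, 1))) next
    for (lev in c(1, 0)) {
      v <- tau[x == lev]
      if (!length(v)) {
        rows[[length(rows) + 1L]] <- data.frame(
          modifier = col, level = lev, n = 0L, median = NA_real_,
          q25 = NA_real_, q75 = NA_real_, whisker_lo = NA_real_,
          whisker_hi = NA_real_, empty = TRUE)
        next
      }
      qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- qs[3] - qs[1]
      lo <- min(v[v >= qs[1] - 1.5 * iqr])
      hi <- max(v[v <= qs[3] + 1.5 * iqr])
      rows[[length(rows) + 1L]] <- data.frame(
        modifier = col, level = lev, n = length(v), median = qs[2],
        q25 = qs[1], q75 = qs[3], whisker_lo = lo, whisker_hi = hi,
        empty = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subgroup box-summary report
#'
#' One box-summary row per subgroup level (members and complement of each
#' binary modifier), with an optional box plot mirroring the standard
#' subgroup-ITE display.  Empty subgroups are flagged, not dropped.
#'
#' @param cate a `cate_result`.
#' @param modifiers optional character vector restricting which modifiers to
#'   report (default: all).
#' @param plot_file optional path; when given, a PNG box plot is written.
#' @return the subgroup summary data frame.
#' @export
subgroup_report <- function(cate, modifiers = NULL, plot_file = NULL) {
  tab <- cate$subgroups
  if (!is.null(modifiers)) tab <- tab[tab$modifier %in% modifiers, , drop = FALSE]
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 700, height = 120 + 45 * nrow(tab))
    plot(cate, modifiers = unique(tab$modifier))
    grDevices::dev.off()
  }
  tab
}

#' @export
print.cate_result <- function(x, digits = 4, ...) {
  cat(sprintf("Conditional average treatment effects (%s final model, n = %d)\n",
              x$final_model, x$n))
  cat(sprintf("  mean tau-hat: %+0.4f\n", x$mean_tau))
  if (!is.null(x$coefficients)) {
    cat("  final-model coefficients:\n")
    for (nm in names(x$coefficients))
      cat(sprintf("    %-14s %+0.4f\n", nm, x$coefficients[[nm]]))
  }
  cat("  subgroup medians (level 1 vs 0):\n")
  for (m in unique(x$subgroups$modifier)) {
    s <- x$subgroups[x$subgroups$modifier == m, ]
    cat(sprintf("    %-14s %+0.4f vs %+0.4f\n", m,
                s$median[s$level == 1], s$median[s$level == 0]))
  }
  invisible(x)
}

#' @export
plot.cate_result <- function(x, modifiers = NULL, ...) {
  tab <- x$subgroups[!x$subgroups$empty, , drop = FALSE]
  if (!is.null(modifiers)) tab <- tab[tab$modifier %in% modifiers, , drop = FALSE]
  k <- nrow(tab)
  lab <- sprintf("%s = %d (n=%d)", tab$modifier, tab$level, tab$n)
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  xlim <- range(c(tab$whisker_lo, tab$whisker_hi, 0))
  graphics::plot(NULL, xlim = xlim, ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = "predicted individual treatment effect (risk difference)",
                 ylab = "", main = "Subgroup ITE distributions", ...)
  for (i in seq_len(k)) {
    graphics::segments(tab$whisker_lo[i], i, tab$whisker_hi[i], i)
    graphics::rect(tab$q25[i], i - 0.3, tab$q75[i], i + 0.3, col = "lightsteelblue")
    graphics::segments(tab$median[i], i - 0.3, tab$median[i], i + 0.3, lwd = 2)
  }
  graphics::axis(2, at = seq_len(k), labels = lab, las = 1, cex.axis = 0.8)
  graphics::abline(v = 0, col = "grey60", lty = 2)
  invisible(x)
}
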