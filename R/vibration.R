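#' Define a vibration-analysis grid
#'
#' A vibration (multiverse) analysis re-estimates the treatment effect under
#' every combination of defensible analytic choices along four axes: the
#' eligibility window (study design), the confounder set (identification),
#' the aggregation strategy and the estimator/nuisance pair (estimation).
#'
#' @param windows_h eligibility windows in hours.
#' @param confounder_sets named subsets (see [select_confounders()]).
#' @param aggregations aggregation strategies.
#' @param estimators causal estimators.
#' @param nuisances nuisance families.
#' @param seeds replicate seeds; each cell's effective seed is derived
#'   deterministically from a hash of the cell's provenance so every cell is
#'   independently reproducible.
#' @return an object of class `vibration_grid` (a data frame of cells).
#' @export
vibration_grid <- function(windows_h = 24,
                           confounder_sets = "full",
                           aggregations = "first_and_last",
                           estimators = "aipw",
                           nuisances = "random_forest",
                           seeds = 1L) {
  stopifnot(length(windows_h) > 0, all(windows_h > 0))
  bad <- setdiff(confounder_sets,
                 c("full", "no_drugs", "no_biology", "sociodemographic_only"))
  if (length(bad)) .stopf("unknown confounder set(s): %s", paste(bad, collapse = ", "))
  grid <- expand.grid(window_h = windows_h, confounder_set = confounder_sets,
                      aggregation = aggregations, estimator = estimators,
                      nuisance = nuisances, seed = seeds,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  class(grid) <- c("vibration_grid", "data.frame")
  grid
}

#' Run a vibration analysis over the analytic-choice grid
#'
#' Executes the full pipeline once per grid cell.  Cell failures are recorded
#' in the result (with the error message) and never abort the grid.  When
#' ground truth is supplied, a per-cell bias column (estimated RD minus true
#' ATE) is added.
#'
#' @param tables an `event_tables` object.
#' @param base_spec a [cohort_spec()]; each cell overrides its eligibility
#'   window.
#' @param grid a [vibration_grid()].
#' @param truth optional ground-truth data frame (adds bias and truth line).
#' @param B bootstrap repetitions per cell (reduced to 30 by default inside
#'   grids for tractability; flagged in the output).
#' @param search_budget random-search budget for nuisance models per cell.
#' @return a `vibration_result` data frame: one row per cell with point
#'   estimate, CI, arm means, bias (if truth given) and error messages for
#'   failed cells.
#' @export
run_vibration <- function(tables, base_spec = cohort_spec(), grid,
                          truth = NULL, B = 30, search_budget = 0) {
  stopifnot(inherits(grid, "vibration_grid"))
  rows <- vector("list", nrow(grid))
  true_ate <- if (!is.null(truth)) attr(truth, "true_ate") else NA_real_
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    key <- paste(cell$window_h, cell$confounder_set, cell$aggregation,
                 cell$estimator, cell$nuisance, cell$seed, sep = "|")
    cell_seed <- (as.integer(cell$seed) + .hash31(key)) %% 2147483647L
    spec <- base_spec
    spec$eligibility_window_h <- cell$window_h
    res <- tryCatch({
      fit <- ate_pipeline(tables, spec,
                          aggregation = cell$aggregation,
                          confounder_set = cell$confounder_set,
                          estimator = cell$estimator,
                          nuisance = nuisance_spec(cell$nuisance,
                                                   search_budget = search_budget),
                          B = B, seed = cell_seed, truth = truth)
      rd <- fit$estimand[fit$estimand$estimand == "risk_difference", ]
      data.frame(cell, cell_seed = cell_seed,
                 rd = rd$estimate, lower = rd$lower, upper = rd$upper,
                 ey1 = fit$arm_means[["ey1"]], ey0 = fit$arm_means[["ey0"]],
                 n = fit$n, n_treated = fit$n_treated,
                 bias = rd$estimate - true_ate, error = NA_character_)
    }, error = function(err) {
      data.frame(cell, cell_seed = cell_seed,
                 rd = NA_real_, lower = NA_real_, upper = NA_real_,
                 ey1 = NA_real_, ey0 = NA_real_, n = NA_integer_,
                 n_treated = NA_integer_, bias = NA_real_,
                 error = conditionMessage(err))
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_ate") <- true_ate
  attr(out, "B") <- B
  class(out) <- c("vibration_result", "data.frame")
  out
}

#' Summarize and export a vibration analysis
#'
#' Produces forest-plot-ready data (cells sorted by point estimate, with CI
#' and the ground-truth line when available), a text summary, and optional
#' file output (`vibration.csv`, `vibration.md`, `vibration.png`).
#'
#' @param results a `vibration_result`.
#' @param dir optional output directory.
#' @return invisibly, a list with `table` (sorted cells) and `summary`
#'   (character vector).
#' @export
report_vibration <- function(results, dir = NULL) {
  stopifnot(inherits(results, "vibration_result"), nrow(results) > 0)
  ok <- results[is.na(results$error), , drop = FALSE]
  tab <- ok[order(ok$rd), , drop = FALSE]
  true_ate <- attr(results, "true_ate")
  lines <- c(
    sprintf("Vibration analysis: %d cells (%d failed)",
            nrow(results), sum(!is.na(results$error))),
    sprintf("Risk difference range: [%.4f, %.4f]",
            min(tab$rd), max(tab$rd)))
  if (!is.na(true_ate)) {
    covered <- mean(tab$lower <= true_ate & true_ate <= tab$upper, na.rm = TRUE)
    lines <- c(lines,
               sprintf("True ATE %.4f covered by %.0f%% of cell CIs",
                       true_ate, 100 * covered))
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(results), file.path(dir, "vibration.csv"),
                     row.names = FALSE)
    writeLines(c("# Vibration analysis", "", lines), file.path(dir, "vibration.md"))
    grDevices::png(file.path(dir, "vibration.png"), width = 900, height = 200 +
                     28 * nrow(tab))
    plot(results)
    grDevices::dev.off()
  }
  invisible(list(table = tab, summary = lines))
}

#' @export
plot.vibration_result <- function(x, ...) {
  ok <- x[is.na(x$error), , drop = FALSE]
  ok <- ok[order(ok$rd), , drop = FALSE]
  k <- nrow(ok)
  lab <- sprintf("W=%gh | %s | %s | %s/%s", ok$window_h, ok$confounder_set,
                 ok$aggregation, ok$estimator, ok$nuisance)
  op <- graphics::par(mar = c(4, 16, 2, 1))
  on.exit(graphics::par(op))
  xlim <- range(c(ok$lower, ok$upper, ok$rd, 0), na.rm = TRUE)
  graphics::plot(ok$rd, seq_len(k), xlim = xlim, ylim = c(0.5, k + 0.5),
                 pch = 19, yaxt = "n", xlab = "risk difference", ylab = "",
                 main = "Vibration analysis", ...)
  graphics::segments(ok$lower, seq_len(k), ok$upper, seq_len(k))
  graphics::axis(2, at = seq_len(k), labels = lab, las = 1, cex.axis = 0.7)
  ta <- attr(x, "true_ate")
  if (!is.na(ta)) graphics::abline(v = ta, col = "darkgreen", lty = 2)
  graphics::abline(v = 0, col = "grey60")
  invisible(x)
}

#' @export
print.vibration_result <- function(x, ...) {
  cat(sprintf("Vibration analysis: %d cells (%d failed), B = %d per cell\n",
              nrow(x), sum(!is.na(x$error)), attr(x, "B")))
  print.data.frame(utils::head(as.data.frame(x)[, c("window_h", "confounder_set",
    "aggregation", "estimator", "nuisance", "seed", "rd", "lower", "upper",
    "bias")], 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}
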