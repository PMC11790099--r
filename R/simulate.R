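## Synthetic longitudinal ICU data with known potential outcomes.
##
## Causal structure: a latent standardized severity score z drives both
## treatment assignment (confounding_strength) and 28-day mortality
## (severity_mortality_coef).  Septic shock raises severity-adjusted mortality
## and modifies the treatment effect; emergency admission lowers the odds of
## receiving the intervention fluid and slightly raises mortality.  Treatment
## is administered at a random delay after the follow-up anchor and only if
## the patient is still alive at that moment -- the coupling that makes
## immortal-time bias reproducible by design.

.HORIZON_H <- 28 * 24
.ANCHOR_PROB <- 0.97      # fraction of patients with a crystalloid anchor
.EARLY_DISCHARGE <- 0.02  # alive patients discharged before 28 d follow-up
.OBS_WINDOW_H <- 36       # repeat measurements drawn on [0, 36) h

#' Simulate a longitudinal ICU cohort with known ground truth
#'
#' Generates the four raw event tables (static, measurements, interventions,
#' outcomes) of an ICU-like cohort together with the hidden ground truth
#' (true propensity, potential-outcome probabilities and individual treatment
#' effects) needed to score causal estimators.
#'
#' @param config a [sim_config()].
#' @return an object of class `ehr_sim`: a list with elements
#'   * `tables`: an `event_tables` object (`static`, `measurements`,
#'     `interventions`, `outcomes` data frames),
#'   * `truth`: a data frame with one row per patient (`e` true propensity,
#'     `p1`, `p0`, `tau`, intended assignment, delay, latent untreated death
#'     time, realized arm and outcome); `attr(truth, "true_ate")` holds the
#'     population average of `tau`,
#'   * `config`: the configuration used.
#' @export
#' @examples
#' sim <- simulate_ehr(sim_config(n_patients = 300, seed = 42))
#' head(sim$tables$static)
#' attr(sim$truth, "true_ate")
simulate_ehr <- function(config) {
  if (!inherits(config, "sim_config"))
    .stopf("'config' must be a sim_config object")
  .with_seed(config$seed, .simulate_ehr_impl(config))
}

.simulate_ehr_impl <- function(cfg) {
  n <- cfg$n_patients
  id <- seq_len(n)

  ## -- static covariates (marginals patterned on a real sepsis ICU cohort) --
  age <- .clip(stats::rnorm(n, 66.3, 16.2), 16, 99)
  sex <- ifelse(stats::runif(n) < 0.415, "female", "male")
  race <- sample(c("white", "black", "other"), n, replace = TRUE,
                 prob = c(0.671, 0.15, 0.179))
  emergency <- as.integer(stats::runif(n) < 0.521)
  septic_shock <- as.integer(stats::runif(n) < 0.30)
  weight0 <- .clip(stats::rnorm(n, 82, 18), 35, 200)
  z <- stats::rnorm(n)                       # latent standardized severity
  sofa_latent <- .clip(6 + 3.5 * z + 1.5 * septic_shock, 0, 24)
  age_std <- (age - 66.3) / 16.2

  ## -- potential outcomes ---------------------------------------------------
  mort_off <- cfg$severity_mortality_coef * z + 0.5 * septic_shock +
    0.30 * age_std + 0.20 * emergency
  b0 <- stats::uniroot(
    function(b) mean(stats::plogis(b + mort_off)) - cfg$baseline_mortality_28d,
    c(-15, 15), tol = 1e-10)$root
  p0 <- stats::plogis(b0 + mort_off)
  me <- cfg$modifier_effects
  p1 <- .clip(p0 + cfg$true_ate_rd +
                me[["age_ge_60"]] * (age >= 60) +
                me[["male"]] * (sex == "male") +
                me[["septic_shock"]] * septic_shock,
              0.001, 0.999)
  tau <- p1 - p0

  u <- stats::runif(n)                       # shared potential-outcome draw
  y0 <- as.integer(u < p0)
  y1 <- as.integer(u < p1)

  ## Time to death among decedents: lognormal truncated to 28 d; the same
  ## quantile draw is shared across arms so death-time order is coupled.
  v <- stats::runif(n)
  f_h <- stats::plnorm(.HORIZON_H, log(cfg$death_time_median_h), cfg$death_time_sdlog)
  qdeath <- stats::qlnorm(v * f_h, log(cfg$death_time_median_h), cfg$death_time_sdlog)
  t_death0 <- ifelse(y0 == 1, qdeath, Inf)   # latent untreated death time
  t_death1 <- ifelse(y1 == 1, qdeath, Inf)

  ## -- anchor, delay, treatment assignment ----------------------------------
  has_anchor <- stats::runif(n) < .ANCHOR_PROB
  t_anchor <- ifelse(has_anchor, stats::runif(n, 0, cfg$followup_anchor_window_h), NA)
  delay <- stats::runif(n, cfg$treatment_delay_range_h[1], cfg$treatment_delay_range_h[2])
  t_admin <- t_anchor + delay
  alive_at_admin <- has_anchor & (t_death0 > t_admin)

  treat_off <- cfg$confounding_strength * z - 1.1 * emergency + 0.10 * age_std
  idx <- which(has_anchor)
  a0 <- stats::uniroot(
    function(a) mean(stats::plogis(a + treat_off[idx]) * alive_at_admin[idx]) -
      cfg$treated_fraction_target,
    c(-15, 15), tol = 1e-10)$root
  e <- stats::plogis(a0 + treat_off)         # intended propensity P(W = 1 | X)
  w <- as.integer(stats::runif(n) < e)
  arm <- as.integer(w == 1L & alive_at_admin)

  y <- ifelse(arm == 1L, y1, y0)
  t_death <- ifelse(arm == 1L, t_death1, t_death0)
  ## a treated decedent was alive at administration by construction (shared
  ## quantile draw); guard the rare harmful-effect corner case anyway
  t_death[arm == 1L & is.finite(t_death)] <-
    pmax(t_death[arm == 1L & is.finite(t_death)],
         t_admin[arm == 1L & is.finite(t_death)] + 0.5)

  ## -- outcomes table -------------------------------------------------------
  died <- is.finite(t_death)
  last_seen <- ifelse(died, t_death, .HORIZON_H + stats::runif(n, 0, 240))
  early <- !died & stats::runif(n) < .EARLY_DISCHARGE
  last_seen[early] <- stats::runif(sum(early), 6, 26)
  outcomes <- data.frame(
    id = id,
    death_time = ifelse(died, round(t_death, 2), NA_real_),
    last_seen = round(last_seen, 2)
  )

  static <- data.frame(
    id = id, age = round(age, 1), sex = sex, race = race,
    emergency = emergency, septic_shock = septic_shock,
    admission_time = 0
  )

  ## -- measurements: admission battery + Poisson repeats --------------------
  meas <- .sim_measurements(cfg, id, sofa_latent, weight0, pmin(t_death, last_seen))

  ## -- interventions --------------------------------------------------------
  interv <- .sim_interventions(cfg, id, z, septic_shock, has_anchor, t_anchor,
                               arm, t_admin, pmin(t_death, last_seen))

  tables <- structure(list(static = static, measurements = meas,
                           interventions = interv, outcomes = outcomes),
                      class = "event_tables")

  truth <- data.frame(
    id = id, e = e, p0 = p0, p1 = p1, tau = tau,
    w_intended = w, delay_h = delay, anchor_time_h = t_anchor,
    latent_death_h = ifelse(is.finite(t_death0), t_death0, NA_real_),
    arm = arm, y0 = y0, y1 = y1, y = y
  )
  attr(truth, "true_ate") <- mean(tau)
  class(truth) <- c("ehr_truth", "data.frame")

  structure(list(tables = tables, truth = truth, config = cfg),
            class = "ehr_sim")
}

.sim_measurements <- function(cfg, id, sofa_latent, weight0, t_end) {
  n <- length(id)
  vars <- c("sofa", "lactate", "weight")
  rows <- vector("list", 2L * length(vars))
  k <- 0L
  for (v in vars) {
    ## admission battery at t = 0
    k <- k + 1L
    rows[[k]] <- data.frame(id = id, time = 0, variable = v,
                            value = .meas_value(v, sofa_latent, weight0, n))
    ## Poisson repeats
    m <- stats::rpois(n, cfg$measurement_rate_per_hour * .OBS_WINDOW_H)
    rid <- rep(id, m)
    if (length(rid)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        id = rid,
        time = round(stats::runif(length(rid), 0, .OBS_WINDOW_H), 2),
        variable = v,
        value = .meas_value(v, rep(sofa_latent, m), rep(weight0, m), length(rid))
      )
    }
  }
  meas <- do.call(rbind, rows[seq_len(k)])
  ## completely-at-random missingness; admission SOFA is always recorded
  drop <- stats::runif(nrow(meas)) < cfg$missing_rate &
    !(meas$variable == "sofa" & meas$time == 0)
  meas <- meas[!drop, , drop = FALSE]
  meas <- meas[meas$time <= t_end[meas$id], , drop = FALSE]
  meas <- meas[order(meas$id, meas$variable, meas$time), , drop = FALSE]
  rownames(meas) <- NULL
  meas
}

.meas_value <- function(var, sofa_latent, weight0, n) {
  switch(var,
    sofa = round(.clip(sofa_latent + stats::rnorm(n, 0, 0.5), 0, 24)),
    lactate = round(.clip(0.5 + 0.42 * sofa_latent + stats::rnorm(n, 0, 1.2), 0.2, 25), 1),
    weight = round(weight0 + stats::rnorm(n, 0, 0.8), 1)
  )
}

.sim_interventions <- function(cfg, id, z, septic_shock, has_anchor, t_anchor,
                               arm, t_admin, t_end) {
  n <- length(id)
  add <- function(ids, times, class) {
    keep <- times <= t_end[ids] & !is.na(times)
    data.frame(id = ids[keep], time = round(times[keep], 2), class = class)
  }
  p_vaso <- stats::plogis(-0.6 + 0.9 * z + 0.8 * septic_shock)
  p_vent <- stats::plogis(1.5 + 0.5 * z)
  p_blac <- stats::plogis(-0.5 - 0.35 * z)
  ## drug exposures correlated with severity, times uniform over the first day
  draw <- function(p, class) {
    sel <- stats::runif(n) < p
    add(id[sel], stats::runif(sum(sel), 0, 24), class)
  }
  interv <- rbind(add(id[has_anchor], t_anchor[has_anchor], "crystalloid"),
                  add(id[arm == 1L], t_admin[arm == 1L], "albumin"),
                  draw(p_vaso, "vasopressor"),
                  draw(p_vent, "ventilation"),
                  draw(rep(0.52, n), "glycopeptide"),
                  draw(p_blac, "beta_lactam"))
  interv <- interv[order(interv$id, interv$time, interv$class), , drop = FALSE]
  rownames(interv) <- NULL
  interv
}

#' Validate raw event tables
#'
#' Checks the structural invariants of an `event_tables` object: every
#' measurement/intervention/outcome id appears in the static table, all times
#' are non-negative, and no event is recorded after a patient's death.
#'
#' @param tables an `event_tables` object (or a list with the four tables).
#' @return `tables`, invisibly, if valid; otherwise an error.
#' @export
validate_event_tables <- function(tables) {
  need <- c("static", "measurements", "interventions", "outcomes")
  if (!all(need %in% names(tables)))
    .stopf("event tables must contain: %s", paste(need, collapse = ", "))
  ids <- tables$static$id
  for (nm in c("measurements", "interventions", "outcomes")) {
    bad <- setdiff(tables[[nm]]$id, ids)
    if (length(bad))
      .stopf("table '%s' has ids absent from static: %s", nm,
             paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(tables$measurements$time < 0) || any(tables$interventions$time < 0))
    .stopf("event times must be >= 0")
  dt <- tables$outcomes$death_time[match(tables$measurements$id, tables$outcomes$id)]
  if (any(!is.na(dt) & tables$measurements$time > dt))
    .stopf("measurement recorded after death")
  dt <- tables$outcomes$death_time[match(tables$interventions$id, tables$outcomes$id)]
  if (any(!is.na(dt) & tables$interventions$time > dt))
    .stopf("intervention recorded after death")
  invisible(tables)
}

#' @export
print.ehr_sim <- function(x, ...) {
  cat(sprintf("Synthetic ICU cohort: %d patients (seed %d)\n",
              x$config$n_patients, x$config$seed))
  cat(sprintf("  realized treated: %d (%.1f%%) | 28-day deaths: %d (%.1f%%)\n",
              sum(x$truth$arm), 100 * mean(x$truth$arm),
              sum(x$truth$y), 100 * mean(x$truth$y)))
  cat(sprintf("  true ATE (risk difference): %+0.4f\n", attr(x$truth, "true_ate")))
  cat(sprintf("  tables: %d measurements, %d interventions\n",
              nrow(x$tables$measurements), nrow(x$tables$interventions)))
  invisible(x)
}

#' True subgroup treatment effects from simulation ground truth
#'
#' Averages the individual treatment effects `tau` over subgroups defined on
#' static patient fields, the oracle against which conditional-effect
#' estimates are scored.  A whole-population row is always included; an empty
#' subgroup yields a flagged row with an undefined effect rather than an
#' error.
#'
#' @param sim an `ehr_sim` object (or a list with `truth` and `tables`).
#' @param subgroups named list of one-sided expressions (as strings) evaluated
#'   on the static table, e.g. `list(age_ge_60 = "age >= 60")`.  Defaults to
#'   the four standard binary characteristics: age >= 60, male sex, septic
#'   shock, white race.
#' @return a data frame with columns `subgroup`, `n`, `true_ate`, `empty`;
#'   both levels (members and complement) are reported for each definition.
#' @export
true_effects <- function(sim, subgroups = NULL) {
  truth <- sim$truth
  static <- sim$tables$static
  if (is.null(subgroups))
    subgroups <- list(age_ge_60 = "age >= 60",
                      male = "sex == \"male\"",
                      septic_shock = "septic_shock == 1",
                      white = "race == \"white\"")
  tau <- truth$tau[match(static$id, truth$id)]
  row <- function(name, sel) {
    n <- sum(sel)
    data.frame(subgroup = name, n = n,
               true_ate = if (n) mean(tau[sel]) else NA_real_,
               empty = n == 0L)
  }
  out <- list(row("overall", rep(TRUE, nrow(static))))
  for (nm in names(subgroups)) {
    sel <- eval(parse(text = subgroups[[nm]]), static)
    if (!is.logical(sel) || length(sel) != nrow(static))
      .stopf("subgroup '%s' must evaluate to a logical over static rows", nm)
    sel[is.na(sel)] <- FALSE
    out[[length(out) + 1L]] <- row(paste0(nm, "=1"), sel)
    out[[length(out) + 1L]] <- row(paste0(nm, "=0"), !sel)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
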