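## Shared fixtures, all built in code.

ridge_fast <- function() nuisance_spec("ridge_logistic", search_budget = 0)
forest_fast <- function() nuisance_spec("random_forest", search_budget = 0)

## Six hand-written patients for the cohort builder:
##   ids 1, 2 under-age; id 3 has no crystalloid anchor; ids 4-6 eligible,
##   of which id 5 receives albumin inside the 24 h window.
toy_tables <- function() {
  static <- data.frame(
    id = 1:6,
    age = c(16, 17, 70, 55, 64, 81),
    sex = c("male", "female", "male", "female", "male", "female"),
    race = c("white", "white", "black", "other", "white", "white"),
    emergency = c(1, 0, 1, 1, 0, 1),
    septic_shock = c(0, 0, 1, 0, 1, 0),
    admission_time = 0
  )
  interventions <- data.frame(
    id    = c(1L,  2L,  4L,  5L,  5L,   6L,  6L),
    time  = c(1,   2,   1.5, 2,   10,   3,   30),
    class = c("crystalloid", "crystalloid", "crystalloid", "crystalloid",
              "albumin", "crystalloid", "albumin")  # id 6: albumin after window
  )
  measurements <- data.frame(
    id = c(4L, 4L, 5L, 6L),
    time = c(0, 12, 0, 0),
    variable = "sofa",
    value = c(5, 9, 7, 4)
  )
  outcomes <- data.frame(
    id = 1:6,
    death_time = c(NA, NA, NA, 200, NA, NA),
    last_seen = c(700, 700, 700, 200, 700, 700)
  )
  structure(list(static = static, measurements = measurements,
                 interventions = interventions, outcomes = outcomes),
            class = "event_tables")
}

## Minimal cohort data frame for direct aggregation tests.
toy_cohort <- function(ids = 1L, t0 = 24, arm = 0L) {
  co <- data.frame(id = ids, t0 = t0, arm = arm, death = 0L,
                   treatment_time = NA_real_)
  class(co) <- c("ehr_cohort", "data.frame")
  co
}

## Full pipeline shortcut: simulated tables -> encoded feature matrix.
sim_features <- function(sim, spec = cohort_spec(), strategy = "first_and_last") {
  built <- build_cohort(sim$tables, spec)
  fm <- aggregate_features(built$cohort, sim$tables$measurements,
                           strategy = strategy,
                           interventions = sim$tables$interventions)
  list(cohort = built$cohort, flowchart = built$flowchart,
       fm = impute_encode(fm))
}

## Independent quartile oracle: direct order-statistics interpolation
## (type-7 definition computed from scratch).
quartile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}
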