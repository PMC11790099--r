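#' PICOT cohort specification
#'
#' Machine-readable description of the emulated trial: who is eligible
#' (population), which intervention class defines the treated arm, what event
#' anchors follow-up (time zero), the eligibility window within which
#' treatment must start to count as treated, and the outcome horizon.
#'
#' @param min_age minimum age in years (inclusive).
#' @param min_followup_h minimum follow-up in hours for patients who do not
#'   die; an observed death always counts as complete follow-up.
#' @param anchor_event intervention class whose first occurrence starts
#'   follow-up (time zero), e.g. `"crystalloid"`.
#' @param treatment_event intervention class defining the treated arm, e.g.
#'   `"albumin"`.
#' @param eligibility_window_h treatment must start within `[t0, t0 + W)`
#'   hours of the anchor to count as treated (half-open window).  Longer
#'   windows deliberately induce immortal-time bias.
#' @param outcome_horizon_d outcome is death within this many days of t0.
#' @param exclusions named list of additional exclusion predicates, as strings
#'   evaluated on the static table (patients for whom the predicate is TRUE
#'   are excluded), applied after the built-in rules.
#' @return an object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec()
#' spec$eligibility_window_h
cohort_spec <- function(min_age = 18,
                        min_followup_h = 24,
                        anchor_event = "crystalloid",
                        treatment_event = "albumin",
                        eligibility_window_h = 24,
                        outcome_horizon_d = 28,
                        exclusions = list()) {
  if (eligibility_window_h <= 0)
    .stopf("invalid cohort_spec: 'eligibility_window_h' must be > 0")
  if (outcome_horizon_d <= 0)
    .stopf("invalid cohort_spec: 'outcome_horizon_d' must be > 0")
  if (!is.character(anchor_event) || !is.character(treatment_event))
    .stopf("invalid cohort_spec: event classes must be character")
  structure(list(min_age = min_age, min_followup_h = min_followup_h,
                 anchor_event = anchor_event, treatment_event = treatment_event,
                 eligibility_window_h = eligibility_window_h,
                 outcome_horizon_d = outcome_horizon_d,
                 exclusions = exclusions),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("PICOT cohort specification\n")
  cat(sprintf("  Population: age >= %g y, follow-up >= %g h (or death)\n",
              x$min_age, x$min_followup_h))
  cat(sprintf("  Intervention: '%s' within [t0, t0 + %g h)\n",
              x$treatment_event, x$eligibility_window_h))
  cat(sprintf("  Control: '%s' only\n", x$anchor_event))
  cat(sprintf("  Outcome: death within %g days of t0\n", x$outcome_horizon_d))
  cat(sprintf("  Time zero: first '%s' administration\n", x$anchor_event))
  invisible(x)
}

#' Build an analyzable cohort from raw event tables
#'
#' Applies the PICOT specification to the raw longitudinal tables: determines
#' each patient's follow-up start (first anchor event), labels arms by whether
#' the treatment event occurs inside the half-open eligibility window, derives
#' the binary outcome (death within the horizon of t0), and records every
#' exclusion in a selection flowchart whose counts telescope exactly.
#'
#' Patients who die inside the eligibility window before receiving treatment
#' remain in the control arm.  This labeling is intentional: it is the
#' mechanism through which over-long eligibility windows generate
#' immortal-time bias, which the vibration analysis is designed to expose.
#'
#' @param tables an `event_tables` object.
#' @param spec a [cohort_spec()].
#' @return a list with elements `cohort` (data frame, class `ehr_cohort`, one
#'   row per included patient: `id`, `t0`, `arm`, `death`, static fields) and
#'   `flowchart` (data frame, class `cohort_flowchart`).
#' @export
build_cohort <- function(tables, spec = cohort_spec()) {
  classes <- unique(tables$interventions$class)
  for (ev in c(spec$anchor_event, spec$treatment_event))
    if (!ev %in% classes)
      .stopf("cohort_spec references unknown intervention class '%s' (known: %s)",
             ev, paste(sort(classes), collapse = ", "))

  static <- tables$static
  out <- tables$outcomes[match(static$id, tables$outcomes$id), , drop = FALSE]

  ## first anchor event per patient
  anch <- tables$interventions[tables$interventions$class == spec$anchor_event, ]
  anch <- anch[order(anch$id, anch$time), ]
  first_anchor <- anch[!duplicated(anch$id), ]
  t0 <- first_anchor$time[match(static$id, first_anchor$id)]

  steps <- list()
  keep <- rep(TRUE, nrow(static))
  apply_rule <- function(label, drop) {
    n_before <- sum(keep)
    keep <<- keep & !drop
    steps[[length(steps) + 1L]] <<- data.frame(
      rule = label, n_before = n_before,
      n_excluded = n_before - sum(keep), n_after = sum(keep))
  }
  apply_rule(sprintf("age >= %g years", spec$min_age), static$age < spec$min_age)
  apply_rule(sprintf("anchor event ('%s') present", spec$anchor_event), is.na(t0))
  insufficient <- is.na(out$death_time) &
    (out$last_seen - ifelse(is.na(t0), 0, t0)) < spec$min_followup_h
  apply_rule(sprintf("follow-up >= %g h or observed death", spec$min_followup_h),
             insufficient)
  for (nm in names(spec$exclusions)) {
    drop <- eval(parse(text = spec$exclusions[[nm]]), static)
    drop[is.na(drop)] <- FALSE
    apply_rule(nm, drop)
  }
  flowchart <- do.call(rbind, steps)
  class(flowchart) <- c("cohort_flowchart", "data.frame")

  inc <- which(keep)
  ## treated iff treatment event inside [t0, t0 + W)
  trt <- tables$interventions[tables$interventions$class == spec$treatment_event, ]
  t0i <- t0[inc]
  ids <- static$id[inc]
  tw <- trt[trt$id %in% ids, ]
  rel <- tw$time - t0i[match(tw$id, ids)]
  in_window <- rel >= 0 & rel < spec$eligibility_window_h
  treated_ids <- unique(tw$id[in_window])
  arm <- as.integer(ids %in% treated_ids)
  tw_in <- tw[in_window, ]
  tw_in <- tw_in[order(tw_in$id, tw_in$time), ]
  first_trt <- tw_in[!duplicated(tw_in$id), ]
  treatment_time <- first_trt$time[match(ids, first_trt$id)]

  horizon_h <- spec$outcome_horizon_d * 24
  death <- as.integer(!is.na(out$death_time[inc]) &
                        out$death_time[inc] <= t0i + horizon_h)

  cohort <- cbind(
    data.frame(id = ids, t0 = t0i, arm = arm, death = death,
               treatment_time = treatment_time),
    static[inc, setdiff(names(static), c("id", "admission_time")), drop = FALSE],
    data.frame(death_time = out$death_time[inc], last_seen = out$last_seen[inc])
  )
  rownames(cohort) <- NULL
  class(cohort) <- c("ehr_cohort", "data.frame")
  attr(cohort, "spec") <- spec
  list(cohort = cohort, flowchart = flowchart)
}

#' @export
print.cohort_flowchart <- function(x, ...) {
  cat("Selection flowchart\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-45s %6d -> %6d  (excluded %d)\n",
                x$rule[i], x$n_before[i], x$n_after[i], x$n_excluded[i]))
  invisible(x)
}

#' Rebuild the cohort under several eligibility windows
#'
#' Re-runs [build_cohort()] with every eligibility window in `windows_h`,
#' holding all other specification fields fixed.  Because a longer window is a
#' superset condition, treated counts are non-decreasing in window length.
#'
#' @param tables an `event_tables` object.
#' @param spec a [cohort_spec()]; its `eligibility_window_h` is overridden.
#' @param windows_h numeric vector of positive window lengths (hours).
#' @return a named list (one element per window) of [build_cohort()] results.
#' @export
vary_eligibility_window <- function(tables, spec = cohort_spec(), windows_h) {
  if (!length(windows_h) || any(windows_h <= 0))
    .stopf("'windows_h' must be a non-empty vector of positive hours")
  res <- lapply(windows_h, function(w) {
    s <- spec; s$eligibility_window_h <- w
    build_cohort(tables, s)
  })
  names(res) <- as.character(windows_h)
  res
}
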