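## Patient-level feature construction: collapse time-stamped pre-treatment
## measurements to one row per patient, then impute and encode.  Only events
## strictly before the per-patient cutoff enter any feature (half-open
## window [0, cutoff)) -- the absolute guard against post-treatment leakage.

.AGG_STRATEGIES <- c("first", "last", "first_and_last", "mean")

#' Aggregate time-stamped measurements into a patient-level feature matrix
#'
#' Collapses the longitudinal measurement table to one row per cohort patient
#' under one of four aggregation strategies, adds static covariates, and
#' (optionally) pre-cutoff drug-exposure indicators.  Events at or after the
#' cutoff time never contribute: deleting or shuffling post-cutoff records
#' leaves the output unchanged.
#'
#' @param cohort an `ehr_cohort` from [build_cohort()].
#' @param measurements the raw measurement table (`id`, `time`, `variable`,
#'   `value`).
#' @param strategy one of `"first"`, `"last"`, `"first_and_last"`, `"mean"`:
#'   first/last observed value before the cutoff, both as separate features,
#'   or the mean over the pre-cutoff window.
#' @param interventions optional raw intervention table; when supplied, a
#'   binary pre-cutoff exposure indicator is added for every drug class other
#'   than the anchor and treatment events.
#' @param cutoff `"t0"` (default: follow-up start, the standard pre-treatment
#'   cutoff) or `"treatment"` (each treated patient's own treatment time;
#'   controls keep t0) for leakage-sensitivity experiments.
#' @return a `feature_matrix`: a data frame with `id` plus raw feature
#'   columns (numeric aggregates may contain `NA`; categoricals are still
#'   factors/characters), carrying attributes `roles` (per-feature role and
#'   group tags), `strategy` and `cutoff`.  Pass through [impute_encode()]
#'   before modelling.
#' @export
aggregate_features <- function(cohort, measurements,
                               strategy = c("first_and_last", "first", "last", "mean"),
                               interventions = NULL,
                               cutoff = c("t0", "treatment")) {
  if (!is.character(strategy) || !strategy[1] %in% .AGG_STRATEGIES)
    .stopf("unknown aggregation strategy '%s'; valid options: %s",
           strategy[1], paste(.AGG_STRATEGIES, collapse = ", "))
  strategy <- strategy[1]
  cutoff <- match.arg(cutoff)

  cut_t <- cohort$t0
  if (cutoff == "treatment")
    cut_t <- ifelse(cohort$arm == 1 & !is.na(cohort$treatment_time),
                    cohort$treatment_time, cohort$t0)

  m <- measurements[measurements$id %in% cohort$id, , drop = FALSE]
  m <- m[m$time < cut_t[match(m$id, cohort$id)], , drop = FALSE]
  vars <- sort(unique(measurements$variable))

  wide <- data.frame(id = cohort$id)
  pick <- function(mm, take_last) {
    ## stable order by (id, variable, time); ties broken by input record order
    o <- order(match(mm$id, cohort$id), match(mm$variable, vars), mm$time)
    mm <- mm[o, , drop = FALSE]
    key <- paste(mm$id, mm$variable)
    sel <- if (take_last) !duplicated(key, fromLast = TRUE) else !duplicated(key)
    mm[sel, , drop = FALSE]
  }
  fill <- function(picked, suffix) {
    for (v in vars) {
      pv <- picked[picked$variable == v, ]
      wide[[paste0(v, suffix)]] <<- pv$value[match(cohort$id, pv$id)]
    }
  }
  if (strategy %in% c("first", "first_and_last")) fill(pick(m, FALSE), "_first")
  if (strategy %in% c("last", "first_and_last")) fill(pick(m, TRUE), "_last")
  if (strategy == "mean") {
    key <- paste(m$id, m$variable)
    s <- rowsum(m$value, key)
    cnt <- rowsum(rep(1, nrow(m)), key)
    mu <- s[, 1] / cnt[, 1]
    for (v in vars)
      wide[[paste0(v, "_mean")]] <- unname(mu[match(paste(cohort$id, v), rownames(s))])
  }

  ## static covariates travel with the cohort rows
  for (col in intersect(c("age", "sex", "race", "emergency", "septic_shock"),
                        names(cohort)))
    wide[[col]] <- cohort[[col]]

  ## pre-cutoff drug exposure indicators
  drug_classes <- character()
  if (!is.null(interventions)) {
    spec <- attr(cohort, "spec")
    skip <- c(spec$anchor_event %||% "crystalloid",
              spec$treatment_event %||% "albumin")
    iv <- interventions[interventions$id %in% cohort$id &
                          !interventions$class %in% skip, , drop = FALSE]
    iv <- iv[iv$time < cut_t[match(iv$id, cohort$id)], , drop = FALSE]
    drug_classes <- sort(unique(interventions$class[!interventions$class %in% skip]))
    for (cl in drug_classes)
      wide[[cl]] <- as.integer(cohort$id %in% iv$id[iv$class == cl])
  }

  attr(wide, "roles") <- .feature_roles(setdiff(names(wide), "id"), vars, drug_classes)
  attr(wide, "strategy") <- strategy
  attr(wide, "cutoff") <- cutoff
  class(wide) <- c("feature_matrix", "data.frame")
  wide
}

## Role and group tags.  Roles follow the causal taxonomy (everything kept in
## the default matrix is a confounder or an effect modifier); groups drive the
## named confounder subsets of the vibration analysis.
.feature_roles <- function(features, meas_vars, drug_classes) {
  base <- sub("_(first|last|mean)$", "", features)
  group <- ifelse(base %in% meas_vars | base %in% c("septic_shock", "weight"),
                  "biology",
           ifelse(base %in% drug_classes, "drugs", "sociodemographic"))
  modifier <- base %in% c("age", "sex", "race", "septic_shock") |
    features %in% c("sex_male", "race_white")
  data.frame(feature = features,
             role = ifelse(modifier, "effect_modifier", "confounder"),
             group = group)
}

#' Impute missing values and one-hot encode categoricals
#'
#' Numeric missing values are replaced by the column median (computed on the
#' matrix itself; the medians are recorded for reuse on resamples), and
#' categorical columns are expanded to indicator columns with the reference
#' level (first in sort order) dropped to avoid collinearity in ridge models.
#'
#' @param fm a `feature_matrix` from [aggregate_features()].
#' @return a fully numeric `feature_matrix` with no missing values; attributes
#'   `roles`, `strategy`, `cutoff` are carried over and
#'   `imputation_medians` records the medians used.
#' @export
impute_encode <- function(fm) {
  roles <- attr(fm, "roles")
  out <- data.frame(id = fm$id)
  medians <- c()
  for (col in setdiff(names(fm), "id")) {
    x <- fm[[col]]
    if (is.numeric(x)) {
      if (all(is.na(x)))
        .stopf("cannot impute column '%s': all values missing", col)
      med <- stats::median(x, na.rm = TRUE)
      x[is.na(x)] <- med
      medians[col] <- med
      out[[col]] <- x
    } else {
      lev <- sort(unique(as.character(x[!is.na(x)])))
      for (l in lev[-1]) {                    # drop reference level
        nm <- paste0(col, "_", l)
        out[[nm]] <- as.integer(!is.na(x) & x == l)
        roles <- rbind(roles, .feature_roles(nm, character(), character()))
        roles$group[roles$feature == nm] <- roles$group[roles$feature == col][1]
      }
      roles <- roles[roles$feature != col, , drop = FALSE]
    }
  }
  rownames(roles) <- NULL
  attr(out, "roles") <- roles
  attr(out, "strategy") <- attr(fm, "strategy")
  attr(out, "cutoff") <- attr(fm, "cutoff")
  attr(out, "imputation_medians") <- medians
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Select a named confounder subset
#'
#' Restricts a feature matrix to one of the named confounder sets used by the
#' vibration analysis, defined through the group tags attached by
#' [aggregate_features()]: `full` keeps everything; `no_drugs` drops drug
#' exposure indicators; `no_biology` drops laboratory/severity aggregates
#' (and septic shock); `sociodemographic_only` keeps age, sex, race and
#' admission type only.
#'
#' @param fm a `feature_matrix`.
#' @param set one of `"full"`, `"no_drugs"`, `"no_biology"`,
#'   `"sociodemographic_only"`.
#' @return the restricted `feature_matrix`.
#' @export
select_confounders <- function(fm, set = c("full", "no_drugs", "no_biology",
                                           "sociodemographic_only")) {
  set <- match.arg(set)
  roles <- attr(fm, "roles")
  keep <- switch(set,
    full = roles$feature,
    no_drugs = roles$feature[roles$group != "drugs"],
    no_biology = roles$feature[roles$group != "biology"],
    sociodemographic_only = roles$feature[roles$group == "sociodemographic"])
  out <- fm[, c("id", keep), drop = FALSE]
  attr(out, "roles") <- roles[roles$feature %in% keep, , drop = FALSE]
  for (a in c("strategy", "cutoff", "imputation_medians"))
    attr(out, a) <- attr(fm, a)
  attr(out, "confounder_set") <- set
  class(out) <- c("feature_matrix", "data.frame")
  out
}
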