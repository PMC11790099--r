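test_that("aggregation strategies implement their definitions", {
  co <- toy_cohort(ids = 1L, t0 = 24)
  meas <- data.frame(id = 1L, time = c(1, 10), variable = "sofa", value = c(5, 9))

  expect_identical(aggregate_features(co, meas, "first")$sofa_first, 5)
  expect_identical(aggregate_features(co, meas, "last")$sofa_last, 9)
  fl <- aggregate_features(co, meas, "first_and_last")
  expect_identical(fl$sofa_first, 5)
  expect_identical(fl$sofa_last, 9)
  expect_identical(aggregate_features(co, meas, "mean")$sofa_mean, 7)

  ## a post-cutoff reading changes nothing (half-open window [0, cutoff))
  meas2 <- rbind(meas, data.frame(id = 1L, time = 30, variable = "sofa", value = 24))
  expect_identical(as.data.frame(aggregate_features(co, meas2, "first_and_last")),
                   as.data.frame(fl))
  ## reading exactly at the cutoff is excluded too
  meas3 <- rbind(meas, data.frame(id = 1L, time = 24, variable = "sofa", value = 24))
  expect_identical(aggregate_features(co, meas3, "last")$sofa_last, 9)

  expect_error(aggregate_features(co, meas, "median"), "first.*last.*mean")
})

test_that("deleting or shuffling post-cutoff events never changes the features", {
  sim <- simulate_ehr(sim_config(n_patients = 800, seed = 41))
  built <- build_cohort(sim$tables, cohort_spec())
  co <- built$cohort
  meas <- sim$tables$measurements
  cut <- co$t0[match(meas$id, co$id)]
  pre <- !is.na(cut) & meas$time < cut
  truncated <- meas[pre, ]
  ## permute only the post-cutoff records: pre-cutoff record order is the
  ## documented tie-break and must stay fixed
  post <- meas[!pre, ]
  shuffled <- rbind(truncated, post[sample.int(nrow(post)), ])
  for (strat in c("first", "last", "first_and_last", "mean")) {
    a <- aggregate_features(co, meas, strat)
    expect_identical(as.data.frame(aggregate_features(co, truncated, strat)),
                     as.data.frame(a))
    expect_identical(as.data.frame(aggregate_features(co, shuffled, strat)),
                     as.data.frame(a))
  }
})

test_that("first and last agree for patients with a single pre-cutoff reading", {
  sim <- simulate_ehr(sim_config(n_patients = 1000, seed = 43))
  built <- build_cohort(sim$tables, cohort_spec())
  co <- built$cohort
  meas <- sim$tables$measurements
  f <- aggregate_features(co, meas, "first")
  l <- aggregate_features(co, meas, "last")
  cut <- co$t0[match(meas$id, co$id)]
  pre <- meas[!is.na(cut) & meas$time < cut & meas$variable == "lactate", ]
  singles <- names(which(table(pre$id) == 1))
  idx <- co$id %in% as.integer(singles)
  expect_gt(sum(idx), 0)
  expect_identical(f$lactate_first[idx], l$lactate_last[idx])
  ## strategy changes the columns, never the row set
  expect_identical(f$id, l$id)
  expect_identical(f$id, aggregate_features(co, meas, "mean")$id)
})

test_that("median imputation and one-hot encoding follow the application rules", {
  co <- toy_cohort(ids = 1:3, t0 = 24)
  fm <- data.frame(id = 1:3, sofa_last = c(1, NA, 3),
                   sex = c("female", "male", "male"))
  attr(fm, "roles") <- data.frame(feature = c("sofa_last", "sex"),
                                  role = "confounder",
                                  group = c("biology", "sociodemographic"))
  class(fm) <- c("feature_matrix", "data.frame")
  enc <- impute_encode(fm)
  expect_identical(enc$sofa_last, c(1, 2, 3))        # median of {1, 3}
  expect_identical(attr(enc, "imputation_medians")[["sofa_last"]], 2)
  ## one indicator column, reference level dropped
  expect_identical(enc$sex_male, c(0L, 1L, 1L))
  expect_false("sex_female" %in% names(enc))

  fm$sofa_last <- NA_real_
  expect_error(impute_encode(fm), "sofa_last")
})

test_that("imputed medians match an independent percentile computation", {
  sim <- simulate_ehr(sim_config(n_patients = 1500, seed = 47))
  built <- build_cohort(sim$tables, cohort_spec())
  raw <- aggregate_features(built$cohort, sim$tables$measurements,
                            "last", interventions = sim$tables$interventions)
  expect_gt(sum(is.na(raw$lactate_last)), 0)   # missingness is being exercised
  enc <- impute_encode(raw)
  expect_false(anyNA(as.data.frame(enc)))
  med <- attr(enc, "imputation_medians")[["lactate_last"]]
  expect_equal(med, quartile_oracle(raw$lactate_last[!is.na(raw$lactate_last)], 0.5))
  ## one-hot groups sum to at most one per patient
  expect_true(all(enc$race_white + enc$race_other <= 1))
})

test_that("confounder subsets follow their role-group definitions", {
  sim <- simulate_ehr(sim_config(n_patients = 600, seed = 53))
  parts <- sim_features(sim)
  full <- parts$fm
  nd <- select_confounders(full, "no_drugs")
  expect_false(any(c("vasopressor", "ventilation", "glycopeptide",
                     "beta_lactam") %in% names(nd)))
  nb <- select_confounders(full, "no_biology")
  expect_false(any(grepl("^(sofa|lactate|weight)", names(nb))))
  sd_only <- select_confounders(full, "sociodemographic_only")
  expect_setequal(setdiff(names(sd_only), "id"),
                  c("age", "sex_male", "race_other", "race_white", "emergency"))
  expect_error(select_confounders(full, "everything"), "arg")
})
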