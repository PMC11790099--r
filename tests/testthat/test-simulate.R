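test_that("generator is deterministic and matches its configured marginals", {
  cfg <- sim_config(n_patients = 18421, seed = 7)
  sim1 <- simulate_ehr(cfg)
  sim2 <- simulate_ehr(cfg)
  expect_identical(sim1$tables, sim2$tables)
  expect_identical(sim1$truth, sim2$truth)
  sim3 <- simulate_ehr(sim_config(n_patients = 18421, seed = 8))
  expect_false(identical(sim1$truth$e, sim3$truth$e))

  ## treated fraction calibrated to ~0.193 of the anchored population
  built <- build_cohort(sim1$tables, cohort_spec())
  frac <- mean(built$cohort$arm)
  expect_lt(abs(frac - 0.193), 0.012)
  ## 28-day mortality near its configured level
  expect_lt(abs(mean(sim1$truth$y0) - 0.25), 0.02)
  expect_true(all(sim1$truth$p0 > 0 & sim1$truth$p0 < 1))
  expect_true(all(sim1$truth$e > 0 & sim1$truth$e < 1))
  validate_event_tables(sim1$tables)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(n_patients = 0, seed = 1), "n_patients")
  expect_error(sim_config(100, 1, treated_fraction_target = 1.2),
               "treated_fraction_target")
  expect_error(sim_config(100, 1, baseline_mortality_28d = 0), "baseline_mortality_28d")
  expect_error(sim_config(100, 1, missing_rate = -0.1), "missing_rate")
  expect_error(sim_config(100, 1, modifier_effects = c(bogus = 0.1)),
               "modifier_effects")
  expect_error(sim_config(100, 1, treatment_delay_range_h = c(10, 5)),
               "treatment_delay_range_h")
  expect_error(sim_config(100, 1, true_ate_rd = 2), "true_ate_rd")
})

test_that("null-effect construction gives tau identically zero", {
  sim <- simulate_ehr(sim_config(n_patients = 10000, seed = 1))
  expect_identical(sim$truth$tau, rep(0, 10000))
  expect_identical(attr(sim$truth, "true_ate"), 0)
  ## potential outcomes coincide patient by patient under the null
  expect_identical(sim$truth$y0, sim$truth$y1)
})

test_that("realized outcomes are consistent with the assigned arm's potential outcome", {
  sim <- simulate_ehr(sim_config(
    n_patients = 5000, seed = 21, true_ate_rd = -0.02,
    modifier_effects = c(septic_shock = -0.05)))
  tr <- sim$truth
  expect_identical(tr$y, ifelse(tr$arm == 1L, tr$y1, tr$y0))
})

test_that("no patient whose latent death precedes the treatment draw is treated", {
  sim <- simulate_ehr(sim_config(n_patients = 8000, seed = 13,
                                 treatment_delay_range_h = c(0, 72)))
  tr <- sim$truth
  dead_before <- !is.na(tr$latent_death_h) & !is.na(tr$anchor_time_h) &
    tr$latent_death_h < tr$anchor_time_h + tr$delay_h
  expect_identical(sum(tr$arm[dead_before]), 0L)
})

test_that("severity is exchangeable between arms when the confounding knob is off", {
  sim <- simulate_ehr(sim_config(n_patients = 10000, seed = 5,
                                 confounding_strength = 0))
  adm <- sim$tables$measurements
  adm <- adm[adm$variable == "sofa" & adm$time == 0, ]
  arm <- sim$truth$arm[match(adm$id, sim$truth$id)]
  p_off <- stats::t.test(adm$value[arm == 1], adm$value[arm == 0])$p.value
  expect_gt(p_off, 0.001)

  sim2 <- simulate_ehr(sim_config(n_patients = 10000, seed = 5,
                                  confounding_strength = 0.6))
  adm2 <- sim2$tables$measurements
  adm2 <- adm2[adm2$variable == "sofa" & adm2$time == 0, ]
  arm2 <- sim2$truth$arm[match(adm2$id, sim2$truth$id)]
  p_on <- stats::t.test(adm2$value[arm2 == 1], adm2$value[arm2 == 0])$p.value
  expect_lt(p_on, 1e-10)
})

test_that("the naive observed contrast overstates the true effect under confounding", {
  sim <- simulate_ehr(sim_config(n_patients = 5000, seed = 3))
  tr <- sim$truth
  naive <- mean(tr$y[tr$arm == 1]) - mean(tr$y[tr$arm == 0])
  expect_gt(naive, mean(tr$tau))       # brute-force contrast vs mean(tau)
  expect_gt(naive, 0.03)               # severity confounding is material
})

test_that("true subgroup effects average tau over members", {
  sim <- simulate_ehr(sim_config(
    n_patients = 20000, seed = 11,
    modifier_effects = c(septic_shock = -0.05, age_ge_60 = -0.03)))
  te <- true_effects(sim)
  expect_identical(te$subgroup[1], "overall")
  shock <- te$true_ate[te$subgroup == "septic_shock=1"]
  noshock <- te$true_ate[te$subgroup == "septic_shock=0"]
  ## stratified means of tau reproduce the configured increment (up to
  ## clipping of extreme potential outcomes)
  expect_lt(abs((shock - noshock) - (-0.05)), 1.5 / sqrt(20000))
  age <- te$true_ate[te$subgroup == "age_ge_60=1"] -
    te$true_ate[te$subgroup == "age_ge_60=0"]
  expect_lt(abs(age - (-0.03)), 1.5 / sqrt(20000))

  ## null config: every subgroup ATE is exactly zero
  sim0 <- simulate_ehr(sim_config(n_patients = 2000, seed = 2))
  te0 <- true_effects(sim0)
  expect_identical(unique(te0$true_ate), 0)

  ## empty subgroup is flagged, not an error
  te_empty <- true_effects(sim0, subgroups = list(impossible = "age > 200"))
  row <- te_empty[te_empty$subgroup == "impossible=1", ]
  expect_true(row$empty)
  expect_true(is.na(row$true_ate))
})
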