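# Virtual cohort generator: determinism, statistical structure, round-trips.

test_that("zero between-subject CV reproduces the class means exactly", {
  spec <- cohort_spec(n_subjects = 4, pm_fraction = 0,
                      between_subject_cv = 0, seed = 3)
  cohort <- generate_cohort(spec)
  for (dog in cohort) {
    expect_equal(dog$metabolizer, "EM")
    expect_equal(dog$pk$clearance, 0.31)
    expect_equal(dog$pk$volume, 1.12)
    expect_equal(dog$pd$creeping_speed$c50, 239.4)
  }
})

test_that("same seed gives identical cohorts and observations", {
  spec <- cohort_spec(n_subjects = 6, seed = 77)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(cohort_truth_table(c1), cohort_truth_table(c2))
  o1 <- generate_concentration_data(c1, "oral_study1", 2)
  o2 <- generate_concentration_data(c2, "oral_study1", 2)
  expect_identical(o1, o2)
  e1 <- generate_effect_data(c1, "creeping_speed", 2)
  e2 <- generate_effect_data(c2, "creeping_speed", 2)
  expect_identical(e1, e2)
})

test_that("PM prevalence follows the binomial law", {
  spec <- cohort_spec(n_subjects = 1000, pm_fraction = 1 / 3, seed = 5)
  cohort <- generate_cohort(spec)
  n_pm <- sum(vapply(cohort, `[[`, "", "metabolizer") == "PM")
  # binomial 99% interval around 333
  expect_gte(n_pm, qbinom(0.005, 1000, 1 / 3))
  expect_lte(n_pm, qbinom(0.995, 1000, 1 / 3))
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(pm_fraction = 1.2), "pm_fraction")
  expect_error(cohort_spec(between_subject_cv = -5), "CV")
  spec <- cohort_spec(n_subjects = 2, seed = 1)
  cohort <- generate_cohort(spec)
  expect_error(generate_concentration_data(cohort, "nope", 2), "schedule")
  expect_error(generate_effect_data(cohort, "paw_circumference", 2),
               "no PD parameters")
})

test_that("noise-free oral generation equals the Bateman curve exactly", {
  spec <- cohort_spec(n_subjects = 3, pm_fraction = 0, residual_cv_conc = 0,
                      between_subject_cv = 0, seed = 2)
  cohort <- generate_cohort(spec)
  profs <- generate_concentration_data(cohort, "oral_study1", 2)
  pk <- oral_pk_parameters(1.12, 2, 0.31 / 1.12, 0.3)
  for (p in profs)
    expect_equal(p$concentrations, oral_concentration(pk, 2, p$times))
})

test_that("EM IV profiles at 48 h are below the LOQ and flagged", {
  spec <- cohort_spec(n_subjects = 5, pm_fraction = 0, seed = 8)
  cohort <- generate_cohort(spec)
  profs <- generate_concentration_data(cohort, "iv_study1", 2)
  for (p in profs) {
    i48 <- which(p$times == 48)
    expect_true(p$bql_flags[i48])
  }
  # closed-form check on the class means: (D/V) exp(-k10 * 48) << LOQ
  expect_lt(2000 / 1.12 * exp(-0.31 / 1.12 * 48), 10)
})

test_that("noise-free generated PK data round-trips through fit_oral_pk", {
  spec <- cohort_spec(n_subjects = 2, residual_cv_conc = 0, seed = 21)
  cohort <- generate_cohort(spec)
  profs <- generate_concentration_data(cohort, "oral_study1", 2)
  for (i in seq_along(cohort)) {
    fit <- fit_oral_pk(profs[[i]])
    expect_lt(abs(fit$params$k10 / cohort[[i]]$pk$k10 - 1), 1e-3)
    expect_lt(abs(fit$params$v_over_f / cohort[[i]]$pk$volume - 1), 1e-3)
    expect_lt(abs(fit$params$k01 / cohort[[i]]$pk$k01 - 1), 1e-3)
  }
})

test_that("zero-noise effect data sit at baseline without drug", {
  spec <- cohort_spec(n_subjects = 2, pm_fraction = 0,
                      residual_sd_effect = list(body_temperature = 0),
                      seed = 4)
  cohort <- generate_cohort(spec)
  # zero concentration input: constant inflamed baseline
  zero <- lapply(cohort, function(d) conc_constant(0))
  eff <- generate_effect_data(cohort, "body_temperature", 2,
                              conc_inputs = zero)
  for (i in seq_along(eff)) {
    r0 <- cohort[[i]]$pd$body_temperature$kin /
      cohort[[i]]$pd$body_temperature$kout
    expect_equal(eff[[i]]$values, rep(r0, length(eff[[i]]$times)),
                 tolerance = 1e-6)
    expect_equal(eff[[i]]$t_plus, r0)
  }
})

test_that("lameness scores are integers in [0, 5]", {
  spec <- cohort_spec(n_subjects = 6, seed = 10)
  cohort <- generate_cohort(spec)
  eff <- generate_effect_data(cohort, "lameness_score", 2)
  for (e in eff) {
    expect_true(all(e$values == round(e$values)))
    expect_true(all(e$values >= 0 & e$values <= 5))
  }
})

test_that("zero-noise generated effects round-trip through fit_turnover", {
  spec <- cohort_spec(n_subjects = 2, pm_fraction = 0, residual_cv_conc = 0,
                      residual_sd_effect = list(creeping_speed = 0),
                      seed = 31)
  cohort <- generate_cohort(spec)
  eff <- generate_effect_data(cohort, "creeping_speed", 2)
  for (i in seq_along(cohort)) {
    truth <- cohort[[i]]$pd$creeping_speed
    pk <- oral_pk_parameters(cohort[[i]]$pk$volume, cohort[[i]]$pk$k01,
                             cohort[[i]]$pk$k10, cohort[[i]]$pk$tlag)
    fit <- fit_turnover(eff[[i]], conc_oral(pk, 2))
    expect_lt(abs(fit$params$kin / truth$kin - 1), 0.01)
    expect_lt(abs(fit$params$kout / truth$kout - 1), 0.01)
    expect_lt(abs(fit$params$effect_cap / truth$effect_cap - 1), 0.01)
    expect_lt(abs(fit$params$c50 / truth$c50 - 1), 0.05)
  }
})

test_that("sparse study-2 generation supports breed ANOVA detection", {
  # four breeds at EM-like half-lives with a >= 1 h spread
  spec <- cohort_spec(n_subjects = 10, pm_fraction = 0, seed = 12)
  hls <- c(hound = 3.2, pointer = 3.9, spaniel = 2.7, mountain = 4.4)
  groups <- lapply(seq_along(hls), function(b) {
    sp <- cohort_spec(n_subjects = 10, pm_fraction = 0, seed = 12 + b,
                      pk_population_means = list(
                        EM = list(clearance = log(2) / hls[[b]] * 1.12)))
    cohort <- generate_cohort(sp)
    profs <- generate_concentration_data(cohort, "sparse_study2", 2)
    vapply(profs, function(p)
      as.numeric(terminal_halflife_sparse(p$times, p$concentrations)),
      numeric(1))
  })
  names(groups) <- names(hls)
  res <- breed_anova(groups)
  # the injected >= 1 h breed spread is detectable by the one-way ANOVA;
  # pairwise Tukey separation is weaker because k10 = CL/V compounds two
  # independent 25% CVs into ~36% half-life variability per breed
  expect_lt(res$p_value, 0.05)
  expect_true(all(res$summaries$cv > 0))
})
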