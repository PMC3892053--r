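# Turnover models: Hill function, ODE simulation, parameter estimation.

test_that("hill_fraction anchors and monotonicity", {
  expect_equal(hill_fraction(0, 0.71, 239.4, 4.74), 0)
  expect_equal(hill_fraction(239.4, 0.71, 239.4, 4.74), 0.71 / 2)
  # twice the potency concentration: strictly between half-cap and cap
  v <- hill_fraction(478.8, 0.71, 239.4, 4.74)
  expect_equal(v, 0.71 * 478.8^4.74 / (239.4^4.74 + 478.8^4.74))
  expect_gt(v, 0.5 * 0.71)
  expect_lt(v, 0.71)
  cc <- seq(0, 2000, by = 5)
  expect_true(all(diff(hill_fraction(cc, 0.71, 239.4, 4.74)) > 0))
  # saturates at the cap; stable for extreme Hill exponents
  expect_equal(hill_fraction(1e6, 0.71, 239.4, 4.74), 0.71, tolerance = 1e-6)
  expect_equal(hill_fraction(1e4, 1, 100, 10), 1, tolerance = 1e-10)
})

test_that("zero concentration holds the baseline steady state", {
  for (ep in modeled_endpoints) {
    p <- em_pd(ep)
    sim <- simulate_turnover(endpoint_model_kind(ep), p, conc_constant(0),
                             c(0, 5, 20, 48))
    expect_equal(sim$response, rep(p$kin / p$kout, 4), tolerance = 1e-6)
  }
})

test_that("saturating concentration reaches the closed-form steady state", {
  # antipyretic: baseline ~39.7 C dropping ~3.8% at full effect
  p <- em_pd("body_temperature")
  sim <- simulate_turnover("stimulate_kout", p, conc_constant(1e7),
                           c(0, 50, 200))
  expect_equal(p$kin / p$kout, 39.71, tolerance = 1e-3)
  expect_equal(sim$response[3], p$kin / (p$kout * (1 + p$effect_cap)),
               tolerance = 1e-6)
  expect_equal(1 - sim$response[3] / (p$kin / p$kout), 0.0385,
               tolerance = 0.01)
  # lameness baseline consistent with the maximal score of 5
  pl <- em_pd("lameness_score")
  expect_equal(round(pl$kin / pl$kout), 5)
  siml <- simulate_turnover("inhibit_kin", pl, conc_constant(1e7),
                            c(0, 50, 200))
  expect_lt(siml$response[3], 1e-3) # full inhibition drives the score to 0
})

test_that("piecewise-constant forcing matches the linear-ODE closed form", {
  p <- indirect_response_parameters(5, 1, 0.5, 100, 2)
  # concentration jumps 0 -> 300 at t = 2, back to 0 at t = 6
  pw <- conc_piecewise(c(0, 2, 6), c(0, 300, 0))
  h <- hill_fraction(300, 0.5, 100, 2)
  kout_on <- 1 - h # inhibit_kout loss rate while drug is on
  exact <- function(t) {
    if (t <= 2) return(5)
    r2 <- 5
    if (t <= 6) return(5 / kout_on + (r2 - 5 / kout_on) * exp(-kout_on * (t - 2)))
    r6 <- 5 / kout_on + (r2 - 5 / kout_on) * exp(-kout_on * 4)
    5 + (r6 - 5) * exp(-(t - 6))
  }
  tt <- c(0, 1, 2, 3, 5, 6, 7, 10, 20)
  sim <- simulate_turnover("inhibit_kout", p, pw, tt)
  expect_equal(sim$response, vapply(tt, exact, numeric(1)), tolerance = 1e-6)
})

test_that("response washes out to baseline and respects structural bounds", {
  pk <- em_pk()
  conc <- conc_oral(pk, 2)
  for (ep in modeled_endpoints) {
    p <- em_pd(ep)
    # 10 elimination half-lives past Cmax
    tmax <- pk$tlag + log(pk$k01 / pk$k10) / (pk$k01 - pk$k10)
    t_end <- tmax + 10 * log(2) / pk$k10
    tt <- seq(0, t_end, length.out = 200)
    sim <- simulate_turnover(endpoint_model_kind(ep), p, conc, tt)
    r0 <- p$kin / p$kout
    expect_lt(abs(sim$response[200] / r0 - 1), 1e-4)
    expect_true(all(sim$response >= -1e-12))
    if (endpoint_model_kind(ep) == "inhibit_kout")
      expect_true(all(sim$response <=
                        p$kin / (p$kout * (1 - p$effect_cap)) + 1e-9))
  }
})

test_that("effect magnitude is monotone non-decreasing in dose", {
  pk <- em_pk()
  tt <- seq(0, 24, by = 0.25)
  for (ep in modeled_endpoints) {
    p <- em_pd(ep)
    kind <- endpoint_model_kind(ep)
    r0 <- p$kin / p$kout
    peak <- vapply(c(0.5, 1, 2, 4, 8), function(d) {
      max(abs(simulate_turnover(kind, p, conc_oral(pk, d), tt)$response - r0))
    }, numeric(1))
    expect_true(all(diff(peak) >= -1e-8))
  }
})

test_that("fit_turnover round-trips noise-free data for all model kinds", {
  pk <- em_pk()
  conc <- conc_oral(pk, 2)
  for (ep in modeled_endpoints) {
    p <- em_pd(ep)
    sim <- simulate_turnover(endpoint_model_kind(ep), p, conc, pd_times())
    course <- effect_time_course("d1", ep, pd_times(), sim$response,
                                 t_minus = 0, t_plus = p$kin / p$kout)
    fit <- fit_turnover(course, conc)
    expect_lt(abs(fit$params$kin / p$kin - 1), 0.01)
    expect_lt(abs(fit$params$kout / p$kout - 1), 0.01)
    expect_lt(abs(fit$params$c50 / p$c50 - 1), 0.05)
    if (endpoint_model_kind(ep) == "inhibit_kin") {
      expect_identical(fit$params$effect_cap, 1) # structurally fixed
      expect_true(fit$diagnostics$cap_fixed)
    } else {
      expect_lt(abs(fit$params$effect_cap / p$effect_cap - 1), 0.01)
    }
  }
})

test_that("fit_turnover rejects mismatched endpoint/kind and short series", {
  pk <- em_pk()
  conc <- conc_oral(pk, 2)
  p <- em_pd("creeping_speed")
  sim <- simulate_turnover("inhibit_kout", p, conc, pd_times())
  course <- effect_time_course("d1", "creeping_speed", pd_times(),
                               sim$response, t_minus = 3.1,
                               t_plus = p$kin / p$kout)
  expect_error(fit_turnover(course, conc, kind = "stimulate_kout"),
               "does not match")
  short <- effect_time_course("d1", "creeping_speed", c(0, 2, 4),
                              sim$response[1:3], t_minus = 3.1,
                              t_plus = p$kin / p$kout)
  expect_error(fit_turnover(short, conc), ">= 6")
})

test_that("an arbitrary R concentration function drives the solver", {
  p <- indirect_response_parameters(5, 1, 0.5, 100, 2)
  fn <- conc_function(function(t) rep(300, length(t)))
  sim_fn <- simulate_turnover("inhibit_kout", p, fn, c(0, 1, 4))
  sim_ct <- simulate_turnover("inhibit_kout", p, conc_constant(300), c(0, 1, 4))
  expect_equal(sim_fn$response, sim_ct$response, tolerance = 1e-8)
})
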