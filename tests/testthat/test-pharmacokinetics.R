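# Oral model, weighted fitting, NCA and sparse half-life.

test_that("oral concentration obeys the closed-form anchors", {
  p <- em_pk()
  # onset boundary: zero at and before the lag time
  expect_equal(oral_concentration(p, 2, c(0, 0.25, p$tlag)), c(0, 0, 0))
  # peak location: tlag + ln(k01/k10)/(k01 - k10), flat derivative there
  tmax <- p$tlag + log(p$k01 / p$k10) / (p$k01 - p$k10)
  h <- 1e-5
  deriv <- diff(oral_concentration(p, 2, c(tmax - h, tmax + h))) / (2 * h)
  cmax <- oral_concentration(p, 2, tmax)
  expect_lt(abs(deriv) / cmax, 1e-4)
  # total exposure: integral equals D / (V/F * k10)
  tt <- seq(0, 400, by = 0.01)
  cc <- oral_concentration(p, 2, tt)
  auc <- sum(diff(tt) * (cc[-1] + cc[-length(cc)]) / 2)
  expect_equal(auc, 2000 / (1.12 * 0.277), tolerance = 0.01)
  # non-negative and unimodal
  grid <- oral_concentration(p, 2, seq(0, 48, by = 0.05))
  expect_true(all(grid >= 0))
  expect_equal(sum(diff(sign(diff(grid[grid > 0]))) != 0), 1)
})

test_that("degenerate k01 == k10 is rejected", {
  expect_error(oral_pk_parameters(1, 0.5, 0.5, 0), "degenerate")
})

test_that("fit_oral_pk recovers noise-free parameters within 0.1%", {
  p <- em_pk()
  fit <- fit_oral_pk(oral_profile_from(p))
  expect_true(fit$diagnostics$converged)
  expect_equal(fit$diagnostics$selected_n_exponentials, 2L)
  expect_lt(abs(fit$params$v_over_f / p$v_over_f - 1), 1e-3)
  expect_lt(abs(fit$params$k01 / p$k01 - 1), 1e-3)
  expect_lt(abs(fit$params$k10 / p$k10 - 1), 1e-3)
  expect_lt(abs(fit$params$tlag - p$tlag), 1e-3)
  # flip-flop convention enforced
  expect_gt(fit$params$k01, fit$params$k10)
  ci <- fit$diagnostics$parameter_cis
  expect_true(all(ci[, "lower"] <= ci[, "estimate"] &
                  ci[, "estimate"] <= ci[, "upper"]))
})

test_that("AIC prefers the biexponential for data simulated from it", {
  p <- em_pk()
  set.seed(7)
  times <- c(0.5, 1, 1.5, 2, 3, 4, 6, 9, 12, 15, 24, 30)
  conc <- oral_concentration(p, 2, times) * exp(rnorm(length(times), 0, 0.01))
  prof <- concentration_profile("d1", "oral", 2, times, conc,
                                bql_flags = rep(FALSE, length(times)))
  fit <- fit_oral_pk(prof, candidate_n_exponentials = c(2, 3))
  expect_equal(fit$diagnostics$selected_n_exponentials, 2L)
  expect_lt(fit$diagnostics$aic_by_model[["2"]],
            fit$diagnostics$aic_by_model[["3"]])
})

test_that("under-determined and wrong-route inputs are rejected", {
  p <- em_pk()
  short <- concentration_profile("d1", "oral", 2, c(1, 2, 4),
                                 oral_concentration(p, 2, c(1, 2, 4)),
                                 bql_flags = rep(FALSE, 3))
  expect_error(fit_oral_pk(short), ">= 6")
  ivp <- concentration_profile("d1", "iv", 2, c(1, 2, 4), c(900, 700, 400),
                               bql_flags = rep(FALSE, 3))
  expect_error(fit_oral_pk(ivp), "oral route")
})

test_that("BQL observations are excluded from the fit", {
  p <- em_pk()
  times <- c(0.5, 1, 1.5, 4, 6, 9, 15, 30, 48)
  conc <- oral_concentration(p, 2, times)
  conc[8:9] <- c(5000, 7000) # corrupt the BQL-flagged tail wildly
  prof <- concentration_profile("d1", "oral", 2, times, conc,
                                bql_flags = c(rep(FALSE, 7), TRUE, TRUE))
  fit <- fit_oral_pk(prof)
  # 7 uncorrupted points minus the pre-absorption zero at t = 0.5
  expect_equal(fit$diagnostics$n_used, 6L)
  expect_lt(abs(fit$params$k10 / p$k10 - 1), 0.01)
})

test_that("nca_iv matches the monoexponential closed form within 1%", {
  lam <- 0.25; c0 <- 1800
  times <- seq(0.05, 48, by = 0.05)
  prof <- concentration_profile("d1", "iv", 2, times, c0 * exp(-lam * times),
                                bql_flags = rep(FALSE, length(times)))
  res <- nca_iv(prof)
  expect_equal(res$auc_0_inf, c0 / lam, tolerance = 0.01)
  expect_equal(res$half_life, log(2) / lam, tolerance = 0.01)
  expect_equal(res$clearance, 2000 / (c0 / lam), tolerance = 0.01)
  expect_equal(res$v_z, res$clearance / res$lambda_z)
  expect_false(res$high_extrapolation)
})

test_that("nca_iv is homogeneous in concentration scale", {
  lam <- 0.25; c0 <- 1800
  times <- seq(0.05, 48, by = 0.5)
  p1 <- concentration_profile("d1", "iv", 2, times, c0 * exp(-lam * times),
                              bql_flags = rep(FALSE, length(times)))
  p2 <- concentration_profile("d1", "iv", 2, times, 2 * c0 * exp(-lam * times),
                              bql_flags = rep(FALSE, length(times)))
  r1 <- nca_iv(p1); r2 <- nca_iv(p2)
  expect_equal(r2$auc_0_inf, 2 * r1$auc_0_inf, tolerance = 1e-8)
  expect_equal(r2$clearance, r1$clearance / 2, tolerance = 1e-8)
  expect_equal(r2$half_life, r1$half_life, tolerance = 1e-8)
})

test_that("nca_iv lambda_z matches the slow eigen-rate of a 2-compartment decay", {
  # macro constants of a two-compartment bolus: alpha/beta from k10, k12, k21
  k10 <- 0.8; k12 <- 0.5; k21 <- 0.3
  s <- k10 + k12 + k21
  beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  a <- (alpha - k21) / (alpha - beta); b <- (k21 - beta) / (alpha - beta)
  times <- seq(0.1, 30, by = 0.1)
  conc <- 1500 * (a * exp(-alpha * times) + b * exp(-beta * times))
  prof <- concentration_profile("d1", "iv", 2, times, conc,
                                bql_flags = rep(FALSE, length(times)))
  res <- nca_iv(prof)
  expect_equal(res$lambda_z, beta, tolerance = 0.02)
})

test_that("nca_iv flags a non-decaying terminal phase", {
  times <- 1:6
  prof <- concentration_profile("d1", "iv", 2, times, c(100, 90, 85, 88, 95, 120),
                                bql_flags = rep(FALSE, 6))
  expect_error(nca_iv(prof), "decay")
})

test_that("terminal_halflife_sparse matches the exact log-linear slope", {
  tt <- c(6, 8, 10, 24)
  hl <- terminal_halflife_sparse(tt, 100 * exp(-0.2 * tt))
  expect_equal(as.numeric(hl), log(2) / 0.2, tolerance = 1e-10)
  # agrees with nca_iv half-life on the same monoexponential input
  times <- seq(0.1, 30, by = 0.1)
  prof <- concentration_profile("d1", "iv", 2, times, 800 * exp(-0.2 * times),
                                bql_flags = rep(FALSE, length(times)))
  expect_equal(as.numeric(terminal_halflife_sparse(times, 800 * exp(-0.2 * times))),
               nca_iv(prof)$half_life, tolerance = 1e-6)
})

test_that("terminal_halflife_sparse is unbiased under 5% proportional noise", {
  set.seed(11)
  tt <- c(6, 8, 10, 24)
  est <- replicate(500, {
    conc <- 100 * exp(-0.2 * tt) * exp(rnorm(4, 0, 0.05))
    as.numeric(terminal_halflife_sparse(tt, conc))
  })
  expect_lt(abs(median(est) / (log(2) / 0.2) - 1), 0.03)
})

test_that("terminal_halflife_sparse rejects rising or unusable input", {
  expect_error(terminal_halflife_sparse(c(6, 8, 10), c(10, 20, 40)), "declining")
  expect_warning(
    expect_error(terminal_halflife_sparse(c(6, 8, 10), c(50, 0, -1)),
                 "fewer than 2"),
    "non-positive")
})
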