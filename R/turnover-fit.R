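# Per-subject estimation of turnover model parameters (sequential PK/PD:
# the concentration input is the subject's fitted PK curve, not raw data).

# Levenberg-Marquardt polish on the residual vector: Gauss-Newton steps
# handle the nearly flat c50-n ridge far better than quasi-Newton on the
# summed objective. Box constraints kept by projection.
.lm_polish <- function(theta, resid_fn, lower, upper, max_iter = 200) {
  r <- resid_fn(theta)
  if (is.null(r)) return(list(par = theta, value = Inf))
  ssr <- sum(r^2)
  lambda <- 1e-3
  p <- length(theta)
  for (iter in seq_len(max_iter)) {
    jac <- matrix(0, length(r), p)
    ok <- TRUE
    for (j in seq_len(p)) {
      h <- max(1e-7, abs(theta[j]) * 1e-7)
      thp <- theta; thp[j] <- min(thp[j] + h, upper[j])
      thm <- theta; thm[j] <- max(thm[j] - h, lower[j])
      rp <- resid_fn(thp); rm <- resid_fn(thm)
      if (is.null(rp) || is.null(rm)) { ok <- FALSE; break }
      jac[, j] <- (rp - rm) / (thp[j] - thm[j])
    }
    if (!ok) break
    g <- crossprod(jac, r)
    a <- crossprod(jac)
    improved <- FALSE
    for (k in 1:25) {
      step <- tryCatch(solve(a + lambda * diag(diag(a) + 1e-12), g),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- pmin(pmax(theta - as.numeric(step), lower), upper)
      rc <- resid_fn(cand)
      if (!is.null(rc) && sum(rc^2) < ssr) {
        theta <- cand; r <- rc
        ssr_new <- sum(rc^2)
        converged_rel <- (ssr - ssr_new) < 1e-14 * (ssr + 1e-300)
        ssr <- ssr_new
        lambda <- max(lambda / 10, 1e-12)
        improved <- TRUE
        if (converged_rel) return(list(par = theta, value = ssr))
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) break
  }
  list(par = theta, value = ssr)
}

# fast prediction path used inside the optimizer: calls the C++ solver
# directly, bypassing constructor validation
.fit_turnover_pred <- function(kind, natural, conc, times, rtol) {
  t_sim <- if (times[1] > 0) c(0, times) else times
  r0 <- natural[["kin"]] / natural[["kout"]]
  resp <- .simulate_turnover_cpp(.kind_codes[[kind]], natural[["kin"]],
                                 natural[["kout"]], natural[["effect_cap"]],
                                 natural[["c50"]], natural[["n"]],
                                 unclass(conc), t_sim, r0, rtol, 1e-10)
  if (times[1] > 0) resp[-1] else resp
}

#' Fit a turnover model to one subject's effect time course
#'
#' Estimates Kin, Kout, the effect cap (Emax or Imax), EC50/IC50 and the
#' Hill coefficient by unweighted least squares on the raw endpoint scale,
#' with the response simulated from the inflamed steady state
#' `R(0) = kin/kout` at treatment time. For the lameness (`inhibit_kin`)
#' variant the drug-effect cap is structurally fixed at 1 and not
#' estimated. Bounds: Hill `n` in (0, 10], `Imax` in (0, 1], all rates
#' positive. Several deterministic starting points are tried and the best
#' optimum kept.
#'
#' @param course An [effect_time_course] for one of the four modeled
#'   endpoints.
#' @param conc_fn Concentration input (see [conc_input]); typically
#'   `conc_oral(fit$params, dose)` from the same subject's PK fit.
#' @param kind Model variant; defaults to the endpoint's canonical mapping
#'   ([endpoint_model_kind]) and must agree with it.
#' @param rtol ODE solver relative tolerance used during fitting.
#' @return An object of class `turnover_fit`: `params`
#'   ([indirect_response_parameters]), `diagnostics` (RSS, convergence,
#'   Wald confidence intervals, residuals, baseline `r0 = kin/kout`).
#' @export
fit_turnover <- function(course, conc_fn, kind = endpoint_model_kind(course$endpoint),
                         rtol = 1e-8) {
  stopifnot(inherits(course, "effect_time_course"))
  if (!course$endpoint %in% c("body_temperature", "creeping_speed",
                              "vertical_force", "lameness_score"))
    stop("fit_turnover: endpoint ", course$endpoint, " is not modeled")
  if (kind != endpoint_model_kind(course$endpoint))
    stop("fit_turnover: kind '", kind, "' does not match endpoint '",
         course$endpoint, "'")
  times <- course$times
  y <- course$values
  if (length(y) < 6) stop("fit_turnover: need >= 6 observations")
  conc <- .as_conc_input(conc_fn)

  cobs <- eval_conc(conc, times)
  c50_0 <- max(median(cobs[cobs > 0]), 1e-3)
  r0_0 <- if (is.finite(course$t_plus) && course$t_plus > 0) course$t_plus else y[1]
  kout_0 <- 1
  fixed_cap <- kind == "inhibit_kin"

  # crude cap guess from the most extreme observed excursion off baseline
  cap_0 <- switch(kind,
    stimulate_kout = max(r0_0 / max(min(y), 1e-8) - 1, 0.02),
    inhibit_kout = min(max(1 - r0_0 / max(y), 0.05), 0.99),
    inhibit_kin = 1)

  # theta layout: log kin, log kout, [cap transform], log c50, log n
  make_theta <- function(kin, kout, cap, c50, n) {
    th <- c(log(kin), log(kout))
    if (!fixed_cap)
      th <- c(th, if (kind == "stimulate_kout") log(cap) else cap)
    c(th, log(c50), log(n))
  }
  natural_of <- function(th) {
    i <- 3L
    cap <- if (fixed_cap) 1 else {
      v <- if (kind == "stimulate_kout") exp(th[3]) else th[3]
      i <- 4L; v
    }
    c(kin = exp(th[1]), kout = exp(th[2]), effect_cap = cap,
      c50 = exp(th[i]), n = exp(th[i + 1L]))
  }
  npar <- if (fixed_cap) 4L else 5L
  lower <- c(rep(-20, 2), if (!fixed_cap) {
    if (kind == "stimulate_kout") -10 else 1e-3
  }, -10, log(0.05))
  upper <- c(rep(20, 2), if (!fixed_cap) {
    if (kind == "stimulate_kout") 10 else 1
  }, 20, log(10))

  obj <- function(th) {
    nat <- natural_of(th)
    yhat <- tryCatch(.fit_turnover_pred(kind, nat, conc, times, rtol),
                     error = function(e) NULL)
    if (is.null(yhat) || any(!is.finite(yhat))) return(1e300)
    sum((y - yhat)^2)
  }

  starts <- list(
    make_theta(r0_0 * kout_0, kout_0, cap_0, c50_0, 2),
    make_theta(r0_0 * kout_0, kout_0, cap_0, c50_0, 5),
    make_theta(r0_0 * 4, 4, cap_0, c50_0 * 2, 3))
  # Levenberg-Marquardt from each start (Gauss-Newton steps cope with the
  # nearly flat c50-n ridge); quasi-Newton fallback if all LM runs fail
  resid_fn <- function(th) {
    nat <- natural_of(th)
    yhat <- tryCatch(.fit_turnover_pred(kind, nat, conc, times, rtol),
                     error = function(e) NULL)
    if (is.null(yhat) || any(!is.finite(yhat))) return(NULL)
    y - yhat
  }
  best <- NULL
  for (th0 in starts) {
    lmf <- tryCatch(.lm_polish(th0, resid_fn, lower, upper),
                    error = function(e) NULL)
    if (!is.null(lmf) && is.finite(lmf$value) &&
        (is.null(best) || lmf$value < best$value))
      best <- list(par = lmf$par, value = lmf$value, convergence = 0L)
    if (!is.null(best) && best$value < 1e-16 * sum(y^2)) break
  }
  if (is.null(best) || !is.finite(best$value)) {
    op <- tryCatch(
      optim(starts[[1]], obj, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 400, factr = 1e2)),
      error = function(e) NULL)
    if (is.null(op)) stop("fit_turnover: all optimizations failed")
    best <- op
  }

  # profile refinement over the Hill coefficient: the c50-n ridge makes the
  # joint problem ill-conditioned, so a coarse profile over fixed n
  # globalizes the search before a final free-n pass
  np <- length(best$par)
  red_lower <- lower[-np]; red_upper <- upper[-np]
  for (nfix in 1:10) {
    resid_red <- function(th) resid_fn(c(th, log(nfix)))
    lmr <- tryCatch(.lm_polish(best$par[-np], resid_red, red_lower,
                               red_upper, max_iter = 60),
                    error = function(e) NULL)
    if (!is.null(lmr) && is.finite(lmr$value) && lmr$value < best$value)
      best <- list(par = c(lmr$par, log(nfix)), value = lmr$value,
                   convergence = 0L)
  }
  lmf <- tryCatch(.lm_polish(best$par, resid_fn, lower, upper),
                  error = function(e) NULL)
  if (!is.null(lmf) && is.finite(lmf$value) && lmf$value < best$value)
    best <- list(par = lmf$par, value = lmf$value, convergence = 0L)
  # one quasi-Newton pass from the LM optimum guards against LM stalling
  op <- tryCatch(
    optim(best$par, obj, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 200, factr = 1e2)),
    error = function(e) NULL)
  if (!is.null(op) && op$value < best$value) best <- op

  nat <- natural_of(best$par)
  params <- indirect_response_parameters(nat[["kin"]], nat[["kout"]],
                                         min(nat[["effect_cap"]],
                                             if (kind == "stimulate_kout") Inf else 1),
                                         nat[["c50"]], min(nat[["n"]], 10))
  pred_theta <- function(th, tt) .fit_turnover_pred(kind, natural_of(th), conc, tt, rtol)
  cis <- tryCatch(
    .wald_cis(best$par, pred_theta, natural_of, times, y,
              rep(1, length(y))),
    error = function(e) NULL)
  if (fixed_cap && !is.null(cis)) {
    # report the fixed cap row explicitly for table assembly
    cis <- rbind(cis[1:2, , drop = FALSE],
                 effect_cap = c(1, 1, 1),
                 cis[3:4, , drop = FALSE])
  }
  yhat <- pred_theta(best$par, times)
  structure(list(
    params = params,
    kind = kind,
    endpoint = course$endpoint,
    diagnostics = list(
      rss = best$value,
      converged = best$convergence == 0,
      parameter_cis = cis,
      cap_fixed = fixed_cap,
      r0 = nat[["kin"]] / nat[["kout"]],
      residuals = data.frame(time = times, observed = y, fitted = yhat,
                             residual = y - yhat))),
    class = "turnover_fit")
}

#' @export
print.turnover_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("Turnover fit (%s, %s)%s\n", x$endpoint, x$kind,
              if (x$diagnostics$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  Kin = %.4g, Kout = %.4g (baseline R0 = %.4g)\n",
              p$kin, p$kout, p$kin / p$kout))
  cat(sprintf("  cap = %s, C50 = %.4g ug/L, n = %.3g\n",
              if (x$diagnostics$cap_fixed) "1 (fixed)" else sprintf("%.3g", p$effect_cap),
              p$c50, p$n))
  invisible(x)
}
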