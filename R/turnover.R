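# Indirect-response (turnover) models. Baseline response is maintained by a
# zero-order production rate Kin and first-order loss rate Kout
# (dR/dt = Kin - Kout * R); drug concentration perturbs one of the two via a
# sigmoid Hill function. Three variants are used, one per endpoint class:
#   stimulate_kout : dR/dt = Kin - Kout * (1 + Emax * H(C)) * R  (antipyresis)
#   inhibit_kout   : dR/dt = Kin - Kout * (1 - Imax * H(C)) * R  (locomotion)
#   inhibit_kin    : dR/dt = Kin * (1 - H(C)) - Kout * R         (lameness,
#                    drug term saturates at full inhibition, cap fixed at 1)
# with H(C) = C^n / (C50^n + C^n).

.kinds <- c("stimulate_kout", "inhibit_kout", "inhibit_kin")
.kind_codes <- c(stimulate_kout = 1L, inhibit_kout = 2L, inhibit_kin = 3L)

#' Map a pharmacodynamic endpoint to its turnover model variant
#'
#' Body temperature is modeled by stimulation of thermolysis (Kout);
#' creeping speed and vertical ground-reaction force by inhibition of the
#' pain-related braking/withdrawal rate (Kout); the clinical lameness score
#' by inhibition of the lameness production rate (Kin).
#'
#' @param endpoint One of the four modeled endpoints.
#' @return One of `"stimulate_kout"`, `"inhibit_kout"`, `"inhibit_kin"`.
#' @export
endpoint_model_kind <- function(endpoint) {
  switch(match.arg(endpoint, c("body_temperature", "creeping_speed",
                               "vertical_force", "lameness_score")),
         body_temperature = "stimulate_kout",
         creeping_speed = "inhibit_kout",
         vertical_force = "inhibit_kout",
         lameness_score = "inhibit_kin")
}

#' Turnover model parameter set
#'
#' @param kin Zero-order production rate (response units per h), > 0.
#' @param kout First-order loss rate (1/h), > 0. Baseline response is
#'   `kin / kout`.
#' @param effect_cap Maximum fractional drug effect: `Emax` (> 0) for
#'   stimulation models, `Imax` in (0, 1] for inhibition models. For the
#'   `inhibit_kin` variant the drug term has no free cap (fixed at 1).
#' @param c50 Concentration of half-maximal effect, EC50 or IC50 (ug/L,
#'   numerically identical to ng/mL), > 0.
#' @param n Hill coefficient (steepness), in (0, 10].
#' @return An object of class `indirect_response_parameters`.
#' @export
indirect_response_parameters <- function(kin, kout, effect_cap, c50, n) {
  if (!(kin > 0 && kout > 0 && c50 > 0))
    stop("indirect_response_parameters: kin, kout, c50 must be > 0")
  if (!(n > 0 && n <= 10))
    stop("indirect_response_parameters: Hill n must be in (0, 10]")
  if (!(effect_cap > 0))
    stop("indirect_response_parameters: effect_cap must be > 0")
  structure(list(kin = kin, kout = kout, effect_cap = effect_cap,
                 c50 = c50, n = n),
            class = "indirect_response_parameters")
}

#' Sigmoid Hill effect fraction
#'
#' `effect_cap * c^n / (c50^n + c^n)`: the fractional modulation of Kin or
#' Kout produced by concentration `c`. Strictly increasing in `c`,
#' approaching `effect_cap` as `c` grows; equals `effect_cap / 2` at
#' `c = c50`. Computed on the log scale so large Hill coefficients stay
#' numerically stable.
#'
#' @param c Concentration (ug/L), >= 0; vectorized.
#' @param effect_cap Maximum effect (Emax or Imax).
#' @param c50 Half-maximal concentration (ug/L).
#' @param n Hill coefficient.
#' @return Numeric vector in `[0, effect_cap]`.
#' @export
hill_fraction <- function(c, effect_cap, c50, n) {
  stopifnot(all(c >= 0), c50 > 0, n > 0)
  z <- n * (log(pmax(c, .Machine$double.xmin)) - log(c50))
  frac <- ifelse(c <= 0, 0, stats::plogis(z))
  effect_cap * frac
}

#' Concentration forcing functions for turnover simulation
#'
#' Constructors for the concentration input driving [simulate_turnover]:
#' a Bateman oral curve from fitted PK parameters (`conc_oral`), a constant
#' level (`conc_constant`), a left-continuous piecewise-constant profile
#' (`conc_piecewise`), or an arbitrary R function of time returning ug/L
#' (`conc_function`; slower, evaluated from inside the solver).
#'
#' @param params An [oral_pk_parameters] object.
#' @param dose Dose (mg/kg).
#' @param value Constant concentration (ug/L).
#' @param times Breakpoints (h), increasing; concentration is 0 before the
#'   first breakpoint.
#' @param values Concentration on each interval `[times[i], times[i+1])`
#'   (ug/L); the last value extends to infinity.
#' @param fun Function of a numeric time vector returning concentrations.
#' @return An object of class `conc_input`.
#' @name conc_input
NULL

#' @rdname conc_input
#' @export
conc_oral <- function(params, dose) {
  stopifnot(inherits(params, "oral_pk_parameters"), dose > 0)
  structure(list(type = "bateman", dose_ug = dose * 1000,
                 v_over_f = params$v_over_f, k01 = params$k01,
                 k10 = params$k10, tlag = params$tlag),
            class = "conc_input")
}

#' @rdname conc_input
#' @export
conc_constant <- function(value) {
  stopifnot(value >= 0)
  structure(list(type = "constant", value = value), class = "conc_input")
}

#' @rdname conc_input
#' @export
conc_piecewise <- function(times, values) {
  stopifnot(length(times) == length(values), all(diff(times) > 0),
            all(values >= 0))
  structure(list(type = "piecewise", times = as.numeric(times),
                 values = as.numeric(values)), class = "conc_input")
}

#' @rdname conc_input
#' @export
conc_function <- function(fun) {
  stopifnot(is.function(fun))
  structure(list(type = "rfunction", fun = fun), class = "conc_input")
}

#' Evaluate a concentration input at given times
#' @param conc A `conc_input` object or plain R function of time.
#' @param times Times (h).
#' @return Concentrations (ug/L).
#' @export
eval_conc <- function(conc, times) {
  if (is.function(conc)) return(conc(times))
  stopifnot(inherits(conc, "conc_input"))
  switch(conc$type,
         constant = rep(conc$value, length(times)),
         bateman = {
           p <- oral_pk_parameters(conc$v_over_f, conc$k01, conc$k10, conc$tlag)
           oral_concentration(p, conc$dose_ug / 1000, times)
         },
         piecewise = {
           idx <- findInterval(times, conc$times)
           ifelse(idx == 0, 0, conc$values[pmax(idx, 1L)])
         },
         rfunction = conc$fun(times))
}

.as_conc_input <- function(conc_fn) {
  if (inherits(conc_fn, "conc_input")) return(conc_fn)
  if (is.function(conc_fn)) return(conc_function(conc_fn))
  stop("simulate_turnover: conc_fn must be a conc_input or a function of time")
}

#' Simulate a turnover response driven by a concentration curve
#'
#' Integrates the chosen indirect-response ODE from the unperturbed steady
#' state `R(0) = kin / kout` (the inflamed baseline at treatment time) with
#' an adaptive Runge-Kutta (Dormand-Prince 5(4)) solver. For the
#' `inhibit_kin` variant the drug term uses the bare Hill fraction (its cap
#' is structurally fixed at 1).
#'
#' @param kind Model variant; see [endpoint_model_kind].
#' @param params An [indirect_response_parameters] object.
#' @param conc_fn Concentration input: a `conc_input` (see [conc_input]) or
#'   a function of time.
#' @param times Output times (h), increasing; the first element is the
#'   initial time.
#' @param r0 Initial response; defaults to the steady state `kin / kout`.
#' @param rtol,atol Solver tolerances (defaults 1e-10 relative, 1e-12
#'   absolute).
#' @return List of class `simulated_response`: `times`, `response`,
#'   `concentration_input`.
#' @export
simulate_turnover <- function(kind, params, conc_fn, times, r0 = NULL,
                              rtol = 1e-10, atol = 1e-12) {
  kind <- match.arg(kind, .kinds)
  stopifnot(inherits(params, "indirect_response_parameters"))
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("simulate_turnover: times must be increasing")
  if (kind == "inhibit_kout" && params$effect_cap > 1)
    stop("simulate_turnover: Imax must be <= 1 for inhibit_kout")
  conc <- .as_conc_input(conc_fn)
  if (is.null(r0)) r0 <- params$kin / params$kout
  resp <- .simulate_turnover_cpp(.kind_codes[[kind]], params$kin, params$kout,
                                 params$effect_cap, params$c50, params$n,
                                 unclass(conc), times, r0, rtol, atol)
  structure(list(times = times, response = resp,
                 concentration_input = eval_conc(conc, times)),
            class = "simulated_response")
}
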