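#' Oral one-compartment (Bateman) PK parameter set
#'
#' Parameters of the one-compartment first-order absorption model with lag
#' time, the structural model used for all oral concentration curves. `F`
#' (oral bioavailability) is not separately identifiable from oral data, so
#' the apparent volume `V/F` is carried as a single parameter.
#'
#' @param v_over_f Apparent volume of distribution over bioavailability
#'   (L/kg), > 0.
#' @param k01 First-order absorption rate constant (1/h), > 0.
#' @param k10 First-order elimination rate constant (1/h), > 0. By
#'   convention `k01 > k10` (absorption faster than elimination): the
#'   Bateman form is symmetric under exchange of the two constants and the
#'   terminal phase is attributed to elimination.
#' @param tlag Absorption lag time (h), >= 0.
#' @return An object of class `oral_pk_parameters`.
#' @export
oral_pk_parameters <- function(v_over_f, k01, k10, tlag = 0) {
  stopifnot(is.numeric(v_over_f), is.numeric(k01), is.numeric(k10),
            is.numeric(tlag), length(v_over_f) == 1L, length(k01) == 1L,
            length(k10) == 1L, length(tlag) == 1L)
  if (!(v_over_f > 0 && k01 > 0 && k10 > 0 && tlag >= 0))
    stop("oral_pk_parameters: v_over_f, k01, k10 must be > 0 and tlag >= 0")
  if (k01 == k10)
    stop("oral_pk_parameters: k01 == k10 is degenerate (limiting form not supported)")
  structure(list(v_over_f = v_over_f, k01 = k01, k10 = k10, tlag = tlag),
            class = "oral_pk_parameters")
}

#' @export
print.oral_pk_parameters <- function(x, ...) {
  cat("Oral one-compartment PK parameters (Bateman with lag)\n")
  cat(sprintf("  V/F  = %.4g L/kg\n  k01  = %.4g 1/h\n  k10  = %.4g 1/h\n  tlag = %.4g h\n",
              x$v_over_f, x$k01, x$k10, x$tlag))
  cat(sprintf("  terminal half-life = %.3g h\n", log(2) / min(x$k01, x$k10)))
  invisible(x)
}

#' Subject-level concentration-time profile
#'
#' Container for one subject's dosing route, dose and observed plasma
#' concentrations, with below-quantification (BQL) flags. Concentrations are
#' in ug/L (identical to ng/mL); the assay limit of quantification defaults
#' to 10 ug/L (0.01 ug/mL).
#'
#' @param subject_id Subject identifier (character scalar).
#' @param route `"oral"` or `"iv"`.
#' @param dose Dose in mg/kg, > 0.
#' @param times Sampling times (h), strictly increasing, >= 0.
#' @param concentrations Observed concentrations (ug/L).
#' @param bql_flags Logical vector: observation below the limit of
#'   quantification. Defaults to `concentrations < loq & times > 0` with
#'   pre-dose zeros kept as exact zeros.
#' @param loq Limit of quantification (ug/L).
#' @return An object of class `concentration_profile`.
#' @export
concentration_profile <- function(subject_id, route, dose, times,
                                  concentrations, bql_flags = NULL,
                                  loq = 10) {
  route <- match.arg(route, c("oral", "iv"))
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations))
    stop("concentration_profile: times and concentrations differ in length")
  if (any(diff(times) <= 0) || any(times < 0))
    stop("concentration_profile: times must be strictly increasing and >= 0")
  if (!(dose > 0)) stop("concentration_profile: dose must be > 0")
  if (is.null(bql_flags)) bql_flags <- concentrations < loq & times > 0
  bql_flags <- as.logical(bql_flags)
  if (length(bql_flags) != length(times))
    stop("concentration_profile: bql_flags length mismatch")
  if (any(concentrations[!bql_flags] < 0, na.rm = TRUE))
    stop("concentration_profile: negative non-BQL concentration")
  structure(list(subject_id = as.character(subject_id), route = route,
                 dose = dose, times = times, concentrations = concentrations,
                 bql_flags = bql_flags, loq = loq),
            class = "concentration_profile")
}

#' Predicted oral plasma concentration (Bateman curve)
#'
#' Closed-form concentration of the one-compartment model with first-order
#' absorption and a lag time:
#' \deqn{C(t) = \frac{D\,k_{01}}{(V/F)(k_{01}-k_{10})}
#'   \left(e^{-k_{10}(t-t_{lag})} - e^{-k_{01}(t-t_{lag})}\right)}
#' for `t > tlag` and 0 before, with the dose `D` converted internally from
#' mg/kg to ug/kg so concentrations come out in ug/L.
#'
#' @param params An [oral_pk_parameters] object.
#' @param dose Dose (mg/kg).
#' @param times Times (h) at which to evaluate; any numeric vector.
#' @return Numeric vector of concentrations (ug/L), non-negative.
#' @export
oral_concentration <- function(params, dose, times) {
  stopifnot(inherits(params, "oral_pk_parameters"), dose > 0)
  dose_ug <- dose * 1000
  tau <- times - params$tlag
  a <- dose_ug * params$k01 / (params$v_over_f * (params$k01 - params$k10))
  conc <- ifelse(tau <= 0, 0,
                 a * (exp(-params$k10 * tau) - exp(-params$k01 * tau)))
  pmax(conc, 0)
}
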