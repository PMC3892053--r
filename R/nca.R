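# Non-compartmental analysis of IV profiles and sparse-sampling half-life.

# linear-up / log-down trapezoid over one interval
.trapz_linlog <- function(t1, t2, c1, c2) {
  dt <- t2 - t1
  if (c2 < c1 && c1 > 0 && c2 > 0) {
    (c1 - c2) / log(c1 / c2) * dt
  } else {
    (c1 + c2) / 2 * dt
  }
}

# terminal-phase selection: among the last n >= 3 points, choose the n
# maximizing adjusted R^2 of log C vs t; ties broken toward more points
.select_lambda_z <- function(times, conc) {
  n_all <- length(conc)
  best <- NULL
  for (k in 3:n_all) {
    idx <- seq(n_all - k + 1L, n_all)
    fit <- lm(log(conc[idx]) ~ times[idx])
    slope <- unname(coef(fit)[2])
    if (!is.finite(slope) || slope >= 0) next
    # adjusted R^2 by hand: summary.lm warns on near-perfect fits
    res <- fit$residuals
    tss <- sum((log(conc[idx]) - mean(log(conc[idx])))^2)
    r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
    r2adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    # ">=" so equal fits resolve toward more points (larger k comes later)
    if (is.null(best) || r2adj >= best$r2adj - 1e-12) {
      if (is.null(best) || r2adj > best$r2adj + 1e-12 || k > best$k)
        best <- list(k = k, lambda_z = -slope, r2adj = r2adj, idx = idx)
    }
  }
  best
}

#' Non-compartmental analysis of an intravenous profile
#'
#' Computes AUC to the last quantifiable observation by the linear-up /
#' log-down trapezoidal rule, extrapolates to infinity with
#' `Clast / lambda_z`, and derives terminal half-life, plasma clearance and
#' terminal volume of distribution. The terminal rate constant `lambda_z`
#' comes from a log-linear regression over the last `n >= 3` points that
#' maximize adjusted R-squared (ties toward more points).
#'
#' @param profile A [concentration_profile] with `route == "iv"`.
#' @return An object of class `nca_result` with fields `auc_0_inf`
#'   (h·ug/L), `auc_extrapolated_fraction`, `lambda_z` (1/h), `half_life`
#'   (h), `clearance` (L/h/kg), `v_z` (L/kg), `n_lambda_z_points`, and
#'   `high_extrapolation` flag (extrapolated fraction > 20%).
#' @export
nca_iv <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (profile$route != "iv") stop("nca_iv: iv route required")
  use <- !profile$bql_flags & profile$concentrations > 0
  times <- profile$times[use]
  conc <- profile$concentrations[use]
  if (length(conc) < 3) stop("nca_iv: need >= 3 positive observations")

  sel <- .select_lambda_z(times, conc)
  if (is.null(sel))
    stop("nca_iv: terminal phase does not decay (lambda_z <= 0)")

  n <- length(conc)
  auc_last <- sum(vapply(seq_len(n - 1), function(i) {
    .trapz_linlog(times[i], times[i + 1], conc[i], conc[i + 1])
  }, numeric(1)))
  # back-extrapolate from first observation to t = 0 assuming log-linear
  # decline at the initial slope (bolus input)
  if (times[1] > 0) {
    c0 <- if (n >= 2 && conc[2] < conc[1] && conc[2] > 0) {
      exp(log(conc[1]) + (log(conc[1]) - log(conc[2])) /
            (times[2] - times[1]) * times[1])
    } else conc[1]
    auc_last <- auc_last + .trapz_linlog(0, times[1], c0, conc[1])
  }
  auc_extra <- conc[n] / sel$lambda_z
  auc_inf <- auc_last + auc_extra
  frac <- auc_extra / auc_inf
  dose_ug <- profile$dose * 1000
  cl <- dose_ug / auc_inf
  res <- structure(list(
    auc_0_inf = auc_inf,
    auc_extrapolated_fraction = frac,
    lambda_z = sel$lambda_z,
    half_life = log(2) / sel$lambda_z,
    clearance = cl,
    v_z = cl / sel$lambda_z,
    n_lambda_z_points = sel$k,
    high_extrapolation = frac > 0.2), class = "nca_result")
  if (res$high_extrapolation)
    warning("nca_iv: extrapolated AUC fraction exceeds 20% (",
            round(100 * frac, 1), "%)")
  res
}

#' @export
print.nca_result <- function(x, ...) {
  cat("Non-compartmental analysis (IV)\n")
  cat(sprintf("  AUC(0-inf)   = %.4g h.ug/L (%.1f%% extrapolated)\n",
              x$auc_0_inf, 100 * x$auc_extrapolated_fraction))
  cat(sprintf("  lambda_z     = %.4g 1/h (%d points)\n",
              x$lambda_z, x$n_lambda_z_points))
  cat(sprintf("  half-life    = %.4g h\n", x$half_life))
  cat(sprintf("  CL           = %.4g L/h/kg\n", x$clearance))
  cat(sprintf("  Vz           = %.4g L/kg\n", x$v_z))
  invisible(x)
}

#' Terminal half-life from sparse sampling by log-linear regression
#'
#' Estimates the elimination half-life from a handful of post-peak samples
#' (the field-study design uses 6, 8, 10 and 24 h after an oral dose) as
#' `log(2) / (-slope)` of the regression of `log(C)` on time.
#'
#' @param times Sampling times (h).
#' @param concentrations Concentrations (ug/L).
#' @return Half-life (h), with attributes `slope` and `n_used`.
#' @export
terminal_halflife_sparse <- function(times, concentrations) {
  stopifnot(length(times) == length(concentrations))
  ord <- order(times)
  times <- times[ord]; concentrations <- concentrations[ord]
  peak <- which.max(concentrations)
  idx <- seq(peak, length(times))
  pos <- concentrations[idx] > 0
  if (any(!pos)) {
    warning("terminal_halflife_sparse: excluding ", sum(!pos),
            " non-positive concentration(s)")
    idx <- idx[pos]
  }
  if (length(idx) < 2)
    stop("terminal_halflife_sparse: fewer than 2 usable declining-phase points")
  fit <- lm(log(concentrations[idx]) ~ times[idx])
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("terminal_halflife_sparse: no terminal decay (slope >= 0)")
  structure(log(2) / (-slope), slope = slope, n_used = length(idx))
}
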