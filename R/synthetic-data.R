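# Virtual cohort generator emulating the two-study canine design:
# study 1 - 12 beagles, 2x2 crossover, oral + IV 2 mg/kg, bimodal EM/PM
# clearance; study 2 - 4 breeds x 10 dogs, oral 2 mg/kg, sparse sampling.

.pd_defaults <- list(
  EM = list(
    body_temperature = list(kin = 41.30, kout = 1.04, effect_cap = 0.04,
                            c50 = 193.2, n = 5.09),
    creeping_speed = list(kin = 0.90, kout = 0.95, effect_cap = 0.71,
                          c50 = 239.4, n = 4.74),
    lameness_score = list(kin = 5.34, kout = 1.08, effect_cap = 1,
                          c50 = 284.3, n = 4.25),
    vertical_force = list(kin = 0.09, kout = 7.40, effect_cap = 0.98,
                          c50 = 160.8, n = 6.13)),
  PM = list(
    body_temperature = list(kin = 45.84, kout = 1.17, effect_cap = 0.04,
                            c50 = 473.4, n = 6.99),
    creeping_speed = list(kin = 0.76, kout = 1.07, effect_cap = 0.70,
                          c50 = 344.5, n = 3.68),
    lameness_score = list(kin = 2.57, kout = 0.509, effect_cap = 1,
                          c50 = 785.8, n = 2.70),
    vertical_force = list(kin = 0.09, kout = 8.47, effect_cap = 0.97,
                          c50 = 325.1, n = 5.67)))

.pk_defaults <- list(
  EM = list(clearance = 0.31, volume = 1.12, k01 = 2.0, tlag = 0.3),
  PM = list(clearance = 0.11, volume = 0.89, k01 = 2.0, tlag = 0.3))

.schedules <- list(
  oral_study1 = c(0, 0.5, 1, 1.5, 4, 6, 9, 15, 30, 48),
  iv_study1 = c(2 / 60, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 9, 12, 24, 30, 48),
  sparse_study2 = c(6, 8, 10, 24),
  pd_study1 = c(0, 2, 4, 9, 15, 22, 27))

#' Specification of a virtual cohort
#'
#' Bundles the design constants of a simulated study: cohort size,
#' poor-metabolizer prevalence, population mean PK and PD parameters per
#' metabolizer class, between-subject and residual variability, assay
#' limit of quantification, sampling schedules and a seed.
#'
#' Defaults emulate the beagle crossover study: EM clearance 0.31 L/h/kg
#' with volume 1.12 L/kg, PM clearance 0.11 L/h/kg with volume 0.89 L/kg
#' (about 3-fold lower clearance), PM prevalence 1/3, between-subject CV
#' 25%, proportional residual concentration CV 10%, additive effect noise
#' at instrument precision per endpoint (0.1 C temperature, 0.02 m/s speed,
#' 0.002 normalized force, 0.2 score), and LOQ 10 ug/L.
#'
#' @param n_subjects Number of dogs (default 12).
#' @param pm_fraction Probability a dog is a poor metabolizer (default 1/3).
#' @param pk_population_means,pd_population_means Per-class parameter
#'   means; partial lists are merged over the defaults.
#' @param between_subject_cv Between-subject log-normal CV in percent
#'   (default 25).
#' @param residual_cv_conc Proportional residual concentration CV in
#'   percent (default 10).
#' @param residual_sd_effect Named list of additive effect-noise SDs in
#'   endpoint units; entries override the per-endpoint defaults.
#' @param loq Assay limit of quantification (ug/L, default 10).
#' @param seed Integer seed; identical specs generate identical cohorts.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12, pm_fraction = 1 / 3,
                        pk_population_means = list(),
                        pd_population_means = list(),
                        between_subject_cv = 25, residual_cv_conc = 10,
                        residual_sd_effect = list(), loq = 10, seed = 1) {
  if (pm_fraction < 0 || pm_fraction > 1)
    stop("cohort_spec: pm_fraction must be in [0, 1]")
  if (between_subject_cv < 0 || residual_cv_conc < 0)
    stop("cohort_spec: CVs must be >= 0")
  pk <- .pk_defaults
  for (cls in names(pk_population_means))
    pk[[cls]] <- modifyList(pk[[cls]], pk_population_means[[cls]])
  pd <- .pd_defaults
  for (cls in names(pd_population_means))
    for (ep in names(pd_population_means[[cls]]))
      pd[[cls]][[ep]] <- modifyList(pd[[cls]][[ep]],
                                    pd_population_means[[cls]][[ep]])
  # defaults reflect instrument precision: electronic thermometer ~0.1 C,
  # stopwatch-derived speed ~0.02 m/s, triplicate-mean force plate ~0.002 (normalized),
  # ordinal score ~0.2 before rounding
  sd_eff <- list(body_temperature = 0.1, creeping_speed = 0.02,
                 lameness_score = 0.2, vertical_force = 0.002)
  sd_eff[names(residual_sd_effect)] <- residual_sd_effect
  structure(list(n_subjects = as.integer(n_subjects),
                 pm_fraction = pm_fraction,
                 pk_population_means = pk, pd_population_means = pd,
                 between_subject_cv = between_subject_cv,
                 residual_cv_conc = residual_cv_conc,
                 residual_sd_effect = sd_eff, loq = loq,
                 schedules = .schedules, seed = as.integer(seed)),
            class = "cohort_spec")
}

# log-normal draw with given mean and CV (in %), median-preserving in the
# CV = 0 limit
.rlnorm_cv <- function(n, mean, cv_pct) {
  if (cv_pct == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + (cv_pct / 100)^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a virtual cohort of dogs
#'
#' Assigns each dog a metabolizer class (Bernoulli with `pm_fraction`) and
#' draws individual PK and PD parameters log-normally around the class
#' means with the between-subject CV. Derived elimination rate
#' `k10 = clearance / volume`. Imax draws are capped at 1 and Hill
#' coefficients at 10 to respect structural bounds.
#'
#' @param spec A [cohort_spec].
#' @return List of class `virtual_cohort`: one `virtual_dog` per subject
#'   (fields `subject_id`, `metabolizer`, `pk`, `pd`), with the spec
#'   attached as attribute `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cv <- spec$between_subject_cv
  dogs <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    cls <- if (rbinom(1, 1, spec$pm_fraction) == 1) "PM" else "EM"
    pkm <- spec$pk_population_means[[cls]]
    cl <- .rlnorm_cv(1, pkm$clearance, cv)
    v <- .rlnorm_cv(1, pkm$volume, cv)
    k01 <- .rlnorm_cv(1, pkm$k01, cv)
    tlag <- .rlnorm_cv(1, pkm$tlag, cv)
    pd <- lapply(spec$pd_population_means[[cls]], function(p) {
      cap <- if (p$effect_cap == 1) 1 else min(.rlnorm_cv(1, p$effect_cap, cv), 1)
      indirect_response_parameters(
        kin = .rlnorm_cv(1, p$kin, cv), kout = .rlnorm_cv(1, p$kout, cv),
        effect_cap = cap, c50 = .rlnorm_cv(1, p$c50, cv),
        n = min(.rlnorm_cv(1, p$n, cv), 10))
    })
    dogs[[i]] <- structure(list(
      subject_id = sprintf("dog%02d", i), metabolizer = cls,
      pk = list(clearance = cl, volume = v, k01 = k01, tlag = tlag,
                k10 = cl / v),
      pd = pd), class = "virtual_dog")
  }
  structure(dogs, class = "virtual_cohort", spec = spec)
}

#' True parameters of a virtual cohort as a tidy table
#' @param cohort A `virtual_cohort`.
#' @return data.frame with one row per subject x parameter.
#' @export
cohort_truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  do.call(rbind, lapply(cohort, function(d) {
    pk <- data.frame(subject_id = d$subject_id, metabolizer = d$metabolizer,
                     endpoint = NA_character_,
                     parameter = names(d$pk),
                     value = unlist(d$pk), stringsAsFactors = FALSE)
    pd <- do.call(rbind, lapply(names(d$pd), function(ep) {
      p <- d$pd[[ep]]
      data.frame(subject_id = d$subject_id, metabolizer = d$metabolizer,
                 endpoint = ep,
                 parameter = c("kin", "kout", "effect_cap", "c50", "n"),
                 value = c(p$kin, p$kout, p$effect_cap, p$c50, p$n),
                 stringsAsFactors = FALSE)
    }))
    rbind(pk, pd)
  }))
}

.dog_oral_pk <- function(dog) {
  oral_pk_parameters(v_over_f = dog$pk$volume, k01 = dog$pk$k01,
                     k10 = dog$pk$k10, tlag = dog$pk$tlag)
}

#' Generate concentration observations for a cohort
#'
#' Oral profiles follow each dog's Bateman curve; IV profiles follow
#' monoexponential decay `(D/V) exp(-k10 t)`. Proportional log-normal
#' residual error at the spec's `residual_cv_conc` is applied and values
#' below the LOQ are flagged BQL.
#'
#' @param cohort A `virtual_cohort`.
#' @param schedule `"oral_study1"`, `"iv_study1"` or `"sparse_study2"`.
#' @param dose Dose (mg/kg, default 2).
#' @param seed Optional seed for the residual noise (defaults to
#'   `spec$seed + 1` so cohort and observations are independently
#'   reproducible).
#' @return List of [concentration_profile] objects.
#' @export
generate_concentration_data <- function(cohort, schedule, dose = 2,
                                        seed = NULL) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  spec <- attr(cohort, "spec")
  if (!schedule %in% c("oral_study1", "iv_study1", "sparse_study2"))
    stop("generate_concentration_data: unknown schedule '", schedule, "'")
  times <- spec$schedules[[schedule]]
  route <- if (schedule == "iv_study1") "iv" else "oral"
  set.seed(if (is.null(seed)) spec$seed + 1L else as.integer(seed))
  cvr <- spec$residual_cv_conc
  lapply(cohort, function(dog) {
    mu <- if (route == "oral") {
      oral_concentration(.dog_oral_pk(dog), dose, times)
    } else {
      dose * 1000 / dog$pk$volume * exp(-dog$pk$k10 * times)
    }
    obs <- mu * .rlnorm_cv(length(mu), 1, cvr)
    obs[mu == 0] <- 0
    concentration_profile(dog$subject_id, route, dose, times, obs,
                          bql_flags = obs < spec$loq & times > 0,
                          loq = spec$loq)
  })
}

#' Generate effect observations for a cohort
#'
#' Simulates each dog's turnover response to its own oral concentration
#' curve, samples it at the pharmacodynamic schedule (0, 2, 4, 9, 15, 22,
#' 27 h; the time-0 value is the pre-treatment measurement), and adds
#' Gaussian noise. Baselines are emitted consistently with the model:
#' `t_plus` is the inflamed steady state `kin / kout` and `t_minus` the
#' full-drug-effect steady state (the healthy value the endpoint returns to
#' at 100% improvement). Lameness scores are rounded to integers and
#' clipped to `[0, 5]`.
#'
#' @param cohort A `virtual_cohort`.
#' @param endpoint One of the four modeled endpoints.
#' @param dose Dose (mg/kg, default 2); ignored when `conc_inputs` given.
#' @param conc_inputs Optional list of `conc_input` objects, one per dog
#'   (e.g. fitted PK curves); defaults to each dog's true oral curve.
#' @param schedule Name of the PD schedule (default `"pd_study1"`).
#' @param seed Optional seed (defaults to `spec$seed + 2`).
#' @return List of [effect_time_course] objects.
#' @export
generate_effect_data <- function(cohort, endpoint, dose = 2,
                                 conc_inputs = NULL, schedule = "pd_study1",
                                 seed = NULL) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  spec <- attr(cohort, "spec")
  if (!endpoint %in% names(.pd_defaults$EM))
    stop("generate_effect_data: no PD parameters for endpoint '", endpoint, "'")
  times <- spec$schedules[[schedule]]
  if (is.null(times)) stop("generate_effect_data: unknown schedule '", schedule, "'")
  kind <- endpoint_model_kind(endpoint)
  sd_eff <- spec$residual_sd_effect[[endpoint]]
  set.seed(if (is.null(seed)) spec$seed + 2L else as.integer(seed))
  out <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    dog <- cohort[[i]]
    p <- dog$pd[[endpoint]]
    conc <- if (is.null(conc_inputs)) conc_oral(.dog_oral_pk(dog), dose)
            else conc_inputs[[i]]
    t_sim <- if (times[1] > 0) c(0, times) else times
    sim <- simulate_turnover(kind, p, conc, t_sim)
    resp <- if (times[1] > 0) sim$response[-1] else sim$response
    vals <- resp + rnorm(length(resp), 0, sd_eff)
    t_plus <- p$kin / p$kout
    t_minus <- switch(kind,
      stimulate_kout = p$kin / (p$kout * (1 + p$effect_cap)),
      inhibit_kout = p$kin / (p$kout * (1 - p$effect_cap)),
      inhibit_kin = 0)
    if (endpoint == "lameness_score")
      vals <- pmin(pmax(round(vals), 0), 5)
    else
      vals <- pmax(vals, 0)
    out[[i]] <- effect_time_course(dog$subject_id, endpoint, times, vals,
                                   t_minus = t_minus, t_plus = t_plus)
  }
  out
}
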