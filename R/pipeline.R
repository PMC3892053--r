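# Pipeline orchestration: the full study-1 analysis chain and small unit
# conversion helpers.

#' Convert between mass and molar concentration units
#'
#' `ng/mL -> nmol/mL` divides by the molar mass (g/mol); the reverse
#' multiplies. The default molar mass is cimicoxib's (381.81 g/mol).
#'
#' @param value Concentration, >= 0 (ng/mL or nmol/mL depending on
#'   `direction`).
#' @param molar_mass Molar mass (g/mol), > 0.
#' @param direction `"mass_to_molar"` or `"molar_to_mass"`.
#' @return Converted concentration.
#' @export
convert_mass_molar <- function(value, molar_mass = 381.81,
                               direction = c("mass_to_molar", "molar_to_mass")) {
  direction <- match.arg(direction)
  if (!(molar_mass > 0)) stop("convert_mass_molar: molar mass must be > 0")
  stopifnot(all(value >= 0))
  if (direction == "mass_to_molar") value / molar_mass else value * molar_mass
}

#' Configuration for a study-1 pipeline run
#'
#' @param out_dir Output directory for report CSVs and the run log.
#' @param seed Seed controlling cohort generation and noise.
#' @param n_subjects,pm_fraction,residual_cv_conc Passed to [cohort_spec].
#' @param dose Treatment dose (mg/kg).
#' @param doses Dose grid for the regimen simulation.
#' @param endpoints Endpoints to model.
#' @param conc_oral_csv,conc_iv_csv,effect_csv Optional paths to observed
#'   tables; when `NULL` the synthetic generator supplies them.
#' @param molar_mass Molar mass for unit conversions (g/mol).
#' @param plateau_tolerance,effect_threshold Passed to [summarize_effect].
#' @param dose_criterion Near-maximal-dose criterion for [select_dose].
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("study1_"), seed = 1,
                       n_subjects = 12, pm_fraction = 1 / 3,
                       residual_cv_conc = 10, dose = 2,
                       doses = default_dose_grid(),
                       endpoints = c("body_temperature", "creeping_speed",
                                     "vertical_force", "lameness_score"),
                       conc_oral_csv = NULL, conc_iv_csv = NULL,
                       effect_csv = NULL, molar_mass = 381.81,
                       plateau_tolerance = 10, effect_threshold = 10,
                       dose_criterion = 0.90) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full study-1 analysis pipeline
#'
#' Chain: load or generate concentration and effect tables; fit the oral PK
#' model per subject; classify metabolizers from the oral terminal
#' half-lives; non-compartmental analysis of the IV profiles with EM/PM
#' subgroup comparison (Welch t-test on half-life and clearance); fit the
#' turnover model per subject and endpoint (sequential PK/PD: each dog's PD
#' is driven by its own fitted oral curve); summarize percent-improvement
#' plateau and durations per group; simulate the dose grid with the mean EM
#' parameters and select the dose. Writes tidy CSV reports plus a JSON run
#' log into `config$out_dir`.
#'
#' @param config A [run_config].
#' @return List of class `study1_report` with components `pk_fits`,
#'   `metabolizers`, `nca`, `subgroup_tests`, `pd_fits`,
#'   `effect_summaries`, `dose_grids`, `dose_selection`, `files`.
#' @export
run_study1_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  run_log <- list(seed = config$seed, started = format(t_start),
              package_version = as.character(utils::packageVersion("cimipkpd")),
              stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    run_log$stages[[name]] <<- list(completed = TRUE)
    res
  }

  # --- inputs ------------------------------------------------------------
  synthetic <- is.null(config$conc_oral_csv)
  spec <- cohort_spec(n_subjects = config$n_subjects,
                      pm_fraction = config$pm_fraction,
                      residual_cv_conc = config$residual_cv_conc,
                      seed = config$seed)
  inputs <- stage("inputs", {
    if (synthetic) {
      cohort <- generate_cohort(spec)
      oral <- generate_concentration_data(cohort, "oral_study1", config$dose)
      iv <- generate_concentration_data(cohort, "iv_study1", config$dose,
                                        seed = spec$seed + 11L)
      eff <- lapply(setNames(config$endpoints, config$endpoints), function(ep)
        generate_effect_data(cohort, ep, config$dose,
                             seed = spec$seed + 20L + match(ep, config$endpoints)))
      list(oral = oral, iv = iv, effects = eff, cohort = cohort)
    } else {
      oral <- read_concentration_csv(config$conc_oral_csv, loq = spec$loq)
      iv <- if (!is.null(config$conc_iv_csv))
        read_concentration_csv(config$conc_iv_csv, loq = spec$loq) else NULL
      if (is.null(config$effect_csv))
        stop("effect table required (fit-pkpd inputs: --effect <csv>)")
      all_eff <- read_effect_csv(config$effect_csv)
      eff <- lapply(setNames(config$endpoints, config$endpoints), function(ep)
        Filter(function(x) x$endpoint == ep, all_eff))
      list(oral = oral, iv = iv, effects = eff, cohort = NULL)
    }
  })

  # --- oral PK fits (subjects whose profile cannot support the model are
  # excluded downstream, with the exclusion logged) ----------------------
  pk_fits <- stage("fit-pk", {
    fits <- lapply(inputs$oral, function(p)
      tryCatch(fit_oral_pk(p), error = function(e) e))
    names(fits) <- vapply(inputs$oral, `[[`, "", "subject_id")
    failed <- vapply(fits, inherits, logical(1), "error")
    if (any(failed)) {
      run_log$warnings <- c(run_log$warnings, paste0(
        "fit-pk: excluded ", paste(names(fits)[failed], collapse = ", "),
        " (", vapply(fits[failed], conditionMessage, ""), ")"))
      warning("fit-pk: excluded subjects ",
              paste(names(fits)[failed], collapse = ", "))
    }
    fits[!failed]
  })
  if (length(pk_fits) < 4)
    stop("pipeline: fewer than 4 subjects with a usable oral PK fit")
  keep_ids <- names(pk_fits)
  inputs$effects <- lapply(inputs$effects, function(courses)
    Filter(function(x) x$subject_id %in% keep_ids, courses))
  if (!is.null(inputs$iv))
    inputs$iv <- Filter(function(p) p$subject_id %in% keep_ids, inputs$iv)
  halflives <- vapply(pk_fits, function(f) log(2) / f$params$k10, numeric(1))

  # --- metabolizer classification ---------------------------------------
  metab <- stage("classify-metabolizers", classify_metabolizers(halflives))
  labels <- setNames(metab$assignments$label, metab$assignments$subject_id)

  # --- IV NCA and subgroup comparison -----------------------------------
  nca <- subgroup_tests <- NULL
  if (!is.null(inputs$iv)) {
    nca <- stage("nca", lapply(inputs$iv, nca_iv))
    names(nca) <- vapply(inputs$iv, `[[`, "", "subject_id")
    byg <- function(field) split(vapply(nca, `[[`, 0, field), labels[names(nca)])
    subgroup_tests <- stage("compare-subgroups", {
      if (length(unique(labels)) == 2)
        list(half_life = compare_subgroups(byg("half_life"), "half_life"),
             clearance = compare_subgroups(byg("clearance"), "clearance"))
      else NULL
    })
  }

  # --- sequential PK/PD fits --------------------------------------------
  pd_fits <- stage("fit-pkpd", {
    lapply(inputs$effects, function(courses) {
      lapply(courses, function(course) {
        fit <- pk_fits[[course$subject_id]]
        fit_turnover(course, conc_oral(fit$params, config$dose))
      })
    })
  })

  # --- effect summaries (percent improvement) ---------------------------
  effect_summaries <- stage("summarize-effects", {
    lapply(inputs$effects, function(courses) {
      lapply(Filter(function(x) x$endpoint != "lameness_score", courses),
             function(course)
               summarize_effect(percent_improvement(course),
                                config$plateau_tolerance,
                                config$effect_threshold))
    })
  })

  # --- dose simulation with mean EM parameters --------------------------
  dose_out <- stage("simulate-dose", {
    em_ids <- names(labels)[labels == "EM"]
    mean_pk <- {
      fits <- pk_fits[em_ids]
      oral_pk_parameters(
        v_over_f = mean(vapply(fits, function(f) f$params$v_over_f, 0)),
        k01 = mean(vapply(fits, function(f) f$params$k01, 0)),
        k10 = mean(vapply(fits, function(f) f$params$k10, 0)),
        tlag = mean(vapply(fits, function(f) f$params$tlag, 0)))
    }
    grids <- lapply(setNames(config$endpoints, config$endpoints), function(ep) {
      ids <- vapply(inputs$effects[[ep]], `[[`, "", "subject_id")
      fl <- pd_fits[[ep]][ids %in% em_ids]
      mp <- function(field) mean(vapply(fl, function(f) f$params[[field]], 0))
      pd <- indirect_response_parameters(mp("kin"), mp("kout"),
                                         min(mp("effect_cap"), 1),
                                         mp("c50"), min(mp("n"), 10))
      simulate_dose_grid(mean_pk, pd, endpoint_model_kind(ep),
                         doses = config$doses,
                         criterion = config$dose_criterion)
    })
    list(grids = grids,
         selection = select_dose(grids, config$dose_criterion),
         mean_pk = mean_pk)
  })

  # --- reports -----------------------------------------------------------
  files <- stage("write-reports", {
    f <- list()
    f$pk <- file.path(config$out_dir, "pk_parameters.csv")
    write.csv(data.frame(
      subject_id = names(pk_fits),
      metabolizer = labels[names(pk_fits)],
      v_over_f = vapply(pk_fits, function(x) x$params$v_over_f, 0),
      k01 = vapply(pk_fits, function(x) x$params$k01, 0),
      k10 = vapply(pk_fits, function(x) x$params$k10, 0),
      tlag = vapply(pk_fits, function(x) x$params$tlag, 0),
      half_life = halflives), f$pk, row.names = FALSE)
    if (!is.null(nca)) {
      f$nca <- file.path(config$out_dir, "nca_by_group.csv")
      nd <- data.frame(
        subject_id = names(nca), metabolizer = labels[names(nca)],
        auc_0_inf = vapply(nca, `[[`, 0, "auc_0_inf"),
        half_life = vapply(nca, `[[`, 0, "half_life"),
        clearance = vapply(nca, `[[`, 0, "clearance"),
        v_z = vapply(nca, `[[`, 0, "v_z"))
      write.csv(nd, f$nca, row.names = FALSE)
    }
    f$pd <- file.path(config$out_dir, "pd_parameters.csv")
    pdrows <- do.call(rbind, lapply(names(pd_fits), function(ep) {
      ids <- vapply(inputs$effects[[ep]], `[[`, "", "subject_id")
      do.call(rbind, Map(function(fit, id) data.frame(
        subject_id = id, metabolizer = labels[[id]], endpoint = ep,
        kin = fit$params$kin, kout = fit$params$kout,
        effect_cap = fit$params$effect_cap, c50 = fit$params$c50,
        n = fit$params$n, converged = fit$diagnostics$converged),
        pd_fits[[ep]], ids))
    }))
    write.csv(pdrows, f$pd, row.names = FALSE)
    f$dose <- file.path(config$out_dir, "dose_selection.csv")
    sel <- dose_out$selection
    write.csv(data.frame(endpoint = names(sel$per_endpoint),
                         near_maximal_dose = sel$per_endpoint,
                         selected_dose = sel$selected_dose,
                         attained = sel$attained), f$dose, row.names = FALSE)
    f
  })

  run_log$finished <- format(Sys.time())
  run_log$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  log_path <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(run_log, log_path, auto_unbox = TRUE, pretty = TRUE)
  files$log <- log_path

  structure(list(pk_fits = pk_fits, metabolizers = metab, nca = nca,
                 subgroup_tests = subgroup_tests, pd_fits = pd_fits,
                 effect_summaries = effect_summaries,
                 dose_grids = dose_out$grids,
                 dose_selection = dose_out$selection, files = files,
                 config = config), class = "study1_report")
}
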