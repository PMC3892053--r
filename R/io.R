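# Header-first CSV interchange formats.
#
# Concentration table: subject_id,route,dose_mg_per_kg,time_h,conc_ug_per_L,bql
# Effect table:        subject_id,endpoint,time_h,value,t_minus,t_plus

#' Read a concentration CSV into per-subject profiles
#'
#' Expected columns: `subject_id`, `route`, `dose_mg_per_kg`, `time_h`,
#' `conc_ug_per_L` and optionally `bql` (0/1; recomputed from `loq` when
#' absent).
#'
#' @param path CSV path.
#' @param loq Limit of quantification (ug/L) used when `bql` is absent.
#' @return Named list of [concentration_profile] objects.
#' @export
read_concentration_csv <- function(path, loq = 10) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "route", "dose_mg_per_kg", "time_h", "conc_ug_per_L")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_concentration_csv: missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$time_h), ]
    concentration_profile(
      d$subject_id[1], d$route[1], d$dose_mg_per_kg[1], d$time_h,
      d$conc_ug_per_L,
      bql_flags = if ("bql" %in% names(d)) as.logical(d$bql) else NULL,
      loq = loq)
  })
  out[order(names(out))]
}

#' Write per-subject profiles to a concentration CSV
#' @param profiles List of [concentration_profile] objects.
#' @param path Output CSV path.
#' @export
write_concentration_csv <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id, route = p$route,
               dose_mg_per_kg = p$dose, time_h = p$times,
               conc_ug_per_L = p$concentrations,
               bql = as.integer(p$bql_flags), stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an effect CSV into per-subject time courses
#'
#' Expected columns: `subject_id`, `endpoint`, `time_h`, `value`,
#' `t_minus`, `t_plus`.
#'
#' @param path CSV path.
#' @return List of [effect_time_course] objects (one per subject x
#'   endpoint).
#' @export
read_effect_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "endpoint", "time_h", "value", "t_minus", "t_plus")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_effect_csv: missing columns: ", paste(miss, collapse = ", "))
  key <- interaction(df$subject_id, df$endpoint, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_h), ]
    effect_time_course(d$subject_id[1], d$endpoint[1], d$time_h, d$value,
                       t_minus = d$t_minus[1], t_plus = d$t_plus[1])
  })
}

#' Write effect time courses to CSV
#' @param courses List of [effect_time_course] objects.
#' @param path Output CSV path.
#' @export
write_effect_csv <- function(courses, path) {
  df <- do.call(rbind, lapply(courses, function(x) {
    data.frame(subject_id = x$subject_id, endpoint = x$endpoint,
               time_h = x$times, value = x$values, t_minus = x$t_minus,
               t_plus = x$t_plus, stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
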