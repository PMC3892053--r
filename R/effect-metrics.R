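# Percent-improvement transform and descriptive effect summaries.

.endpoints <- c("body_temperature", "paw_circumference", "skin_temperature",
                "creeping_speed", "lameness_score", "vertical_force",
                "withdrawal_time")

#' Subject-level effect time course
#'
#' One subject's measurements of one pharmacodynamic endpoint over time,
#' anchored by two baselines: `t_minus`, the mean pre-inflammation (healthy)
#' value, and `t_plus`, the mean post-inflammation pre-treatment value.
#'
#' @param subject_id Subject identifier.
#' @param endpoint One of `body_temperature`, `paw_circumference`,
#'   `skin_temperature`, `creeping_speed`, `lameness_score`,
#'   `vertical_force`, `withdrawal_time`.
#' @param times Hours relative to treatment, strictly increasing.
#' @param values Measurements in endpoint units; lameness scores must be
#'   integers in 0..5.
#' @param t_minus,t_plus Baselines (endpoint units).
#' @return An object of class `effect_time_course`.
#' @export
effect_time_course <- function(subject_id, endpoint, times, values,
                               t_minus, t_plus) {
  endpoint <- match.arg(endpoint, .endpoints)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("effect_time_course: times and values differ in length")
  if (any(diff(times) <= 0))
    stop("effect_time_course: times must be strictly increasing")
  # observed lameness is an integer score; model-scale (fitted/simulated)
  # series are continuous, so only the 0-5 range is enforced here
  if (endpoint == "lameness_score" && any(values < 0 | values > 5))
    stop("effect_time_course: lameness scores must lie in [0, 5]")
  structure(list(subject_id = as.character(subject_id), endpoint = endpoint,
                 times = times, values = values,
                 t_minus = t_minus, t_plus = t_plus),
            class = "effect_time_course")
}

#' Percent improvement relative to the two inflammation baselines
#'
#' Converts raw endpoint values `M` to
#' \deqn{\%improvement = \frac{T^+ - M}{T^+ - T^-} \times 100}
#' where `T+` is the inflamed pre-treatment baseline and `T-` the healthy
#' baseline. 0% means no change from the inflamed state, 100% means full
#' return to the healthy value; values beyond 100% (hypoalgesia) are
#' allowed. The same formula handles endpoints that rise under inflammation
#' (fever: `T+ > T-`) and endpoints that fall (speed: `T+ < T-`). Not
#' defined for the ordinal lameness score.
#'
#' @param course An [effect_time_course], endpoint not `lameness_score`.
#' @return List of class `improvement_series`: `times`, `percent`,
#'   `endpoint`.
#' @export
percent_improvement <- function(course) {
  stopifnot(inherits(course, "effect_time_course"))
  if (course$endpoint == "lameness_score")
    stop("percent_improvement: lameness is summarized on its ordinal scale")
  denom <- course$t_plus - course$t_minus
  if (denom == 0)
    stop("percent_improvement: degenerate baselines (t_plus == t_minus)")
  structure(list(times = course$times,
                 percent = (course$t_plus - course$values) / denom * 100,
                 endpoint = course$endpoint),
            class = "improvement_series")
}

#' Summarize an improvement series: plateau and durations
#'
#' Identifies the plateau of maximal effect as the longest contiguous run
#' of observations within `plateau_tolerance` percentage points of the
#' series maximum, reports the mean improvement over that window as the
#' maximum effect, and measures the total duration of effect as the width
#' of the region where improvement stays at or above `effect_threshold`
#' (crossing times by linear interpolation between observations).
#'
#' A plateau is flagged undetermined when the within-tolerance run ends at
#' the final observation while values are still strictly rising across it
#' (the effect has not visibly peaked), or when it contains a single point.
#'
#' @param series An `improvement_series` from [percent_improvement].
#' @param plateau_tolerance Percentage points below the maximum still
#'   counted as plateau (default 10).
#' @param effect_threshold Improvement (%) above which the drug is counted
#'   as having an effect (default 10).
#' @return List of class `effect_summary`: `max_effect_percent`,
#'   `plateau_start`, `plateau_end`, `plateau_duration`, `total_duration`,
#'   `plateau_determined`.
#' @export
summarize_effect <- function(series, plateau_tolerance = 10,
                             effect_threshold = 10) {
  stopifnot(inherits(series, "improvement_series"))
  tt <- series$times; y <- series$percent
  n <- length(y)
  if (n < 3) stop("summarize_effect: need >= 3 observations")

  ymax <- max(y)
  if (ymax <= 0) {
    return(structure(list(max_effect_percent = 0, plateau_start = NA_real_,
                          plateau_end = NA_real_, plateau_duration = 0,
                          total_duration = 0, plateau_determined = FALSE),
                     class = "effect_summary"))
  }
  inwin <- y >= ymax - plateau_tolerance
  # longest contiguous TRUE run (by time span; ties toward the earlier run)
  runs <- rle(inwin)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  spans <- tt[ends[cand]] - tt[starts[cand]]
  pick <- cand[which.max(spans)]
  i0 <- starts[pick]; i1 <- ends[pick]

  rising <- i1 == n && i1 > i0 && all(diff(y[i0:i1]) > 0)
  determined <- (i1 > i0) && !rising

  # total duration: measure of {t : y(t) >= threshold} under linear interpolation
  above <- y >= effect_threshold
  total <- 0
  for (i in seq_len(n - 1)) {
    y1 <- y[i]; y2 <- y[i + 1]; dt <- tt[i + 1] - tt[i]
    if (above[i] && above[i + 1]) {
      total <- total + dt
    } else if (above[i] != above[i + 1]) {
      frac <- (effect_threshold - y1) / (y2 - y1)
      total <- total + if (above[i]) frac * dt else (1 - frac) * dt
    }
  }

  structure(list(
    max_effect_percent = mean(y[i0:i1]),
    plateau_start = if (determined) tt[i0] else NA_real_,
    plateau_end = if (determined) tt[i1] else NA_real_,
    plateau_duration = if (determined) tt[i1] - tt[i0] else NA_real_,
    total_duration = total,
    plateau_determined = determined), class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  if (x$plateau_determined) {
    cat(sprintf("Maximum effect %.1f%% over plateau %.1f-%.1f h (%.1f h); total duration %.1f h\n",
                x$max_effect_percent, x$plateau_start, x$plateau_end,
                x$plateau_duration, x$total_duration))
  } else {
    cat(sprintf("No plateau observed (series still rising or single-point maximum); total duration %.1f h\n",
                x$total_duration))
  }
  invisible(x)
}
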