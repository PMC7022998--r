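#' Session-RPE internal training load
#'
#' Internal load of a single session: the CR-10 rating of perceived exertion
#' multiplied by the session duration in minutes, in arbitrary units (AU).
#'
#' @param rpe Rating of perceived exertion on the modified Borg CR-10 scale
#'   (0--10, half-point steps allowed).
#' @param duration Session duration in minutes, strictly positive.
#' @return Session load in AU. Vectorized.
#' @examples
#' session_rpe(7, 60)    # 420 AU
#' session_rpe(8.5, 110) # 935 AU
#' @export
session_rpe <- function(rpe, duration) {
  if (any(!is.finite(rpe)) || any(rpe < 0 | rpe > 10)) {
    stop("`rpe` must lie in [0, 10]", call. = FALSE)
  }
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    stop("`duration` must be positive minutes", call. = FALSE)
  }
  rpe * duration
}

#' Training monotony of one week
#'
#' Mean daily load divided by the standard deviation of daily load over the
#' seven days of a week (rest days count as 0 AU). High monotony indicates
#' uniform day-to-day loading. The sample SD (n - 1 denominator) is used; set
#' `sd_type = "population"` for the n denominator.
#'
#' @param daily_loads Exactly 7 daily load totals in AU.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return Dimensionless monotony, or `NA` for a constant week (SD = 0).
#' @examples
#' training_monotony(c(500, 400, 300, 600, 200, 0, 0))
#' @export
training_monotony <- function(daily_loads, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(daily_loads) != 7L) {
    stop("`daily_loads` must contain exactly 7 daily totals", call. = FALSE)
  }
  if (any(!is.finite(daily_loads)) || any(daily_loads < 0)) {
    stop("daily loads must be non-negative and finite", call. = FALSE)
  }
  s <- stats::sd(daily_loads)
  if (sd_type == "population") s <- s * sqrt(6 / 7)
  if (s == 0) return(NA_real_)
  mean(daily_loads) / s
}

#' Training strain of one week
#'
#' Weekly total load multiplied by the week's monotony, in AU. An undefined
#' monotony (constant week) propagates to an undefined strain.
#'
#' @param weekly_total_load Total weekly load in AU.
#' @param monotony Weekly monotony (possibly `NA`).
#' @return Strain in AU, `NA` if monotony is undefined.
#' @export
training_strain <- function(weekly_total_load, monotony) {
  if (any(weekly_total_load < 0, na.rm = TRUE)) {
    stop("weekly total load must be non-negative", call. = FALSE)
  }
  weekly_total_load * monotony
}

#' Acute:chronic workload ratio
#'
#' Ratio of the most recent week's load to the rolling mean weekly load over a
#' 4-week chronic window. With `chronic_window = "inclusive"` (default) the
#' chronic mean covers weeks `w-3 .. w`; `"exclusive"` uses `w-3 .. w-1`.
#'
#' @param weekly_loads Weekly total loads in AU, weeks 1..W in order.
#' @param week Week index at which to evaluate the ratio.
#' @param chronic_window `"inclusive"` or `"exclusive"` chronic mean.
#' @return The ratio, or `NA` when `week < 4` or the chronic load is 0.
#' @examples
#' acwr(c(1000, 1000, 1000, 2000), 4) # 1.6
#' @export
acwr <- function(weekly_loads, week,
                 chronic_window = c("inclusive", "exclusive")) {
  chronic_window <- match.arg(chronic_window)
  if (week < 1 || week > length(weekly_loads)) {
    stop("`week` outside the recorded season", call. = FALSE)
  }
  if (week < 4) return(NA_real_)
  idx <- if (chronic_window == "inclusive") (week - 3):week else (week - 3):(week - 1)
  chronic <- mean(weekly_loads[idx])
  if (!is.finite(chronic) || chronic <= 0) return(NA_real_)
  weekly_loads[week] / chronic
}

#' Percentage of personal best time
#'
#' Converts a competition time into the squared ratio of the previous personal
#' best to the achieved time, times 100. Values above 100 mean the athlete
#' beat the personal best held at the start of the season.
#'
#' @param previous_pb_s Personal best at study start, in seconds.
#' @param time_s Achieved time, in seconds.
#' @return %PBT as a percentage. Vectorized.
#' @examples
#' percent_pbt(62, 60.5) # 105.02...
#' @export
percent_pbt <- function(previous_pb_s, time_s) {
  if (any(!is.finite(previous_pb_s)) || any(previous_pb_s <= 0)) {
    stop("`previous_pb_s` must be positive seconds", call. = FALSE)
  }
  if (any(!is.finite(time_s)) || any(time_s <= 0)) {
    stop("`time_s` must be positive seconds", call. = FALSE)
  }
  (previous_pb_s / time_s)^2 * 100
}

#' Total mood disturbance
#'
#' Sum of the five negative mood dimensions minus vigour. No +100 offset is
#' added: the offset is a monotone shift irrelevant to rank-based association,
#' so negative values are possible.
#'
#' @param anger,confusion,depression,fatigue,tension,vigour Non-negative POMS
#'   dimension scores.
#' @return TMD in POMS units; `NA` if any dimension is missing.
#' @export
total_mood_disturbance <- function(anger, confusion, depression, fatigue,
                                   tension, vigour) {
  dims <- cbind(anger, confusion, depression, fatigue, tension, vigour)
  if (any(dims < 0, na.rm = TRUE)) {
    stop("POMS dimension scores must be non-negative", call. = FALSE)
  }
  anger + confusion + depression + fatigue + tension - vigour
}

#' Normalize a series by its maximum
#'
#' Divides every value by the series maximum so the output maximum is exactly
#' 1 and order is preserved. `NA` values pass through.
#'
#' @param values Numeric vector with a positive maximum.
#' @return Values scaled into `[0, 1]` (assuming non-negative input).
#' @export
normalize_series <- function(values) {
  m <- suppressWarnings(max(values, na.rm = TRUE))
  if (!is.finite(m) || m <= 0) {
    stop("cannot normalize: series maximum is not positive", call. = FALSE)
  }
  values / m
}

#' Binarize %PBT into the adaptation label
#'
#' The perceptron label: +1 (adaptation) when %PBT strictly exceeds 100,
#' -1 (maladaptation) otherwise, including exactly 100 — improvement means
#' strictly beating the personal best.
#'
#' @param z_pct %PBT values; `NA` (no competition) yields `NA`.
#' @return Integer labels in `{+1, -1, NA}`.
#' @export
binarize_pbt <- function(z_pct) {
  if (any(z_pct <= 0, na.rm = TRUE)) {
    stop("%PBT must be positive", call. = FALSE)
  }
  ifelse(is.na(z_pct), NA_integer_, ifelse(z_pct > 100, 1L, -1L))
}

#' Quartile banding by minimum rank
#'
#' Assigns each value to a quartile band 1..4 using competition-style minimum
#' ranks: `quartile = floor((r - 1) * 4 / n) + 1` where `r` is the ascending
#' minimum rank and tied values share the minimum rank. This is the banding
#' convention used for cohort characteristic tables.
#'
#' @param values At least 4 numeric values.
#' @return Integer quartiles, one per value.
#' @examples
#' assign_quartiles(c(1, 2, 3, 4)) # 1 2 3 4
#' @export
assign_quartiles <- function(values) {
  n <- length(values)
  if (n < 4L) stop("need at least 4 values for quartile banding", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  r <- rank(values, ties.method = "min")
  as.integer(floor((r - 1) * 4 / n) + 1L)
}
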