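#' Assemble an athlete's monitoring series
#'
#' Bundles all raw per-athlete monitoring streams on a common weekly calendar.
#' Weeks start on Monday; `start_date` is snapped back to the Monday of its
#' week and week `w` covers days `7*(w-1) .. 7*w - 1` after it.
#'
#' @param athlete_id Athlete identifier.
#' @param sessions Data frame with `date`, `sport`, `rpe`, `duration_min`,
#'   `distance_m` (one row per training session).
#' @param wellbeing Data frame with `date` and the six 7-point Likert items
#'   `sleep_quality`, `sleep_quantity`, `soreness`, `enjoyment`, `stress`,
#'   `global_recovery`.
#' @param poms Data frame with `date` and the six mood dimensions `anger`,
#'   `confusion`, `depression`, `fatigue`, `tension`, `vigour`.
#' @param performances Data frame with `date`, `discipline`, `time_s`,
#'   `previous_pb_s`.
#' @param start_date First day of the study window (`Date` or ISO-8601 text).
#'   Defaults to the Monday of the earliest recorded date.
#' @param n_weeks Number of study weeks (default 26). All dates must fall
#'   inside the window.
#' @return An `athlete_series` object.
#' @export
athlete_series <- function(athlete_id, sessions, wellbeing = NULL, poms = NULL,
                           performances = NULL, start_date = NULL,
                           n_weeks = 26L) {
  sessions <- as.data.frame(sessions)
  wellbeing <- as.data.frame(wellbeing %||% empty_wellbeing())
  poms <- as.data.frame(poms %||% empty_poms())
  performances <- as.data.frame(performances %||% empty_performances())
  for (nm in c("sessions", "wellbeing", "poms", "performances")) {
    df <- get(nm)
    df$date <- as.Date(df$date)
    assign(nm, df)
  }
  validate_sessions(sessions)
  validate_wellbeing(wellbeing)
  validate_poms(poms)
  validate_performances(performances)

  all_dates <- c(sessions$date, wellbeing$date, poms$date, performances$date)
  if (is.null(start_date)) {
    if (length(all_dates) == 0) stop("no dated records and no `start_date`",
                                     call. = FALSE)
    start_date <- min(all_dates)
  }
  start_date <- monday_of(as.Date(start_date))
  n_weeks <- as.integer(n_weeks)
  if (n_weeks < 1L) stop("`n_weeks` must be at least 1", call. = FALSE)
  if (length(all_dates) > 0) {
    wk <- week_index(all_dates, start_date)
    if (any(wk < 1L | wk > n_weeks)) {
      stop("some records fall outside the ", n_weeks, "-week study window",
           call. = FALSE)
    }
  }
  structure(
    list(athlete_id = as.character(athlete_id), sessions = sessions,
         wellbeing = wellbeing, poms = poms, performances = performances,
         start_date = start_date, n_weeks = n_weeks),
    class = "athlete_series"
  )
}

#' @export
print.athlete_series <- function(x, ...) {
  cat("<athlete_series> ", x$athlete_id, "\n",
      "  window  : ", format(x$start_date), " + ", x$n_weeks, " weeks\n",
      "  sessions: ", nrow(x$sessions),
      " | wellness: ", nrow(x$wellbeing),
      " | POMS: ", nrow(x$poms),
      " | competitions: ", nrow(x$performances), "\n", sep = "")
  invisible(x)
}

monday_of <- function(date) {
  # weekday 0 = Monday
  date - ((as.integer(format(date, "%u")) - 1L))
}

week_index <- function(dates, start_monday) {
  as.integer(floor(as.numeric(dates - start_monday) / 7)) + 1L
}

day_of_week <- function(dates) as.integer(format(dates, "%u"))

empty_sessions <- function() {
  data.frame(date = as.Date(character()), sport = character(),
             rpe = numeric(), duration_min = numeric(), distance_m = numeric())
}
empty_wellbeing <- function() {
  data.frame(date = as.Date(character()), sleep_quality = integer(),
             sleep_quantity = integer(), soreness = integer(),
             enjoyment = integer(), stress = integer(),
             global_recovery = integer())
}
empty_poms <- function() {
  data.frame(date = as.Date(character()), anger = numeric(),
             confusion = numeric(), depression = numeric(),
             fatigue = numeric(), tension = numeric(), vigour = numeric())
}
empty_performances <- function() {
  data.frame(date = as.Date(character()), discipline = character(),
             time_s = numeric(), previous_pb_s = numeric())
}

validate_sessions <- function(df) {
  need_cols(df, c("date", "rpe", "duration_min", "distance_m"), "sessions")
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!is.finite(df$rpe) | df$rpe < 0 | df$rpe > 10)
  if (length(bad)) stop("sessions row ", bad[1], ": rpe outside [0, 10]",
                        call. = FALSE)
  bad <- which(!is.finite(df$duration_min) | df$duration_min <= 0)
  if (length(bad)) stop("sessions row ", bad[1], ": non-positive duration",
                        call. = FALSE)
  bad <- which(!is.finite(df$distance_m) | df$distance_m < 0)
  if (length(bad)) stop("sessions row ", bad[1], ": negative distance",
                        call. = FALSE)
  invisible(df)
}

validate_wellbeing <- function(df) {
  items <- c("sleep_quality", "sleep_quantity", "soreness", "enjoyment",
             "stress", "global_recovery")
  need_cols(df, c("date", items), "wellbeing")
  for (it in items) {
    bad <- which(!(df[[it]] %in% 1:7))
    if (length(bad)) stop("wellbeing row ", bad[1], ": `", it,
                          "` not on the 1-7 Likert scale", call. = FALSE)
  }
  invisible(df)
}

validate_poms <- function(df) {
  dims <- c("anger", "confusion", "depression", "fatigue", "tension", "vigour")
  need_cols(df, c("date", dims), "poms")
  for (d in dims) {
    bad <- which(!is.finite(df[[d]]) | df[[d]] < 0)
    if (length(bad)) stop("poms row ", bad[1], ": `", d,
                          "` must be a non-negative score", call. = FALSE)
  }
  invisible(df)
}

validate_performances <- function(df) {
  need_cols(df, c("date", "time_s", "previous_pb_s"), "performances")
  bad <- which(!is.finite(df$time_s) | df$time_s <= 0)
  if (length(bad)) stop("performances row ", bad[1], ": non-positive time_s",
                        call. = FALSE)
  bad <- which(!is.finite(df$previous_pb_s) | df$previous_pb_s <= 0)
  if (length(bad)) stop("performances row ", bad[1],
                        ": non-positive previous_pb_s", call. = FALSE)
  invisible(df)
}

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

#' Weekly aggregation of an athlete's monitoring streams
#'
#' Collapses the raw streams into one row per study week: per-session means of
#' distance and session-RPE load, the daily-load-based monotony and strain,
#' the acute:chronic workload ratio, the mean global recovery rating, the mean
#' total mood disturbance, and the best weekly %PBT (missing in weeks without
#' competition). Weeks without sessions have zero load/distance and undefined
#' monotony-derived metrics.
#'
#' @param series An [athlete_series()].
#' @param chronic_window Passed to [acwr()].
#' @return A `weekly_metrics` tibble with one row per week 1..`n_weeks` and
#'   columns `week`, `mean_distance`, `mean_session_rpe`, `total_load`,
#'   `monotony`, `strain`, `acwr`, `mean_recovery`, `tmd`, `best_pbt`.
#' @export
weekly_aggregate <- function(series, chronic_window = "inclusive") {
  stopifnot(inherits(series, "athlete_series"))
  W <- series$n_weeks
  out <- tibble::tibble(
    week = seq_len(W), mean_distance = 0, mean_session_rpe = 0,
    total_load = 0, monotony = NA_real_, strain = NA_real_, acwr = NA_real_,
    mean_recovery = NA_real_, tmd = NA_real_, best_pbt = NA_real_
  )

  s <- series$sessions
  daily <- matrix(0, nrow = W, ncol = 7L)  # daily load totals, Monday first
  if (nrow(s) > 0) {
    s$week <- week_index(s$date, series$start_date)
    s$load <- session_rpe(s$rpe, s$duration_min)
    s$dow <- day_of_week(s$date)
    for (w in unique(s$week)) {
      rows <- s[s$week == w, ]
      out$mean_distance[w] <- mean(rows$distance_m)
      out$mean_session_rpe[w] <- mean(rows$load)
      out$total_load[w] <- sum(rows$load)
      for (i in seq_len(nrow(rows))) {
        daily[w, rows$dow[i]] <- daily[w, rows$dow[i]] + rows$load[i]
      }
    }
  }
  for (w in seq_len(W)) {
    if (out$total_load[w] > 0) {
      out$monotony[w] <- training_monotony(daily[w, ])
      out$strain[w] <- training_strain(out$total_load[w], out$monotony[w])
    }
  }
  for (w in seq_len(W)) {
    out$acwr[w] <- acwr(out$total_load, w, chronic_window)
  }

  wb <- series$wellbeing
  if (nrow(wb) > 0) {
    wb$week <- week_index(wb$date, series$start_date)
    agg <- tapply(wb$global_recovery, wb$week, mean)
    out$mean_recovery[as.integer(names(agg))] <- as.numeric(agg)
  }

  pm <- series$poms
  if (nrow(pm) > 0) {
    pm$week <- week_index(pm$date, series$start_date)
    pm$tmd <- total_mood_disturbance(pm$anger, pm$confusion, pm$depression,
                                     pm$fatigue, pm$tension, pm$vigour)
    agg <- tapply(pm$tmd, pm$week, mean)
    out$tmd[as.integer(names(agg))] <- as.numeric(agg)
  }

  pf <- series$performances
  if (nrow(pf) > 0) {
    pf$week <- week_index(pf$date, series$start_date)
    pf$pbt <- percent_pbt(pf$previous_pb_s, pf$time_s)
    agg <- tapply(pf$pbt, pf$week, max)
    out$best_pbt[as.integer(names(agg))] <- as.numeric(agg)
  }

  class(out) <- c("weekly_metrics", class(out))
  out
}

# x/y indicator per combination id, in raw (pre-normalization) units
combination_axes <- function(combo) {
  switch(as.character(combo),
    "1" = c(x = "mean_distance", y = "mean_session_rpe"),
    "2" = c(x = "mean_session_rpe", y = "mean_recovery"),
    "3" = c(x = "strain", y = "mean_recovery"),
    "4" = c(x = "monotony", y = "mean_recovery"),
    "5" = c(x = "mean_distance", y = "acwr"),
    stop("unknown combination id: ", combo, " (must be 1..5)", call. = FALSE)
  )
}

#' Build the weekly (x, y, z) triplets for one indicator combination
#'
#' Picks the two weekly indicators of the requested combination
#' (1: distance / session-RPE; 2: session-RPE / recovery; 3: strain /
#' recovery; 4: monotony / recovery; 5: distance / ACWR), drops weeks where
#' either is undefined (with a warning), normalizes each axis by its maximum,
#' and attaches the best weekly %PBT and its adaptation label.
#'
#' @param metrics A `weekly_metrics` tibble from [weekly_aggregate()].
#' @param combo Combination id in 1..5.
#' @return A `weekly_triplets` tibble with columns `week`, `x`, `y`
#'   (normalized to `[0, 1]`), `z_pct` and `label` (`NA` in weeks without
#'   competition).
#' @export
build_combination <- function(metrics, combo) {
  axes <- combination_axes(combo)
  x_raw <- metrics[[axes[["x"]]]]
  y_raw <- metrics[[axes[["y"]]]]
  keep <- is.finite(x_raw) & is.finite(y_raw)
  if (any(!keep)) {
    warning(sum(!keep), " week(s) dropped from combination ", combo,
            ": undefined ", axes[["x"]], " or ", axes[["y"]], call. = FALSE)
  }
  if (!any(keep)) stop("no weeks with defined (x, y) for combination ", combo,
                       call. = FALSE)
  out <- tibble::tibble(
    week = metrics$week[keep],
    x = normalize_series(x_raw[keep]),
    y = normalize_series(y_raw[keep]),
    z_pct = metrics$best_pbt[keep]
  )
  out$label <- binarize_pbt(out$z_pct)
  attr(out, "combo") <- as.integer(combo)
  class(out) <- c("weekly_triplets", class(out))
  out
}

#' Inclusion prerequisites for modelling
#'
#' An athlete enters the geometric modelling only if (1) every questionnaire
#' response rate strictly exceeds 80%, (2) strictly more than 75% of training
#' sessions were recorded, (3) the season contains at least one %PBT above
#' 100 and one below 100, and (4) the (x, y) indicators of the chosen
#' combination are defined for every week that has a %PBT value.
#'
#' @param series An [athlete_series()].
#' @param attendance Fraction of training sessions recorded, in `[0, 1]`.
#' @param response_rates Named or unnamed vector of per-questionnaire response
#'   rates in `[0, 1]`.
#' @param combo Combination id used for the completeness check (default 1).
#' @return A list with `include` (logical) and `reasons` (character vector of
#'   failed criteria, empty when included).
#' @export
apply_prerequisites <- function(series, attendance, response_rates, combo = 1) {
  stopifnot(inherits(series, "athlete_series"))
  if (any(response_rates < 0 | response_rates > 1) ||
      attendance < 0 || attendance > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  reasons <- character()
  if (!all(response_rates > 0.80)) {
    reasons <- c(reasons, "questionnaire response rate not above 80%")
  }
  if (!(attendance > 0.75)) {
    reasons <- c(reasons, "recorded-session fraction not above 75%")
  }
  metrics <- weekly_aggregate(series)
  pbt <- metrics$best_pbt[!is.na(metrics$best_pbt)]
  if (!any(pbt > 100)) reasons <- c(reasons, "no %PBT value over 100%")
  if (!any(pbt < 100)) reasons <- c(reasons, "no %PBT value under 100%")
  axes <- combination_axes(combo)
  comp_weeks <- which(!is.na(metrics$best_pbt))
  incomplete <- comp_weeks[!is.finite(metrics[[axes[["x"]]]][comp_weeks]) |
                             !is.finite(metrics[[axes[["y"]]]][comp_weeks])]
  if (length(incomplete)) {
    reasons <- c(reasons, paste0("incomplete (x, y) data in competition week(s) ",
                                 paste(incomplete, collapse = ", ")))
  }
  list(include = length(reasons) == 0L, reasons = reasons)
}
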