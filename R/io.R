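#' Read and write the standard monitoring CSV files
#'
#' Four flat files carry a cohort's raw streams, each keyed by `athlete_id`
#' and ISO-8601 `date`:
#' \itemize{
#'   \item `sessions.csv`: `athlete_id,date,sport,rpe,duration_min,distance_m`
#'   \item `wellbeing.csv`: `athlete_id,date,sleep_quality,sleep_quantity,soreness,enjoyment,stress,global_recovery`
#'   \item `poms.csv`: `athlete_id,date,anger,confusion,depression,fatigue,tension,vigour`
#'   \item `performances.csv`: `athlete_id,date,discipline,time_s,previous_pb_s`
#' }
#' Readers reject malformed rows with line-numbered errors; writers
#' round-trip losslessly.
#'
#' @param path File path.
#' @return A data frame with `date` parsed to `Date`.
#' @name monitoring_io
NULL

read_monitoring_csv <- function(path, cols, validator, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) | is.na(df$date))
  if (length(bad)) {
    stop(what, " file ", path, " line ", bad[1] + 1L,
         ": unparseable ISO-8601 date `", df$date[bad[1]], "`", call. = FALSE)
  }
  df$date <- dates
  tryCatch(validator(df), error = function(e) {
    stop(what, " file ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  df
}

#' @rdname monitoring_io
#' @export
read_sessions <- function(path) {
  read_monitoring_csv(path, c("athlete_id", "date", "sport", "rpe",
                              "duration_min", "distance_m"),
                      validate_sessions, "sessions")
}

#' @rdname monitoring_io
#' @export
read_wellbeing <- function(path) {
  read_monitoring_csv(path, c("athlete_id", "date", "sleep_quality",
                              "sleep_quantity", "soreness", "enjoyment",
                              "stress", "global_recovery"),
                      validate_wellbeing, "wellbeing")
}

#' @rdname monitoring_io
#' @export
read_poms <- function(path) {
  read_monitoring_csv(path, c("athlete_id", "date", "anger", "confusion",
                              "depression", "fatigue", "tension", "vigour"),
                      validate_poms, "poms")
}

#' @rdname monitoring_io
#' @export
read_performances <- function(path) {
  read_monitoring_csv(path, c("athlete_id", "date", "discipline", "time_s",
                              "previous_pb_s"),
                      validate_performances, "performances")
}

#' Read a cohort directory into athlete series
#'
#' Expects `sessions.csv`, `wellbeing.csv`, `poms.csv` and
#' `performances.csv` under `dir` and splits them by `athlete_id`.
#'
#' @param dir Directory containing the four CSV files.
#' @param start_date,n_weeks Study window passed to [athlete_series()];
#'   `start_date = NULL` infers the Monday of each athlete's earliest record.
#' @return Named list of [athlete_series()] objects.
#' @export
read_cohort <- function(dir, start_date = NULL, n_weeks = 26L) {
  s <- read_sessions(file.path(dir, "sessions.csv"))
  w <- read_wellbeing(file.path(dir, "wellbeing.csv"))
  p <- read_poms(file.path(dir, "poms.csv"))
  f <- read_performances(file.path(dir, "performances.csv"))
  ids <- sort(unique(c(s$athlete_id, w$athlete_id, p$athlete_id,
                       f$athlete_id)))
  out <- lapply(ids, function(id) {
    athlete_series(
      id,
      s[s$athlete_id == id, setdiff(names(s), "athlete_id")],
      w[w$athlete_id == id, setdiff(names(w), "athlete_id")],
      p[p$athlete_id == id, setdiff(names(p), "athlete_id")],
      f[f$athlete_id == id, setdiff(names(f), "athlete_id")],
      start_date = start_date, n_weeks = n_weeks
    )
  })
  stats::setNames(out, ids)
}

#' Write a cohort to the standard CSV files
#'
#' Writes `sessions.csv`, `wellbeing.csv`, `poms.csv`, `performances.csv`
#' for a list of athlete series, plus `truth.json` (rule, parameters and
#' true area ratio) when the cohort carries a generator config.
#'
#' @param cohort List of [athlete_series()] (e.g. from [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bind_stream <- function(field) {
    do.call(rbind, lapply(cohort, function(a) {
      df <- a[[field]]
      if (nrow(df) == 0) return(NULL)
      cbind(athlete_id = a$athlete_id, df)
    }))
  }
  streams <- list(sessions = "sessions.csv", wellbeing = "wellbeing.csv",
                  poms = "poms.csv", performances = "performances.csv")
  for (field in names(streams)) {
    df <- bind_stream(field)
    if (is.null(df)) df <- cbind(athlete_id = character(),
                                 get(paste0("empty_", field),
                                     mode = "function")())
    df$date <- format(df$date, "%Y-%m-%d")
    utils::write.csv(df, file.path(dir, streams[[field]]), row.names = FALSE)
  }
  config <- attr(cohort, "config")
  if (!is.null(config)) {
    truth <- list(
      rule = list(kind = config$rule$kind, params = config$rule$params,
                  true_area_ratio = config$rule$true_area_ratio),
      combo = config$combo, label_noise = config$label_noise,
      seed = config$seed, n_athletes = config$n_athletes,
      n_weeks = config$n_weeks
    )
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
               file.path(dir, "truth.json"))
  }
  invisible(dir)
}
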