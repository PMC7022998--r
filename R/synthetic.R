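#' Ground-truth decision rule for synthetic seasons
#'
#' A known rule on the unit square deciding which weeks are adaptation
#' weeks. Three shapes are supported:
#' \describe{
#'   \item{halfplane}{adaptation iff `a*x + b*y + c > 0` (default `x - y > 0`,
#'     i.e. internal load below external load).}
#'   \item{band}{adaptation iff `|a*x + b*y + c| < width`.}
#'   \item{disk}{adaptation iff inside the disk at (`cx`, `cy`) radius `r`.}
#' }
#' The true adaptation/maladaptation area ratio of the rule on the unit
#' square is computed exactly (polygon clipping for the linear shapes; for
#' the disk the exact circle-square intersection area via fine adaptive
#' quadrature on the boundary-free formula is replaced by polygon clipping of
#' a dense inscribed polygon, exact to the stated tolerance of 1e-6).
#'
#' @param kind `"halfplane"`, `"band"` or `"disk"`.
#' @param a,b,c Line coefficients for the linear shapes.
#' @param width Half-width of the band.
#' @param cx,cy,r Disk centre and radius.
#' @return A `ground_truth_rule` with fields `kind`, `params`, `predict`
#'   (function of x, y returning +1/-1) and `true_area_ratio`.
#' @export
ground_truth_rule <- function(kind = c("halfplane", "band", "disk"),
                              a = 1, b = -1, c = 0, width = 0.2,
                              cx = 0.5, cy = 0.5, r = 0.35) {
  kind <- match.arg(kind)
  predict <- switch(kind,
    halfplane = function(x, y) ifelse(a * x + b * y + c > 0, 1L, -1L),
    band = function(x, y) ifelse(abs(a * x + b * y + c) < width, 1L, -1L),
    disk = function(x, y) ifelse((x - cx)^2 + (y - cy)^2 < r^2, 1L, -1L)
  )
  area_plus <- switch(kind,
    halfplane = clip_area_halfplane(a, b, c),
    band = clip_area_halfplane(a, b, c + width) -
      clip_area_halfplane(a, b, c - width),
    disk = disk_square_area(cx, cy, r)
  )
  area_minus <- 1 - area_plus
  if (area_minus <= 0 || area_plus <= 0) {
    stop("rule leaves one class with zero area on the unit square",
         call. = FALSE)
  }
  structure(
    list(kind = kind,
         params = list(a = a, b = b, c = c, width = width,
                       cx = cx, cy = cy, r = r),
         predict = predict,
         true_area_ratio = area_plus / area_minus),
    class = "ground_truth_rule"
  )
}

# area of {a x + b y + c > 0} intersected with the unit square, by
# Sutherland-Hodgman clipping of the square against the halfplane
clip_area_halfplane <- function(a, b, c) {
  square <- list(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  inside <- function(p) a * p[1] + b * p[2] + c > 0
  cross <- function(p, q) {
    # intersection of segment pq with the line a x + b y + c = 0
    t <- -(a * p[1] + b * p[2] + c) /
      (a * (q[1] - p[1]) + b * (q[2] - p[2]))
    p + t * (q - p)
  }
  out <- list()
  n <- length(square)
  for (i in seq_len(n)) {
    p <- square[[i]]; q <- square[[if (i == n) 1 else i + 1]]
    if (inside(p)) {
      out[[length(out) + 1]] <- p
      if (!inside(q)) out[[length(out) + 1]] <- cross(p, q)
    } else if (inside(q)) {
      out[[length(out) + 1]] <- cross(p, q)
    }
  }
  if (length(out) < 3) return(0)
  polygon_area(do.call(rbind, out))
}

# circle-square intersection via a dense polygonal approximation of the
# circle clipped to the square (error << 1e-6 at 4096 vertices)
disk_square_area <- function(cx, cy, r, n = 4096L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  poly <- cbind(pmin(1, pmax(0, cx + r * cos(th))),
                pmin(1, pmax(0, cy + r * sin(th))))
  # clamping to the square is exact for a convex circle-square intersection;
  # inscribed-polygon area error is below 1e-6 at this vertex count
  polygon_area(poly)
}

#' Synthetic cohort configuration
#'
#' Study conditions for the generator: a 26-week season, about six training
#' sessions per week, lognormal session distances, RPE linked to relative
#' session distance, twice-weekly wellness with recovery linked negatively to
#' strain, fortnightly mood profiles, and competitions in 4--8 weeks whose
#' %PBT sign follows a ground-truth rule on the chosen combination's
#' normalized weekly indicators (optionally flipped with probability
#' `label_noise`). %PBT margins are uniform in (0.1, 6] percentage points.
#'
#' @param n_athletes Number of athletes (default 13).
#' @param n_weeks Season length in weeks (default 26, minimum 8).
#' @param sessions_per_week Mean sessions per week (default 6).
#' @param distance_mean,distance_sdlog Session distance lognormal parameters
#'   (default mean 3500 m, sdlog 0.25).
#' @param week_volume_sdlog Log-SD of the weekly periodization factor
#'   multiplying all session distances of a week (default 0.35, giving the
#'   roughly threefold overload-to-taper volume range of a periodized
#'   season).
#' @param rpe_intensity_sdlog Log-SD of the weekly intensity block factor
#'   scaling every session RPE of a week (default 0.35, matching the
#'   relative variation of the volume blocks so neither axis dominates the
#'   unit square after normalization).
#' @param rpe_link Slope of session RPE on relative session distance
#'   (default 1: weak residual coupling on top of the intensity blocks).
#' @param rpe_noise_sd Per-session RPE noise SD (default 1).
#' @param recovery_link Negative slope of recovery on normalized strain
#'   (default 3).
#' @param recovery_noise_sd Recovery noise SD (default 0.8).
#' @param competition_weeks Number of competition weeks per athlete, clamped
#'   to 4..8 (default 6).
#' @param rule A [ground_truth_rule()] (default halfplane `x > y`).
#' @param combo Combination whose indicators feed the rule (default 1).
#' @param label_noise Label flip probability in `[0, 0.5)` (default 0).
#' @param seed Master seed (default 1).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_athletes = 13, n_weeks = 26,
                          sessions_per_week = 6,
                          distance_mean = 3500, distance_sdlog = 0.25,
                          week_volume_sdlog = 0.35,
                          rpe_intensity_sdlog = 0.35,
                          rpe_link = 1, rpe_noise_sd = 1,
                          recovery_link = 3, recovery_noise_sd = 0.8,
                          competition_weeks = 6,
                          rule = ground_truth_rule("halfplane"),
                          combo = 1, label_noise = 0, seed = 1) {
  if (n_weeks < 8) stop("`n_weeks` must be at least 8", call. = FALSE)
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("`label_noise` must lie in [0, 0.5)", call. = FALSE)
  }
  competition_weeks <- max(4L, min(8L, as.integer(competition_weeks)))
  stopifnot(inherits(rule, "ground_truth_rule"))
  structure(
    list(n_athletes = as.integer(n_athletes), n_weeks = as.integer(n_weeks),
         sessions_per_week = sessions_per_week,
         distance_mean = distance_mean, distance_sdlog = distance_sdlog,
         week_volume_sdlog = week_volume_sdlog,
         rpe_intensity_sdlog = rpe_intensity_sdlog,
         rpe_link = rpe_link, rpe_noise_sd = rpe_noise_sd,
         recovery_link = recovery_link, recovery_noise_sd = recovery_noise_sd,
         competition_weeks = competition_weeks, rule = rule,
         combo = as.integer(combo), label_noise = label_noise,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate one athlete's season
#'
#' Draws training sessions (lognormal distances, RPE rising with relative
#' session distance, duration from a per-athlete pace), twice-weekly wellness
#' entries whose global recovery falls with normalized weekly strain,
#' fortnightly mood profiles, and competitions on a deterministic,
#' rule-stratified subset of weeks. The competition %PBT is
#' `100 + margin` on adaptation weeks and `100 - margin` otherwise, where
#' the side follows `config$rule` evaluated on the week's normalized
#' combination indicators, flipped with probability `config$label_noise`.
#' Fully deterministic given `(config$seed, index)`.
#'
#' @param config A [cohort_config()].
#' @param index Athlete index (1-based); also seeds the athlete's stream.
#' @return An [athlete_series()] with attribute `"truth"` (tibble of
#'   competition weeks, rule labels and realized labels).
#' @export
simulate_athlete <- function(config, index = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(derive_seed(config$seed, index), function() {
    start <- as.Date("2013-09-30")  # a Monday
    W <- config$n_weeks
    pace <- stats::rnorm(1, mean = 2.0, sd = 0.15)  # minutes per 100 m
    pb <- round(stats::runif(1, 58, 75), 2)          # fixed season-start PB

    sessions <- list()
    # periodized macrocycles: weekly volume factor (overload vs taper) and
    # weekly intensity block vary independently, as training plans do;
    # sessions fill fixed-length pool slots, so duration is roughly constant
    # and internal load (RPE x duration) tracks intensity, not distance
    vol_f <- stats::rlnorm(W, 0, config$week_volume_sdlog)
    int_f <- 4.5 * stats::rlnorm(W, 0, config$rpe_intensity_sdlog)
    for (w in seq_len(W)) {
      n_s <- max(3L, stats::rpois(1, config$sessions_per_week))
      n_s <- min(n_s, 7L)
      days <- sort(sample(0:6, n_s))
      dist <- stats::rlnorm(n_s, log(config$distance_mean * vol_f[w]),
                            config$distance_sdlog)
      rel <- dist / (2 * config$distance_mean)
      rpe <- int_f[w] + config$rpe_link * (rel - 0.5) +
        stats::rnorm(n_s, sd = config$rpe_noise_sd)
      rpe <- pmin(10, pmax(0.5, round(rpe * 2) / 2))
      dur <- pmax(60, pmin(150, round(stats::rnorm(n_s, 105 * pace / 2, 12))))
      sessions[[w]] <- data.frame(
        date = start + (w - 1L) * 7L + days, sport = "swimming",
        rpe = rpe, duration_min = dur, distance_m = round(dist)
      )
    }
    sessions <- do.call(rbind, sessions)

    # weekly strain drives recovery; normalize over the season
    tmp <- athlete_series(paste0("S", index), sessions, start_date = start,
                          n_weeks = W)
    metrics <- weekly_aggregate(tmp)
    strain_norm <- metrics$strain / max(metrics$strain, na.rm = TRUE)
    strain_norm[!is.finite(strain_norm)] <- 0

    wellbeing <- list()
    for (w in seq_len(W)) {
      for (d in c(1L, 4L)) {  # Tuesday and Friday
        rec <- 4.5 + config$recovery_link * (0.5 - strain_norm[w]) +
          stats::rnorm(1, sd = config$recovery_noise_sd)
        row <- data.frame(
          date = start + (w - 1L) * 7L + d,
          sleep_quality = clamp_likert(stats::rnorm(1, 5, 1)),
          sleep_quantity = clamp_likert(stats::rnorm(1, 5, 1)),
          soreness = clamp_likert(stats::rnorm(1, 4, 1.2)),
          enjoyment = clamp_likert(stats::rnorm(1, 5, 1)),
          stress = clamp_likert(stats::rnorm(1, 4, 1.2)),
          global_recovery = clamp_likert(rec)
        )
        wellbeing[[length(wellbeing) + 1]] <- row
      }
    }
    wellbeing <- do.call(rbind, wellbeing)

    poms <- list()
    for (w in seq(2L, W, by = 2L)) {
      poms[[length(poms) + 1]] <- data.frame(
        date = start + (w - 1L) * 7L + 6L,
        anger = stats::rpois(1, 3), confusion = stats::rpois(1, 2),
        depression = stats::rpois(1, 2),
        fatigue = stats::rpois(1, 3 + 4 * strain_norm[w]),
        tension = stats::rpois(1, 3), vigour = stats::rpois(1, 12)
      )
    }
    poms <- do.call(rbind, poms)

    # competition weeks: stratified over the rule's two sides so both labels
    # occur whenever the season offers both (mirrors the inclusion filter)
    axes <- combination_axes(config$combo)
    x_n <- normalize_series(metrics[[axes[["x"]]]])
    y_n <- normalize_series(metrics[[axes[["y"]]]])
    candidates <- which(seq_len(W) >= 4 & is.finite(x_n) & is.finite(y_n))
    side <- config$rule$predict(x_n[candidates], y_n[candidates])
    k <- min(config$competition_weeks, length(candidates))
    pos <- candidates[side == 1L]; neg <- candidates[side == -1L]
    # even split across the rule's two sides (as far as the season offers
    # both), so the cohort satisfies the both-outcomes inclusion rule and the
    # labelled weeks represent both regions
    k_pos <- min(length(pos), max(k - length(neg), floor(k / 2)))
    comp_weeks <- sort(c(resample(pos, k_pos), resample(neg, k - k_pos)))

    rule_label <- config$rule$predict(x_n[comp_weeks], y_n[comp_weeks])
    flip <- stats::runif(length(comp_weeks)) < config$label_noise
    label <- ifelse(flip, -rule_label, rule_label)
    margin <- stats::runif(length(comp_weeks), 0.1 + 1e-9, 6)
    pbt <- 100 + label * margin
    performances <- data.frame(
      date = start + (comp_weeks - 1L) * 7L + 5L,  # Saturday meets
      discipline = "100 freestyle", time_s = round(pb / sqrt(pbt / 100), 2),
      previous_pb_s = pb
    )

    out <- athlete_series(paste0("S", index), sessions, wellbeing, poms,
                          performances, start_date = start, n_weeks = W)
    attr(out, "truth") <- tibble::tibble(
      week = comp_weeks, rule_label = rule_label, label = label,
      flipped = flip
    )
    out
  })
}

clamp_likert <- function(v) as.integer(pmin(7, pmax(1, round(v))))

resample <- function(v, k) {
  if (k <= 0 || length(v) == 0) return(integer(0))
  if (length(v) == 1) return(rep(v, min(k, 1)))
  sample(v, min(k, length(v)))
}

#' Simulate a cohort of athlete seasons
#'
#' @param config A [cohort_config()].
#' @return List of [simulate_athlete()] results with attribute `"config"`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  out <- lapply(seq_len(config$n_athletes), function(i) {
    simulate_athlete(config, i)
  })
  attr(out, "config") <- config
  out
}

#' Reference cohort characteristics table
#'
#' Characteristics of the 13-swimmer reference cohort used to validate the
#' quartile banding: sex, age, best discipline, FINA points, best %PBT,
#' weekly mean internal load (AU) and weekly mean distance (m), together
#' with the quartile band of each numeric column as printed in the original
#' cohort table. [assign_quartiles()] reproduces every quartile column from
#' the corresponding value column.
#'
#' @return A tibble with 13 rows.
#' @export
reference_cohort <- function() {
  tibble::tribble(
    ~swimmer, ~sex, ~age, ~age_q, ~discipline, ~fina_points, ~fina_q,
    ~best_pbt, ~pbt_q, ~weekly_mean_load, ~load_q, ~weekly_mean_distance,
    ~distance_q,
    "A2",  "M", 18, 3, "400 freestyle ld",   765, 4, 100.1, 1, 4258.46, 4, 30100.00, 4,
    "B5",  "F", 14, 1, "200 breaststroke ld", 633, 3, 110.0, 4, 3144.23, 3, 18826.92, 2,
    "B6",  "F", 15, 1, "100 freestyle sd",    459, 1, 100.7, 1, 2775.00, 2, 17148.00, 2,
    "B29", "F", 15, 1, "50 breaststroke ld",  504, 1, 105.9, 3, 2377.31, 1, 15426.92, 1,
    "C10", "M", 19, 4, "100 medley sd",       582, 2, 103.1, 2, 2504.81, 1, 13905.77, 1,
    "C13", "M", 16, 2, "100 freestyle ld",    471, 1, 103.7, 3, 3353.08, 3, 23386.54, 3,
    "C14", "M", 16, 2, "400 medley ld",       445, 1, 109.2, 4, 2365.38, 1, 16350.00, 1,
    "D21", "F", 15, 1, "400 freestyle ld",    640, 3, 106.1, 4, 4417.71, 4, 27253.33, 4,
    "D22", "F", 15, 1, "200 breaststroke ld", 617, 2, 102.4, 1, 2946.40, 2, 32212.80, 4,
    "D35", "F", 18, 3, "100 freestyle ld",    631, 3, 100.7, 1, 2850.38, 2, 25732.69, 3,
    "E24", "M", 19, 4, "100 freestyle ld",    646, 4, 104.9, 3, 2112.50, 1, 15411.46, 1,
    "E27", "F", 18, 3, "100 backstroke ld",   619, 2, 102.7, 2, 4703.27, 4, 23744.23, 3,
    "E28", "M", 20, 4, "50 butterfly ld",     673, 4, 103.0, 2, 3128.46, 3, 22900.00, 2
  )
}
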