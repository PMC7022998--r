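#' Jittering configuration
#'
#' Settings for the noise-augmentation ensemble: Gaussian noise with standard
#' deviation `noise_level` times each raw series' sample SD is added to the
#' x, y and z series before normalization and binarization (`"relative_sd"`
#' mode); `"multiplicative"` scales each value by `1 + N(0, noise_level)`
#' instead.
#'
#' @param noise_level Noise fraction (default 0.10).
#' @param replicates Ensemble size (default 50).
#' @param seed Master RNG seed; replicate `r` uses an independent stream
#'   derived from it.
#' @param mode `"relative_sd"` (default) or `"multiplicative"`.
#' @return A `jitter_config` list.
#' @export
jitter_config <- function(noise_level = 0.10, replicates = 50, seed = 1,
                          mode = c("relative_sd", "multiplicative")) {
  mode <- match.arg(mode)
  if (noise_level < 0) stop("`noise_level` must be >= 0", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  structure(list(noise_level = noise_level,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), mode = mode),
            class = "jitter_config")
}

#' Jitter the raw weekly series of one replicate
#'
#' Adds independent Gaussian noise to the raw (pre-normalization) x, y and z
#' series. The noise SD per series is `noise_level` times that series'
#' sample SD, so labels of weeks whose %PBT sits near 100 can flip between
#' replicates. Output is deterministic given `(config$seed, replicate)` and
#' clipped at zero so the series stay non-negative.
#'
#' @param x_raw,y_raw,z_raw Raw weekly series (`z_raw` is %PBT, `NA` in weeks
#'   without competition).
#' @param config A [jitter_config()].
#' @param replicate Replicate index (1-based).
#' @return List with perturbed `x`, `y`, `z`.
#' @export
jitter_series <- function(x_raw, y_raw, z_raw, config, replicate = 1L) {
  stopifnot(inherits(config, "jitter_config"))
  if (config$noise_level == 0) {
    return(list(x = x_raw, y = y_raw, z = z_raw))
  }
  with_local_seed(derive_seed(config$seed, replicate), function() {
    perturb <- function(v) {
      ok <- is.finite(v)
      if (!any(ok)) return(v)
      out <- v
      if (config$mode == "relative_sd") {
        s <- stats::sd(v[ok])
        if (!is.finite(s) || s == 0) return(v)
        out[ok] <- v[ok] + stats::rnorm(sum(ok), sd = config$noise_level * s)
      } else {
        out[ok] <- v[ok] * (1 + stats::rnorm(sum(ok), sd = config$noise_level))
      }
      pmax(out, 0)
    }
    list(x = perturb(x_raw), y = perturb(y_raw), z = perturb(z_raw))
  })
}

#' Jittered ensemble fit for one athlete-combination
#'
#' Creates `config$replicates` noise-perturbed copies of the raw weekly
#' series, refits the geometric model and GAPI on each, and combines the
#' outputs by simple averaging (arithmetic means of GAPI and goodness of
#' fit) plus a per-cell modal label map for visualization. Replicates whose
#' perturbed labels collapse to a single class (or that otherwise produce a
#' degenerate map) are recorded and excluded from the means, with a warning.
#' With `noise_level = 0` all members are provably identical, so the model is
#' fitted once and replicated.
#'
#' @param metrics A `weekly_metrics` tibble ([weekly_aggregate()]), or an
#'   [athlete_series()] (aggregated internally).
#' @param combo Combination id in 1..5.
#' @param config A [jitter_config()].
#' @param layer_width,delta,grid_resolution,k_max Passed to [fit_geometry()].
#' @return An `ensemble_result`: tibble `members` (replicate, areas, gapi,
#'   gof, degenerate flag), `mean_gapi`, `mean_gof`, `gapi_sd`,
#'   `majority_map` (matrix of modal labels), `config`, `n_excluded`.
#' @export
run_ensemble <- function(metrics, combo, config = jitter_config(),
                         layer_width = 0.01, delta = 0.02,
                         grid_resolution = 256, k_max = 4) {
  if (inherits(metrics, "athlete_series")) metrics <- weekly_aggregate(metrics)
  axes <- combination_axes(combo)
  x_raw <- metrics[[axes[["x"]]]]
  y_raw <- metrics[[axes[["y"]]]]
  z_raw <- metrics$best_pbt
  week <- metrics$week

  fit_one <- function(xj, yj, zj) {
    keep <- is.finite(xj) & is.finite(yj)
    tr <- tibble::tibble(week = week[keep],
                         x = normalize_series(xj[keep]),
                         y = normalize_series(yj[keep]),
                         z_pct = zj[keep])
    tr$label <- binarize_pbt(tr$z_pct)
    fit_geometry(tr, layer_width = layer_width, delta = delta,
                 grid_resolution = grid_resolution, k_max = k_max)
  }

  R <- config$replicates
  fits <- vector("list", R)
  if (config$noise_level == 0) {
    fit <- fit_one(x_raw, y_raw, z_raw)
    for (r in seq_len(R)) fits[[r]] <- fit
  } else {
    for (r in seq_len(R)) {
      jit <- jitter_series(x_raw, y_raw, z_raw, config, r)
      fits[[r]] <- tryCatch(fit_one(jit$x, jit$y, jit$z),
                            error = function(e) e)
    }
  }

  degenerate <- vapply(fits, inherits, logical(1), what = "condition")
  if (any(degenerate)) {
    warning(sum(degenerate), " replicate(s) produced a degenerate map and ",
            "were excluded from the ensemble means", call. = FALSE)
  }
  members <- tibble::tibble(
    replicate = seq_len(R),
    area_adapt = NA_real_, area_malad = NA_real_, area_neutral = NA_real_,
    gapi = NA_real_, gof = NA_real_, degenerate = degenerate
  )
  for (r in which(!degenerate)) {
    f <- fits[[r]]
    members$area_adapt[r] <- f$areas[["area_adapt"]]
    members$area_malad[r] <- f$areas[["area_malad"]]
    members$area_neutral[r] <- f$areas[["area_neutral"]]
    members$gapi[r] <- f$gapi
    members$gof[r] <- f$goodness_of_fit
  }
  ok_gapi <- members$gapi[!degenerate & is.finite(members$gapi)]
  ok_gof <- members$gof[!degenerate]

  majority_map <- NULL
  if (any(!degenerate)) {
    regs <- lapply(fits[!degenerate], function(f) f$map$region)
    res <- nrow(regs[[1]])
    plus <- Reduce(`+`, lapply(regs, function(m) (m == 1L) + 0L))
    minus <- Reduce(`+`, lapply(regs, function(m) (m == -1L) + 0L))
    neut <- length(regs) - plus - minus
    majority_map <- matrix(0L, res, res)
    majority_map[plus >= minus & plus >= neut] <- 1L
    majority_map[minus > plus & minus >= neut] <- -1L
  }

  structure(
    list(members = members,
         mean_gapi = if (length(ok_gapi)) mean(ok_gapi) else NA_real_,
         mean_gof = if (length(ok_gof)) mean(ok_gof) else NA_real_,
         gapi_sd = if (length(ok_gapi) > 1) stats::sd(ok_gapi) else 0,
         n_infinite = sum(!degenerate & !is.finite(members$gapi)),
         n_excluded = sum(degenerate),
         majority_map = majority_map,
         single_fit = if (any(!degenerate)) fits[[which(!degenerate)[1]]],
         config = config,
         combo = as.integer(combo),
         geometry = list(layer_width = layer_width, delta = delta,
                         grid_resolution = grid_resolution, k_max = k_max)),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result> combination ", x$combo, ", ",
      x$config$replicates, " replicates @ noise ", x$config$noise_level,
      "\n  mean GAPI: ", signif(x$mean_gapi, 4),
      " (sd ", signif(x$gapi_sd, 3), ")",
      "\n  mean GOF : ", signif(x$mean_gof, 4), "%",
      if (x$n_excluded > 0) paste0("\n  excluded : ", x$n_excluded,
                                   " degenerate replicate(s)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Serialize an ensemble report to JSON
#'
#' Per-member areas/GAPI/GOF, the simple-average summary and the full
#' configuration (seed, layer width, buffer, resolution, noise, replicates).
#'
#' @param result An [run_ensemble()] result.
#' @param path Output file; when `NULL` the JSON string is returned.
#' @return JSON string, invisibly when written to a file.
#' @export
ensemble_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "ensemble_result"))
  obj <- list(
    combination = result$combo,
    config = c(unclass(result$config), result$geometry),
    summary = list(mean_gapi = result$mean_gapi, mean_gof = result$mean_gof,
                   gapi_sd = result$gapi_sd, n_excluded = result$n_excluded,
                   n_infinite = result$n_infinite),
    members = result$members
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
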