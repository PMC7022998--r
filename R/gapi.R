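#' Geometric Activity Performance Index
#'
#' GAPI is the ratio of the adaptation area to the maladaptation area of a
#' fitted domain map. Values above 1 mean the adaptation region dominates.
#' A zero maladaptation area yields `Inf` (flagged, not an error); both areas
#' zero is a degenerate map and an error.
#'
#' @param areas Named vector from [region_areas()], or a `domain_map`.
#' @return The GAPI ratio (possibly `Inf`).
#' @export
gapi <- function(areas) {
  if (inherits(areas, "domain_map")) areas <- region_areas(areas)
  a <- areas[["area_adapt"]]; m <- areas[["area_malad"]]
  if (a < 0 || m < 0) stop("areas must be non-negative", call. = FALSE)
  if (a == 0 && m == 0) {
    stop("degenerate map: both labelled areas are zero", call. = FALSE)
  }
  if (m == 0) {
    warning("maladaptation area is zero; GAPI is infinite", call. = FALSE)
    return(Inf)
  }
  a / m
}

#' Goodness of fit of a domain map
#'
#' Percentage of labelled weeks whose point falls in the region matching
#' their adaptation label, rounded half-up to an integer percent (so 7/8
#' correct is 88 and 5/8 is 63). Points in the neutral layer are resolved to
#' the nearest labelled region before scoring.
#'
#' @param map A [build_domain_map()] result.
#' @param points Data frame with `x`, `y`, `label` (only labelled rows are
#'   scored).
#' @return Integer percent in 0..100.
#' @export
goodness_of_fit <- function(map, points) {
  pts <- as.data.frame(points)
  pts <- pts[!is.na(pts$label), , drop = FALSE]
  if (nrow(pts) == 0) stop("no labelled points to score", call. = FALSE)
  pred <- classify_point(map, as.matrix(pts[, c("x", "y")]),
                         resolve_neutral = TRUE)
  round_half_up(100 * mean(pred == pts$label))
}

# mean cross-entropy diagnostic of the hard region predictions against the
# labels; hard 0/1 confidences are clamped at `clamp` to keep it finite
mean_cross_entropy <- function(map, points, clamp = 1e-3) {
  pts <- as.data.frame(points)
  pts <- pts[!is.na(pts$label), , drop = FALSE]
  pred <- classify_point(map, as.matrix(pts[, c("x", "y")]),
                         resolve_neutral = TRUE)
  correct <- pred == pts$label
  -mean(ifelse(correct, log(1 - clamp), log(clamp)))
}

#' Fit the geometric adaptation model to one athlete-combination
#'
#' The full single-model pipeline on labelled weekly triplets: cluster each
#' label class under the three dissimilarities (Bray-Curtis, Chebyshev,
#' normalized squared Euclidean), keep the solution with the fewest patterns,
#' convexify every cluster, build the nearest-region domain map, and compute
#' areas, GAPI and goodness of fit.
#'
#' @param triplets A `weekly_triplets` data frame ([build_combination()]);
#'   only labelled (competition) weeks enter the geometry.
#' @param layer_width Neutral layer width (default 0.01).
#' @param delta Degenerate-hull buffer radius (default 0.02).
#' @param grid_resolution Cells per axis (default 256).
#' @param k_max Maximum clusters per label class (default 4).
#' @return A `gapi_result`: list with `areas`, `gapi`, `goodness_of_fit`,
#'   `mce`, `per_point` (week, label, predicted, correct), `map`,
#'   `clustering`.
#' @export
fit_geometry <- function(triplets, layer_width = 0.01, delta = 0.02,
                         grid_resolution = 256, k_max = 4) {
  pts <- as.data.frame(triplets)
  pts <- pts[!is.na(pts$label), , drop = FALSE]
  if (nrow(pts) < 2) stop("need at least 2 labelled weeks", call. = FALSE)
  if (!any(pts$label == 1L) || !any(pts$label == -1L)) {
    stop("need both an adaptation and a maladaptation week; ",
         "the inclusion prerequisites guarantee this", call. = FALSE)
  }
  solutions <- lapply(pattern_metrics, function(m) {
    cluster_patterns(pts, metric = m, k_max = k_max)
  })
  sol <- select_sparsest_solution(solutions)
  patterns <- lapply(sort(unique(sol$assignments)), function(cid) {
    idx <- sol$assignments == cid
    convexify(pts[idx, c("x", "y")], label = pts$label[which(idx)[1]],
              delta = delta, cluster_id = cid)
  })
  map <- build_domain_map(patterns, layer_width = layer_width,
                          grid_resolution = grid_resolution)
  areas <- region_areas(map)
  pred <- classify_point(map, as.matrix(pts[, c("x", "y")]),
                         resolve_neutral = TRUE)
  per_point <- tibble::tibble(
    week = if ("week" %in% names(pts)) pts$week else seq_len(nrow(pts)),
    label = pts$label, predicted = pred, correct = pred == pts$label
  )
  structure(
    list(areas = areas, gapi = gapi(areas),
         goodness_of_fit = round_half_up(100 * mean(per_point$correct)),
         mce = mean_cross_entropy(map, pts),
         per_point = per_point, map = map, clustering = sol),
    class = "gapi_result"
  )
}

#' @export
print.gapi_result <- function(x, ...) {
  cat("<gapi_result>\n",
      "  GAPI            : ", signif(x$gapi, 4), "\n",
      "  goodness of fit : ", x$goodness_of_fit, "%\n",
      "  areas (A/M/N)   : ", paste(signif(x$areas, 4), collapse = " / "),
      "\n  patterns        : ", x$clustering$n_patterns,
      " (", x$clustering$metric, ")\n", sep = "")
  invisible(x)
}
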