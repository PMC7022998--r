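#' Build the adaptation/maladaptation domain map
#'
#' Partitions the unit square among the convex patterns by the
#' nearest-region rule: every grid cell centre takes the label of the pattern
#' minimizing the Euclidean point-to-hull distance (zero inside a hull; a
#' cell covered by overlapping hulls of both labels goes to the hull with the
#' nearest centroid). Cells within `layer_width` of the inter-label frontier
#' form a neutral separating layer, mirroring the thin layers that disconnect
#' the domains of influence and stabilise the area integration. The
#' zero-level contour of the signed distance field is extracted as the
#' boundary polyline set.
#'
#' @param patterns List of [convexify()] patterns, at least one per label.
#' @param layer_width Neutral layer half-thickness \eqn{\epsilon} in
#'   unit-square units (default 0.01).
#' @param grid_resolution Cells per axis (default 256; minimum 32, below
#'   which the area integration is too coarse).
#' @return A `domain_map` object with fields `patterns`, `layer_width`,
#'   `grid_resolution`, `region` (matrix of +1/-1/0 labels, 0 = neutral),
#'   `hard` (matrix of +1/-1 labels with the layer resolved to the nearest
#'   labelled region), `field` (signed distance difference; negative on the
#'   adaptation side) and `boundary` (list of polylines).
#' @export
build_domain_map <- function(patterns, layer_width = 0.01,
                             grid_resolution = 256) {
  if (grid_resolution < 32) {
    stop("`grid_resolution` below 32 makes the integration too coarse",
         call. = FALSE)
  }
  if (layer_width < 0) stop("`layer_width` must be >= 0", call. = FALSE)
  labs <- vapply(patterns, function(p) p$label, integer(1))
  if (!any(labs == 1L) || !any(labs == -1L)) {
    stop("need at least one pattern per label", call. = FALSE)
  }
  res <- as.integer(grid_resolution)
  centers <- (seq_len(res) - 0.5) / res
  px <- rep(centers, times = res)   # x fastest
  py <- rep(centers, each = res)

  ncell <- res * res
  d_plus <- rep(Inf, ncell); d_minus <- rep(Inf, ncell)
  cd_plus <- rep(Inf, ncell); cd_minus <- rep(Inf, ncell) # centroid distances
  for (p in patterns) {
    d <- point_hull_distance(px, py, p$vertices)
    cd <- (px - p$centroid[1])^2 + (py - p$centroid[2])^2
    if (p$label == 1L) {
      covered <- d == 0
      cd_plus[covered] <- pmin(cd_plus[covered], cd[covered])
      d_plus <- pmin(d_plus, d)
    } else {
      covered <- d == 0
      cd_minus[covered] <- pmin(cd_minus[covered], cd[covered])
      d_minus <- pmin(d_minus, d)
    }
  }
  g <- d_plus - d_minus
  both_zero <- d_plus == 0 & d_minus == 0

  hard <- ifelse(g < 0, 1L, -1L)
  hard[g == 0] <- ifelse(cd_plus[g == 0] <= cd_minus[g == 0], 1L, -1L)
  region <- hard
  neutral <- !both_zero & abs(g) <= layer_width & layer_width > 0
  # equidistant cells outside any hull sit exactly on the frontier
  neutral <- neutral | (g == 0 & !both_zero)
  region[neutral] <- 0L

  field <- matrix(g, nrow = res)
  boundary <- grDevices::contourLines(x = centers, y = centers, z = field,
                                      levels = 0)
  structure(
    list(patterns = patterns, layer_width = layer_width,
         grid_resolution = res, centers = centers,
         region = matrix(region, nrow = res),
         hard = matrix(hard, nrow = res),
         field = field, boundary = boundary),
    class = "domain_map"
  )
}

#' @export
print.domain_map <- function(x, ...) {
  a <- region_areas(x)
  cat("<domain_map> ", length(x$patterns), " patterns, grid ",
      x$grid_resolution, "^2, layer 2*", x$layer_width, "\n",
      "  areas: adaptation ", signif(a[["area_adapt"]], 4),
      " | maladaptation ", signif(a[["area_malad"]], 4),
      " | neutral ", signif(a[["area_neutral"]], 4), "\n", sep = "")
  invisible(x)
}

cell_index <- function(map, q) {
  pmin(map$grid_resolution, pmax(1L, ceiling(q * map$grid_resolution)))
}

#' Classify a point on the domain map
#'
#' Looks up the grid cell of `q` and returns its region label: `+1`
#' (adaptation), `-1` (maladaptation) or `0` (neutral layer). With
#' `resolve_neutral = TRUE` a point in the layer is assigned the nearest
#' labelled region instead — the rule used when scoring training points.
#'
#' @param map A [build_domain_map()] result.
#' @param q Length-2 coordinate vector, or an n x 2 matrix of points, inside
#'   the unit square.
#' @param resolve_neutral Resolve layer cells to the nearest labelled region.
#' @return Integer label(s).
#' @export
classify_point <- function(map, q, resolve_neutral = FALSE) {
  stopifnot(inherits(map, "domain_map"))
  q <- if (is.null(dim(q))) matrix(q, ncol = 2) else as.matrix(q)
  if (any(q < 0) || any(q > 1)) {
    stop("point(s) outside the unit square", call. = FALSE)
  }
  ix <- cell_index(map, q[, 1])
  iy <- cell_index(map, q[, 2])
  src <- if (resolve_neutral) map$hard else map$region
  out <- src[cbind(ix, iy)]
  as.integer(out)
}

#' Region areas of a domain map
#'
#' Fractions of the unit square covered by the adaptation region, the
#' maladaptation region and the neutral layer, by grid-cell counting at the
#' map's resolution. The three fractions sum to 1.
#'
#' @param map A [build_domain_map()] result.
#' @return Named numeric vector `area_adapt`, `area_malad`, `area_neutral`.
#' @export
region_areas <- function(map) {
  stopifnot(inherits(map, "domain_map"))
  r <- map$region
  c(area_adapt = mean(r == 1L), area_malad = mean(r == -1L),
    area_neutral = mean(r == 0L))
}

#' Serialize a domain map to JSON
#'
#' Writes the pattern polygons, layer width, resolution, areas and boundary
#' polylines (not the full grid) as a JSON document.
#'
#' @param map A [build_domain_map()] result.
#' @param path Output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
domain_map_json <- function(map, path = NULL) {
  obj <- list(
    layer_width = map$layer_width,
    grid_resolution = map$grid_resolution,
    areas = as.list(region_areas(map)),
    patterns = lapply(map$patterns, function(p) list(
      cluster_id = p$cluster_id, label = p$label,
      vertices = unname(p$vertices)
    )),
    boundary = lapply(map$boundary, function(b) list(x = b$x, y = b$y))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Plot a domain map in the region-map style
#'
#' Yellow adaptation region, blue maladaptation region, white separating
#' layer; labelled week points drawn green (+1) / red (-1), misclassified
#' weeks ringed in black.
#'
#' @param map A [build_domain_map()] result.
#' @param points Optional `weekly_triplets`-like data frame with `x`, `y`,
#'   `label` (and optionally `week` for dot labels).
#' @param file Optional output path (`.svg`, `.png`, `.pdf`); the plot is
#'   saved with [ggplot2::ggsave()].
#' @return The ggplot object.
#' @export
plot_domain_map <- function(map, points = NULL, file = NULL) {
  res <- map$grid_resolution
  df <- data.frame(
    x = rep(map$centers, times = res),
    y = rep(map$centers, each = res),
    region = factor(as.vector(map$region), levels = c(1, 0, -1),
                    labels = c("adaptation", "neutral", "maladaptation"))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = region)) +
    ggplot2::scale_fill_manual(values = c(adaptation = "#f5d547",
                                          neutral = "white",
                                          maladaptation = "#4a7fb5")) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    pts <- as.data.frame(points)
    pts <- pts[!is.na(pts$label), , drop = FALSE]
    pts$observed <- factor(pts$label, levels = c(1, -1),
                           labels = c("improvement", "no improvement"))
    pts$misclassified <- classify_point(map, as.matrix(pts[, c("x", "y")]),
                                        resolve_neutral = TRUE) != pts$label
    p <- p +
      ggplot2::geom_point(
        data = pts,
        ggplot2::aes(colour = observed), size = 3
      ) +
      ggplot2::geom_point(
        data = pts[pts$misclassified, , drop = FALSE],
        shape = 21, size = 5, colour = "black", fill = NA
      ) +
      ggplot2::scale_colour_manual(values = c(improvement = "#1a9641",
                                              `no improvement` = "#d7191c"))
    if ("week" %in% names(pts)) {
      p <- p + ggplot2::geom_text(data = pts,
                                  ggplot2::aes(label = week),
                                  size = 2.5, nudge_y = 0.025)
    }
  }
  if (!is.null(file)) {
    dev <- if (grepl("\\.svg$", file)) grDevices::svg else NULL
    ggplot2::ggsave(file, p, width = 6, height = 6, device = dev)
  }
  p
}
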