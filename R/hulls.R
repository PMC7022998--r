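#' Convexify a cluster into a pattern with positive area
#'
#' Builds the convex hull polygon of a cluster's points. Degenerate clusters
#' — a single point, a pair, or a collinear set — are buffered by radius
#' `delta` into a disk or capsule (polygonal approximation) so that every
#' pattern has positive area and a well-defined interior.
#'
#' @param xy Matrix or data frame of cluster coordinates (n x 2).
#' @param label Class label of the cluster, +1 or -1.
#' @param delta Buffer radius for degenerate clusters, in unit-square units
#'   (default 0.02).
#' @param cluster_id Optional integer id carried through to the pattern.
#' @return A `convex_pattern`: list with `cluster_id`, `label`, `vertices`
#'   (m x 2 matrix, open ring in counter-clockwise order) and `centroid`.
#' @export
convexify <- function(xy, label, delta = 0.02, cluster_id = NA_integer_) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 1) stop("a pattern needs at least one point", call. = FALSE)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  stopifnot(label %in% c(-1, 1))

  verts <- if (nrow(xy) == 1) {
    disk_polygon(xy[1, ], delta)
  } else {
    hull_idx <- grDevices::chull(xy[, 1], xy[, 2])
    hull <- xy[hull_idx, , drop = FALSE]
    if (nrow(hull) >= 3 && polygon_area(hull) > 1e-12) {
      ccw(hull)
    } else {
      # collinear (or coincident) set: capsule around the extreme segment
      capsule_polygon(xy, delta)
    }
  }
  structure(
    list(cluster_id = as.integer(cluster_id), label = as.integer(label),
         vertices = verts, centroid = colMeans(xy), points = xy,
         delta = delta),
    class = "convex_pattern"
  )
}

# signed shoelace area (positive for counter-clockwise rings)
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

ccw <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  if (sum(x * y[j] - x[j] * y) < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v
}

disk_polygon <- function(center, radius, n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# capsule (Minkowski sum of a segment and a disk) around the two extreme
# points of a collinear/coincident set
capsule_polygon <- function(xy, radius, n_cap = 8L) {
  d2 <- as.matrix(stats::dist(xy))
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  a <- xy[ij[1], ]; b <- xy[ij[2], ]
  if (sum((b - a)^2) < 1e-20) return(disk_polygon(a, radius))
  th0 <- atan2(b[2] - a[2], b[1] - a[1])
  arc_b <- th0 - pi / 2 + seq(0, pi, length.out = n_cap + 1L)
  arc_a <- th0 + pi / 2 + seq(0, pi, length.out = n_cap + 1L)
  ccw(rbind(
    cbind(b[1] + radius * cos(arc_b), b[2] + radius * sin(arc_b)),
    cbind(a[1] + radius * cos(arc_a), a[2] + radius * sin(arc_a))
  ))
}

# Euclidean distance from each query point to a convex polygon (0 inside)
point_hull_distance <- function(px, py, vertices) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  m <- nrow(vertices)
  d2 <- rep(Inf, length(px))
  for (e in seq_len(m)) {
    ax <- vx[e]; ay <- vy[e]
    bx <- vx[if (e == m) 1L else e + 1L]; by <- vy[if (e == m) 1L else e + 1L]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2)) else 0
    ex <- px - (ax + t * dx); ey <- py - (ay + t * dy)
    d2 <- pmin(d2, ex * ex + ey * ey)
  }
  d <- sqrt(d2)
  inside <- pracma::inpolygon(px, py, vx, vy, boundary = TRUE)
  d[inside] <- 0
  d
}
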