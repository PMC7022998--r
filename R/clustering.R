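#' Calinski-Harabasz criterion
#'
#' Variance-ratio criterion for a clustering of 2-D points, evaluated in
#' Euclidean coordinates regardless of the dissimilarity that produced the
#' partition: \eqn{(B/(k-1)) / (W/(n-k))} with between- and within-cluster
#' sums of squares `B` and `W`. `Inf` when the partition is exact (`W = 0`);
#' undefined (`NA`) for `k = 1`.
#'
#' @param xy Numeric matrix of coordinates (n x 2).
#' @param assignment Integer cluster ids, one per row of `xy`.
#' @return The criterion value.
#' @export
calinski_harabasz <- function(xy, assignment) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  k <- length(unique(assignment))
  if (k < 2 || k >= n) return(NA_real_)
  m <- colMeans(xy)
  W <- 0
  B <- 0
  for (cl in unique(assignment)) {
    rows <- xy[assignment == cl, , drop = FALSE]
    mk <- colMeans(rows)
    W <- W + sum(sweep(rows, 2, mk)^2)
    B <- B + nrow(rows) * sum((mk - m)^2)
  }
  if (W < .Machine$double.eps) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

# cluster one label class: average-linkage agglomerative clustering under the
# metric, k chosen in 2..min(n-1, k_max) by maximal Calinski-Harabasz score;
# k = 1 when fewer than 3 points (criterion undefined)
cluster_class <- function(xy, metric, k_max) {
  n <- nrow(xy)
  if (n < 3) {
    return(list(assignment = rep(1L, n), k = 1L, ch = NA_real_))
  }
  D <- dissimilarity_matrix(xy, metric)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ks <- 2:min(n - 1L, max(2L, k_max))
  best <- NULL
  for (k in ks) {
    asg <- stats::cutree(hc, k = k)
    ch <- calinski_harabasz(xy, asg)
    better <- is.null(best) || (is.na(best$ch) && !is.na(ch)) ||
      isTRUE(ch > best$ch)
    if (better) best <- list(assignment = as.integer(asg), k = k, ch = ch)
  }
  # degenerate spread (all CH undefined): keep everything in one cluster
  if (is.null(best) || is.na(best$ch)) {
    best <- list(assignment = rep(1L, n), k = 1L, ch = NA_real_)
  }
  best
}

#' Cluster labelled points within each label class
#'
#' Runs average-linkage agglomerative clustering separately on the adaptation
#' (+1) and maladaptation (-1) classes under the requested dissimilarity, and
#' picks the number of clusters per class by the Calinski-Harabasz criterion
#' (singleton/pair classes keep one cluster). The partition is deterministic
#' and invariant to the input point order.
#'
#' @param points Data frame with columns `x`, `y` in `[0, 1]` and `label` in
#'   `{+1, -1}` (rows with `NA` label are rejected).
#' @param metric One of `"bray_curtis"`, `"chebyshev"`, `"norm_sq_euclidean"`.
#' @param k_max Maximum clusters per class (default 4).
#' @return A `clustering_solution`: list with `metric`, `assignments`
#'   (integer cluster id per point, ids unique across classes), `k_per_class`,
#'   `n_patterns` (total cluster count) and `ch_score` (mean of the defined
#'   per-class criterion values, 0 when none is defined).
#' @export
cluster_patterns <- function(points, metric = pattern_metrics, k_max = 4) {
  metric <- match.arg(metric)
  if (any(is.na(points$label))) {
    stop("all points must carry a +1/-1 label", call. = FALSE)
  }
  labels <- sort(unique(points$label), decreasing = TRUE)
  if (!all(labels %in% c(-1L, 1L)) || length(labels) < 2L) {
    stop("need at least one point in each of the +1 and -1 classes",
         call. = FALSE)
  }
  assignments <- integer(nrow(points))
  k_per_class <- stats::setNames(integer(2), c("1", "-1"))
  ch_values <- c()
  next_id <- 0L
  for (lab in c(1L, -1L)) {
    idx <- which(points$label == lab)
    xy <- as.matrix(points[idx, c("x", "y")])
    res <- cluster_class(xy, metric, k_max)
    assignments[idx] <- res$assignment + next_id
    k_per_class[as.character(lab)] <- max(res$assignment)
    next_id <- next_id + max(res$assignment)
    if (!is.na(res$ch)) ch_values <- c(ch_values, res$ch)
  }
  structure(
    list(metric = metric, assignments = assignments,
         k_per_class = k_per_class, n_patterns = next_id,
         ch_score = if (length(ch_values)) mean(ch_values) else 0),
    class = "clustering_solution"
  )
}

#' Select the sparsest clustering solution across metrics
#'
#' Given one solution per dissimilarity, returns the one with the least total
#' number of patterns. Ties are broken by the higher Calinski-Harabasz score,
#' then by the fixed metric order Bray-Curtis, Chebyshev, normalized squared
#' Euclidean.
#'
#' @param solutions List of `clustering_solution` objects.
#' @return The selected `clustering_solution`.
#' @export
select_sparsest_solution <- function(solutions) {
  if (!length(solutions)) stop("no solutions supplied", call. = FALSE)
  ord <- order(
    vapply(solutions, function(s) s$n_patterns, numeric(1)),
    -vapply(solutions, function(s) ifelse(is.finite(s$ch_score),
                                          s$ch_score, Inf), numeric(1)),
    match(vapply(solutions, function(s) s$metric, character(1)),
          pattern_metrics)
  )
  solutions[[ord[1]]]
}
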