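#' Bray-Curtis dissimilarity
#'
#' \eqn{\sum_i |u_i - v_i| / \sum_i (u_i + v_i)} for non-negative coordinate
#' vectors; 0 when both points coincide (including the all-zero pair).
#'
#' @param u,v Numeric coordinate vectors of equal length.
#' @return Dissimilarity in `[0, 1]` for non-negative input.
#' @export
bray_curtis <- function(u, v) {
  if (any(u < 0) || any(v < 0)) {
    stop("Bray-Curtis requires non-negative coordinates", call. = FALSE)
  }
  denom <- sum(u + v)
  if (denom == 0) return(0)
  sum(abs(u - v)) / denom
}

#' Chebyshev distance
#'
#' Maximum absolute coordinate difference \eqn{\max_i |u_i - v_i|}.
#'
#' @inheritParams bray_curtis
#' @return Non-negative distance.
#' @export
chebyshev <- function(u, v) max(abs(u - v))

#' Normalized squared Euclidean distance
#'
#' Each vector is centred by the mean of its own components, and the squared
#' Euclidean distance between the centred vectors is scaled by the sum of
#' their squared norms:
#' \deqn{\frac{1}{2}\,\frac{\|(u-\bar u) - (v-\bar v)\|^2}
#'   {\|u-\bar u\|^2 + \|v-\bar v\|^2}.}
#' The result lies in `[0, 1]`; a pair of antipodal centred vectors scores 1.
#' Two constant vectors (zero variance on both sides) score 0.
#'
#' @inheritParams bray_curtis
#' @return Dissimilarity in `[0, 1]`.
#' @export
norm_sq_euclidean <- function(u, v) {
  uc <- u - mean(u)
  vc <- v - mean(v)
  denom <- sum(uc^2) + sum(vc^2)
  if (denom == 0) return(0)
  0.5 * sum((uc - vc)^2) / denom
}

pattern_metrics <- c("bray_curtis", "chebyshev", "norm_sq_euclidean")

metric_fun <- function(metric) {
  switch(metric,
    bray_curtis = bray_curtis,
    chebyshev = chebyshev,
    norm_sq_euclidean = norm_sq_euclidean,
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

# full pairwise dissimilarity matrix for an n x 2 coordinate matrix
dissimilarity_matrix <- function(xy, metric) {
  f <- metric_fun(metric)
  n <- nrow(xy)
  D <- matrix(0, n, n)
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- f(xy[i, ], xy[j, ])
    }
  }
  D
}
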