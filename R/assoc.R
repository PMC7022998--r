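#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation using average ranks for ties. For `n <= 9` the p-value is
#' exact, computed by full enumeration of the n! permutations of one rank
#' vector (two-sided: the proportion of permutations whose |rho| is at least
#' the observed |rho|). For larger n the usual t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom is used.
#'
#' @param x,y Paired numeric vectors, `n >= 4`.
#' @return A `correlation_result`: list with `statistic`, `p_raw`, `n`,
#'   `method = "spearman"`, `exact` flag. A constant input vector yields an
#'   `NA` statistic with `undefined = TRUE`.
#' @export
spearman_rho <- function(x, y) {
  n <- check_paired(x, y)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(correlation_result(NA_real_, NA_real_, n, "spearman",
                              undefined = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    # correlation of rx with every permutation of ry, via sums of products
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    stats_all <- (matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) / denom
    p <- mean(abs(stats_all) >= abs(rho) - 1e-12)
    exact <- TRUE
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    exact <- FALSE
  }
  correlation_result(rho, min(1, p), n, "spearman", exact = exact)
}

#' Blomqvist beta (medial correlation coefficient)
#'
#' Sign correlation around the two sample medians. With quadrants numbered
#' counter-clockwise from the upper right, \eqn{\beta = (n_1 + n_3 - n_2 -
#' n_4) / (n_1 + n_2 + n_3 + n_4)} over the points lying off both medians
#' (observations equal to either median are dropped, Blomqvist's original
#' treatment — with odd n at least one point per variable is dropped). The
#' p-value is the exact two-sided binomial probability of the concordant
#' count \eqn{n_1 + n_3} under independence (Binomial(m, 1/2)).
#'
#' @param x,y Paired numeric vectors, `n >= 4`.
#' @return A `correlation_result` with `method = "blomqvist"` and quadrant
#'   counts in `quadrants`. All points on a median yields an `NA` statistic
#'   flagged `undefined`.
#' @export
blomqvist_beta <- function(x, y) {
  n <- check_paired(x, y)
  mx <- stats::median(x); my <- stats::median(y)
  off <- x != mx & y != my
  if (!any(off)) {
    return(correlation_result(NA_real_, NA_real_, n, "blomqvist",
                              undefined = TRUE))
  }
  xs <- x[off]; ys <- y[off]
  n1 <- sum(xs > mx & ys > my)
  n2 <- sum(xs < mx & ys > my)
  n3 <- sum(xs < mx & ys < my)
  n4 <- sum(xs > mx & ys < my)
  m <- n1 + n2 + n3 + n4
  beta <- (n1 + n3 - n2 - n4) / m
  p <- stats::binom.test(n1 + n3, m, p = 0.5)$p.value
  res <- correlation_result(beta, p, n, "blomqvist", exact = TRUE)
  res$quadrants <- c(n1 = n1, n2 = n2, n3 = n3, n4 = n4)
  res
}

check_paired <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (length(x) < 4) stop("need at least 4 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  length(x)
}

correlation_result <- function(statistic, p_raw, n, method, exact = NA,
                               undefined = FALSE) {
  structure(list(statistic = statistic, p_raw = p_raw, p_adjusted = NA_real_,
                 n = n, method = method, exact = exact,
                 undefined = undefined),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> ", x$method, " (n = ", x$n, ")\n", sep = "")
  if (x$undefined) {
    cat("  statistic undefined (degenerate input)\n")
  } else {
    cat("  statistic: ", signif(x$statistic, 4),
        " | p: ", signif(x$p_raw, 4),
        if (!is.na(x$p_adjusted)) paste0(" | p (Holm): ",
                                         signif(x$p_adjusted, 4)) else "",
        "\n", sep = "")
  }
  invisible(x)
}

# all n! permutations of 1..n as a matrix (n! rows); n <= 9
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Bonferroni-Holm step-down adjustment
#'
#' Familywise-error control: with the p-values sorted ascending, the i-th
#' adjusted value is `max_{j<=i} min(1, (m-j+1) p_(j))`, mapped back to the
#' input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, never smaller than the raw ones.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t statistic with Welch-Satterthwaite degrees of freedom,
#' used for comparing two athlete groups. Delegates to [stats::t.test()].
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
  }
  res <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Correlation grid between GAPI and performance outcomes
#'
#' For every indicator combination, runs Spearman rank and Blomqvist beta
#' tests of the athletes' GAPI values against the best %PBT and against its
#' quartile band ([assign_quartiles()]). Holm correction is applied within
#' each (test, outcome) family across the combinations (family size = number
#' of combinations). Statistics and p-values are additionally rounded to two
#' decimals in the `*_2dp` report columns.
#'
#' @param gapi_tbl Data frame with columns `athlete_id`, `combination`,
#'   `gapi` (one row per athlete x combination).
#' @param best_pbt_tbl Data frame with columns `athlete_id`, `best_pbt`;
#'   must cover the same athletes, at least 4.
#' @return Tidy tibble with one row per combination x test x outcome:
#'   `combination`, `test`, `outcome`, `n`, `statistic`, `p_raw`, `p_holm`
#'   plus rounded report columns.
#' @export
correlate_gapi <- function(gapi_tbl, best_pbt_tbl) {
  gapi_tbl <- as.data.frame(gapi_tbl)
  best_pbt_tbl <- as.data.frame(best_pbt_tbl)
  need_cols(gapi_tbl, c("athlete_id", "combination", "gapi"), "gapi")
  need_cols(best_pbt_tbl, c("athlete_id", "best_pbt"), "best_pbt")
  athletes <- sort(unique(best_pbt_tbl$athlete_id))
  if (length(athletes) < 4) stop("need at least 4 athletes", call. = FALSE)
  if (!all(gapi_tbl$athlete_id %in% athletes)) {
    stop("GAPI and outcome tables cover different athletes", call. = FALSE)
  }
  outcome_tbl <- best_pbt_tbl[match(athletes, best_pbt_tbl$athlete_id), ]
  outcomes <- list(
    best_pbt = outcome_tbl$best_pbt,
    quartile = assign_quartiles(outcome_tbl$best_pbt)
  )
  combos <- sort(unique(gapi_tbl$combination))
  rows <- list()
  for (cb in combos) {
    sub <- gapi_tbl[gapi_tbl$combination == cb, ]
    g <- sub$gapi[match(athletes, sub$athlete_id)]
    if (any(is.na(g))) {
      stop("missing GAPI for some athletes in combination ", cb,
           call. = FALSE)
    }
    for (test in c("spearman", "blomqvist")) {
      f <- if (test == "spearman") spearman_rho else blomqvist_beta
      for (oc in names(outcomes)) {
        res <- f(g, outcomes[[oc]])
        rows[[length(rows) + 1]] <- tibble::tibble(
          combination = cb, test = test, outcome = oc, n = res$n,
          statistic = res$statistic, p_raw = res$p_raw
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(out, .data$test, .data$outcome)
  out <- dplyr::mutate(out, p_holm = holm_adjust(.data$p_raw))
  out <- dplyr::ungroup(out)
  out$statistic_2dp <- round(out$statistic, 2)
  out$p_raw_2dp <- round(out$p_raw, 2)
  out$p_holm_2dp <- round(out$p_holm, 2)
  out
}
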