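test_that("Spearman statistic hits the monotone extremes", {
  x <- c(3, 1, 4, 5, 9, 2, 6)
  r1 <- spearman_rho(x, x)
  expect_equal(r1$statistic, 1)
  expect_lt(r1$p_raw, 0.01)
  expect_equal(spearman_rho(x, -x)$statistic, -1)
  expect_true(spearman_rho(rep(1, 7), x)$undefined)
})

test_that("exact permutation p-value matches the reference distribution", {
  # tie-free data: cor.test's exact Spearman distribution is the oracle
  set.seed(15)
  for (n in c(6, 7)) {
    for (rep in 1:3) {
      x <- sample(100, n); y <- sample(100, n)
      ours <- spearman_rho(x, y)
      ref <- cor.test(x, y, method = "spearman", exact = TRUE)
      expect_equal(ours$statistic, unname(ref$estimate))
      expect_equal(ours$p_raw, ref$p.value, tolerance = 1e-12)
      expect_true(ours$exact)
    }
  }
})

test_that("rank statistics are invariant to increasing transformations", {
  set.seed(25)
  x <- runif(8, 1, 9); y <- runif(8, 1, 9)
  s1 <- spearman_rho(x, y); s2 <- spearman_rho(exp(x), y^3)
  expect_equal(s1$statistic, s2$statistic)
  expect_equal(s1$p_raw, s2$p_raw)
  b1 <- blomqvist_beta(x, y); b2 <- blomqvist_beta(exp(x), y^3)
  expect_equal(b1$statistic, b2$statistic)
  expect_equal(b1$p_raw, b2$p_raw)
})

test_that("Blomqvist beta counts median quadrants with exact binomial p", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(2, 1, 4, 3, 8, 5, 6, 7)  # concordant around the medians
  ours <- blomqvist_beta(x, y)
  oracle <- oracle_blomqvist(x, y)
  expect_equal(ours$statistic, oracle$beta)
  expect_equal(ours$p_raw,
               binom.test(oracle$concordant, oracle$m, 0.5)$p.value)

  # a hand-checkable concordant layout: all points in quadrants 1 and 3
  expect_equal(blomqvist_beta(1:6, 1:6)$statistic, 1)
  # balanced 2-2 quadrant split
  bal <- blomqvist_beta(c(1, 2, 9, 10), c(9, 2, 1, 10))
  expect_equal(bal$statistic, 0)
  # odd n drops the median point (Blomqvist's original treatment)
  odd <- blomqvist_beta(1:7, c(2, 1, 3, 4, 6, 5, 7))
  expect_equal(sum(odd$quadrants), 6)
})

test_that("random paired data match the quadrant oracle", {
  set.seed(35)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10)
    ours <- blomqvist_beta(x, y)
    oracle <- oracle_blomqvist(x, y)
    expect_equal(ours$statistic, oracle$beta)
  }
})

test_that("Holm adjustment reproduces the hand-stepped example", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(45)
  p <- runif(6)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  # all-equal p reduces to Bonferroni on the smallest
  expect_equal(holm_adjust(rep(0.01, 5))[1], 0.05)
})

test_that("Welch's test matches the closed form and is antisymmetric", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3 / sqrt(2 / 3))
  expect_equal(w$t, -3.674, tolerance = 1e-3)
  expect_equal(w$df, 4)
  expect_equal(welch_t(c(4, 5, 6), c(1, 2, 3))$t, -w$t)
})

test_that("the GAPI correlation grid has the documented shape and rules", {
  set.seed(55)
  n_ath <- 8
  best <- runif(n_ath, 96, 110)
  gapi_tbl <- do.call(rbind, lapply(1:5, function(cb) {
    data.frame(athlete_id = paste0("A", 1:n_ath), combination = cb,
               gapi = best + rnorm(n_ath, sd = 3))
  }))
  out_tbl <- data.frame(athlete_id = paste0("A", 1:n_ath), best_pbt = best)
  grid <- correlate_gapi(gapi_tbl, out_tbl)
  expect_equal(nrow(grid), 20)  # 5 combos x 2 tests x 2 outcomes
  expect_setequal(unique(grid$test), c("spearman", "blomqvist"))
  expect_setequal(unique(grid$outcome), c("best_pbt", "quartile"))
  expect_true(all(grid$p_holm >= grid$p_raw - 1e-12))
  # Holm families are the 5 combinations within each test/outcome pair
  fam <- grid[grid$test == "spearman" & grid$outcome == "best_pbt", ]
  expect_equal(fam$p_holm, holm_adjust(fam$p_raw))

  # GAPI equal to the outcome gives perfect rank correlation
  ident <- correlate_gapi(
    data.frame(athlete_id = paste0("A", 1:n_ath), combination = 1,
               gapi = best),
    out_tbl
  )
  expect_equal(ident$statistic[ident$test == "spearman" &
                                 ident$outcome == "best_pbt"], 1)

  # shuffling athlete order changes nothing
  perm <- sample(nrow(gapi_tbl))
  grid2 <- correlate_gapi(gapi_tbl[perm, ], out_tbl[sample(n_ath), ])
  expect_equal(grid, grid2)

  expect_error(correlate_gapi(gapi_tbl[gapi_tbl$athlete_id %in%
                                         paste0("A", 1:3), ],
                              out_tbl[1:3, ]), "at least 4")
})
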