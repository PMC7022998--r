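test_that("region areas are conserved across random fitted maps", {
  for (seed in c(3, 17, 23, 29)) {
    fit <- random_fit(seed, n = 8, res = 64)
    expect_equal(sum(fit$areas), 1, tolerance = 1e-6)
    expect_true(all(fit$areas >= 0))
  }
})

test_that("doubling the grid resolution moves areas less than 2/resolution", {
  set.seed(9)
  tr <- make_triplets(runif(8), runif(8),
                      c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  a64 <- fit_geometry(tr, grid_resolution = 64)$areas
  a128 <- fit_geometry(tr, grid_resolution = 128)$areas
  expect_true(all(abs(a64 - a128) < 2 / 64))
})

test_that("GAPI is the adaptation to maladaptation area ratio", {
  expect_equal(gapi(c(area_adapt = 0.5, area_malad = 0.5)), 1)
  expect_equal(gapi(c(area_adapt = 0.75, area_malad = 0.25)), 3)
  expect_warning(g <- gapi(c(area_adapt = 0.6, area_malad = 0)), "infinite")
  expect_identical(g, Inf)
  expect_error(gapi(c(area_adapt = 0, area_malad = 0)), "degenerate")
  # a symmetric half/half map scores exactly 1
  expect_equal(gapi(make_symmetric_map(eps = 0, res = 64)), 1)
  expect_equal(gapi(make_symmetric_map(eps = 0.01, res = 64)), 1)
})

test_that("GAPI exceeds 1 exactly when the adaptation area dominates", {
  for (seed in c(3, 17, 23, 29)) {
    fit <- random_fit(seed, n = 8, res = 64)
    expect_equal(fit$gapi > 1,
                 fit$areas[["area_adapt"]] > fit$areas[["area_malad"]])
  }
})

test_that("goodness of fit rounds correct/total to integer percent", {
  # construct a map whose prediction is known, then place points by hand:
  # left half predicts +1, right half predicts -1
  map <- make_symmetric_map(eps = 0.01, res = 64)
  pts_correct <- data.frame(x = c(rep(0.2, 4), rep(0.8, 3)),
                            y = seq(0.2, 0.8, length.out = 7),
                            label = c(rep(1L, 4), rep(-1L, 3)))
  # 7 of 8: one adaptation week deep in the maladaptation half
  pts <- rbind(pts_correct, data.frame(x = 0.8, y = 0.5, label = 1L))
  expect_equal(goodness_of_fit(map, pts), 88)  # 87.5 rounds half-up
  # 5 of 8
  pts$label[c(1, 2)] <- -1L
  expect_equal(goodness_of_fit(map, pts), 63)  # 62.5 rounds half-up
  # 6 of 6
  expect_equal(goodness_of_fit(map, pts_correct[1:6, ]), 100)
})

test_that("training points are scored by the same rule as the area grid", {
  fit <- random_fit(19, n = 8, res = 64)
  pts <- fit$per_point
  # outside the neutral layer the hard and region labels agree
  expect_true(all(fit$map$hard[fit$map$region != 0L] ==
                    fit$map$region[fit$map$region != 0L]))
  expect_equal(pts$correct, pts$label == pts$predicted)
})

test_that("a separable season fits perfectly with a clean boundary", {
  # all adaptation weeks strictly left of all maladaptation weeks
  set.seed(77)
  tr <- make_triplets(x = c(runif(4, 0.05, 0.35), runif(4, 0.65, 0.95)),
                      y = runif(8), adapt = rep(c(TRUE, FALSE), each = 4))
  fit <- fit_geometry(tr, grid_resolution = 64)
  expect_equal(fit$goodness_of_fit, 100)
  # the boundary stays outside both class hulls (it separates them)
  hull_of <- function(lab) {
    xy <- as.matrix(tr[tr$label == lab, c("x", "y")])
    xy[grDevices::chull(xy), , drop = FALSE]
  }
  bx <- unlist(lapply(fit$map$boundary, function(b) b$x))
  by <- unlist(lapply(fit$map$boundary, function(b) b$y))
  for (lab in c(1L, -1L)) {
    d <- trainadapt:::point_hull_distance(bx, by, hull_of(lab))
    expect_true(all(d > 0), label = paste("class", lab))
  }
  # mean cross entropy of a perfect fit is the clamped floor
  expect_equal(fit$mce, -log(1 - 1e-3))
})
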