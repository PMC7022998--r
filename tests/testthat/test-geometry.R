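test_that("convexification returns the hull of a generic point set", {
  sq <- rbind(c(0.2, 0.2), c(0.8, 0.2), c(0.8, 0.8), c(0.2, 0.8))
  p <- convexify(rbind(sq, c(0.5, 0.5)), 1L)  # interior point absorbed
  expect_equal(nrow(p$vertices), 4)
  expect_setequal(apply(p$vertices, 1, paste, collapse = ","),
                  apply(sq, 1, paste, collapse = ","))
})

test_that("degenerate clusters are buffered into positive-area patterns", {
  p1 <- convexify(matrix(c(0.5, 0.5), 1), -1L, delta = 0.02)
  radii <- sqrt(rowSums(sweep(p1$vertices, 2, c(0.5, 0.5))^2))
  expect_equal(radii, rep(0.02, nrow(p1$vertices)))
  expect_gt(trainadapt:::polygon_area(p1$vertices), 0)

  p2 <- convexify(rbind(c(0.2, 0.2), c(0.6, 0.6)), 1L, delta = 0.05)
  expect_gt(trainadapt:::polygon_area(p2$vertices), 0)

  coll <- cbind(seq(0.1, 0.9, length.out = 5), seq(0.1, 0.9, length.out = 5))
  p3 <- convexify(coll, 1L, delta = 0.03)
  expect_gt(trainadapt:::polygon_area(p3$vertices), 0)
})

test_that("every cluster point lies inside (or on) its hull", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(1:7, 1)
    xy <- cbind(runif(n), runif(n))
    p <- convexify(xy, 1L)
    d <- trainadapt:::point_hull_distance(xy[, 1], xy[, 2], p$vertices)
    expect_true(all(d < 1e-9))
  }
})

test_that("a symmetric two-pattern layout splits at the vertical midline", {
  map <- make_symmetric_map(eps = 0, res = 64)
  a <- region_areas(map)
  expect_equal(unname(a[["area_adapt"]]), unname(a[["area_malad"]]))
  # boundary polyline hugs x = 0.5
  bx <- unlist(lapply(map$boundary, function(b) b$x))
  expect_true(all(abs(bx - 0.5) < 0.02))
  # left cells +1, right cells -1
  expect_equal(classify_point(map, c(0.2, 0.5)), 1L)
  expect_equal(classify_point(map, c(0.8, 0.5)), -1L)
})

test_that("hull interiors keep their own label outside the layer", {
  fit <- random_fit(21, n = 8, res = 64)
  map <- fit$map
  for (p in map$patterns) {
    inner <- p$centroid  # centroid of a convex pattern is interior
    lab <- classify_point(map, pmin(pmax(inner, 0), 1),
                          resolve_neutral = TRUE)
    d_own <- trainadapt:::point_hull_distance(inner[1], inner[2], p$vertices)
    if (d_own == 0) {
      opp <- Filter(function(q) q$label != p$label, map$patterns)
      d_opp <- min(vapply(opp, function(q) {
        trainadapt:::point_hull_distance(inner[1], inner[2], q$vertices)
      }, numeric(1)))
      if (d_opp > map$layer_width) expect_equal(lab, p$label)
    }
  }
})

test_that("the neutral layer vanishes as its width goes to zero", {
  fit <- random_fit(31, n = 8, res = 64)
  pats <- fit$map$patterns
  neutral <- vapply(c(0.05, 0.02, 0), function(eps) {
    region_areas(build_domain_map(pats, layer_width = eps,
                                  grid_resolution = 64))[["area_neutral"]]
  }, numeric(1))
  expect_true(all(diff(neutral) < 0))
  expect_lt(neutral[3], 0.001)
})

test_that("an exhaustive nearest-hull scan reproduces the region map", {
  for (seed in c(41, 42)) {
    fit <- random_fit(seed, n = 8, res = 64)
    map <- fit$map
    oracle <- oracle_region(map$patterns, map$layer_width, 64)
    # skip knife-edge cells where floating-point ties could differ
    g <- map$field
    comparable <- abs(abs(g) - map$layer_width) > 1e-9
    expect_gt(mean(comparable), 0.99)
    expect_equal(map$region[comparable], oracle[comparable])
  }
})

test_that("classification is total, bounded to the square, and cellwise constant", {
  map <- make_symmetric_map(res = 64)
  expect_error(classify_point(map, c(1.2, 0.5)), "unit square")
  q <- c(0.305, 0.505)
  expect_equal(classify_point(map, q),
               classify_point(map, q + 0.2 / 64 * c(1, 1)))
  # resolve_neutral never returns 0
  set.seed(5)
  pts <- cbind(runif(200), runif(200))
  expect_true(all(classify_point(map, pts, resolve_neutral = TRUE) %in%
                    c(-1L, 1L)))
})

test_that("domain map construction enforces its preconditions", {
  p <- convexify(matrix(c(0.5, 0.5), 1), 1L)
  expect_error(build_domain_map(list(p), grid_resolution = 16), "coarse")
  expect_error(build_domain_map(list(p), grid_resolution = 64), "per label")
})

test_that("domain maps serialize to JSON with patterns and areas", {
  map <- make_symmetric_map(res = 64)
  js <- jsonlite::fromJSON(domain_map_json(map))
  expect_equal(js$grid_resolution, 64)
  expect_equal(length(js$patterns$label), 2)
  expect_equal(js$areas$area_adapt + js$areas$area_malad +
                 js$areas$area_neutral, 1, tolerance = 1e-9)
})
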