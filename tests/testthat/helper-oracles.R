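# Independent slow oracles used to cross-check the implementation.

# labelled triplets from explicit coordinates and an adaptation indicator
make_triplets <- function(x, y, adapt) {
  tr <- tibble::tibble(week = seq_along(x), x = x, y = y,
                       z_pct = ifelse(adapt, 103, 97))
  tr$label <- binarize_pbt(tr$z_pct)
  tr
}

# scalar point-in-polygon by ray casting (independent of pracma)
oracle_inside <- function(px, py, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((v[i, 2] > py) != (v[j, 2] > py)) {
      xint <- v[j, 1] + (py - v[j, 2]) * (v[i, 1] - v[j, 1]) /
        (v[i, 2] - v[j, 2])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# scalar point-to-convex-polygon distance, plain double loop
oracle_hull_distance <- function(px, py, v) {
  if (oracle_inside(px, py, v)) return(0)
  n <- nrow(v)
  best <- Inf
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
    ab <- b - a
    t <- sum((c(px, py) - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    p <- a + t * ab
    best <- min(best, sqrt((px - p[1])^2 + (py - p[2])^2))
  }
  best
}

# exhaustive nearest-hull region scan mirroring the documented decision rule
oracle_region <- function(patterns, eps, res) {
  centers <- (seq_len(res) - 0.5) / res
  out <- matrix(0L, res, res)
  for (ix in seq_len(res)) {
    for (iy in seq_len(res)) {
      px <- centers[ix]; py <- centers[iy]
      dp <- Inf; dm <- Inf; cp <- Inf; cm <- Inf
      for (p in patterns) {
        d <- oracle_hull_distance(px, py, p$vertices)
        cd <- (px - p$centroid[1])^2 + (py - p$centroid[2])^2
        if (p$label == 1L) {
          dp <- min(dp, d); if (d == 0) cp <- min(cp, cd)
        } else {
          dm <- min(dm, d); if (d == 0) cm <- min(cm, cd)
        }
      }
      g <- dp - dm
      lab <- if (g < 0) 1L else if (g > 0) -1L else if (cp <= cm) 1L else -1L
      both0 <- dp == 0 && dm == 0
      if (!both0 && ((abs(g) <= eps && eps > 0) || g == 0)) lab <- 0L
      out[ix, iy] <- lab
    }
  }
  out
}

# brute-force Blomqvist quadrant count (explicit loop, no vectorization)
oracle_blomqvist <- function(x, y) {
  mx <- median(x); my <- median(y)
  n1 <- n2 <- n3 <- n4 <- 0
  for (i in seq_along(x)) {
    if (x[i] == mx || y[i] == my) next
    if (x[i] > mx && y[i] > my) n1 <- n1 + 1
    else if (x[i] < mx && y[i] > my) n2 <- n2 + 1
    else if (x[i] < mx && y[i] < my) n3 <- n3 + 1
    else n4 <- n4 + 1
  }
  list(beta = (n1 + n3 - n2 - n4) / (n1 + n2 + n3 + n4),
       concordant = n1 + n3, m = n1 + n2 + n3 + n4)
}

# two well-separated, tie-free blobs with a shared label; the symmetric
# cross layout keeps the variance-ratio criterion from over-splitting
# NB: centers must be off the main diagonal — the normalized squared
# Euclidean dissimilarity of 2-vectors depends only on x - y
make_blobs <- function(centers = list(c(0.2, 0.7), c(0.8, 0.2)),
                       d = 0.025) {
  th <- (c(0, 90, 180, 270) + 10) * pi / 180
  r <- c(1, 1.15, 0.9, 1.05)
  do.call(rbind, lapply(centers, function(ct) {
    cbind(ct[1] + d * r * cos(th), ct[2] + d * r * sin(th))
  }))
}

# a simple two-pattern map: +1 square on the left, -1 square on the right
make_symmetric_map <- function(eps = 0.01, res = 64) {
  p_plus <- convexify(rbind(c(0.05, 0.1), c(0.40, 0.1),
                            c(0.40, 0.9), c(0.05, 0.9)), 1L)
  p_minus <- convexify(rbind(c(0.60, 0.1), c(0.95, 0.1),
                             c(0.95, 0.9), c(0.60, 0.9)), -1L)
  build_domain_map(list(p_plus, p_minus), layer_width = eps,
                   grid_resolution = res)
}

# end-to-end cohort recovery run: simulate athletes, keep the first
# `n_keep` passing the inclusion prerequisites, fit the zero-jitter ensemble
cohort_recovery <- function(seed, label_noise = 0, n_keep = 20,
                            grid = 128) {
  cfg <- cohort_config(n_athletes = n_keep, label_noise = label_noise,
                       seed = seed)
  gofs <- c(); a_adapt <- c(); a_malad <- c(); gapis <- c(); i <- 0
  while (length(gofs) < n_keep && i < 3 * n_keep) {
    i <- i + 1
    ath <- simulate_athlete(cfg, i)
    rates <- trainadapt:::protocol_rates(ath)
    dec <- apply_prerequisites(ath, rates$attendance, rates$response_rates)
    if (!dec$include) next
    ens <- run_ensemble(weekly_aggregate(ath), 1,
                        jitter_config(0, 50, seed = seed),
                        grid_resolution = grid)
    ok <- ens$members[!ens$members$degenerate, ]
    gofs <- c(gofs, ens$mean_gof)
    gapis <- c(gapis, ens$mean_gapi)
    a_adapt <- c(a_adapt, mean(ok$area_adapt))
    a_malad <- c(a_malad, mean(ok$area_malad))
  }
  list(mean_gof = mean(gofs), pooled_gapi = sum(a_adapt) / sum(a_malad),
       mean_gapi = mean(gapis), n = length(gofs))
}

# random labelled points -> fitted map, for conservation-style sweeps
random_fit <- function(seed, n = 8, res = 64) {
  set.seed(seed)
  make_triplets(runif(n), runif(n), runif(n) > 0.5) |>
    (\(tr) {
      # guarantee both classes
      tr$label[1] <- 1L; tr$z_pct[1] <- 103
      tr$label[2] <- -1L; tr$z_pct[2] <- 97
      fit_geometry(tr, grid_resolution = res)
    })()
}
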