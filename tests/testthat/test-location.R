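# Location phenotypes: distance, speeds, stationary/moving split, significant
# places, entropy features.

test_that("haversine distance matches closed-form arcs and is symmetric", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  # one degree of longitude on the equator: 2*pi*R/360
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371 / 360, tolerance = 1e-6)
  # antipodal points: pi*R
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  expect_equal(haversine_km(37.5, 127.0, 37.56, 127.02),
               haversine_km(37.56, 127.02, 37.5, 127.0))
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 200, 0, 0), "longitude")
})

test_that("speeds are distance over time with strict timestamp checks", {
  expect_equal(estimate_speeds(gps_points(c(0, 10), c(5, 5), c(5, 5))), 0)
  # 1 degree of equatorial longitude in one hour
  pts <- gps_points(c(0, 60), c(0, 0), c(0, 1))
  expect_equal(estimate_speeds(pts), 2 * pi * 6371 / 360, tolerance = 1e-6)
  expect_length(estimate_speeds(gps_points(0, 10, 10)), 0)
  expect_error(estimate_speeds(gps_points(c(5, 5), c(0, 0), c(0, 1))),
               "strictly increasing")
})

test_that("stationary/moving classification uses a strict 1 km/h threshold", {
  expect_equal(classify_segments(c(0.5, 1.5)), c("stationary", "moving"))
  expect_equal(classify_segments(1.0), "moving")   # boundary counts as moving
  expect_equal(classify_segments(c(0, 0, 0)), rep("stationary", 3))
  expect_error(classify_segments(-1), "non-negative")
})

test_that("place clustering finds the right k and dwell fractions", {
  # one tight blob -> a single place holding all dwell time
  set.seed(1)
  blob <- data.frame(lat = 37.55 + rnorm(30, 0, 5e-5),
                     lon = 127.0 + rnorm(30, 0, 5e-5),
                     dwell_min = rep(5, 30))
  pc <- cluster_places(blob, seed = 3)
  expect_equal(pc$k, 1L)
  expect_equal(pc$dwell_fraction, 1)
  # two tight clouds 5 km apart with equal dwell -> k = 2, p = (1/2, 1/2)
  two <- data.frame(lat = c(rep(37.55, 50), rep(37.595, 50)) + rnorm(100, 0, 2e-5),
                    lon = rep(127, 100) + rnorm(100, 0, 2e-5),
                    dwell_min = rep(3, 100))
  pc2 <- cluster_places(two, seed = 3)
  expect_equal(pc2$k, 2L)
  expect_equal(sort(pc2$dwell_fraction), c(0.5, 0.5), tolerance = 1e-9)
  # determinism under a fixed seed
  pc3 <- cluster_places(two, seed = 3)
  expect_identical(pc2$centroids, pc3$centroids)
  expect_identical(pc2$assignment, pc3$assignment)
  # empty sentinel
  empty <- cluster_places(two[0, ], seed = 1)
  expect_equal(empty$k, 0L)
})

test_that("clustering matches the exhaustive minimum-WCSS assignment on small inputs", {
  # brute-force oracle: enumerate every assignment of n points to k clusters
  brute_wcss <- function(xy, k) {
    n <- nrow(xy)
    grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      a <- as.integer(grid[r, ])
      if (length(unique(a)) < k) next
      w <- 0
      for (c0 in seq_len(k)) {
        m <- xy[a == c0, , drop = FALSE]
        w <- w + sum(sweep(m, 2, colMeans(m))^2)
      }
      best <- min(best, w)
    }
    best
  }
  set.seed(42)
  for (rep in 1:5) {
    centers <- matrix(runif(4, 0, 2000), 2, 2)
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    xy <- rbind(centers[rep(1, n1), ] + matrix(rnorm(2 * n1, 0, 30), n1, 2),
                centers[rep(2, n2), ] + matrix(rnorm(2 * n2, 0, 30), n2, 2))
    km <- suppressWarnings(stats::kmeans(xy, centers = 2, nstart = 5))
    expect_equal(km$tot.withinss, brute_wcss(xy, 2), tolerance = 1e-8)
  }
})

test_that("location features reproduce closed-form entropy values", {
  # motionless day: everything zero
  still <- gps_points(seq(0, 600, by = 10), rep(37.55, 61), rep(127, 61))
  f <- compute_location_features(still, seed = 1)
  expect_equal(f$total_distance_km, 0)
  expect_equal(f$total_travel_time_min, 0)
  expect_equal(f$location_entropy, 0)
  expect_equal(f$normalized_entropy, 0)
  # two places, equal dwell -> entropy ln 2, normalised 1
  # stationary dwell min_a at place A, 20-min transit, dwell min_b at place B
  mk_day <- function(min_a, min_b) {
    ta <- seq(0, min_a, by = 10)
    tb <- seq(min_a + 20, min_a + 20 + min_b, by = 10)
    gps_points(c(ta, tb),
               c(rep(37.55, length(ta)), rep(37.65, length(tb))),
               rep(127, length(ta) + length(tb)))
  }
  f2 <- compute_location_features(mk_day(300, 300), seed = 1)
  expect_equal(f2$location_entropy, log(2), tolerance = 1e-9)
  expect_equal(f2$normalized_entropy, 1, tolerance = 1e-9)
  # dwell 0.9 / 0.1 -> -sum p log p = 0.3251
  f3 <- compute_location_features(mk_day(540, 60), seed = 1)
  expect_equal(f3$location_entropy,
               -(0.9 * log(0.9) + 0.1 * log(0.1)), tolerance = 1e-9)
  # insufficient data sentinel
  expect_true(all(is.na(compute_location_features(still[1, , drop = FALSE]))))
})

test_that("entropy bounds, translation invariance and interval accounting hold", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    pts <- gps_points(cumsum(runif(n, 1, 20)),
                      37.5 + cumsum(rnorm(n, 0, 0.002)),
                      127 + cumsum(rnorm(n, 0, 0.002)))
    f <- compute_location_features(pts, seed = i)
    if (is.finite(f$location_entropy)) {
      expect_gte(f$location_entropy, -1e-12)
      expect_gte(f$normalized_entropy, 0)
      expect_lte(f$normalized_entropy, 1 + 1e-12)
    }
    expect_lte(f$total_travel_time_min, max(pts$t_min) - min(pts$t_min) + 1e-9)
    labels <- classify_segments(estimate_speeds(pts))
    expect_equal(length(labels), n - 1)
    # longitude translation preserves distance and entropy
    shifted <- pts; shifted$lon <- shifted$lon + 10
    f2 <- compute_location_features(shifted, seed = i)
    expect_equal(f2$total_distance_km, f$total_distance_km, tolerance = 1e-3)
    expect_equal(f2$location_entropy, f$location_entropy, tolerance = 1e-6)
  }
})
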