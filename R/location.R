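# Location phenotypes: a day's GPS trace is reduced to five features --- total
# travel distance, total travel time, location variance, location entropy and
# normalised location entropy. Speeds are obtained by time-differencing the
# trace; intervals below 1 km/h count as stationary; stationary points are
# grouped into significant places by K-means before the entropy features.

EARTH_RADIUS_KM <- 6371.0

validate_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    dp_stop("non-finite coordinates")
  if (any(lat < -90 | lat > 90))
    dp_stop("latitude out of range [-90, 90]")
  if (any(lon <= -180 | lon > 180))
    dp_stop("longitude out of range (-180, 180]")
  invisible(TRUE)
}

#' Great-circle distance between coordinate pairs
#'
#' Haversine formula on a spherical Earth of radius 6371 km. Vectorised over
#' all four arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distances in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1)   # one degree of longitude on the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  validate_coords(lat1, lon1)
  validate_coords(lat2, lon2)
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Per-interval travel speeds from an ordered GPS trace
#'
#' @param points data frame with numeric columns `t_min` (minutes, strictly
#'   increasing), `lat`, `lon`.
#' @return numeric vector of `nrow(points) - 1` speeds in km/h (empty for a
#'   single point).
#' @export
estimate_speeds <- function(points) {
  n <- nrow(points)
  if (n < 2) return(numeric(0))
  dt <- diff(points$t_min)
  if (any(dt <= 0)) dp_stop("timestamps must be strictly increasing")
  d <- haversine_km(points$lat[-n], points$lon[-n],
                    points$lat[-1], points$lon[-1])
  d / (dt / 60)
}

#' Classify speed intervals as stationary or moving
#'
#' Intervals strictly below the threshold are stationary; a speed exactly at
#' the threshold counts as moving.
#'
#' @param speeds non-negative speeds in km/h.
#' @param threshold_kmh classification threshold, default 1 km/h.
#' @return character vector of `"stationary"` / `"moving"` labels.
#' @export
classify_segments <- function(speeds, threshold_kmh = 1.0) {
  if (any(!is.finite(speeds)) || any(speeds < 0))
    dp_stop("speeds must be finite and non-negative")
  ifelse(speeds < threshold_kmh, "stationary", "moving")
}

# Local equirectangular projection (metres); adequate at city scale and keeps
# K-means distances Euclidean.
project_m <- function(lat, lon, lat0) {
  m_per_deg <- 2 * pi * EARTH_RADIUS_KM * 1000 / 360
  cbind(x = lon * m_per_deg * cos(lat0 * pi / 180), y = lat * m_per_deg)
}

#' Cluster stationary points into significant places
#'
#' K-means is run for k = 1, 2, ... and the chosen k is the smallest for which
#' every point lies within `merge_radius_m` of its centroid, capped at
#' `max_k`. Dwell fractions are the share of stationary time attributed to
#' each place.
#'
#' @param stationary data frame with `lat`, `lon` and a `dwell_min` column of
#'   per-point dwell times (minutes).
#' @param max_k maximum number of places considered.
#' @param merge_radius_m coverage radius defining an acceptable clustering.
#' @param seed integer seed making the K-means initialisation reproducible.
#' @return list with `k`, `centroids` (data frame `lat`, `lon`), `assignment`
#'   (cluster index per point) and `dwell_fraction`. With zero input rows an
#'   empty sentinel (`k = 0`) is returned.
#' @export
cluster_places <- function(stationary, max_k = 10, merge_radius_m = 500,
                           seed = 1) {
  if (nrow(stationary) == 0)
    return(list(k = 0L, centroids = data.frame(lat = numeric(), lon = numeric()),
                assignment = integer(0), dwell_fraction = numeric(0)))
  xy <- project_m(stationary$lat, stationary$lon, mean(stationary$lat))
  n_distinct <- nrow(unique(round(xy, 6)))
  k_cap <- min(max_k, n_distinct)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fit <- NULL
  for (k in seq_len(k_cap)) {
    if (k == n_distinct) {
      # one place per distinct point: exact assignment, no K-means needed
      key <- apply(round(xy, 6), 1, paste, collapse = "/")
      cl <- as.integer(factor(key, levels = unique(key)))
      centers <- apply(xy, 2, function(col) tapply(col, cl, mean))
      centers <- matrix(centers, ncol = 2,
                        dimnames = list(NULL, c("x", "y")))
      fit <- list(cluster = cl, centers = centers)
      break
    }
    fit <- suppressWarnings(stats::kmeans(xy, centers = k, nstart = 5,
                                          iter.max = 50))
    r <- sqrt(rowSums((xy - fit$centers[fit$cluster, , drop = FALSE])^2))
    if (max(r) < merge_radius_m) break
  }
  dwell <- stationary$dwell_min
  tot <- sum(dwell)
  frac <- as.numeric(tapply(dwell, factor(fit$cluster, levels = seq_len(k)),
                            sum, default = 0))
  frac <- if (tot > 0) frac / tot else rep(1 / k, k)
  m_per_deg <- 2 * pi * EARTH_RADIUS_KM * 1000 / 360
  cent <- data.frame(lat = fit$centers[, "y"] / m_per_deg,
                     lon = fit$centers[, "x"] /
                       (m_per_deg * cos(mean(stationary$lat) * pi / 180)))
  list(k = as.integer(k), centroids = cent,
       assignment = as.integer(fit$cluster), dwell_fraction = frac)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Five location phenotypes for one day of GPS points
#'
#' Total distance and travel time are summed over moving intervals; location
#' variance is `log(var(lat) + var(lon) + 1e-10)`; entropy is the Shannon
#' entropy (nats) of the significant-place dwell fractions; normalised entropy
#' divides by `log(k)` and is defined as 0 when `k <= 1`.
#'
#' @param points one day's GPS trace (`t_min`, `lat`, `lon`), time-ordered.
#' @param seed seed forwarded to [cluster_places()].
#' @param threshold_kmh stationary/moving threshold in km/h.
#' @param max_k,merge_radius_m place-clustering controls.
#' @return one-row data frame with `total_distance_km`, `total_travel_time_min`,
#'   `location_variance`, `location_entropy`, `normalized_entropy`. With fewer
#'   than 2 points all values are `NA` (insufficient data, never imputed).
#' @export
compute_location_features <- function(points, seed = 1, threshold_kmh = 1.0,
                                      max_k = 10, merge_radius_m = 500) {
  na_row <- data.frame(total_distance_km = NA_real_,
                       total_travel_time_min = NA_real_,
                       location_variance = NA_real_,
                       location_entropy = NA_real_,
                       normalized_entropy = NA_real_)
  if (is.null(points) || nrow(points) < 2) return(na_row)
  points <- points[order(points$t_min), , drop = FALSE]
  n <- nrow(points)
  speeds <- estimate_speeds(points)
  labels <- classify_segments(speeds, threshold_kmh)
  dt <- diff(points$t_min)
  d <- haversine_km(points$lat[-n], points$lon[-n],
                    points$lat[-1], points$lon[-1])
  moving <- labels == "moving"
  total_distance <- sum(d[moving])
  total_travel_time <- sum(dt[moving])
  loc_var <- log(stats::var(points$lat) + stats::var(points$lon) + 1e-10)
  # dwell time of a stationary interval goes to the cluster of its leading point
  stat_idx <- which(!moving)
  if (length(stat_idx)) {
    stationary <- data.frame(lat = points$lat[stat_idx],
                             lon = points$lon[stat_idx],
                             dwell_min = dt[stat_idx])
    pc <- cluster_places(stationary, max_k = max_k,
                         merge_radius_m = merge_radius_m, seed = seed)
    ent <- shannon_entropy(pc$dwell_fraction)
    nent <- if (pc$k <= 1) 0 else ent / log(pc$k)
  } else {
    ent <- NA_real_
    nent <- NA_real_
  }
  data.frame(total_distance_km = total_distance,
             total_travel_time_min = total_travel_time,
             location_variance = loc_var,
             location_entropy = ent,
             normalized_entropy = nent)
}
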