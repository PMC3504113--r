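# Great-circle and waypoint-constrained geographic distances, and the
# diversity-versus-distance-from-origin regression.
#
# Human range expansion out of Africa followed land routes, so straight
# great-circle distances between continents understate migratory distance.
# Distances between landmasses are therefore routed through obligatory
# waypoints representing the likely migration gateways: Anadyr (Russia),
# Cairo (Egypt), Istanbul (Turkey), Phnom Penh (Cambodia) and Prince
# Rupert (Canada).

.EARTH_RADIUS_KM <- 6371.0

#' Great-circle (haversine) distance in kilometres
#'
#' @param a,b points as `c(lat, lon)` in decimal degrees, or two-column
#'   matrices of such points.
#' @param radius sphere radius in km (Earth mean radius by default; no
#'   ellipsoid — great circles suffice at continental resolution).
#' @return distance(s) in km.
#' @export
haversine_km <- function(a, b, radius = .EARTH_RADIUS_KM) {
  a <- matrix(as.numeric(a), ncol = 2L)
  b <- matrix(as.numeric(b), ncol = 2L)
  if (any(abs(a[, 1L]) > 90) || any(abs(b[, 1L]) > 90) ||
      any(abs(a[, 2L]) > 180) || any(abs(b[, 2L]) > 180)) {
    stop("invalid coordinates: need lat in [-90, 90], lon in [-180, 180]")
  }
  to_rad <- pi / 180
  dlat <- (b[, 1L] - a[, 1L]) * to_rad / 2
  dlon <- (b[, 2L] - a[, 2L]) * to_rad / 2
  h <- sin(dlat)^2 +
    cos(a[, 1L] * to_rad) * cos(b[, 1L] * to_rad) * sin(dlon)^2
  d <- 2 * radius * asin(pmin(1, sqrt(h)))
  if (length(d) == 1L) as.numeric(d) else d
}

#' Default waypoint configuration
#'
#' Five obligatory waypoints represent the migration gateways between
#' continental landmasses. Each routing region is given a "gateway path":
#' the ordered waypoint list leading toward the African origin area. The
#' default table covers the 12 standard world regions (NAF, SAF, EUR,
#' SWAS, SAS, CAS, SEAS, EAS, NEAS, AUS, NAM, CSAM): Africa direct; Europe
#' via Istanbul and Cairo; West/South/Central Asia via Cairo; East and
#' Northeast Asia via Cairo; Southeast Asia and Australia via Phnom Penh
#' and Cairo; North America via Anadyr and Cairo; Central/South America
#' via Prince Rupert, Anadyr and Cairo. The exact assignment for region
#' pairs not spelled out by the gateway logic is an assumption of this
#' package and the whole table is overridable.
#'
#' @param paths named list: region -> character vector of waypoint names
#'   ordered from the region toward the origin (empty = direct).
#' @param waypoints named list of `c(lat, lon)` waypoint coordinates.
#' @param radius sphere radius (km).
#' @return list of class `waypoint_config`.
#' @export
waypoint_config <- function(paths = NULL, waypoints = NULL,
                            radius = .EARTH_RADIUS_KM) {
  if (is.null(waypoints)) {
    waypoints <- list(
      Anadyr = c(64.73, 177.51),
      Cairo = c(30.05, 31.25),
      Istanbul = c(41.01, 28.96),
      PhnomPenh = c(11.56, 104.92),
      PrinceRupert = c(54.31, -130.32))
  }
  if (is.null(paths)) {
    paths <- list(
      NAF = character(), SAF = character(),
      EUR = c("Istanbul", "Cairo"),
      SWAS = c("Cairo"), SAS = c("Cairo"), CAS = c("Cairo"),
      EAS = c("Cairo"), NEAS = c("Cairo"),
      SEAS = c("PhnomPenh", "Cairo"), AUS = c("PhnomPenh", "Cairo"),
      NAM = c("Anadyr", "Cairo"),
      CSAM = c("PrinceRupert", "Anadyr", "Cairo"))
  }
  for (p in paths) {
    if (!all(p %in% names(waypoints))) stop("unknown waypoint in path")
  }
  structure(list(paths = paths, waypoints = waypoints, radius = radius),
            class = "waypoint_config")
}

# Ordered waypoint list between two regions: each region carries a
# gateway path toward the African origin hub; the pair route follows one
# path forward and the other backward, with their shared suffix (the
# gateways both would pass anyway) stripped so no detour through the hub
# side is introduced. Same region -> empty route (direct distance).
.route_between <- function(r1, r2, cfg) {
  if (!r1 %in% names(cfg$paths)) stop("unresolvable region: ", r1)
  if (!r2 %in% names(cfg$paths)) stop("unresolvable region: ", r2)
  if (r1 == r2) return(character())
  w1 <- cfg$paths[[r1]]
  w2 <- cfg$paths[[r2]]
  while (length(w1) > 0L && length(w2) > 0L &&
         w1[length(w1)] == w2[length(w2)]) {
    w1 <- w1[-length(w1)]
    w2 <- w2[-length(w2)]
  }
  c(w1, rev(w2))
}

#' Routed distance from a population to a destination point
#'
#' Sum of great-circle legs through the ordered waypoints prescribed by
#' the routing configuration for (population region, destination region);
#' an empty route is a direct great-circle distance. An example routed
#' query: a North American population to an East African origin runs
#' population -> Anadyr -> Cairo -> origin.
#'
#' @param pop_point `c(lat, lon)` of the population.
#' @param pop_region the population's routing region.
#' @param dest_point `c(lat, lon)` of the destination.
#' @param dest_region the destination's routing region.
#' @param cfg a [waypoint_config].
#' @return km along the routed path.
#' @export
route_distance <- function(pop_point, pop_region, dest_point, dest_region,
                           cfg = waypoint_config()) {
  wps <- .route_between(pop_region, dest_region, cfg)
  pts <- rbind(matrix(pop_point, ncol = 2L),
               do.call(rbind, lapply(wps, function(w) cfg$waypoints[[w]])),
               matrix(dest_point, ncol = 2L))
  sum(haversine_km(pts[-nrow(pts), , drop = FALSE],
                   pts[-1L, , drop = FALSE], radius = cfg$radius))
}

#' Routed distance of every population from an origin point
#'
#' @param meta a `pop_metadata` data frame.
#' @param origin `c(lat, lon)` of the origin; default Addis Ababa
#'   (9.03 N, 38.74 E), the conventional East African origin proxy.
#' @param origin_region routing region of the origin.
#' @param cfg a [waypoint_config].
#' @return named numeric vector of km, one per population.
#' @export
distance_from_origin <- function(meta, origin = c(9.03, 38.74),
                                 origin_region = "SAF",
                                 cfg = waypoint_config()) {
  d <- vapply(seq_len(nrow(meta)), function(i) {
    route_distance(c(meta$lat[i], meta$lon[i]), meta$region[i],
                   origin, origin_region, cfg)
  }, 0)
  stats::setNames(d, meta$population)
}

#' Pairwise routed geographic distance matrix
#'
#' Intra-region pairs use the direct great-circle distance; inter-region
#' pairs sum the legs through the configured waypoints.
#'
#' @inheritParams distance_from_origin
#' @return symmetric km matrix with zero diagonal, populations in
#'   metadata order.
#' @export
pairwise_geo_matrix <- function(meta, cfg = waypoint_config()) {
  P <- nrow(meta)
  m <- matrix(0, P, P, dimnames = list(meta$population, meta$population))
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      m[i, j] <- m[j, i] <- route_distance(
        c(meta$lat[i], meta$lon[i]), meta$region[i],
        c(meta$lat[j], meta$lon[j]), meta$region[j], cfg)
    }
  }
  m
}

#' Diversity versus distance-from-origin regression
#'
#' Ordinary least-squares regression of a per-population diversity index
#' on routed geographic distance from the origin, reporting the
#' determination coefficient R^2 (the proportion of diversity variation
#' explained by distance) and the two-sided t-test on the slope.
#'
#' @param values numeric diversity values, one per population.
#' @param distances matching distances (km).
#' @return list of class `regression_result`: `slope`, `intercept`, `r2`,
#'   `t`, `p`, `n`.
#' @export
diversity_distance_regression <- function(values, distances) {
  if (length(values) != length(distances)) stop("length mismatch")
  if (length(values) < 3L) stop("need >= 3 populations")
  if (stats::var(distances) == 0) stop("zero variance in distances")
  fit <- stats::lm(values ~ distances)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = sm$r.squared,
                 t = sm$coefficients[2L, "t value"],
                 p = sm$coefficients[2L, "Pr(>|t|)"],
                 n = length(values)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "OLS: slope = %.4g /km, R^2 = %.4f, t = %.3f, p = %.3g, n = %d\n",
    x$slope, x$r2, x$t, x$p, x$n))
  invisible(x)
}
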