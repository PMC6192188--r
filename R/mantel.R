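#' Great-circle distance in kilometres
#'
#' Haversine formula on a sphere of radius 6371.0 km. Vectorized over
#' its arguments.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees.
#' @return distance in km.
#' @export
#' @examples
#' greatCircleKm(0, 0, 0, 180)  # half the circumference, ~20015 km
greatCircleKm <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Population great-circle distance matrix
#'
#' @param popmap a \linkS4class{PopulationMap} (or
#'   \linkS4class{HaplotypeTable}, whose map is used).
#' @return symmetric matrix of great-circle distances in km between
#'   populations with coordinates.
#' @export
geoDistMatrix <- function(popmap) {
  if (is(popmap, "HaplotypeTable")) popmap <- popmap@popmap
  pd <- popmap@populations
  ok <- stats::complete.cases(pd[, c("lat", "lon")])
  pd <- pd[ok, ]
  n <- nrow(pd)
  out <- matrix(0, n, n, dimnames = list(pd$population, pd$population))
  for (i in seq_len(n)) out[i, ] <-
    greatCircleKm(pd$lat[i], pd$lon[i], pd$lat, pd$lon)
  out
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the off-diagonal elements of a genetic
#' and a geographic distance matrix, with significance from
#' simultaneous row/column permutations of one matrix (one-sided for
#' r > 0), via \code{vegan::mantel}.
#'
#' @param geneticDist symmetric population-pairwise genetic distance
#'   matrix (e.g. from \code{\link{pairwisePhiST}}).
#' @param geoDist symmetric matrix of great-circle distances in km, in
#'   the same population order.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @param method label recorded in the result (the genetic-distance
#'   variant used upstream).
#' @return a \linkS4class{MantelResult}.
#' @export
mantelTest <- function(geneticDist, geoDist, nPerm = 1000L, seed = 1L,
                       method = "phist") {
  geneticDist <- as.matrix(geneticDist)
  geoDist <- as.matrix(geoDist)
  if (!identical(dim(geneticDist), dim(geoDist)))
    stop("matrices must have identical dimensions")
  if (nrow(geneticDist) < 4)
    stop("need at least 4 populations for a Mantel test")
  if (!is.null(rownames(geneticDist)) && !is.null(rownames(geoDist)) &&
      !identical(rownames(geneticDist), rownames(geoDist)))
    stop("matrices must be in the same population order")
  lower <- geneticDist[lower.tri(geneticDist)]
  if (stats::sd(lower) == 0 ||
      stats::sd(geoDist[lower.tri(geoDist)]) == 0)
    stop("zero-variance distance matrix: r undefined")
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(geneticDist),
                      stats::as.dist(geoDist),
                      method = "pearson", permutations = nPerm)
  new("MantelResult", r = unname(mt$statistic),
      pValue = unname(mt$signif), nPerm = as.integer(nPerm),
      seed = as.integer(seed), method = method)
}
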