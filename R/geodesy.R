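#' Great-circle distance between points, in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean Earth
#' radius). Vectorised over coordinates; inputs are decimal degrees (WGS84).
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees. Latitudes must
#'   lie in \[-90, 90\], longitudes in \[-180, 180\].
#' @param radius_km Sphere radius in km. The default is the IUGG mean radius;
#'   all outputs scale linearly with it.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(23.1136, -82.3666, 20.0247, -75.8219) # Havana -> Santiago
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0088) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  n <- max(length(lat1), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = radius_km))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    abort("coordinates must be finite numbers")
  }
  if (any(abs(lat) > 90)) abort("latitude out of range [-90, 90]")
  if (any(abs(lon) > 180)) abort("longitude out of range [-180, 180]")
  invisible(TRUE)
}

#' Pairwise geographic distance matrix for a locality table
#'
#' @param localities Data frame with columns `locality`, `lat`, `lon`
#'   (decimal degrees). Locality ids must be unique.
#' @param radius_km Sphere radius passed to [haversine_km()].
#' @return Symmetric matrix of km distances with zero diagonal, dimnames set
#'   to the locality ids, rows in input order.
#' @export
geographic_matrix <- function(localities, radius_km = 6371.0088) {
  stopifnot(is.data.frame(localities))
  need <- c("locality", "lat", "lon")
  if (!all(need %in% names(localities))) {
    abort(paste("locality table must have columns:", paste(need, collapse = ", ")))
  }
  ids <- as.character(localities$locality)
  if (anyDuplicated(ids)) abort("duplicate locality ids")
  if (nrow(localities) < 2) abort("need at least 2 localities")
  check_coords(localities$lat, localities$lon)
  m <- geosphere::distm(cbind(localities$lon, localities$lat),
                        fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = radius_km))
  dimnames(m) <- list(ids, ids)
  diag(m) <- 0
  m
}

#' Mean over unordered pairs of a distance matrix subset
#'
#' The per-clade summary used throughout: the unweighted mean of all
#' off-diagonal values d(i, j), i < j, for the chosen labels.
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param labels Optional character vector of labels to subset; default all.
#' @return Scalar mean over the `choose(n, 2)` unordered pairs.
#' @export
mean_pairwise <- function(d, labels = NULL) {
  stopifnot(is.matrix(d))
  if (is.null(labels)) labels <- rownames(d)
  labels <- as.character(labels)
  missing <- setdiff(labels, rownames(d))
  if (length(missing)) {
    abort(paste("labels not in matrix:", paste(missing, collapse = ", ")))
  }
  if (length(labels) < 2) abort("need at least 2 labels for a pairwise mean")
  sub <- d[labels, labels, drop = FALSE]
  mean(sub[upper.tri(sub)])
}
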