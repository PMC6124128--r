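# Earth radius (km) used throughout; all distances are haversine
# great-circle distances on a sphere of this radius.
EARTH_RADIUS_KM <- 6371.0

.check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("coordinates must be finite")
  }
  if (any(lat < -90 | lat > 90)) stop("latitude out of range [-90, 90]")
  if (any(lon <= -180 | lon > 180)) stop("longitude out of range (-180, 180]")
  invisible(TRUE)
}

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371 km.  Coordinates are
#' signed decimal degrees, latitude first.
#'
#' @param a,b numeric length-2 vectors `c(lat, lon)`.
#' @return distance in kilometres.
#' @export
#' @examples
#' great_circle_distance(c(0, 0), c(0, 180)) # half the circumference
great_circle_distance <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2)
  .check_coords(c(a[1], b[1]), c(a[2], b[2]))
  # geosphere wants (lon, lat)
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]),
                           r = EARTH_RADIUS_KM)
}

#' All-pairs great-circle distance matrix
#'
#' @param coords data.frame with columns `society_id`, `lat`, `lon`
#'   (signed decimal degrees).
#' @return symmetric matrix of distances in km, zero diagonal, dimnames =
#'   society ids.
#' @export
distance_matrix <- function(coords) {
  stopifnot(all(c("society_id", "lat", "lon") %in% names(coords)))
  if (nrow(coords) < 2) stop("need at least two societies")
  if (anyDuplicated(coords$society_id)) {
    stop("duplicate society_id in coordinate table")
  }
  .check_coords(coords$lat, coords$lon)
  D <- geosphere::distm(cbind(coords$lon, coords$lat),
                        fun = function(p1, p2) {
                          geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM)
                        })
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(coords$society_id, coords$society_id)
  D
}

#' Gaussian spatial similarity kernel
#'
#' `S_ij = exp(-(d_ij / sigma_s)^2)` where `d_ij` is the great-circle
#' distance and `sigma_s` the spatial length-scale in km.  Gaussian
#' kernels of geodesic distance are not guaranteed positive definite on
#' the sphere, so the matrix is eigenvalue-floor repaired (see
#' [psd_repair()]) before use in covariance assembly.
#'
#' @param D distance matrix in km (from [distance_matrix()]).
#' @param sigma_s length-scale in km, > 0.
#' @param repair logical; repair to PSD (default TRUE).
#' @return symmetric kernel matrix with unit diagonal.
#' @export
gaussian_similarity <- function(D, sigma_s, repair = TRUE) {
  if (!is.numeric(sigma_s) || length(sigma_s) != 1 || sigma_s <= 0) {
    stop("sigma_s must be a single positive number (km)")
  }
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  S <- exp(-(D / sigma_s)^2)
  if (repair) {
    S <- psd_repair(S)
    # renormalize to a correlation matrix: keeps PSD and the unit diagonal
    if (isTRUE(attr(S, "psd_repaired"))) S <- stats::cov2cor(S)
  }
  diag(S) <- 1
  dimnames(S) <- dimnames(D)
  S
}
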