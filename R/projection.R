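#' Project longitude/latitude to planar kilometres
#'
#' Equirectangular projection centred at the domain mid-latitude: one degree
#' of latitude is taken as 110.57 km and one degree of longitude as
#' 111.32 * cos(mid-latitude) km. All distances used by the spatial model are
#' Euclidean in these coordinates, so the correlation range `phi` is always
#' in kilometres. Adequate for country-scale extents at low latitudes where
#' survey clusters span a few degrees.
#'
#' @param lon,lat numeric vectors of decimal degrees.
#' @param origin optional `c(lon0, lat0)` reference point; defaults to the
#'   midpoint of the data range so coordinates are centred on the domain.
#' @return data.frame with columns `x_km`, `y_km` and the origin as an
#'   attribute `origin`.
#' @examples
#' lonlat_to_km(c(80, 81), c(7, 8))
#' @export
lonlat_to_km <- function(lon, lat, origin = NULL) {
  if (length(lon) != length(lat)) stopf("lon and lat lengths differ")
  if (any(!is.finite(lon)) || any(!is.finite(lat))) {
    stopf("non-finite coordinates")
  }
  if (any(abs(lat) > 90) || any(abs(lon) > 360)) {
    stopf("coordinates outside valid degree ranges")
  }
  if (is.null(origin)) origin <- c(mean(range(lon)), mean(range(lat)))
  midlat <- origin[2]
  out <- data.frame(
    x_km = (lon - origin[1]) * 111.32 * cos(midlat * pi / 180),
    y_km = (lat - origin[2]) * 110.57
  )
  attr(out, "origin") <- origin
  out
}
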