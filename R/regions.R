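#' Read region polygons from GeoJSON
#'
#' Parses a GeoJSON `FeatureCollection` of `Polygon`/`MultiPolygon` features
#' into a list of named rings usable by [assign_regions()]. The region name is
#' taken from the first of the `name`, `country` or `continent` properties
#' that is present.
#'
#' @param path GeoJSON file.
#' @return list of regions; each region is `list(name =, rings = list of
#'   n x 2 matrices (lon, lat))`. Interior rings are treated by even-odd
#'   parity, so holes behave correctly.
#' @export
regions_from_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (!is.null(gj$features)) gj$features else list(gj)
  lapply(feats, function(f) {
    props <- f$properties
    nm <- props$name
    if (is.null(nm)) nm <- props$country
    if (is.null(nm)) nm <- props$continent
    if (is.null(nm)) nm <- "region"
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    rings <- list()
    for (poly in polys) {
      for (ring in poly) {
        m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
        rings[[length(rings) + 1L]] <- m
      }
    }
    list(name = as.character(nm), rings = rings)
  })
}

# Even-odd ray-casting point-in-polygon over a set of rings.
.point_in_rings <- function(lon, lat, rings) {
  inside <- rep(FALSE, length(lon))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
      cross <- ((yi > lat) != (yj > lat)) &
        (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross & !is.na(cross))
    }
  }
  inside
}

#' Assign points to regions
#'
#' @param lon,lat point coordinates (degrees).
#' @param regions list from [regions_from_geojson()].
#' @return character vector of region names; `"unassigned"` for points in no
#'   region (first match wins when regions overlap).
#' @export
assign_regions <- function(lon, lat, regions) {
  out <- rep("unassigned", length(lon))
  for (rg in regions) {
    hit <- out == "unassigned" & .point_in_rings(lon, lat, rg$rings)
    out[hit] <- rg$name
  }
  out
}
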