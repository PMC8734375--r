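#' Normalise a UK-style postcode
#'
#' Upper-cases, trims, and collapses internal whitespace to a single space;
#' a postcode written without any space gains one before its final three
#' characters (the inward code), so `"ba1  7np"` and `"BA17NP"` both
#' normalise to `"BA1 7NP"`.
#'
#' @param x Character vector of raw postcodes.
#' @return Character vector of normalised postcodes.
#' @export
normalise_postcode <- function(x) {
  p <- stringr::str_squish(toupper(x))
  no_space <- !is.na(p) & !stringr::str_detect(p, " ") & nchar(p) >= 5
  p[no_space] <- paste(
    stringr::str_sub(p[no_space], 1L, -4L),
    stringr::str_sub(p[no_space], -3L, -1L)
  )
  p
}

#' Attach coordinates to a practice directory
#'
#' Normalises practice postcodes and joins the postcode lookup. Practices
#' whose postcode is absent from the lookup are retained with missing
#' coordinates and counted in a warning — they drop out of region
#' membership but never out of mass aggregation.
#'
#' @param practices Practice directory from [read_practices()].
#' @param lookup Postcode lookup from [read_postcode_lookup()].
#' @return Tibble `(practice, name, address, postcode, lon, lat)` in WGS84.
#' @export
geolocate_practices <- function(practices, lookup) {
  out <- practices
  out$postcode <- normalise_postcode(out$postcode)
  out <- dplyr::left_join(out, lookup, by = "postcode")
  n_missing <- sum(is.na(out$lon))
  if (n_missing > 0) {
    warning(n_missing, " practice(s) have postcodes absent from the lookup",
            call. = FALSE)
  }
  out
}

#' Read region boundary polygons from a GeoJSON FeatureCollection
#'
#' Supports `Polygon` and `MultiPolygon` geometries; the region name is
#' taken from a `name` property (falling back to the first property).
#' Coordinates are WGS84 lon/lat; rings must be closed.
#'
#' @param path Path to a GeoJSON file.
#' @return Named list of `region_boundary` objects; each holds `name` and
#'   `polygons`, a list of polygons, each a list of rings (two-column
#'   lon/lat matrices).
#' @export
read_region_boundaries <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- lapply(feats, function(f) {
    props <- f$properties
    name <- if (!is.null(props$name)) props$name else props[[1]]
    geom <- f$geometry
    ring_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    }
    polys <- switch(
      geom$type,
      Polygon = list(lapply(geom$coordinates, ring_mat)),
      MultiPolygon = lapply(geom$coordinates, function(p) lapply(p, ring_mat)),
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    region_boundary(name, polys)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Construct a region boundary
#'
#' @param name Region name.
#' @param polygons List of polygons; each polygon a list of rings; each ring
#'   a closed two-column lon/lat matrix (first row equals last row, at least
#'   four rows).
#' @return A `region_boundary` object.
#' @export
region_boundary <- function(name, polygons) {
  for (poly in polygons) {
    for (ring in poly) {
      stopifnot(is.matrix(ring), ncol(ring) == 2, nrow(ring) >= 4,
                all(ring[1, ] == ring[nrow(ring), ]))
    }
  }
  structure(list(name = name, polygons = polygons), class = "region_boundary")
}

#' Rectangular region boundary helper
#'
#' @param name Region name.
#' @param xmin,ymin,xmax,ymax Rectangle corners (lon/lat).
#' @return A [region_boundary()].
#' @export
region_rectangle <- function(name, xmin, ymin, xmax, ymax) {
  ring <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
                c(xmin, ymax), c(xmin, ymin))
  region_boundary(name, list(list(ring)))
}

# even-odd crossing test for one ring; points on an edge are "on"
ring_crossings <- function(lon, lat, ring, eps = 1e-12) {
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(lon))
  on_edge <- rep(FALSE, length(lon))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    # point exactly on the segment (cross product ~ 0 and inside the bbox)
    cross <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
    on_seg <- abs(cross) <= eps &
      lon >= pmin(x1, x2) - eps & lon <= pmax(x1, x2) + eps &
      lat >= pmin(y1, y2) - eps & lat <= pmax(y1, y2) + eps
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > lat) != (y2 > lat)) &
      (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  list(inside = inside, on_edge = on_edge)
}

#' Point-in-region containment test
#'
#' Even-odd (ray-casting) containment over every ring of every polygon of
#' the boundary, so holes are honoured without winding conventions. Points
#' lying exactly on a boundary edge count as inside (closed polygons — a
#' deterministic tie-break for practices on a region border). Planar
#' geometry in lon/lat: at the scale of health-region polygons the geodesic
#' error is negligible.
#'
#' @param lon,lat Numeric vectors (recycled to common length).
#' @param boundary A [region_boundary()].
#' @return Logical vector, `NA` where a coordinate is missing.
#' @export
point_in_region <- function(lon, lat, boundary) {
  stopifnot(inherits(boundary, "region_boundary"))
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  inside <- rep(FALSE, n)
  on_edge <- rep(FALSE, n)
  for (poly in boundary$polygons) {
    poly_in <- rep(FALSE, n)
    for (ring in poly) {
      r <- ring_crossings(lon, lat, ring)
      poly_in <- xor(poly_in, r$inside)
      on_edge <- on_edge | r$on_edge
    }
    inside <- inside | poly_in
  }
  out <- inside | on_edge
  out[is.na(lon) | is.na(lat)] <- NA
  out
}

#' Practices falling inside a region
#'
#' @param geo A geolocated practice table from [geolocate_practices()].
#' @param boundary A [region_boundary()].
#' @return Sorted character vector of practice codes with known coordinates
#'   inside the boundary.
#' @export
practices_in_region <- function(geo, boundary) {
  inside <- point_in_region(geo$lon, geo$lat, boundary)
  sort(geo$practice[!is.na(inside) & inside])
}

#' Assign each practice to the first region containing it
#'
#' @param geo A geolocated practice table.
#' @param boundaries List of [region_boundary()] objects (as from
#'   [read_region_boundaries()]).
#' @return `geo` with a `region` column (`NA` when no region contains the
#'   practice or its coordinates are unknown).
#' @export
assign_regions <- function(geo, boundaries) {
  region <- rep(NA_character_, nrow(geo))
  for (b in boundaries) {
    inside <- point_in_region(geo$lon, geo$lat, b)
    hit <- is.na(region) & !is.na(inside) & inside
    region[hit] <- b$name
  }
  dplyr::mutate(geo, region = region)
}
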