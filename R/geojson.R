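# Boundaries live in a tibble with a geometry list-column, always in
# WGS84 lon/lat. Each geometry element is a list(type = "Polygon" |
# "MultiPolygon" | "Point", coords = ...): Point coords are c(lon, lat);
# Polygon coords are a list of rings, each a 2-column matrix; a
# MultiPolygon is a list of polygons.

inv_web_mercator <- function(xy) {
  r <- 6378137
  cbind(
    xy[, 1] / r * 180 / pi,
    (2 * atan(exp(xy[, 2] / r)) - pi / 2) * 180 / pi
  )
}

reproject_geom <- function(geom, epsg) {
  if (epsg == 4326) return(geom)
  if (epsg != 3857) {
    abort(sprintf("unsupported CRS EPSG:%s (expected 4326 or 3857)", epsg))
  }
  tx <- function(m) inv_web_mercator(m)
  if (geom$type == "Point") {
    geom$coords <- as.numeric(tx(matrix(geom$coords, 1)))
  } else if (geom$type == "Polygon") {
    geom$coords <- lapply(geom$coords, tx)
  } else {
    geom$coords <- lapply(geom$coords, function(p) lapply(p, tx))
  }
  geom
}

ring_matrix <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(pt) as.numeric(pt[1:2])))
  # close the ring if the source left it open
  if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

# Crossing-segments check for small rings; O(n^2), skipped for large ones.
ring_self_intersects <- function(m) {
  n <- nrow(m) - 1
  if (n > 500) return(FALSE)
  seg <- function(i) list(a = m[i, ], b = m[i + 1, ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next # shared endpoint of the closing segment
      s1 <- seg(i); s2 <- seg(j)
      d1 <- cross(s2$a, s2$b, s1$a); d2 <- cross(s2$a, s2$b, s1$b)
      d3 <- cross(s1$a, s1$b, s2$a); d4 <- cross(s1$a, s1$b, s2$b)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

parse_geometry <- function(g) {
  type <- g$type
  if (type == "Point") {
    list(type = "Point", coords = as.numeric(unlist(g$coordinates)[1:2]))
  } else if (type == "Polygon") {
    list(type = "Polygon", coords = lapply(g$coordinates, ring_matrix))
  } else if (type == "MultiPolygon") {
    list(type = "MultiPolygon",
      coords = lapply(g$coordinates, function(p) lapply(p, ring_matrix)))
  } else {
    abort(sprintf("unsupported geometry type `%s`", type))
  }
}

validate_geometry <- function(geom, id) {
  pts <- geometry_points(geom)
  if (any(!is.finite(pts))) {
    abort(sprintf("region %s has non-finite coordinates", id))
  }
  if (geom$type != "Point") {
    rings <- if (geom$type == "Polygon") geom$coords else unlist(geom$coords, recursive = FALSE)
    for (m in rings) {
      if (nrow(m) < 4) abort(sprintf("region %s has a degenerate ring", id))
      if (ring_self_intersects(m)) {
        abort(sprintf("region %s has a self-intersecting ring", id))
      }
    }
  }
  invisible(geom)
}

geometry_points <- function(geom) {
  if (geom$type == "Point") return(matrix(geom$coords, 1))
  rings <- if (geom$type == "Polygon") geom$coords else unlist(geom$coords, recursive = FALSE)
  do.call(rbind, rings)
}

#' Read region boundaries from GeoJSON
#'
#' Parses a GeoJSON FeatureCollection of polygons/multipolygons (area
#' regions such as counties or tracts) or points (individual
#' locations). Every feature must carry a `region_id` property;
#' geometries are stored in WGS84 (a legacy `crs` member naming
#' EPSG:3857 triggers inverse web-mercator reprojection at load).
#'
#' @param path Path to a GeoJSON file.
#' @return A region-set tibble (`region_id`, `geometry` list-column)
#'   with attribute `kind` = `"area"` or `"point"`.
#' @export
read_regions <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    abort("boundaries must be a GeoJSON FeatureCollection")
  }
  epsg <- 4326
  crs_name <- tryCatch(gj$crs$properties$name, error = function(e) NULL)
  if (!is.null(crs_name)) {
    digits <- stringr::str_extract(crs_name, "[0-9]+$")
    if (!is.na(digits)) epsg <- as.integer(digits)
  }
  feats <- gj$features
  if (length(feats) == 0) abort("boundary file has no features")
  ids <- purrr::map_chr(feats, function(f) {
    id <- f$properties$region_id
    if (is.null(id) || !nzchar(as.character(id))) {
      abort("every feature needs a non-empty `region_id` property")
    }
    as.character(id)
  })
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate region_id in boundaries: %s",
      ids[duplicated(ids)][1]))
  }
  geoms <- purrr::map(feats, function(f) {
    reproject_geom(parse_geometry(f$geometry), epsg)
  })
  purrr::walk2(geoms, ids, validate_geometry)
  kinds <- purrr::map_chr(geoms, function(g) {
    if (g$type == "Point") "point" else "area"
  })
  if (length(unique(kinds)) > 1) {
    abort("mixed point and area geometries in one region set")
  }
  set_boundaries(tibble::tibble(region_id = ids), geoms)
}

#' Attach geometries to a region table
#'
#' Builds (or replaces) the geometry list-column of a region set. Point
#' geometries describe individual locations (e.g. residential
#' addresses) and are analyzed as regions of population size 1 unless
#' `n_per_region` overrides.
#'
#' @param regions Data frame with a `region_id` column.
#' @param geometry List of geometries (see [read_regions()]) or a
#'   two-column matrix of lon/lat points.
#' @return A region-set tibble with attribute `kind`.
#' @export
set_boundaries <- function(regions, geometry) {
  assert_columns(regions, "region_id", "regions")
  if (is.matrix(geometry)) {
    geometry <- purrr::map(seq_len(nrow(geometry)), function(i) {
      list(type = "Point", coords = as.numeric(geometry[i, 1:2]))
    })
  }
  if (length(geometry) != nrow(regions)) {
    abort("one geometry per region required")
  }
  purrr::walk2(geometry, regions$region_id, validate_geometry)
  kinds <- unique(purrr::map_chr(geometry, function(g) {
    if (g$type == "Point") "point" else "area"
  }))
  if (length(kinds) > 1) abort("mixed point and area geometries in one region set")
  out <- tibble::as_tibble(regions)
  out$region_id <- as.character(out$region_id)
  out$geometry <- geometry
  structure(out, kind = kinds)
}

geometry_to_geojson <- function(geom) {
  unmat <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  coords <- switch(geom$type,
    Point = as.numeric(geom$coords),
    Polygon = lapply(geom$coords, unmat),
    MultiPolygon = lapply(geom$coords, function(p) lapply(p, unmat))
  )
  list(type = geom$type, coordinates = coords)
}

#' Write a region set to GeoJSON
#'
#' @param regions A region set (see [read_regions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  feats <- purrr::map2(regions$region_id, regions$geometry, function(id, g) {
    list(
      type = "Feature",
      properties = list(region_id = id),
      geometry = geometry_to_geojson(g)
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# Flatten polygon rings for ggplot choropleths.
regions_to_df <- function(regions) {
  purrr::map2(regions$region_id, regions$geometry, function(id, g) {
    polys <- switch(g$type,
      Point = return(tibble::tibble(region_id = id, lon = g$coords[1],
        lat = g$coords[2], ring = paste0(id, ".pt"))),
      Polygon = list(g$coords),
      MultiPolygon = g$coords
    )
    purrr::imap(polys, function(rings, pi) {
      purrr::imap(rings, function(m, ri) {
        tibble::tibble(region_id = id, lon = m[, 1], lat = m[, 2],
          ring = paste(id, pi, ri, sep = "."))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
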