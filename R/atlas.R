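#' Region atlas: botanical-country polygons, centroids and ISO mapping
#'
#' A `region_atlas` holds the geographic reference data the pipeline needs:
#' one or more WGS84 polygons per botanical-country code, a centroid per
#' region, a mapping from ISO 3166-1 alpha-2 country codes to the botanical
#' countries they contain, and an oceanic-island flag per region. Botanical
#' countries are the standard recording unit of the World Geographical Scheme
#' for Recording Plant Distributions; real atlases are read from GeoJSON with
#' [read_region_atlas()], and [toy_atlas()] builds a small rectangular atlas
#' for simulation and testing.
#'
#' @param regions Named list; each element is a list of polygon rings, each
#'   ring a two-column numeric matrix of (longitude, latitude) vertices in
#'   WGS84. Holes are not supported.
#' @param centroids Optional data frame with columns `region_code`, `lat`,
#'   `lon`. Defaults to the vertex bounding-box centre of each region.
#' @param iso_map Named list mapping ISO country codes to character vectors of
#'   region codes.
#' @param island Optional named logical vector flagging oceanic-island
#'   regions; defaults to `FALSE` for all regions.
#' @return An object of class `region_atlas`.
#' @export
region_atlas <- function(regions, centroids = NULL, iso_map = list(),
                         island = NULL) {
  .assert(is.list(regions) && length(regions) > 0 && !is.null(names(regions)),
          "`regions` must be a non-empty named list of polygon lists")
  for (rc in names(regions)) {
    polys <- regions[[rc]]
    .assert(is.list(polys) && length(polys) > 0,
            "region %s: polygons must be a non-empty list", rc)
    for (p in polys) {
      .assert(is.matrix(p) && ncol(p) == 2 && nrow(p) >= 3,
              "region %s: each ring must be an n x 2 (lon, lat) matrix, n >= 3",
              rc)
    }
  }
  if (is.null(centroids)) {
    centroids <- do.call(rbind, lapply(names(regions), function(rc) {
      v <- do.call(rbind, regions[[rc]])
      data.frame(region_code = rc,
                 lat = mean(range(v[, 2])),
                 lon = mean(range(v[, 1])),
                 stringsAsFactors = FALSE)
    }))
  }
  .assert(all(c("region_code", "lat", "lon") %in% names(centroids)),
          "centroids must have columns region_code, lat, lon")
  if (is.null(island)) {
    island <- stats::setNames(rep(FALSE, length(regions)), names(regions))
  }
  miss <- setdiff(names(regions), names(island))
  island[miss] <- FALSE
  structure(list(regions = regions,
                 centroids = centroids,
                 iso_map = iso_map,
                 island = island[names(regions)]),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("<region_atlas> %d regions, %d ISO codes mapped, %d island-flagged\n",
              length(x$regions), length(x$iso_map), sum(x$island)))
  invisible(x)
}

#' Build a rectangular toy atlas
#'
#' Constructs an atlas of rectangular "botanical countries": `n_equatorial`
#' 10 x 10 degree rectangles on the equatorial band (latitude -5..5),
#' `n_temperate` rectangles at latitude 25..35, and `n_island` equatorial
#' rectangles flagged as oceanic islands. ISO codes `C01`, `C02`, ... map
#' one-to-one onto the regions. Used by the synthetic-data generator so that
#' scenarios never depend on real-world geometry.
#'
#' @param n_equatorial,n_temperate,n_island Counts of each region type.
#' @return A `region_atlas`.
#' @export
toy_atlas <- function(n_equatorial = 4, n_temperate = 2, n_island = 1) {
  rect <- function(lon0, lat0, w = 10, h = 10) {
    list(cbind(lon = c(lon0, lon0 + w, lon0 + w, lon0, lon0),
               lat = c(lat0, lat0, lat0 + h, lat0 + h, lat0)))
  }
  regions <- list(); island <- logical(0)
  k <- 0
  for (i in seq_len(n_equatorial)) {
    k <- k + 1
    regions[[sprintf("R%02d", k)]] <- rect((i - 1) * 10, -5)
    island[sprintf("R%02d", k)] <- FALSE
  }
  for (i in seq_len(n_temperate)) {
    k <- k + 1
    regions[[sprintf("R%02d", k)]] <- rect((i - 1) * 10, 25)
    island[sprintf("R%02d", k)] <- FALSE
  }
  for (i in seq_len(n_island)) {
    k <- k + 1
    regions[[sprintf("R%02d", k)]] <- rect(100 + (i - 1) * 10, -5)
    island[sprintf("R%02d", k)] <- TRUE
  }
  iso_map <- stats::setNames(as.list(names(regions)),
                             sprintf("C%02d", seq_along(regions)))
  region_atlas(regions, iso_map = iso_map, island = island)
}

# Point-in-ring test by ray casting, with points on the boundary counted as
# inside (a record on the shared border of a native and a foreign region is
# kept). Tolerance is absolute in degrees.
#' @noRd
.point_in_ring <- function(lat, lon, ring, tol = 1e-12) {
  xs <- ring[, 1]; ys <- ring[, 2]
  n <- nrow(ring)
  if (xs[1] != xs[n] || ys[1] != ys[n]) { # close the ring
    xs <- c(xs, xs[1]); ys <- c(ys, ys[1]); n <- n + 1
  }
  # boundary check: point on any segment
  for (i in seq_len(n - 1)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[i + 1]; y2 <- ys[i + 1]
    cross <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
    if (abs(cross) <= tol &&
        lon >= min(x1, x2) - tol && lon <= max(x1, x2) + tol &&
        lat >= min(y1, y2) - tol && lat <= max(y1, y2) + tol) {
      return(TRUE)
    }
  }
  inside <- FALSE
  j <- n - 1
  for (i in seq_len(n - 1)) {
    if ((ys[i] > lat) != (ys[j] > lat)) {
      xint <- (xs[j] - xs[i]) * (lat - ys[i]) / (ys[j] - ys[i]) + xs[i]
      if (lon < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Test whether points fall inside a set of regions
#'
#' @param atlas A `region_atlas`.
#' @param lat,lon Numeric vectors of WGS84 coordinates.
#' @param region_codes Character vector of region codes to test against.
#' @return Logical vector: `TRUE` where the point lies inside (or on the
#'   boundary of) any polygon of any listed region.
#' @export
point_in_regions <- function(atlas, lat, lon, region_codes) {
  stopifnot(inherits(atlas, "region_atlas"))
  missing_rc <- setdiff(region_codes, names(atlas$regions))
  .assert(length(missing_rc) == 0,
          "region code(s) without polygons in atlas: %s",
          paste(missing_rc, collapse = ", "))
  vapply(seq_along(lat), function(i) {
    for (rc in region_codes) {
      for (ring in atlas$regions[[rc]]) {
        if (.point_in_ring(lat[i], lon[i], ring)) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

#' Write a region atlas to GeoJSON
#'
#' One Feature per region (geometry `Polygon`, lon-lat axis order) with
#' properties `region_code`, `iso_codes`, `oceanic_island` and `centroid`
#' (`[lon, lat]`).
#'
#' @param atlas A `region_atlas`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "region_atlas"))
  feats <- lapply(names(atlas$regions), function(rc) {
    rings <- lapply(atlas$regions[[rc]], function(m) {
      if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
      unname(lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2])))
    })
    isos <- names(atlas$iso_map)[vapply(atlas$iso_map, function(v) rc %in% v,
                                        logical(1))]
    cen <- atlas$centroids[atlas$centroids$region_code == rc, , drop = FALSE]
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = rings),
         properties = list(region_code = rc,
                           iso_codes = as.list(isos),
                           oceanic_island = unname(atlas$island[rc]),
                           centroid = c(cen$lon[1], cen$lat[1])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a region atlas from GeoJSON
#'
#' Accepts FeatureCollections of `Polygon` (or single-polygon `MultiPolygon`)
#' features in WGS84, lon-lat axis order. Features must carry a
#' `region_code` property; `iso_codes`, `oceanic_island` and `centroid`
#' properties are honoured when present.
#'
#' @param path GeoJSON file path.
#' @return A `region_atlas`.
#' @export
read_region_atlas <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  gj <- jsonlite::read_json(path)
  .assert(identical(gj$type, "FeatureCollection"),
          "expected a GeoJSON FeatureCollection")
  regions <- list(); island <- logical(0); iso_map <- list()
  cent <- list()
  for (f in gj$features) {
    rc <- f$properties$region_code
    .assert(!is.null(rc), "feature without region_code property")
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    rings <- lapply(polys, function(p) {
      ring <- p[[1]] # outer ring only; holes unsupported
      do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    })
    regions[[rc]] <- rings
    isl <- f$properties$oceanic_island
    island[rc] <- isTRUE(isl)
    for (iso in unlist(f$properties$iso_codes)) {
      iso_map[[iso]] <- unique(c(iso_map[[iso]], rc))
    }
    cen <- f$properties$centroid
    if (!is.null(cen)) {
      cent[[rc]] <- data.frame(region_code = rc,
                               lat = cen[[2]], lon = cen[[1]])
    }
  }
  centroids <- if (length(cent)) do.call(rbind, cent) else NULL
  if (!is.null(centroids) && !all(names(regions) %in% centroids$region_code)) {
    centroids <- NULL # fall back to bbox centres for all
  }
  region_atlas(regions, centroids = centroids, iso_map = iso_map,
               island = island)
}

#' Check that every native region of a checklist resolves in an atlas
#'
#' @param checklist A checklist data frame (see [read_checklist()]).
#' @param atlas A `region_atlas`.
#' @return `TRUE` invisibly; errors listing unresolved codes otherwise.
#' @export
validate_checklist_regions <- function(checklist, atlas) {
  used <- unique(unlist(checklist$native_regions))
  missing_rc <- setdiff(used, names(atlas$regions))
  .assert(length(missing_rc) == 0,
          "checklist native regions missing from atlas: %s",
          paste(missing_rc, collapse = ", "))
  invisible(TRUE)
}
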