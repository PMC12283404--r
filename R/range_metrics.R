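#' Count native botanical countries
#'
#' The coarsest of the three range-size metrics: the number of botanical
#' countries (World Geographical Scheme units) a species is native to.
#'
#' @param native_regions Character vector of region codes for one species, or
#'   a list of such vectors for many species.
#' @return Integer count(s); an empty region set is an error.
#' @export
count_botanical_countries <- function(native_regions) {
  if (!is.list(native_regions)) native_regions <- list(native_regions)
  n <- lengths(lapply(native_regions, unique))
  .assert(all(n >= 1), "species with empty native region set")
  as.integer(n)
}

#' Count cleaned specimen records for a species
#'
#' The sum of unique (cleaned) herbarium specimen records across both the
#' georeferenced and non-georeferenced arms; a proxy for range size and
#' relative abundance.
#'
#' @param clean_geo,clean_nongeo Cleaned occurrence data frames.
#' @param species Character vector of species names.
#' @return Integer vector of counts (0 allowed).
#' @export
specimen_count <- function(clean_geo, clean_nongeo, species) {
  tab <- table(c(clean_geo$species, clean_nongeo$species))
  out <- as.integer(tab[species])
  out[is.na(out)] <- 0L
  out
}

#' Extent of occurrence (EOO) as geodesic convex-hull area
#'
#' Computes the minimum convex polygon of a species' cleaned georeferenced
#' points in the lon-lat plane and evaluates its area as a geodesic polygon
#' on a sphere of authalic radius 6371.0072 km. Species with fewer than
#' three points have undefined EOO (`NA`); an exactly degenerate (collinear)
#' hull has EOO 0 and is flagged via attribute `"degenerate"`.
#'
#' Point sets spanning more than 180 degrees of longitude are recentred
#' before hulling (antimeridian crossing); point sets that still span more
#' than 180 degrees after recentring, or that approach the poles (|lat| >
#' 89), are not supported and raise an error. These cases cannot occur for
#' the small-ranged species (four or fewer botanical countries) this metric
#' targets.
#'
#' @param points Two-column matrix or data frame of (lat, lon) in decimal
#'   degrees, one species.
#' @return Area in km² (full precision, no flooring), or `NA_real_` if fewer
#'   than 3 points.
#' @export
compute_eoo <- function(points) {
  points <- as.matrix(points)
  .assert(ncol(points) == 2, "points must have two columns (lat, lon)")
  .assert(!anyNA(points), "missing coordinates in points (clean upstream)")
  lat <- as.numeric(points[, 1]); lon <- as.numeric(points[, 2])
  if (length(lat) < 3) return(NA_real_)
  .assert(all(abs(lat) <= 89), "polar point sets are not supported")
  if (diff(range(lon)) > 180) {
    lon <- (lon + 360) %% 360  # recentre across the antimeridian
    .assert(diff(range(lon)) <= 180,
            "point set spans more than 180 degrees of longitude")
  }
  hull <- grDevices::chull(lon, lat)
  if (length(hull) < 3) {  # collinear or coincident points
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  poly <- cbind(lon[hull], lat[hull])
  area_m2 <- geosphere::areaPolygon(poly, a = .EARTH_RADIUS_M, f = 0)
  abs(area_m2) / 1e6
}

#' Assemble the per-species range table
#'
#' Combines the three range-size metrics with the eligibility rules: the
#' occurrence-based metrics (specimen count, EOO) are computed only for
#' species native to four or fewer botanical countries (`eligible_le4`), and
#' EOO additionally requires at least three cleaned georeferenced records.
#' Occurrence records of species absent from the checklist are excluded and
#' reported in attribute `"unknown_species"`.
#'
#' @param checklist Checklist data frame.
#' @param clean_geo,clean_nongeo Cleaned occurrence data frames.
#' @param zero_records_missing If `TRUE` (default), an eligible species with
#'   no cleaned records at all gets a missing specimen count ("never
#'   observed") rather than 0, and is thereby excluded from downstream
#'   regressions; set `FALSE` to record an explicit 0.
#' @return Data frame of class `range_table` with columns `species`,
#'   `lifeform`, `family`, `n_botanical_countries`, `specimen_count`,
#'   `eoo_km2`, `eligible_le4`.
#' @export
build_range_table <- function(checklist, clean_geo, clean_nongeo,
                              zero_records_missing = TRUE) {
  unknown <- setdiff(unique(c(clean_geo$species, clean_nongeo$species)),
                     checklist$species)
  n_bc <- count_botanical_countries(checklist$native_regions)
  eligible <- n_bc <= 4L
  counts <- specimen_count(clean_geo, clean_nongeo, checklist$species)
  spec <- ifelse(eligible, counts, NA_integer_)
  if (zero_records_missing) spec[!is.na(spec) & spec == 0L] <- NA_integer_

  eoo <- rep(NA_real_, nrow(checklist))
  geo_by_sp <- split(seq_len(nrow(clean_geo)), clean_geo$species)
  for (i in which(eligible)) {
    idx <- geo_by_sp[[checklist$species[i]]]
    if (length(idx) >= 3) {
      eoo[i] <- compute_eoo(cbind(clean_geo$latitude[idx],
                                  clean_geo$longitude[idx]))
    }
  }
  out <- data.frame(species = checklist$species,
                    lifeform = checklist$lifeform,
                    family = checklist$family,
                    n_botanical_countries = n_bc,
                    specimen_count = as.integer(spec),
                    eoo_km2 = eoo,
                    eligible_le4 = eligible,
                    stringsAsFactors = FALSE)
  class(out) <- c("range_table", "data.frame")
  attr(out, "unknown_species") <- unknown
  out
}
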