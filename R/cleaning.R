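#' Cleaning configuration
#'
#' Parameters of the occurrence-cleaning filters. Defaults follow standard
#' herbarium-data practice: coordinate duplicates are detected after rounding
#' to 3 decimal places (~111 m at the equator), spatial thinning keeps at
#' most one record per species per 110 m grid cell, records with coordinate
#' uncertainty above 100 km are discarded, and records within 1 km of a
#' reference point (country centroid, capital, biodiversity institution) are
#' treated as suspect.
#'
#' @param round_dp Decimal places for duplicate detection.
#' @param grid_m Thinning cell size in metres.
#' @param max_uncertainty_m Maximum tolerated coordinate uncertainty (strict
#'   `>` removes); records with missing uncertainty are retained.
#' @param ref_buffer_m Great-circle radius around reference points within
#'   which records are removed.
#' @param apply_native_filter Apply the native-range filter in [clean_all()].
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(round_dp = 3, grid_m = 110,
                            max_uncertainty_m = 1e5, ref_buffer_m = 1000,
                            apply_native_filter = TRUE) {
  for (v in c(round_dp, grid_m, max_uncertainty_m, ref_buffer_m)) {
    .assert(is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0,
            "cleaning_config: all numeric fields must be positive scalars")
  }
  structure(list(round_dp = as.integer(round_dp), grid_m = grid_m,
                 max_uncertainty_m = max_uncertainty_m,
                 ref_buffer_m = ref_buffer_m,
                 apply_native_filter = isTRUE(apply_native_filter)),
            class = "cleaning_config")
}

# Package a keep/remove split, attaching removal reasons.
#' @noRd
.split_records <- function(records, keep, reason) {
  removed <- records[!keep, , drop = FALSE]
  if (nrow(removed)) {
    removed$reason <- if (length(reason) == 1) reason else reason[!keep]
  } else {
    removed$reason <- character(0)
  }
  list(records = records[keep, , drop = FALSE], removed = removed)
}

#' Remove records with suspect coordinates
#'
#' Discards georeferenced records where latitude equals longitude, either
#' coordinate equals zero (exact comparison on the parsed decimal values,
#' not on rounded values), or the record lies within `ref_buffer_m`
#' great-circle metres of any reference point (country centroid, capital or
#' biodiversity institution).
#'
#' @param records Georeferenced occurrence data frame.
#' @param ref_points Data frame with columns `lat`, `lon` (and optionally
#'   `kind`), or `NULL` for the equality/zero rules only.
#' @param config A [cleaning_config()].
#' @return List with elements `records` (kept, input order preserved) and
#'   `removed` (with a `reason` column: `lat_zero`, `lon_zero`,
#'   `lat_eq_lon`, `near_reference_point`).
#' @export
filter_suspect_coordinates <- function(records, ref_points = NULL,
                                       config = cleaning_config()) {
  lat <- records$latitude; lon <- records$longitude
  .assert(!anyNA(lat) && !anyNA(lon),
          "filter_suspect_coordinates: records must be georeferenced")
  reason <- rep(NA_character_, nrow(records))
  reason[lon == 0] <- "lon_zero"
  reason[lat == 0] <- "lat_zero"
  reason[is.na(reason) & lat == lon] <- "lat_eq_lon"
  if (!is.null(ref_points) && nrow(ref_points)) {
    todo <- which(is.na(reason))
    for (i in todo) {
      d <- .gc_dist_m(lat[i], lon[i], ref_points$lat, ref_points$lon)
      if (any(d <= config$ref_buffer_m)) reason[i] <- "near_reference_point"
    }
  }
  .split_records(records, is.na(reason), reason)
}

#' Deduplicate and spatially thin georeferenced records
#'
#' Per species, in input order: records whose coordinates round (to
#' `round_dp` decimal places) to an earlier record's rounded coordinates are
#' removed as duplicates; among the survivors at most one record is retained
#' per `grid_m` x `grid_m` cell, with cell indices taken as
#' `floor(metres / grid_m)` of the equirectangular projection at each
#' record's own latitude. Ties keep the first record in input order, making
#' the operation deterministic.
#'
#' @inheritParams filter_suspect_coordinates
#' @return List `records` / `removed` (`reason`: `duplicate_rounded`,
#'   `thinned_grid`).
#' @export
dedup_and_thin <- function(records, config = cleaning_config()) {
  lat <- records$latitude; lon <- records$longitude
  .assert(!anyNA(lat) && !anyNA(lon), "dedup_and_thin: records must be georeferenced")
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  key_dup <- paste(records$species,
                   formatC(round(lat, config$round_dp), format = "f",
                           digits = config$round_dp),
                   formatC(round(lon, config$round_dp), format = "f",
                           digits = config$round_dp))
  reason[duplicated(key_dup)] <- "duplicate_rounded"
  keep1 <- is.na(reason)
  x <- .EARTH_RADIUS_M * (pi / 180) * lon * cos(lat * pi / 180)
  y <- .EARTH_RADIUS_M * (pi / 180) * lat
  key_cell <- paste(records$species,
                    floor(x / config$grid_m), floor(y / config$grid_m))
  dup_cell <- duplicated(key_cell[keep1])
  reason[which(keep1)[dup_cell]] <- "thinned_grid"
  .split_records(records, is.na(reason), reason)
}

#' Remove low-precision records
#'
#' Removes georeferenced records whose stated coordinate uncertainty exceeds
#' `max_uncertainty_m` (strict `>`, so exactly 100 km is kept under the
#' default). Records with missing uncertainty are retained — most herbarium
#' records lack the field and dropping them would gut the dataset. Negative
#' uncertainties are removed as invalid.
#'
#' @inheritParams filter_suspect_coordinates
#' @return List `records` / `removed` (`reason`: `low_precision`,
#'   `invalid_uncertainty`).
#' @export
filter_low_precision <- function(records, config = cleaning_config()) {
  unc <- records$coord_uncertainty_m
  reason <- rep(NA_character_, nrow(records))
  reason[!is.na(unc) & unc < 0] <- "invalid_uncertainty"
  reason[!is.na(unc) & unc > config$max_uncertainty_m] <- "low_precision"
  .split_records(records, is.na(reason), reason)
}

#' Remove georeferenced records outside a species' native range
#'
#' A record is kept iff its coordinate falls inside (boundary inclusive) a
#' polygon of any botanical country in the species' native region set.
#' Records of species absent from the checklist are removed with reason
#' `unknown_species`. A native region code without a polygon in the atlas is
#' a hard error.
#'
#' @param records Georeferenced occurrence data frame.
#' @param checklist Checklist data frame.
#' @param atlas A `region_atlas`.
#' @return List `records` / `removed` (`reason`: `outside_native_range`,
#'   `unknown_species`).
#' @export
filter_native_geo <- function(records, checklist, atlas) {
  idx <- match(records$species, checklist$species)
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(idx)] <- "unknown_species"
  for (i in which(!is.na(idx))) {
    native <- checklist$native_regions[[idx[i]]]
    inside <- point_in_regions(atlas, records$latitude[i],
                               records$longitude[i], native)
    if (!inside) reason[i] <- "outside_native_range"
  }
  .split_records(records, is.na(reason), reason)
}

#' Clean non-georeferenced records
#'
#' Per species, three rules applied sequentially (any one suffices to remove
#' a record): (1) records whose normalized collection locality (case-folded,
#' whitespace-collapsed, punctuation-stripped) duplicates an earlier
#' record's locality are removed;
#' (2) records whose (year, administrative unit) pair duplicates an earlier
#' record's, both fields present, are removed — these likely represent
#' duplicates of one population or collection event; (3) records whose ISO
#' country code maps to no native botanical country of the species (via the
#' atlas ISO mapping) are removed. Records with missing country code are kept
#' at step 3; species absent from the checklist are removed as
#' `unknown_species`.
#'
#' @param records Non-georeferenced occurrence data frame.
#' @param checklist Checklist data frame.
#' @param atlas A `region_atlas` providing `iso_map`.
#' @return List `records` / `removed` (`reason`: `dup_locality`,
#'   `dup_year_admin`, `outside_native_range`, `unknown_species`).
#' @export
clean_nongeo <- function(records, checklist, atlas) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  idx <- match(records$species, checklist$species)
  reason[is.na(idx)] <- "unknown_species"

  loc <- ifelse(is.na(records$locality), NA, .norm_locality(records$locality))
  key_loc <- ifelse(is.na(loc), NA, paste(records$species, loc))
  dup_loc <- duplicated(key_loc, incomparables = NA)
  reason[is.na(reason) & dup_loc] <- "dup_locality"

  ya_ok <- !is.na(records$year) & !is.na(records$admin_unit)
  key_ya <- ifelse(ya_ok, paste(records$species, records$year,
                                .norm_text(records$admin_unit)), NA)
  alive <- is.na(reason)
  dup_ya <- rep(FALSE, n)
  dup_ya[alive] <- duplicated(key_ya[alive], incomparables = NA)
  reason[alive & dup_ya] <- "dup_year_admin"

  for (i in which(is.na(reason))) {
    cc <- records$country_code[i]
    if (is.na(cc)) next
    mapped <- atlas$iso_map[[cc]]
    native <- checklist$native_regions[[idx[i]]]
    if (length(intersect(mapped, native)) == 0) {
      reason[i] <- "outside_native_range"
    }
  }
  .split_records(records, is.na(reason), reason)
}

#' Run the full cleaning procedure on both record arms
#'
#' Georeferenced records pass, in order: native-range filter (optional),
#' precision filter, suspect-coordinates filter, then deduplication and
#' spatial thinning — cheap failures are removed before thinning so that
#' thinning only operates on plausible records. Non-georeferenced records
#' pass the three rules of [clean_nongeo()]. The audit report records, per
#' filter, the number of records entering and removed, so totals are
#' conserved at every stage.
#'
#' @param geo_records Georeferenced occurrence data frame.
#' @param nongeo_records Non-georeferenced occurrence data frame.
#' @param checklist Checklist data frame.
#' @param atlas A `region_atlas`.
#' @param ref_points Reference-point data frame or `NULL`.
#' @param config A [cleaning_config()].
#' @return List with `clean_geo`, `clean_nongeo`, `removed_geo`,
#'   `removed_nongeo` (each with `reason`), and `report` — a data frame
#'   `filter, arm, records_in, records_removed` in application order.
#' @export
clean_all <- function(geo_records, nongeo_records, checklist, atlas,
                      ref_points = NULL, config = cleaning_config()) {
  report <- list(); removed_geo <- list()
  add <- function(name, arm, n_in, n_rm) {
    report[[length(report) + 1L]] <<- data.frame(
      filter = name, arm = arm, records_in = n_in, records_removed = n_rm,
      stringsAsFactors = FALSE)
  }

  g <- geo_records
  if (config$apply_native_filter) {
    st <- filter_native_geo(g, checklist, atlas)
    add("native_range", "geo", nrow(g), nrow(st$removed))
    removed_geo[[length(removed_geo) + 1L]] <- st$removed
    g <- st$records
  }
  st <- filter_low_precision(g, config)
  add("low_precision", "geo", nrow(g), nrow(st$removed))
  removed_geo[[length(removed_geo) + 1L]] <- st$removed
  g <- st$records

  st <- filter_suspect_coordinates(g, ref_points, config)
  add("suspect_coordinates", "geo", nrow(g), nrow(st$removed))
  removed_geo[[length(removed_geo) + 1L]] <- st$removed
  g <- st$records

  st <- dedup_and_thin(g, config)
  add("dedup_thin", "geo", nrow(g), nrow(st$removed))
  removed_geo[[length(removed_geo) + 1L]] <- st$removed
  g <- st$records

  ng_st <- clean_nongeo(nongeo_records, checklist, atlas)
  add("nongeo_dedup_native", "nongeo", nrow(nongeo_records),
      nrow(ng_st$removed))

  empty_removed <- geo_records[0, , drop = FALSE]
  empty_removed$reason <- character(0)
  list(clean_geo = g,
       clean_nongeo = ng_st$records,
       removed_geo = if (length(removed_geo))
         do.call(rbind, removed_geo) else empty_removed,
       removed_nongeo = ng_st$removed,
       report = do.call(rbind, report))
}
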