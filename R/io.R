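#' Read occurrence records from CSV or TSV
#'
#' Parses a delimited table of specimen-based occurrence records into the
#' package's standard occurrence data frame. Column names default to
#' Darwin-Core terms (`decimalLatitude`, `decimalLongitude`,
#' `coordinateUncertaintyInMeters`, `countryCode`, `locality`, `year`,
#' `stateProvince`, `basisOfRecord`); `column_map` renames them for other
#' sources.
#'
#' Validation is conservative: unparsable or out-of-range latitudes never drop
#' a row — the record is retained with both coordinates set missing and an
#' entry appended to the validation log (attribute `"validation_log"`).
#' Longitudes are normalized to (-180, 180]; latitudes are never wrapped
#' (silent wrapping would hide sign errors). Species strings that are not
#' binomials (two whitespace-separated tokens) are flagged in the log but
#' retained.
#'
#' @param path CSV or TSV file with a header row. The delimiter is detected
#'   from the header; a header containing both commas and tabs is rejected.
#' @param column_map Optional named character vector mapping standard field
#'   names (`species`, `latitude`, `longitude`, `coord_uncertainty_m`,
#'   `country_code`, `region_code`, `locality`, `year`, `admin_unit`,
#'   `basis`, `record_id`) to the column names used in the file.
#' @return A data frame with columns `record_id`, `species`, `latitude`,
#'   `longitude`, `coord_uncertainty_m`, `country_code`, `region_code`,
#'   `locality`, `year`, `admin_unit`, `basis` and attribute
#'   `"validation_log"` (data frame: `record_id`, `field`, `issue`). Row
#'   order follows the file. A record is georeferenced iff both coordinates
#'   are present.
#' @export
read_occurrences <- function(path, column_map = NULL) {
  .assert(file.exists(path), "file not found: %s", path)
  header <- readLines(path, n = 1L)
  has_tab <- grepl("\t", header, fixed = TRUE)
  has_comma <- grepl(",", header, fixed = TRUE)
  .assert(!(has_tab && has_comma),
          "mixed delimiters (tab and comma) in header of %s", path)
  sep <- if (has_tab) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, na.strings = NULL)

  defaults <- c(species = "species",
                latitude = "decimalLatitude",
                longitude = "decimalLongitude",
                coord_uncertainty_m = "coordinateUncertaintyInMeters",
                country_code = "countryCode",
                region_code = "regionCode",
                locality = "locality",
                year = "year",
                admin_unit = "stateProvince",
                basis = "basisOfRecord",
                record_id = "recordId")
  cmap <- defaults
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map

  getcol <- function(field) {
    cn <- cmap[[field]]
    if (cn %in% names(raw)) raw[[cn]] else rep(NA_character_, nrow(raw))
  }
  .assert(cmap[["species"]] %in% names(raw),
          "mandatory species column '%s' not found in %s",
          cmap[["species"]], path)

  n <- nrow(raw)
  rid <- getcol("record_id")
  if (all(is.na(rid))) rid <- as.character(seq_len(n))
  log <- list()
  addlog <- function(id, field, issue) {
    log[[length(log) + 1L]] <<- data.frame(record_id = id, field = field,
                                           issue = issue,
                                           stringsAsFactors = FALSE)
  }

  blank_to_na <- function(x) { x[!is.na(x) & trimws(x) == ""] <- NA; x }
  species <- blank_to_na(getcol("species"))
  .assert(!anyNA(species), "empty species values in %s", path)
  species <- trimws(species)
  # underscores count as separators (Newick-style labels)
  bad_binomial <- lengths(strsplit(species, "[[:space:]_]+")) != 2L
  for (i in which(bad_binomial)) addlog(rid[i], "species", "non_binomial")

  num <- function(field) {
    x <- blank_to_na(getcol(field))
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    for (i in which(bad)) addlog(rid[i], field, "unparsable")
    out
  }
  lat <- num("latitude")
  lon <- num("longitude")
  # out-of-range latitude invalidates the whole coordinate pair
  bad_lat <- !is.na(lat) & (lat < -90 | lat > 90)
  for (i in which(bad_lat)) addlog(rid[i], "latitude", "out_of_range")
  lat[bad_lat] <- NA; lon[bad_lat] <- NA
  lon <- .norm_lon(lon)
  # a one-sided coordinate is not georeferenced; null the partner for clarity
  one_sided <- xor(is.na(lat), is.na(lon))
  lat[one_sided] <- NA; lon[one_sided] <- NA

  unc <- num("coord_uncertainty_m")
  yr <- suppressWarnings(as.integer(blank_to_na(getcol("year"))))

  out <- data.frame(record_id = rid,
                    species = species,
                    latitude = lat,
                    longitude = lon,
                    coord_uncertainty_m = unc,
                    country_code = blank_to_na(getcol("country_code")),
                    region_code = blank_to_na(getcol("region_code")),
                    locality = blank_to_na(getcol("locality")),
                    year = yr,
                    admin_unit = blank_to_na(getcol("admin_unit")),
                    basis = blank_to_na(getcol("basis")),
                    stringsAsFactors = FALSE)
  attr(out, "validation_log") <-
    if (length(log)) do.call(rbind, log) else
      data.frame(record_id = character(0), field = character(0),
                 issue = character(0), stringsAsFactors = FALSE)
  out
}

#' Is a record georeferenced?
#'
#' @param records Occurrence data frame.
#' @return Logical vector: both latitude and longitude present.
#' @export
is_georeferenced <- function(records) {
  !is.na(records$latitude) & !is.na(records$longitude)
}

#' Read a species checklist
#'
#' @param path CSV with columns `species`, `lifeform`, `family`,
#'   `native_regions` (region codes separated by `|` or `;`).
#' @param drop_other_lifeforms Rows whose lifeform is neither `epiphyte` nor
#'   `terrestrial` (e.g. hemi-epiphytes) are dropped with a message and
#'   recorded in attribute `"dropped_lifeforms"`. Set to `FALSE` to make such
#'   rows a hard error instead.
#' @return Data frame with columns `species`, `lifeform` (factor with levels
#'   `terrestrial`, `epiphyte`), `family`, and list column `native_regions`.
#' @export
read_checklist <- function(path, drop_other_lifeforms = TRUE) {
  .assert(file.exists(path), "file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("species", "lifeform", "family", "native_regions")
  miss <- setdiff(need, names(raw))
  .assert(length(miss) == 0, "checklist missing column(s): %s",
          paste(miss, collapse = ", "))
  lf <- .norm_text(raw$lifeform)
  bad <- !(lf %in% c("epiphyte", "terrestrial"))
  dropped <- raw[bad, c("species", "lifeform")]
  if (any(bad)) {
    if (!drop_other_lifeforms) {
      stop("unsupported lifeform token(s): ",
           paste(unique(raw$lifeform[bad]), collapse = ", "), call. = FALSE)
    }
    message(sprintf("read_checklist: dropped %d species with unsupported lifeforms (%s)",
                    sum(bad), paste(unique(raw$lifeform[bad]), collapse = ", ")))
    raw <- raw[!bad, , drop = FALSE]
    lf <- lf[!bad]
  }
  .assert(!anyDuplicated(raw$species),
          "duplicated species in checklist: %s",
          paste(unique(raw$species[duplicated(raw$species)]), collapse = ", "))
  nr <- lapply(strsplit(raw$native_regions, "[|;]"), function(v) {
    v <- trimws(v); unique(v[v != ""])
  })
  .assert(all(lengths(nr) > 0), "species with empty native_regions")
  out <- data.frame(species = trimws(raw$species),
                    lifeform = factor(lf, levels = c("terrestrial", "epiphyte")),
                    family = raw$family,
                    stringsAsFactors = FALSE)
  out$native_regions <- nr
  attr(out, "dropped_lifeforms") <- dropped
  out
}

#' Write a species checklist
#' @param checklist Checklist data frame (list column `native_regions`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(checklist, path) {
  out <- data.frame(species = checklist$species,
                    lifeform = as.character(checklist$lifeform),
                    family = checklist$family,
                    native_regions = vapply(checklist$native_regions,
                                            paste, character(1),
                                            collapse = "|"),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read phylogenetic trees from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the package's
#' contract: every edge must carry a branch length (the phylogenetic
#' covariance matrix is undefined otherwise). Tip labels are preserved
#' verbatim; polytomies are allowed.
#'
#' @param path Newick file containing one or more trees.
#' @return A `multiPhylo` list of trees, addressable by index.
#' @export
read_trees <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  .assert(length(trees) > 0, "no trees found in %s", path)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    .assert(!is.null(tr$edge.length) && !anyNA(tr$edge.length) &&
              length(tr$edge.length) == nrow(tr$edge),
            "tree %d in %s has edges without branch lengths", i, path)
  }
  trees
}

#' Match checklist species names to tree tip labels
#'
#' Exact string match after trimming whitespace and (by default) replacing
#' underscores with spaces on both sides, accommodating the common Newick
#' convention of underscore-separated labels.
#'
#' @param species Character vector of species names.
#' @param tip_labels Character vector of tree tip labels.
#' @param underscores_as_spaces Replace `_` with a space before matching.
#' @return Integer vector: for each species, the matching tip index or `NA`.
#' @export
match_tips <- function(species, tip_labels, underscores_as_spaces = TRUE) {
  canon <- function(x) {
    x <- trimws(x)
    if (underscores_as_spaces) x <- gsub("_", " ", x, fixed = TRUE)
    x
  }
  match(canon(species), canon(tip_labels))
}

.RANGE_TABLE_COLS <- c("species", "lifeform", "family",
                       "n_botanical_countries", "specimen_count", "eoo_km2",
                       "eligible_le4", "rare_by_eoo", "rare_by_specimens")

#' Write a range table to CSV
#'
#' Fixed column order (`species, lifeform, family, n_botanical_countries,
#' specimen_count, eoo_km2, eligible_le4, rare_by_eoo, rare_by_specimens`);
#' missing values are written as empty fields; EOO is written with 15
#' significant digits so a read round-trip reproduces integers bit-exactly
#' and EOO to at least 12 significant digits.
#'
#' @param table Range table (see [build_range_table()]); the rarity columns
#'   may be absent and are then written empty.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_range_table <- function(table, path) {
  out <- data.frame(row.names = seq_len(nrow(table)))
  for (cn in .RANGE_TABLE_COLS) {
    v <- if (cn %in% names(table)) table[[cn]] else rep(NA, nrow(table))
    out[[cn]] <- if (cn == "eoo_km2") {
      ifelse(is.na(v), "", vapply(v, function(x)
        if (is.na(x)) "" else format(x, digits = 15, scientific = FALSE),
        character(1)))
    } else if (is.numeric(v) || is.logical(v)) {
      ifelse(is.na(v), "", as.character(v))
    } else {
      as.character(v)
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  # quote only the free-text columns; missing numerics stay bare empty fields
  utils::write.table(out, con, sep = ",", row.names = FALSE, na = "",
                     quote = 1:3)
  invisible(path)
}

#' Read a range table written by [write_range_table()]
#' @param path CSV path.
#' @return A range table data frame (class `range_table`).
#' @export
read_range_table <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  miss <- setdiff(.RANGE_TABLE_COLS, names(raw))
  .assert(length(miss) == 0, "range table missing column(s): %s",
          paste(miss, collapse = ", "))
  asnum <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  aslog <- function(x) as.logical(ifelse(x == "", NA, x))
  out <- data.frame(species = raw$species,
                    lifeform = factor(raw$lifeform,
                                      levels = c("terrestrial", "epiphyte")),
                    family = raw$family,
                    n_botanical_countries = as.integer(asnum(raw$n_botanical_countries)),
                    specimen_count = as.integer(asnum(raw$specimen_count)),
                    eoo_km2 = asnum(raw$eoo_km2),
                    eligible_le4 = aslog(raw$eligible_le4),
                    rare_by_eoo = aslog(raw$rare_by_eoo),
                    rare_by_specimens = aslog(raw$rare_by_specimens),
                    stringsAsFactors = FALSE)
  class(out) <- c("range_table", "data.frame")
  out
}

#' Read a reference-point table (centroids, capitals, institutions)
#' @param path CSV with columns `lat`, `lon` and optional `kind`.
#' @return Data frame with columns `lat`, `lon`, `kind`.
#' @export
read_ref_points <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("lat", "lon") %in% names(raw)),
          "reference points need columns lat, lon")
  if (is.null(raw$kind)) raw$kind <- "unspecified"
  raw[, c("lat", "lon", "kind")]
}
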