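#' Rarity thresholds
#'
#' Defaults follow the Red List convention: an extent of occurrence below
#' 20,000 km² meets the area threshold for the "vulnerable" category under
#' criterion B1 (strict `<`), and five or fewer specimen records flags low
#' abundance (`<=`).
#'
#' @param eoo_km2_max EOO threshold in km².
#' @param specimens_max Specimen-count threshold.
#' @return List of class `rarity_thresholds`.
#' @export
rarity_thresholds <- function(eoo_km2_max = 20000, specimens_max = 5L) {
  .assert(eoo_km2_max > 0 && specimens_max > 0,
          "rarity thresholds must be positive")
  structure(list(eoo_km2_max = eoo_km2_max,
                 specimens_max = as.integer(specimens_max)),
            class = "rarity_thresholds")
}

#' Classify species as rare by EOO and by specimen count
#'
#' Adds two logical columns to a range table: `rare_by_eoo` is `TRUE` where
#' `eoo_km2 < eoo_km2_max` (strict, so exactly 20,000 km² is not rare) and
#' `rare_by_specimens` where `specimen_count <= specimens_max` (five or
#' fewer is rare). Species missing a metric get `NA` for that flag and are
#' excluded from the corresponding denominators downstream.
#'
#' @param table A range table.
#' @param thr A [rarity_thresholds()].
#' @return The table with `rare_by_eoo` and `rare_by_specimens` columns.
#' @export
classify_rarity <- function(table, thr = rarity_thresholds()) {
  table$rare_by_eoo <- ifelse(is.na(table$eoo_km2), NA,
                              table$eoo_km2 < thr$eoo_km2_max)
  table$rare_by_specimens <- ifelse(is.na(table$specimen_count), NA,
                                    table$specimen_count <= thr$specimens_max)
  table
}

#' Proportions of rare species per group
#'
#' Computes, per group (lifeform, optionally crossed with further keys such
#' as family), the number of species with each metric defined, the number
#' classified rare, and the proportion rare. Denominators are species with
#' the metric present, not all species. Empty groups report zero
#' denominators and missing proportions.
#'
#' @param table A classified range table (see [classify_rarity()]).
#' @param group_keys Character vector of grouping columns.
#' @return Data frame of class `rarity_summary` with columns `n_with_eoo`,
#'   `n_rare_eoo`, `prop_rare_eoo`, `n_with_specimens`, `n_rare_specimens`,
#'   `prop_rare_specimens` per group.
#' @export
rarity_proportions <- function(table, group_keys = "lifeform") {
  .assert(all(c("rare_by_eoo", "rare_by_specimens") %in% names(table)),
          "run classify_rarity() first")
  .assert(all(group_keys %in% names(table)),
          "unknown grouping column(s)")
  key <- interaction(table[group_keys], drop = FALSE, sep = "\r")
  lev <- levels(key)
  rows <- lapply(lev, function(lv) {
    sel <- which(!is.na(key) & key == lv)
    eoo <- table$rare_by_eoo[sel]
    spc <- table$rare_by_specimens[sel]
    n_eoo <- sum(!is.na(eoo)); n_spc <- sum(!is.na(spc))
    parts <- strsplit(lv, "\r", fixed = TRUE)[[1]]
    g <- as.list(parts)
    names(g) <- group_keys
    data.frame(g,
               n_with_eoo = n_eoo,
               n_rare_eoo = sum(eoo, na.rm = TRUE),
               prop_rare_eoo = if (n_eoo > 0)
                 sum(eoo, na.rm = TRUE) / n_eoo else NA_real_,
               n_with_specimens = n_spc,
               n_rare_specimens = sum(spc, na.rm = TRUE),
               prop_rare_specimens = if (n_spc > 0)
                 sum(spc, na.rm = TRUE) / n_spc else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rarity_summary", "data.frame")
  out
}
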