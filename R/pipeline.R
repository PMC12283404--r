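#' Analysis configuration
#'
#' Bundles everything a full pipeline run needs: input paths, the
#' model-metric pairings (botanical countries -> quasi-Poisson; specimen
#' count and EOO -> log-OLS and PGLS; PGLS is never paired with the
#' botanical-countries metric), the sensitivity subset, grouping keys,
#' thresholds and cleaning parameters.
#'
#' @param occurrences_geo,occurrences_nongeo,checklist,trees,regions,ref_points
#'   Input file paths (`ref_points` may be `NULL`).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param subset One of `all`, `tropical_only`, `exclude_oceanic_islands`.
#' @param group_by Extra grouping columns for within-group fits (e.g.
#'   `"family"`), or `NULL` for the full-dataset fits only.
#' @param thresholds A [rarity_thresholds()].
#' @param cleaning A [cleaning_config()].
#' @param zero_records_missing See [build_range_table()].
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(occurrences_geo, occurrences_nongeo, checklist,
                            trees, regions, ref_points = NULL,
                            out_dir = NULL,
                            subset = c("all", "tropical_only",
                                       "exclude_oceanic_islands"),
                            group_by = NULL,
                            thresholds = rarity_thresholds(),
                            cleaning = cleaning_config(),
                            zero_records_missing = TRUE,
                            seed = NA_integer_) {
  structure(list(occurrences_geo = occurrences_geo,
                 occurrences_nongeo = occurrences_nongeo,
                 checklist = checklist, trees = trees, regions = regions,
                 ref_points = ref_points, out_dir = out_dir,
                 subset = match.arg(subset), group_by = group_by,
                 thresholds = thresholds, cleaning = cleaning,
                 zero_records_missing = zero_records_missing, seed = seed),
            class = "analysis_config")
}

#' Apply a sensitivity subset to a checklist
#'
#' `tropical_only` keeps species whose native range is tropical on average:
#' the simple mean of the native-region centroid latitudes lies within the
#' tropics (|lat| <= 23.436 degrees). `exclude_oceanic_islands` drops any
#' species with at least one native region flagged as an oceanic island
#' (set `island_mode = "all"` to drop only species whose regions are all
#' islands).
#'
#' @param checklist Checklist data frame.
#' @param atlas A `region_atlas` with centroids (and island flags for the
#'   island subset).
#' @param mode `all`, `tropical_only` or `exclude_oceanic_islands`.
#' @param island_mode `"any"` (default) or `"all"`.
#' @param tropics_lat Latitude bound of the tropics.
#' @return The filtered checklist.
#' @export
subset_species <- function(checklist, atlas,
                           mode = c("all", "tropical_only",
                                    "exclude_oceanic_islands"),
                           island_mode = c("any", "all"),
                           tropics_lat = 23.436) {
  mode <- match.arg(mode)
  island_mode <- match.arg(island_mode)
  if (mode == "all") return(checklist)
  if (mode == "tropical_only") {
    cen <- stats::setNames(atlas$centroids$lat, atlas$centroids$region_code)
    keep <- vapply(checklist$native_regions, function(rcs) {
      lats <- cen[rcs]
      .assert(!anyNA(lats), "region(s) without centroid: %s",
              paste(rcs[is.na(lats)], collapse = ", "))
      abs(mean(lats)) <= tropics_lat
    }, logical(1))
  } else {
    keep <- vapply(checklist$native_regions, function(rcs) {
      fl <- atlas$island[rcs]
      .assert(!anyNA(fl), "region(s) without island flag: %s",
              paste(rcs[is.na(fl)], collapse = ", "))
      if (island_mode == "any") !any(fl) else !all(fl)
    }, logical(1))
  }
  checklist[keep, , drop = FALSE]
}

#' @noRd
.fit_metric_group <- function(tab, metric, trees) {
  # returns a list of rows for the fits table plus fit objects
  y_col <- switch(metric, bc = "n_botanical_countries",
                  specimens = "specimen_count", eoo = "eoo_km2")
  d <- tab[!is.na(tab[[y_col]]), , drop = FALSE]
  if (metric != "bc") d <- d[d[[y_col]] > 0, , drop = FALSE]
  out <- list(fits = list(), rows = list(), skipped = NULL)
  if (nrow(d) < 5 || length(unique(d$lifeform)) < 2) {
    out$skipped <- sprintf("%s: insufficient data (n=%d)", metric, nrow(d))
    return(out)
  }
  X <- stats::model.matrix(~lifeform, d)
  addrow <- function(model, fit, tree_index = NA_integer_) {
    k <- match("lifeformepiphyte", names(fit$beta))
    es <- effect_size_percent(fit, k)
    out$rows[[length(out$rows) + 1L]] <<- data.frame(
      metric = metric, model = model, tree_index = tree_index,
      n = fit$n_obs, beta = fit$beta[[k]], se = fit$se[[k]],
      percent = es$percent, ci_low = es$ci_low, ci_high = es$ci_high,
      lambda_hat = fit$lambda_hat, phi = fit$dispersion_phi,
      stringsAsFactors = FALSE)
  }
  if (metric == "bc") {
    fit <- quasipoisson_glm(d[[y_col]], X)
    out$fits$quasipoisson <- fit
    addrow("quasipoisson", fit)
    return(out)
  }
  fit <- ols_log(d[[y_col]], X)
  out$fits$ols <- fit
  addrow("ols", fit)
  pgls_fits <- list()
  n_unmatched <- 0L
  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    tip <- match_tips(d$species, tree$tip.label)
    dd <- d[!is.na(tip), , drop = FALSE]
    n_unmatched <- max(n_unmatched, sum(is.na(tip)))
    if (nrow(dd) < 5 || length(unique(dd$lifeform)) < 2) next
    Xd <- stats::model.matrix(~lifeform, dd)
    f <- pgls_ml(log(dd[[y_col]]), Xd, tree,
                 tree$tip.label[match_tips(dd$species, tree$tip.label)])
    pgls_fits[[length(pgls_fits) + 1L]] <- f
    addrow("pgls", f, ti)
  }
  out$fits$pgls <- pgls_fits
  out$n_unmatched <- n_unmatched
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates clean -> range metrics -> regressions (per metric, per
#' model, optionally per group, across all trees) -> percentage-difference
#' effect sizes -> rarity classification. With `out_dir` set, writes
#' `cleaning_report.csv`, `range_table.csv`, `fits.csv` (one row per fitted
#' model per tree), `effects.csv` (tree-aggregated effect sizes),
#' `rarity.csv` and a `manifest.json` with the config echo, input MD5
#' checksums, package version and seed. The manifest is stable across
#' reruns on identical inputs.
#'
#' @param config An [analysis_config()].
#' @return List with `cleaning`, `range_table`, `fits` (data frame),
#'   `effects` (data frame), `multi_tree` (per metric, `multi_tree_summary`
#'   for PGLS), `rarity`, `manifest`; invisibly if `out_dir` is set.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- "read_inputs"
  res <- tryCatch({
    occ_geo_raw <- read_occurrences(config$occurrences_geo)
    occ_ng_raw <- read_occurrences(config$occurrences_nongeo)
    checklist <- read_checklist(config$checklist)
    trees <- read_trees(config$trees)
    atlas <- read_region_atlas(config$regions)
    refs <- if (!is.null(config$ref_points))
      read_ref_points(config$ref_points) else NULL
    validate_checklist_regions(checklist, atlas)

    geo <- occ_geo_raw[is_georeferenced(occ_geo_raw), , drop = FALSE]
    ng <- rbind(occ_geo_raw[!is_georeferenced(occ_geo_raw), , drop = FALSE],
                occ_ng_raw[!is_georeferenced(occ_ng_raw), , drop = FALSE])
    geo <- rbind(geo, occ_ng_raw[is_georeferenced(occ_ng_raw), , drop = FALSE])

    stage <- "subset"
    checklist <- subset_species(checklist, atlas, config$subset)

    stage <- "cleaning"
    cl <- clean_all(geo, ng, checklist, atlas, refs, config$cleaning)

    stage <- "range_metrics"
    tab <- build_range_table(checklist, cl$clean_geo, cl$clean_nongeo,
                             config$zero_records_missing)

    stage <- "regression"
    groups <- list(all = tab)
    if (!is.null(config$group_by)) {
      for (g in split(as.data.frame(tab), tab[config$group_by])) {
        if (nrow(g)) groups[[paste(unique(g[[config$group_by[1]]]),
                                   collapse = "_")]] <- g
      }
    }
    fit_rows <- list(); multi_tree <- list(); fit_objects <- list()
    skipped <- character(0)
    for (gname in names(groups)) {
      for (metric in c("bc", "specimens", "eoo")) {
        fg <- .fit_metric_group(groups[[gname]], metric, trees)
        if (!is.null(fg$skipped)) {
          skipped <- c(skipped, paste(gname, fg$skipped))
          next
        }
        rows <- do.call(rbind, fg$rows)
        rows <- cbind(group = gname, rows)
        fit_rows[[length(fit_rows) + 1L]] <- rows
        fit_objects[[paste(gname, metric)]] <- fg$fits
        if (length(fg$fits$pgls) > 1) {
          multi_tree[[paste(gname, metric)]] <- aggregate_trees(fg$fits$pgls)
        }
      }
    }
    fits <- do.call(rbind, fit_rows)

    # tree-aggregated effect table (one row per group x metric x model)
    stage <- "effects"
    agg <- lapply(split(fits, interaction(fits$group, fits$metric,
                                          fits$model, drop = TRUE)),
      function(d) data.frame(group = d$group[1], metric = d$metric[1],
                             model = d$model[1],
                             n = max(d$n),
                             n_trees = nrow(d),
                             beta_mean = mean(d$beta),
                             beta_spread = if (nrow(d) > 1) stats::sd(d$beta) else 0,
                             se_mean = mean(d$se),
                             percent = 100 * (exp(mean(d$beta)) - 1),
                             ci_low = 100 * (exp(mean(d$beta) -
                                                   1.959964 * mean(d$se)) - 1),
                             ci_high = 100 * (exp(mean(d$beta) +
                                                    1.959964 * mean(d$se)) - 1),
                             lambda_mean = mean(d$lambda_hat),
                             stringsAsFactors = FALSE))
    effects <- do.call(rbind, agg)
    rownames(effects) <- NULL

    stage <- "rarity"
    tab <- classify_rarity(tab, config$thresholds)
    rar <- rarity_proportions(tab, c("lifeform",
                                     intersect(config$group_by, "family")))

    stage <- "manifest"
    inputs <- c(config$occurrences_geo, config$occurrences_nongeo,
                config$checklist, config$trees, config$regions,
                config$ref_points)
    manifest <- list(
      package = "phyrange",
      version = as.character(utils::packageVersion("phyrange")),
      seed = config$seed,
      subset = config$subset,
      inputs = stats::setNames(as.list(unname(tools::md5sum(inputs))),
                               basename(inputs)),
      n_species_checklist = nrow(checklist),
      n_trees = length(trees),
      skipped_fits = as.list(skipped),
      cleaning = unclass(config$cleaning),
      thresholds = unclass(config$thresholds))

    list(cleaning = cl, range_table = tab, fits = fits, effects = effects,
         multi_tree = multi_tree, fit_objects = fit_objects, rarity = rar,
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    utils::write.csv(res$cleaning$report,
                     file.path(od, "cleaning_report.csv"), row.names = FALSE)
    write_range_table(res$range_table, file.path(od, "range_table.csv"))
    utils::write.csv(res$fits, file.path(od, "fits.csv"), row.names = FALSE)
    utils::write.csv(res$effects, file.path(od, "effects.csv"),
                     row.names = FALSE)
    utils::write.csv(res$rarity, file.path(od, "rarity.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res$manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}
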