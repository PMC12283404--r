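# Named study scenarios with full ground truth. Three designs:
#   baseline          — moderate phylogenetic clustering of epiphytism,
#                       positive lifeform effect, lambda = 0.8 noise.
#   confounded_clades — two anciently diverged clades; the clade whose deep
#                       Brownian displacement is negative carries 90% of the
#                       epiphytes, while the true lifeform effect is
#                       +ln(1.5). Ordinary regression then reports epiphyte
#                       ranges as smaller; PGLS recovers the positive
#                       effect.
#   null_effect       — lifeform effect exactly zero (coverage checks).

#' Scenario configuration
#'
#' Assembles the full parameter set of a named synthetic scenario, applying
#' any overrides. Defaults define the study conditions: 200 species, Yule
#' birth rate 1, symmetric lifeform transition rates 0.3, intercept
#' `log(3000)` (log km²), lifeform effect `+log(1.5)`, Pagel's lambda 0.8,
#' Brownian rate 1, skewed record counts (negative binomial, means ~12
#' georeferenced and ~8 non-georeferenced per species, scaling with true
#' range size), botanical-country counts dominated by single-country
#' species, and 1-2% planting probability per violation class.
#'
#' @param name One of `baseline`, `confounded_clades`, `null_effect`.
#' @param overrides Named list of parameter overrides.
#' @param seed Integer master seed; per-stage child seeds are derived from
#'   it by fixed offsets.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(name = c("baseline", "confounded_clades",
                                     "null_effect"),
                            overrides = list(), seed = 1L) {
  name <- match.arg(name)
  cfg <- list(name = name,
              n_species = 200L,
              birth_rate = 1,
              mk_rates = c(q01 = 0.3, q10 = 0.3),
              alpha = log(3000),
              beta_lifeform = log(1.5),
              lambda_true = 0.8,
              sigma2 = 1,
              n_trees = 1L,
              occ_mean = 12,
              nongeo_mean = 8,
              occ_size = 1.2,
              occ_range_exponent = 0.4,
              bc_probs = c(0.56, 0.20, 0.12, 0.07, 0.03, 0.02),
              eoo_cap_km2 = 3e5,
              eoo_floor_km2 = 10,
              violation_rates = c(dup_exact = 0.02, dup_rounded = 0.02,
                                  coord_zero = 0.01, coord_equal = 0.01,
                                  low_precision = 0.02,
                                  foreign_region = 0.02, ref_point = 0.01,
                                  dup_locality = 0.02, dup_year_admin = 0.02,
                                  foreign_country = 0.02),
              # confounded_clades geometry
              stem_length = 1000,
              within_depth = 1,
              p_epiphyte_clades = c(0.9, 0.1),
              seed = as.integer(seed))
  if (name == "null_effect") cfg$beta_lifeform <- 0
  if (name == "confounded_clades") {
    cfg$lambda_true <- 1
    cfg$sigma2 <- 0.2
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = "scenario_config")
}

# Two Yule clades of equal size joined by long stem branches.
#' @noRd
.two_clade_tree <- function(n_species, birth_rate, stem_length, within_depth,
                            seed) {
  n1 <- floor(n_species / 2); n2 <- n_species - n1
  t1 <- rescale_tree_depth(simulate_tree(n1, birth_rate, .child_seed(seed, 11),
                                         tip_prefix = "GenA_sp"), within_depth)
  t2 <- rescale_tree_depth(simulate_tree(n2, birth_rate, .child_seed(seed, 12),
                                         tip_prefix = "GenB_sp"), within_depth)
  nwk <- function(tr) sub(";$", "", ape::write.tree(tr))
  tree <- ape::read.tree(text = sprintf("(%s:%.10f,%s:%.10f);",
                                        nwk(t1), stem_length,
                                        nwk(t2), stem_length))
  attr(tree, "clade") <- stats::setNames(
    rep(c("A", "B"), c(n1, n2)), c(t1$tip.label, t2$tip.label))
  tree
}

#' Simulate a complete named scenario in memory
#'
#' Runs the generative chain — phylogeny, lifeforms, log range sizes,
#' occurrence records with planted violations — and returns all inputs a
#' pipeline run needs together with the ground truth.
#'
#' @param config A [scenario_config()].
#' @param with_occurrences Set `FALSE` to skip the (comparatively slow)
#'   occurrence-record generation when only the trait layer is needed.
#' @return List: `config`, `tree` (generating tree), `trees` (analysis
#'   trees, `multiPhylo`), `labels`, `y` (true log range), `checklist`,
#'   `atlas`, `ref_points`, `occ` (list `geo`/`nongeo`/`truth`), and
#'   `truth_species` data frame.
#' @export
simulate_scenario <- function(config, with_occurrences = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- config$seed
  atlas <- toy_atlas()

  if (config$name == "confounded_clades") {
    tree <- .two_clade_tree(config$n_species, config$birth_rate,
                            config$stem_length, config$within_depth, seed)
    clade <- attr(tree, "clade")[tree$tip.label]
    # Brownian noise on the full tree; deep-stem displacement realized in it
    set.seed(.child_seed(seed, 2))
    C <- phylo_vcv(tree)
    V <- config$sigma2 * lambda_transform(C, config$lambda_true)
    eps <- as.numeric(t(chol(V)) %*% stats::rnorm(length(tree$tip.label)))
    names(eps) <- tree$tip.label
    clade_means <- tapply(eps, clade, mean)
    rich <- names(which.min(clade_means))  # negative-displacement clade
    p_epi <- ifelse(clade == rich, config$p_epiphyte_clades[1],
                    config$p_epiphyte_clades[2])
    set.seed(.child_seed(seed, 3))
    labels <- stats::setNames(
      factor(ifelse(stats::rbinom(length(p_epi), 1, p_epi) == 1,
                    "epiphyte", "terrestrial"),
             levels = c("terrestrial", "epiphyte")),
      tree$tip.label)
    y <- config$alpha + config$beta_lifeform * (labels == "epiphyte") + eps
    y <- stats::setNames(as.numeric(y), tree$tip.label)
    attr(y, "eps") <- eps
    family <- stats::setNames(ifelse(clade == "A", "FamA", "FamB"),
                              tree$tip.label)
  } else {
    tree <- simulate_tree(config$n_species, config$birth_rate,
                          .child_seed(seed, 1), tip_prefix = "Gen_sp")
    labels <- simulate_lifeform(tree, config$mk_rates, .child_seed(seed, 2))
    y <- simulate_log_range(tree, labels, config$alpha, config$beta_lifeform,
                            config$lambda_true, config$sigma2,
                            .child_seed(seed, 3))
    family <- stats::setNames(
      sprintf("Fam%d", (seq_along(tree$tip.label) - 1L) %/% 50L + 1L),
      tree$tip.label)
  }

  # analysis trees: identical to the generating tree, or random
  # re-resolutions of its short branches when n_trees > 1
  if (config$n_trees > 1) {
    poly <- collapse_short_branches(tree)
    trees <- random_resolutions(poly, config$n_trees, .child_seed(seed, 5))
  } else {
    trees <- c(tree)
  }

  # checklist: equatorial non-island regions host the species
  host <- names(atlas$regions)[!atlas$island &
                                 atlas$centroids$lat[match(names(atlas$regions),
                                   atlas$centroids$region_code)] < 20]
  set.seed(.child_seed(seed, 4))
  taxa <- tree$tip.label
  n <- length(taxa)
  region <- sample(host, n, replace = TRUE)
  # native botanical-country counts follow the empirical prevalence of
  # single-country species, with a small widespread tail
  n_regions <- sample.int(length(config$bc_probs), n, replace = TRUE,
                          prob = config$bc_probs)
  native_regions <- lapply(seq_len(n), function(i) {
    extras <- setdiff(names(atlas$regions), region[i])
    c(region[i], sample(extras, min(n_regions[i] - 1L, length(extras))))
  })
  checklist <- data.frame(species = taxa,
                          lifeform = labels[taxa],
                          family = family[taxa],
                          stringsAsFactors = FALSE)
  checklist$native_regions <- native_regions
  rownames(checklist) <- NULL

  eoo_target <- pmin(pmax(exp(y[taxa]), config$eoo_floor_km2),
                     config$eoo_cap_km2)
  # record counts are skewed (negative binomial) and scale with true range
  # size, so specimen count carries the range-size signal it proxies
  rel <- (eoo_target / exp(config$alpha))^config$occ_range_exponent
  mu_geo <- pmin(pmax(config$occ_mean * rel, 0.5), 8 * config$occ_mean)
  mu_ng <- pmin(pmax(config$nongeo_mean * rel, 0.5), 8 * config$nongeo_mean)
  n_geo <- stats::rnbinom(n, size = config$occ_size, mu = mu_geo)
  n_ng <- stats::rnbinom(n, size = config$occ_size, mu = mu_ng)
  species_tbl <- data.frame(species = taxa, region = region,
                            eoo_target_km2 = as.numeric(eoo_target),
                            n_geo = n_geo, n_nongeo = n_ng,
                            stringsAsFactors = FALSE)
  species_tbl$native_regions <- native_regions

  occ <- NULL
  if (with_occurrences) {
    occ <- simulate_occurrences(species_tbl, config$violation_rates,
                                atlas = atlas, seed = .child_seed(seed, 6))
  }

  truth_species <- data.frame(species = taxa,
                              lifeform = as.character(labels[taxa]),
                              family = family[taxa],
                              log_range = as.numeric(y[taxa]),
                              eoo_target_km2 = as.numeric(eoo_target),
                              n_geo_clean = n_geo,
                              n_nongeo_clean = n_ng,
                              stringsAsFactors = FALSE)

  list(config = config, tree = tree, trees = trees, labels = labels, y = y,
       checklist = checklist, atlas = atlas,
       ref_points = if (is.null(occ)) NULL else occ$ref_points,
       occ = occ, truth_species = truth_species,
       species_tbl = species_tbl)
}

#' Materialize a scenario as a directory of input files
#'
#' Writes everything a pipeline run consumes — `occurrences_geo.csv`,
#' `occurrences_nongeo.csv`, `checklist.csv`, `trees.nwk`,
#' `regions.geojson`, `ref_points.csv` — plus the ground truth
#' (`truth_species.csv`, `truth_records.csv`) and a `scenario.json` config
#' echo. Output is deterministic for a fixed seed.
#'
#' @param name Scenario name (see [scenario_config()]).
#' @param overrides Named list of config overrides.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @return The `simulate_scenario()` result, invisibly.
#' @export
make_scenario <- function(name, overrides = list(), seed = 1L, out_dir) {
  cfg <- scenario_config(name, overrides, seed)
  sim <- simulate_scenario(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) ifelse(is.na(x), "",
                            vapply(x, function(v) if (is.na(v)) "" else
                              format(v, digits = 15, scientific = FALSE),
                              character(1)))
  wocc <- function(df, path) {
    out <- df
    out$latitude <- fmt(out$latitude)
    out$longitude <- fmt(out$longitude)
    out$coord_uncertainty_m <- fmt(out$coord_uncertainty_m)
    names(out) <- c("recordId", "species", "decimalLatitude",
                    "decimalLongitude", "coordinateUncertaintyInMeters",
                    "countryCode", "regionCode", "locality", "year",
                    "stateProvince", "basisOfRecord")
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  wocc(sim$occ$geo, file.path(out_dir, "occurrences_geo.csv"))
  wocc(sim$occ$nongeo, file.path(out_dir, "occurrences_nongeo.csv"))
  write_checklist(sim$checklist, file.path(out_dir, "checklist.csv"))
  ape::write.tree(sim$trees, file.path(out_dir, "trees.nwk"))
  write_region_atlas(sim$atlas, file.path(out_dir, "regions.geojson"))
  utils::write.csv(sim$ref_points, file.path(out_dir, "ref_points.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth_species,
                   file.path(out_dir, "truth_species.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$occ$truth, file.path(out_dir, "truth_records.csv"),
                   row.names = FALSE)
  cfg_out <- unclass(cfg)
  cfg_out$mk_rates <- as.list(cfg_out$mk_rates)
  cfg_out$violation_rates <- as.list(cfg_out$violation_rates)
  jsonlite::write_json(cfg_out, file.path(out_dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}
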