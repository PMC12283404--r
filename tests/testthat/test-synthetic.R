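# The synthetic-data generator: Yule trees, Mk lifeforms, log ranges,
# occurrence records with planted violations, and scenario determinism.

test_that("Yule simulation is deterministic, ultrametric and sized", {
  tr <- simulate_tree(3, 1, seed = 1)
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)
  expect_identical(ape::write.tree(simulate_tree(12, 2, seed = 9)),
                   ape::write.tree(simulate_tree(12, 2, seed = 9)))
  expect_true(ape::is.ultrametric(simulate_tree(40, 1, seed = 2)))
  expect_error(simulate_tree(2, 1), "n_species")
})

test_that("mean Yule depth matches the analytic expectation", {
  n <- 50; b <- 1.3
  expected <- sum(1 / ((2:n) * b))
  set.seed(123)
  depths <- vapply(1:400, function(i)
    max(ape::node.depth.edgelength(simulate_tree(n, b))), numeric(1))
  expect_lt(abs(mean(depths) - expected) / expected, 0.1)
})

test_that("Mk lifeform simulation respects absorbing and stationary regimes", {
  tr <- simulate_tree(30, 1, seed = 3)
  # q01 = 0 with a terrestrial root: epiphytism can never arise
  lab0 <- simulate_lifeform(tr, c(q01 = 0, q10 = 1), seed = 4)
  expect_true(all(lab0 == "terrestrial"))
  # symmetric rates: epiphyte fraction near 1/2 across many trees
  set.seed(5)
  frac <- mean(vapply(1:50, function(i) {
    t2 <- simulate_tree(200, 1)
    mean(simulate_lifeform(t2, c(q01 = 5, q10 = 5)) == "epiphyte")
  }, numeric(1)))
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("low Mk rates on a two-clade tree produce clade-lifeform association", {
  cramers_v <- function(a, b) {
    tab <- table(a, b)
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
    sqrt(as.numeric(chi) / length(a))
  }
  set.seed(6)
  n_eligible <- 0; n_assoc <- 0
  for (r in 1:40) {
    # shallow clades on long stems: transitions happen on the stems, so the
    # trait clusters by clade
    t1 <- rescale_tree_depth(simulate_tree(30, 1, tip_prefix = "a"), 0.1)
    t2 <- rescale_tree_depth(simulate_tree(30, 1, tip_prefix = "b"), 0.1)
    nwk <- function(tr) sub(";$", "", ape::write.tree(tr))
    tr <- ape::read.tree(text = sprintf("(%s:8,%s:8);", nwk(t1), nwk(t2)))
    lab <- simulate_lifeform(tr, c(q01 = 0.15, q10 = 0.15))
    clade <- substr(names(lab), 1, 1)
    if (min(table(lab)) >= 3) {
      n_eligible <- n_eligible + 1
      if (cramers_v(lab, clade) > 0.5) n_assoc <- n_assoc + 1
    }
  }
  expect_gte(n_eligible, 10)
  expect_gte(n_assoc / n_eligible, 0.7)
})

test_that("log-range simulation has the stated noise structure", {
  tr <- simulate_tree(25, 1, seed = 7)
  lab <- simulate_lifeform(tr, seed = 8)
  # noise-free limit is exactly linear in the trait
  y0 <- simulate_log_range(tr, lab, 3, 0.7, 0.5, 1e-20, seed = 9)
  expect_equal(as.numeric(y0),
               3 + 0.7 * as.numeric(lab[tr$tip.label] == "epiphyte"),
               tolerance = 1e-6)
  # lambda 0: residuals uncorrelated across species (Monte Carlo)
  tr2 <- simulate_tree(20, 1, seed = 10)
  lab2 <- simulate_lifeform(tr2, seed = 11)
  set.seed(12)
  eps <- t(vapply(1:1000, function(i)
    attr(simulate_log_range(tr2, lab2, 0, 0, 0, 1), "eps"), numeric(20)))
  cors <- cor(eps)
  offdiag <- abs(cors[upper.tri(cors)])
  expect_lt(mean(offdiag), 0.05)
})

test_that("violation-free occurrences pass cleaning untouched and hulls hit targets", {
  tbl <- data.frame(species = c("Aa bb", "Cc dd"), region = c("R01", "R02"),
                    eoo_target_km2 = c(8000, 20000), n_geo = c(40, 60),
                    n_nongeo = c(5, 5), stringsAsFactors = FALSE)
  occ <- simulate_occurrences(tbl, atlas = toy_atlas(), seed = 13)
  expect_true(all(occ$truth$class == "clean"))
  cl <- checklist_df(tbl$species, regions = as.list(tbl$region))
  res <- clean_all(occ$geo, occ$nongeo, cl, toy_atlas(), occ$ref_points)
  expect_equal(sum(res$report$records_removed), 0)
  # emitted files are consumable with zero validation errors
  dir <- withr::local_tempdir()
  utils::write.csv(data.frame(species = occ$geo$species,
                              decimalLatitude = occ$geo$latitude,
                              decimalLongitude = occ$geo$longitude),
                   file.path(dir, "g.csv"), row.names = FALSE)
  back <- read_occurrences(file.path(dir, "g.csv"))
  expect_equal(nrow(attr(back, "validation_log")), 0)
  # hull area within 15% of target for >= 30 clean points
  for (sp in tbl$species) {
    pts <- occ$geo[occ$geo$species == sp, c("latitude", "longitude")]
    target <- tbl$eoo_target_km2[tbl$species == sp]
    expect_lt(abs(compute_eoo(pts) - target) / target, 0.15)
  }
})

test_that("exact planted violation counts are respected", {
  tbl <- data.frame(species = "sp01", region = "R01", eoo_target_km2 = 5000,
                    n_geo = 20, n_nongeo = 6, stringsAsFactors = FALSE)
  occ <- simulate_occurrences(tbl, atlas = toy_atlas(), seed = 14,
                              violation_counts = c(low_precision = 3))
  expect_equal(sum(occ$truth$class == "low_precision"), 3)
  cl <- checklist_df("sp01", regions = "R01")
  res <- clean_all(occ$geo, occ$nongeo, cl, toy_atlas(), occ$ref_points)
  st <- res$report[res$report$filter == "low_precision", ]
  expect_equal(st$records_removed, 3)
})

test_that("ground-truth labels partition the record set", {
  tbl <- generator_species_tbl(n = 6, seed = 15)
  occ <- simulate_occurrences(tbl, all_violation_rates, atlas = toy_atlas(),
                              seed = 16)
  expect_equal(sort(occ$truth$record_id),
               sort(c(occ$geo$record_id, occ$nongeo$record_id)))
  expect_false(anyDuplicated(occ$truth$record_id) > 0)
})

test_that("scenarios are reproducible and expose their configuration", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_scenario("baseline", list(n_species = 15), seed = 5, out_dir = d1)
  make_scenario("baseline", list(n_species = 15), seed = 5, out_dir = d2)
  for (f in c("occurrences_geo.csv", "checklist.csv", "trees.nwk",
              "truth_species.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_error(scenario_config("no_such_scenario"), "arg")
  cfg <- jsonlite::read_json(file.path(d1, "scenario.json"))
  expect_equal(cfg$n_species, 15)
  expect_equal(cfg$name, "baseline")
})

test_that("random resolutions preserve tip depths and differ in topology", {
  tr <- simulate_tree(40, 1, seed = 17)
  poly <- collapse_short_branches(tr)
  expect_lt(poly$Nnode, tr$Nnode)
  trees <- random_resolutions(poly, 5, seed = 18)
  d0 <- ape::node.depth.edgelength(poly)[seq_len(40)]
  for (t in trees) {
    expect_true(ape::is.binary(t))
    dt <- ape::node.depth.edgelength(t)[seq_len(40)]
    expect_equal(dt[order(t$tip.label)], d0[order(poly$tip.label)],
                 tolerance = 1e-9)
  }
})
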