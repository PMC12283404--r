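# Cleaning filters: suspect coordinates, dedup/thinning, precision,
# native range, non-georeferenced rules, and the composite.

test_that("suspect-coordinate rules remove zero and equal coordinates", {
  recs <- occ_df(rep("Aa bb", 4),
                 lat = c(0.0, 12.34, 5.5, -3.2),
                 lon = c(37.5, 12.34, 0.0, 8.8))
  out <- filter_suspect_coordinates(recs)
  expect_equal(out$removed$reason, c("lat_zero", "lat_eq_lon", "lon_zero"))
  expect_equal(out$records$record_id, "r004")
})

test_that("reference-point buffer removes by great-circle distance", {
  cap <- data.frame(lat = 10, lon = 20, kind = "capital")
  # a record 500 m due north of the capital
  dlat <- 500 / (pi * R_EARTH_KM * 1000 / 180)
  rec <- occ_df("Aa bb", lat = 10 + dlat, lon = 20)
  expect_equal(haversine_m(10, 20, 10 + dlat, 20), 500, tolerance = 1e-6)
  out1k <- filter_suspect_coordinates(rec, cap,
                                      cleaning_config(ref_buffer_m = 1000))
  expect_equal(out1k$removed$reason, "near_reference_point")
  out100 <- filter_suspect_coordinates(rec, cap,
                                       cleaning_config(ref_buffer_m = 100))
  expect_equal(nrow(out100$removed), 0)
})

test_that("deduplication rounds to 3 dp and keeps the first record", {
  recs <- occ_df(c("Aa bb", "Aa bb", "Cc dd"),
                 lat = c(10.0001, 10.0004, 10.0001),
                 lon = c(20.0001, 20.0004, 20.0001))
  out <- dedup_and_thin(recs)
  # same species, identical at 3 dp: second removed; other species kept
  expect_equal(out$removed$record_id, "r002")
  expect_equal(out$removed$reason, "duplicate_rounded")
  expect_equal(out$records$record_id, c("r001", "r003"))
})

test_that("grid thinning keeps one record per 110 m cell (hand-traced)", {
  # cell width at the equator is 110 m ~ 0.000989 deg; points A, B share
  # cell (0, 0) but differ at 3 dp; D, E round onto A; F rounds onto B;
  # G sits in cell (1, 0)
  recs <- occ_df(rep("Aa bb", 6),
                 lat = c(0.0001, 0.0002, 0.0001, 0.00015, 0.00012, 0.0001),
                 lon = c(0.0004, 0.0006, 0.00041, 0.00042, 0.00062, 0.0015))
  out <- dedup_and_thin(recs)
  expect_equal(out$records$record_id, c("r001", "r006"))
  reasons <- setNames(out$removed$reason, out$removed$record_id)
  expect_equal(reasons[["r002"]], "thinned_grid")
  expect_equal(unname(reasons[c("r003", "r004", "r005")]),
               rep("duplicate_rounded", 3))
})

test_that("precision filter is strict at 100 km and keeps missing values", {
  recs <- occ_df(rep("Aa bb", 4), lat = 1:4, lon = 11:14,
                 unc = c(150000, 100000, NA, -5))
  out <- filter_low_precision(recs)
  expect_equal(out$records$record_id, c("r002", "r003"))
  reasons <- setNames(out$removed$reason, out$removed$record_id)
  expect_equal(reasons[["r001"]], "low_precision")
  expect_equal(reasons[["r004"]], "invalid_uncertainty")
})

test_that("native-range filter is boundary-inclusive and flags unknown species", {
  atlas <- region_atlas(list(SQ = list(cbind(lon = c(0, 1, 1, 0, 0),
                                             lat = c(0, 0, 1, 1, 0)))),
                        iso_map = list(CQ = "SQ"))
  cl <- checklist_df("Aa bb", regions = "SQ")
  recs <- occ_df(c("Aa bb", "Aa bb", "Aa bb", "Zz zz"),
                 lat = c(0.5, 0.5, 0.5, 0.5),
                 lon = c(0.5, 1.5, 1.0, 0.5))  # inside, outside, boundary
  out <- filter_native_geo(recs, cl, atlas)
  expect_equal(out$records$record_id, c("r001", "r003"))
  reasons <- setNames(out$removed$reason, out$removed$record_id)
  expect_equal(reasons[["r002"]], "outside_native_range")
  expect_equal(reasons[["r004"]], "unknown_species")
  # region code without polygon -> hard error
  cl2 <- checklist_df("Aa bb", regions = "MISSING")
  expect_error(filter_native_geo(recs[1, ], cl2, atlas), "MISSING")
})

test_that("non-geo cleaning removes duplicates and foreign countries in order", {
  atlas <- toy_atlas()
  cl <- checklist_df("Aa bb", regions = "R01")  # native iso: C01
  recs <- occ_df(rep("Aa bb", 4), lat = NA_real_, lon = NA_real_,
                 cc = c("C01", "C01", "C02", "C01"),
                 locality = c("Mt. Kinabalu trail", "mt  kinabalu  trail",
                              "other place", "fourth site"),
                 year = c(1987L, NA, 1987L, 1990L),
                 admin = c("Sabah", NA, "Perak", "Sabah"))
  out <- clean_nongeo(recs, cl, atlas)
  expect_equal(out$records$record_id, c("r001", "r004"))
  reasons <- setNames(out$removed$reason, out$removed$record_id)
  expect_equal(reasons[["r002"]], "dup_locality")
  expect_equal(reasons[["r003"]], "outside_native_range")

  # duplicated (year, admin) with both fields present
  recs2 <- occ_df(rep("Aa bb", 2), lat = NA_real_, lon = NA_real_,
                  cc = "C01", locality = c("one", "two"),
                  year = 1987L, admin = "Sabah")
  out2 <- clean_nongeo(recs2, cl, atlas)
  expect_equal(out2$removed$reason, "dup_year_admin")
  # missing country code is kept at the native step
  recs3 <- occ_df("Aa bb", lat = NA_real_, lon = NA_real_,
                  cc = NA_character_, locality = "unique", year = NA)
  expect_equal(nrow(clean_nongeo(recs3, cl, atlas)$removed), 0)
})

test_that("clean_all conserves counts, is order-stable and idempotent", {
  tbl <- generator_species_tbl(n = 8, seed = 3)
  occ <- simulate_occurrences(tbl, all_violation_rates, atlas = toy_atlas(),
                              seed = 31)
  cl <- checklist_df(tbl$species, regions = as.list(tbl$region))
  res <- clean_all(occ$geo, occ$nongeo, cl, toy_atlas(), occ$ref_points)
  # conservation at every stage
  for (arm in c("geo", "nongeo")) {
    rep_arm <- res$report[res$report$arm == arm, ]
    for (i in seq_len(nrow(rep_arm) - 1)) {
      expect_equal(rep_arm$records_in[i + 1],
                   rep_arm$records_in[i] - rep_arm$records_removed[i])
    }
  }
  expect_equal(nrow(res$clean_geo) + nrow(res$removed_geo), nrow(occ$geo))
  expect_equal(nrow(res$clean_nongeo) + nrow(res$removed_nongeo),
               nrow(occ$nongeo))
  # order stability
  expect_true(!is.unsorted(match(res$clean_geo$record_id,
                                 occ$geo$record_id)))
  # idempotence
  res2 <- clean_all(res$clean_geo, res$clean_nongeo, cl, toy_atlas(),
                    occ$ref_points)
  expect_equal(nrow(res2$removed_geo), 0)
  expect_equal(nrow(res2$removed_nongeo), 0)
})

test_that("all-clean and empty inputs pass through untouched", {
  tbl <- generator_species_tbl(n = 4, seed = 5)
  occ <- simulate_occurrences(tbl, violation_rates = NULL,
                              atlas = toy_atlas(), seed = 51)
  cl <- checklist_df(tbl$species, regions = as.list(tbl$region))
  res <- clean_all(occ$geo, occ$nongeo, cl, toy_atlas(), occ$ref_points)
  expect_equal(sum(res$report$records_removed), 0)
  expect_equal(nrow(res$clean_geo), nrow(occ$geo))

  res0 <- clean_all(occ$geo[0, ], occ$nongeo[0, ], cl, toy_atlas(),
                    occ$ref_points)
  expect_equal(nrow(res0$clean_geo), 0)
  expect_true(all(res0$report$records_removed == 0))
})
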