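# Independent oracles and fixture builders shared across test files.

R_EARTH_KM <- 6371.0072

# haversine great-circle distance in metres, written independently of the
# package internals
haversine_m <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) *
    sin(dlon / 2)^2
  2 * R_EARTH_KM * 1000 * asin(pmin(1, sqrt(a)))
}

# brute-force phylogenetic VCV: pairwise shared path length via MRCA from
# explicit root-to-node paths (quadratic, independent of the package's
# clade-wise fill)
vcv_bruteforce <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  elen_of <- numeric(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen_of[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  path_to_root <- function(v) {
    out <- integer(0)
    while (v != root) { out <- c(out, v); v <- parent[v] }
    c(out, root)
  }
  depth <- function(v) {
    d <- 0
    while (v != root) { d <- d + elen_of[v]; v <- parent[v] }
    d
  }
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(ntip), path_to_root)
  for (i in seq_len(ntip)) {
    for (j in i:ntip) {
      mrca <- intersect(paths[[i]], paths[[j]])[1]
      C[i, j] <- C[j, i] <- depth(mrca)
    }
  }
  C
}

# dense GLS oracle with an explicit matrix inverse
gls_bruteforce <- function(y, X, V) {
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  e <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  rss <- as.numeric(t(e) %*% Vi %*% e)
  s2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi * s2_ml) + determinant(V)$modulus + n)
  se <- sqrt(diag(rss / (n - p) * solve(t(X) %*% Vi %*% X)))
  list(beta = as.numeric(beta), se = as.numeric(se), loglik = as.numeric(ll))
}

# planar equal-area EOO oracle: Lambert cylindrical equal-area projection,
# hull and shoelace in projected space
eoo_equal_area_oracle <- function(lat, lon) {
  x <- R_EARTH_KM * lon * pi / 180
  y <- R_EARTH_KM * sin(lat * pi / 180)
  h <- grDevices::chull(x, y)
  xx <- x[h]; yy <- y[h]
  abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy)) / 2
}

# small occurrence data frame in the package's standard layout
occ_df <- function(species, lat, lon, unc = NA_real_, cc = NA_character_,
                   locality = NA_character_, year = NA_integer_,
                   admin = NA_character_) {
  n <- length(species)
  data.frame(record_id = sprintf("r%03d", seq_len(n)), species = species,
             latitude = rep_len(lat, n), longitude = rep_len(lon, n),
             coord_uncertainty_m = rep_len(unc, n),
             country_code = rep_len(cc, n),
             region_code = rep_len(NA_character_, n),
             locality = rep_len(locality, n),
             year = rep_len(as.integer(year), n),
             admin_unit = rep_len(admin, n),
             basis = rep_len("PRESERVED_SPECIMEN", n),
             stringsAsFactors = FALSE)
}

checklist_df <- function(species, lifeform = "terrestrial", family = "Fam1",
                         regions = "R01") {
  n <- length(species)
  out <- data.frame(species = species,
                    lifeform = factor(rep_len(lifeform, n),
                                      levels = c("terrestrial", "epiphyte")),
                    family = rep_len(family, n), stringsAsFactors = FALSE)
  if (!is.list(regions)) regions <- as.list(rep_len(regions, n))
  out$native_regions <- regions
  out
}

# standard 12-species table driving the occurrence generator in tests
generator_species_tbl <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(species = sprintf("sp%02d", seq_len(n)),
             region = rep(c("R01", "R02", "R03"), length.out = n),
             eoo_target_km2 = runif(n, 500, 40000),
             n_geo = rpois(n, 30) + 3,
             n_nongeo = rpois(n, 10) + 2,
             stringsAsFactors = FALSE)
}

# expected removal reason(s) per planted violation class
violation_reason_map <- list(
  dup_exact = "duplicate_rounded", dup_rounded = "duplicate_rounded",
  coord_zero = c("lat_zero", "lon_zero"), coord_equal = "lat_eq_lon",
  low_precision = "low_precision", foreign_region = "outside_native_range",
  ref_point = "near_reference_point", dup_locality = "dup_locality",
  dup_year_admin = "dup_year_admin", foreign_country = "outside_native_range")

all_violation_rates <- c(dup_exact = 0.05, dup_rounded = 0.05,
                         coord_zero = 0.02, coord_equal = 0.02,
                         low_precision = 0.05, foreign_region = 0.05,
                         ref_point = 0.03, dup_locality = 0.05,
                         dup_year_admin = 0.05, foreign_country = 0.05)
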