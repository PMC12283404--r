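# Synthetic-data generator: Yule trees, Mk lifeform evolution, log range
# sizes with Pagel's-lambda covariance, and occurrence records with planted
# cleaning violations. Every scenario carries full ground truth so each
# pipeline stage can be checked against what was planted.

#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation of the Yule process: the root splits into two
#' lineages at time zero; with k lineages alive the next speciation arrives
#' after an Exp(k * birth_rate) wait and splits a uniformly chosen lineage;
#' after the n-th lineage appears the tree is cut after a final
#' Exp(n * birth_rate) hold. The tree is ultrametric with expected
#' root-to-tip depth `sum_{k=2..n} 1/(k * birth_rate)`.
#'
#' @param n_species Number of tips (>= 3).
#' @param birth_rate Speciation rate per lineage per unit time.
#' @param seed Optional RNG seed; a fixed seed gives a byte-identical tree.
#' @param tip_prefix Prefix for tip labels (`t001`, `t002`, ...).
#' @return An ultrametric `phylo` tree with `n_species` tips.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL,
                          tip_prefix = "t") {
  .assert(.is_count(n_species) && n_species >= 3, "need n_species >= 3")
  .assert(birth_rate > 0, "birth_rate must be positive")
  .set_seed_if(seed)
  n <- as.integer(n_species)
  # internal nodes, created in order; node 1 is the root at time 0
  int_parent <- 0L; int_time <- 0
  lin_parent <- c(1L, 1L); lin_start <- c(0, 0)
  t <- 0; k <- 2L
  while (k < n) {
    t <- t + stats::rexp(1, k * birth_rate)
    j <- sample.int(k, 1)
    m <- length(int_time) + 1L
    int_parent[m] <- lin_parent[j]; int_time[m] <- t
    lin_parent[j] <- m; lin_start[j] <- t
    lin_parent <- c(lin_parent, m); lin_start <- c(lin_start, t)
    k <- k + 1L
  }
  T_end <- t + stats::rexp(1, n * birth_rate)
  n_int <- length(int_time)
  edge <- matrix(0L, n + n_int - 1L, 2)
  elen <- numeric(n + n_int - 1L)
  r <- 0L
  for (m in seq_len(n_int)[-1]) {
    r <- r + 1L
    edge[r, ] <- c(n + int_parent[m], n + m)
    elen[r] <- int_time[m] - int_time[int_parent[m]]
  }
  for (i in seq_len(n)) {
    r <- r + 1L
    edge[r, ] <- c(n + lin_parent[i], i)
    elen[r] <- T_end - lin_start[i]
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = sprintf("%s%03d", tip_prefix, seq_len(n)),
                       Nnode = n_int), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Rescale a tree to a given root-to-tip depth
#' @param tree An ultrametric `phylo` tree.
#' @param depth Target depth.
#' @return The rescaled tree.
#' @export
rescale_tree_depth <- function(tree, depth) {
  d <- max(ape::node.depth.edgelength(tree))
  .assert(d > 0, "tree has zero depth")
  tree$edge.length <- tree$edge.length * depth / d
  tree
}

#' Simulate a binary lifeform trait by a two-state Markov process
#'
#' Continuous-time Mk simulation from root to tips: the root state is drawn
#' from the stationary distribution (`P(terrestrial) = q10 / (q01 + q10)`)
#' and transitions occur along each branch with rate `q01`
#' (terrestrial -> epiphyte) or `q10` (epiphyte -> terrestrial). Low rates
#' on a deep tree produce the phylogenetically clustered epiphytism seen in
#' real angiosperms, where most epiphytes sit in a few species-rich clades.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param mk_rates Named numeric vector `c(q01 = ..., q10 = ...)`.
#' @param seed Optional RNG seed.
#' @return Factor of tip states (`terrestrial`/`epiphyte`), named by tip
#'   label.
#' @export
simulate_lifeform <- function(tree, mk_rates = c(q01 = 0.3, q10 = 0.3),
                              seed = NULL) {
  q01 <- mk_rates[["q01"]]; q10 <- mk_rates[["q10"]]
  .assert(q01 >= 0 && q10 >= 0 && q01 + q10 > 0, "invalid Mk rates")
  .set_seed_if(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  state <- integer(nnode)
  root <- ntip + 1L
  state[root] <- stats::rbinom(1, 1, q01 / (q01 + q10))  # P(epiphyte at root)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    s <- state[pre$edge[e, 1]]
    L <- pre$edge.length[e]
    t <- 0
    repeat {
      rate <- if (s == 0L) q01 else q10
      if (rate == 0) break
      t <- t + stats::rexp(1, rate)
      if (t > L) break
      s <- 1L - s
    }
    state[pre$edge[e, 2]] <- s
  }
  stats::setNames(factor(ifelse(state[seq_len(ntip)] == 1L,
                                "epiphyte", "terrestrial"),
                         levels = c("terrestrial", "epiphyte")),
                  tree$tip.label)
}

#' Simulate log range sizes under the PGLS generative model
#'
#' `y = alpha + beta_lifeform * 1[epiphyte] + eps`, with
#' `eps ~ MVN(0, sigma2 * lambda_transform(phylo_vcv(tree), lambda_true))`
#' sampled through a Cholesky factor. This is the exact generative
#' counterpart of the PGLS model the package fits, so parameter recovery can
#' be checked against known truth.
#'
#' @param tree A `phylo` tree.
#' @param labels Lifeform factor aligned to tips (see [simulate_lifeform()]).
#' @param alpha Intercept (log range of a terrestrial species).
#' @param beta_lifeform Additive lifeform effect on log range.
#' @param lambda_true Pagel's lambda of the noise, in `[0, 1]`.
#' @param sigma2 Brownian rate.
#' @param seed Optional RNG seed.
#' @return Named numeric vector of log range sizes with attribute `"eps"`
#'   (the noise draw).
#' @export
simulate_log_range <- function(tree, labels, alpha, beta_lifeform,
                               lambda_true, sigma2, seed = NULL) {
  .set_seed_if(seed)
  taxa <- tree$tip.label
  .assert(!is.null(names(labels)) && all(taxa %in% names(labels)),
          "labels must be named by tip label")
  C <- phylo_vcv(tree)
  V <- sigma2 * lambda_transform(C, lambda_true)
  L <- tryCatch(t(chol(V)), error = function(e)
    stop("covariance is not positive definite: ", conditionMessage(e),
         call. = FALSE))
  eps <- as.numeric(L %*% stats::rnorm(length(taxa)))
  y <- alpha + beta_lifeform * (labels[taxa] == "epiphyte") + eps
  out <- stats::setNames(as.numeric(y), taxa)
  attr(out, "eps") <- stats::setNames(eps, taxa)
  out
}

# Expected fraction of a disc's area covered by the convex hull of n
# uniform points (empirical fit 1 - 3.08 * n^(-2/3), floor 0.3).
#' @noRd
.hull_fraction <- function(n) pmax(0.3, 1 - 3.08 * n^(-2 / 3))

.KM_PER_DEG <- pi * 6371.0072 / 180

#' Simulate occurrence records with planted cleaning violations
#'
#' For each species, clean georeferenced records are drawn uniformly inside
#' a disc centred in the species' native region; the disc is inflated by
#' the expected convex-hull coverage so that the hull area of the clean
#' points matches `eoo_target_km2` (within ~15% for 30 or more points).
#' Clean points are rejection-sampled to be pairwise distinct at the
#' rounding/thinning resolution, inside the native region, away from
#' reference points, and free of zero/equal coordinates, so that the
#' cleaning filters remove nothing that was not planted.
#'
#' Violations are planted one class per record (never overlapping), each
#' class targeted at exactly one filter: `dup_exact` and `dup_rounded`
#' (deduplication), `coord_zero` and `coord_equal` (suspect coordinates),
#' `low_precision` (uncertainty filter), `foreign_region` (native-range
#' filter), `ref_point` (suspect coordinates); and for the
#' non-georeferenced arm `dup_locality`, `dup_year_admin`,
#' `foreign_country`.
#'
#' @param species_tbl Data frame with columns `species`, `region` (native
#'   region code used for placement), `eoo_target_km2`, `n_geo`,
#'   `n_nongeo`.
#' @param violation_rates Named numeric vector of per-clean-record planting
#'   probabilities for the classes above (missing classes default to 0).
#' @param atlas A `region_atlas` with at least two regions.
#' @param ref_points Reference points data frame (`lat`, `lon`, `kind`), or
#'   `NULL` to place one synthetic reference point per region.
#' @param config [cleaning_config()] whose resolutions the generator must
#'   respect.
#' @param seed Optional RNG seed.
#' @param violation_counts Optional named integer vector of exact total
#'   counts per class (overrides `violation_rates`).
#' @return List `geo`, `nongeo` (occurrence data frames), `truth`
#'   (`record_id`, `species`, `arm`, `class`), `ref_points`.
#' @export
simulate_occurrences <- function(species_tbl, violation_rates = NULL,
                                 atlas = toy_atlas(), ref_points = NULL,
                                 config = cleaning_config(), seed = NULL,
                                 violation_counts = NULL) {
  .set_seed_if(seed)
  .assert(length(atlas$regions) >= 2, "atlas needs at least 2 regions")
  classes <- c("dup_exact", "dup_rounded", "coord_zero", "coord_equal",
               "low_precision", "foreign_region", "ref_point",
               "dup_locality", "dup_year_admin", "foreign_country")
  rates <- stats::setNames(rep(0, length(classes)), classes)
  if (!is.null(violation_rates)) {
    rates[names(violation_rates)] <- violation_rates
  }

  if (is.null(ref_points)) {
    ref_points <- do.call(rbind, lapply(seq_len(nrow(atlas$centroids)),
      function(i) data.frame(lat = atlas$centroids$lat[i] + 1,
                             lon = atlas$centroids$lon[i] + 1,
                             kind = "capital", stringsAsFactors = FALSE)))
  }

  # inverse ISO map: region -> iso codes
  iso_of <- function(rc) {
    names(atlas$iso_map)[vapply(atlas$iso_map, function(v) rc %in% v,
                                logical(1))]
  }

  round_key <- function(lat, lon) {
    paste(formatC(round(lat, config$round_dp), format = "f",
                  digits = config$round_dp),
          formatC(round(lon, config$round_dp), format = "f",
                  digits = config$round_dp))
  }
  cell_key <- function(lat, lon) {
    x <- .EARTH_RADIUS_M * (pi / 180) * lon * cos(lat * pi / 180)
    y <- .EARTH_RADIUS_M * (pi / 180) * lat
    paste(floor(x / config$grid_m), floor(y / config$grid_m))
  }

  geo <- list(); nongeo <- list(); truth <- list()
  gid <- 0L; nid <- 0L
  add_geo <- function(sp, lat, lon, unc, cls) {
    gid <<- gid + 1L
    id <- sprintf("g%06d", gid)
    geo[[length(geo) + 1L]] <<- data.frame(
      record_id = id, species = sp, latitude = lat, longitude = lon,
      coord_uncertainty_m = unc, country_code = NA_character_,
      region_code = NA_character_, locality = NA_character_,
      year = NA_integer_, admin_unit = NA_character_,
      basis = "PRESERVED_SPECIMEN", stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      record_id = id, species = sp, arm = "geo", class = cls,
      stringsAsFactors = FALSE)
  }
  add_nongeo <- function(sp, cc, loc, yr, adm, cls) {
    nid <<- nid + 1L
    id <- sprintf("n%06d", nid)
    nongeo[[length(nongeo) + 1L]] <<- data.frame(
      record_id = id, species = sp, latitude = NA_real_,
      longitude = NA_real_, coord_uncertainty_m = NA_real_,
      country_code = cc, region_code = NA_character_, locality = loc,
      year = yr, admin_unit = adm, basis = "PRESERVED_SPECIMEN",
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      record_id = id, species = sp, arm = "nongeo", class = cls,
      stringsAsFactors = FALSE)
  }

  n_per_class <- function(n_clean, n_sp) {
    if (!is.null(violation_counts)) {
      cnt <- stats::setNames(rep(0L, length(classes)), classes)
      cnt[names(violation_counts)] <- as.integer(violation_counts)
      cnt
    } else {
      stats::setNames(stats::rbinom(length(classes), n_clean, rates), classes)
    }
  }

  for (si in seq_len(nrow(species_tbl))) {
    sp <- species_tbl$species[si]
    rc <- species_tbl$region[si]
    .assert(rc %in% names(atlas$regions), "unknown region %s", rc)
    # full native set (placement region plus any extra native regions)
    native_set <- rc
    if (!is.null(species_tbl$native_regions)) {
      nr <- species_tbl$native_regions[[si]]
      if (is.character(nr) && length(nr) == 1) nr <- strsplit(nr, "[|;]")[[1]]
      native_set <- unique(c(rc, trimws(nr)))
    }
    bbox <- do.call(rbind, atlas$regions[[rc]])
    lon_rng <- range(bbox[, 1]); lat_rng <- range(bbox[, 2])
    n_geo <- species_tbl$n_geo[si]
    n_ng <- species_tbl$n_nongeo[si]
    target <- species_tbl$eoo_target_km2[si]

    # disc centre jittered inside the region, disc inflated for hull coverage
    r_km <- sqrt(target / .hull_fraction(max(n_geo, 4)) / pi)
    # the disc must fit inside a 10-degree toy region; very large targets
    # with few points are clamped (the hull-matching contract only covers
    # point counts >= 30, where no clamping occurs)
    r_deg <- min(r_km / .KM_PER_DEG, 4.2)
    pad <- r_deg * 1.05
    c_lat <- stats::runif(1, max(lat_rng[1] + pad, mean(lat_rng) - 2),
                          min(lat_rng[2] - pad, mean(lat_rng) + 2))
    c_lon <- stats::runif(1, max(lon_rng[1] + pad, mean(lon_rng) - 2),
                          min(lon_rng[2] - pad, mean(lon_rng) + 2))
    cosc <- cos(c_lat * pi / 180)

    seen_round <- character(0); seen_cell <- character(0)
    clean_pts <- matrix(NA_real_, n_geo, 2)
    for (i in seq_len(n_geo)) {
      for (try in seq_len(1000)) {
        th <- stats::runif(1, 0, 2 * pi)
        rr <- r_deg * sqrt(stats::runif(1))
        lat <- c_lat + rr * sin(th)
        lon <- c_lon + rr * cos(th) / cosc
        if (lat == 0 || lon == 0 || lat == lon) next
        if (!point_in_regions(atlas, lat, lon, rc)) next
        rk <- round_key(lat, lon); ck <- cell_key(lat, lon)
        if (rk %in% seen_round || ck %in% seen_cell) next
        if (nrow(ref_points) &&
            any(.gc_dist_m(lat, lon, ref_points$lat, ref_points$lon) <=
                  config$ref_buffer_m * 1.5)) next
        seen_round <- c(seen_round, rk); seen_cell <- c(seen_cell, ck)
        clean_pts[i, ] <- c(lat, lon)
        break
      }
      .assert(!is.na(clean_pts[i, 1]),
              "could not place a clean point for %s (disc too dense?)", sp)
      unc <- if (stats::runif(1) < 0.5) NA_real_ else
        stats::runif(1, 10, 0.3 * config$max_uncertainty_m)
      add_geo(sp, clean_pts[i, 1], clean_pts[i, 2], unc, "clean")
    }

    cnt <- n_per_class(n_geo, sp)

    pick_clean <- function() clean_pts[sample.int(n_geo, 1), , drop = TRUE]
    for (k in seq_len(cnt[["dup_exact"]])) {
      p <- pick_clean()
      add_geo(sp, p[1], p[2], NA_real_, "dup_exact")
    }
    for (k in seq_len(cnt[["dup_rounded"]])) {
      ok <- FALSE
      for (try in seq_len(200)) {
        p <- pick_clean()
        lat <- round(p[1], config$round_dp) + stats::runif(1, -4, 4) * 10^(-config$round_dp - 1)
        lon <- round(p[2], config$round_dp) + stats::runif(1, -4, 4) * 10^(-config$round_dp - 1)
        if (round_key(lat, lon) != round_key(p[1], p[2])) next
        if (!point_in_regions(atlas, lat, lon, rc)) next
        if (lat == 0 || lon == 0 || lat == lon) next
        if (any(.gc_dist_m(lat, lon, ref_points$lat, ref_points$lon) <=
                  config$ref_buffer_m)) next
        add_geo(sp, lat, lon, NA_real_, "dup_rounded"); ok <- TRUE; break
      }
      .assert(ok, "could not plant dup_rounded for %s", sp)
    }
    for (k in seq_len(cnt[["coord_zero"]] + cnt[["coord_equal"]])) {
      want_equal <- k > cnt[["coord_zero"]]
      planted <- FALSE
      if (want_equal) {
        cand <- seq(max(lat_rng[1], lon_rng[1]), min(lat_rng[2], lon_rng[2]),
                    length.out = 23)
        cand <- cand[cand != 0]
        cand <- cand[vapply(cand, function(cc)
          .point_in_ring(cc, cc, atlas$regions[[rc]][[1]]), logical(1))]
        if (length(cand)) {
          cc <- cand[sample.int(length(cand), 1)] + stats::runif(1, -1e-4, 1e-4)
          if (.point_in_ring(cc, cc, atlas$regions[[rc]][[1]])) {
            add_geo(sp, cc, cc, NA_real_, "coord_equal"); planted <- TRUE
          }
        }
      }
      if (!planted) {
        if (lat_rng[1] <= 0 && lat_rng[2] >= 0) {
          lon <- stats::runif(1, lon_rng[1] + 0.5, lon_rng[2] - 0.5)
          add_geo(sp, 0, lon, NA_real_, "coord_zero")
        } else {
          # region off the equator: plant a zero longitude on its boundary
          .assert(lon_rng[1] <= 0 && lon_rng[2] >= 0,
                  "cannot plant a zero/equal coordinate inside region %s", rc)
          lat <- stats::runif(1, lat_rng[1] + 0.5, lat_rng[2] - 0.5)
          add_geo(sp, lat, 0, NA_real_, "coord_zero")
        }
      }
    }
    for (k in seq_len(cnt[["low_precision"]])) {
      lat <- stats::runif(1, lat_rng[1] + 0.5, lat_rng[2] - 0.5)
      lon <- stats::runif(1, lon_rng[1] + 0.5, lon_rng[2] - 0.5)
      if (lat == 0 || lon == 0 || lat == lon) lat <- lat + 0.01
      add_geo(sp, lat, lon,
              config$max_uncertainty_m * stats::runif(1, 1.5, 5),
              "low_precision")
    }
    foreign <- setdiff(names(atlas$regions), native_set)
    for (k in seq_len(cnt[["foreign_region"]])) {
      fr <- sample(foreign, 1)
      fb <- do.call(rbind, atlas$regions[[fr]])
      lat <- stats::runif(1, min(fb[, 2]) + 0.5, max(fb[, 2]) - 0.5)
      lon <- stats::runif(1, min(fb[, 1]) + 0.5, max(fb[, 1]) - 0.5)
      if (lat == 0 || lon == 0 || lat == lon) lat <- lat + 0.01
      add_geo(sp, lat, lon, NA_real_, "foreign_region")
    }
    if (cnt[["ref_point"]] > 0) {
      inside <- which(vapply(seq_len(nrow(ref_points)), function(i)
        point_in_regions(atlas, ref_points$lat[i], ref_points$lon[i], rc),
        logical(1)))
      .assert(length(inside) > 0,
              "no reference point inside region %s to collide with", rc)
      for (k in seq_len(cnt[["ref_point"]])) {
        rp <- ref_points[inside[sample.int(length(inside), 1)], ]
        d_deg <- stats::runif(1, 0.1, 0.5) * config$ref_buffer_m /
          (.KM_PER_DEG * 1000)
        add_geo(sp, rp$lat + d_deg, rp$lon, NA_real_, "ref_point")
      }
    }

    # non-georeferenced arm
    native_iso <- iso_of(rc)
    .assert(length(native_iso) > 0, "region %s has no ISO code", rc)
    foreign_iso <- Filter(function(ic)
      length(intersect(atlas$iso_map[[ic]], native_set)) == 0,
      names(atlas$iso_map))
    yrs <- sample(1900:2020, max(n_ng, 1) * 3, replace = TRUE)
    adms <- sprintf("admin_%02d", sample.int(60, max(n_ng, 1) * 3, replace = TRUE))
    used_ya <- character(0)
    clean_ng <- list()
    for (i in seq_len(n_ng)) {
      j <- i
      while (paste(yrs[j], adms[j]) %in% used_ya) j <- j + 1
      used_ya <- c(used_ya, paste(yrs[j], adms[j]))
      loc <- sprintf("%s collection site %03d", sp, i)
      cc <- if (stats::runif(1) < 0.2) NA_character_ else
        sample(native_iso, 1)
      add_nongeo(sp, cc, loc, yrs[j], adms[j], "clean")
      clean_ng[[i]] <- list(loc = loc, yr = yrs[j], adm = adms[j])
    }
    if (n_ng > 0) {
      for (k in seq_len(cnt[["dup_locality"]])) {
        o <- clean_ng[[sample.int(n_ng, 1)]]
        mangled <- paste0("  ", toupper(o$loc), "  ")
        add_nongeo(sp, sample(native_iso, 1), mangled, NA_integer_,
                   NA_character_, "dup_locality")
      }
      for (k in seq_len(cnt[["dup_year_admin"]])) {
        o <- clean_ng[[sample.int(n_ng, 1)]]
        add_nongeo(sp, sample(native_iso, 1), NA_character_, o$yr, o$adm,
                   "dup_year_admin")
      }
    }
    if (length(foreign_iso)) {
      for (k in seq_len(cnt[["foreign_country"]])) {
        j <- length(used_ya) + k
        add_nongeo(sp, sample(foreign_iso, 1),
                   sprintf("%s foreign site %03d", sp, k),
                   yrs[j], adms[j], "foreign_country")
      }
    }
  }

  empty_occ <- data.frame(record_id = character(0), species = character(0),
                          latitude = numeric(0), longitude = numeric(0),
                          coord_uncertainty_m = numeric(0),
                          country_code = character(0),
                          region_code = character(0), locality = character(0),
                          year = integer(0), admin_unit = character(0),
                          basis = character(0), stringsAsFactors = FALSE)
  list(geo = if (length(geo)) do.call(rbind, geo) else empty_occ,
       nongeo = if (length(nongeo)) do.call(rbind, nongeo) else empty_occ,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(record_id = character(0), species = character(0),
                    arm = character(0), class = character(0)),
       ref_points = ref_points)
}

#' Collapse short internal branches into polytomies
#' @param tree A `phylo` tree.
#' @param tol Branch-length tolerance passed to [ape::di2multi()]; defaults
#'   to the 20% quantile of internal branch lengths.
#' @return A tree with polytomies.
#' @export
collapse_short_branches <- function(tree, tol = NULL) {
  internal <- tree$edge[, 2] > length(tree$tip.label)
  if (is.null(tol)) tol <- stats::quantile(tree$edge.length[internal], 0.2)
  ape::di2multi(tree, tol = tol)
}

#' Random resolutions of a tree's polytomies
#'
#' Emulates a set of imputed phylogenies: each polytomy is resolved
#' uniformly at random and the new internal branches receive a small random
#' length, taken from their child branches so that tip depths (and
#' ultrametricity) are preserved. The resolutions therefore differ slightly
#' in their implied covariances, mimicking uncertainty in the placement of
#' taxa lacking molecular data.
#'
#' @param tree A `phylo` tree (with or without polytomies).
#' @param n_trees Number of resolutions.
#' @param seed Optional RNG seed.
#' @param jitter Give new branches random positive lengths (default);
#'   `FALSE` leaves them at zero, making all resolutions covariance-
#'   identical.
#' @return A `multiPhylo` list.
#' @export
random_resolutions <- function(tree, n_trees, seed = NULL, jitter = TRUE) {
  .set_seed_if(seed)
  out <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- ape::multi2di(tree, random = TRUE)
    if (jitter) {
      # postorder over new zero-length internal edges: borrow length from
      # the immediate child edges so root-to-tip depths are unchanged
      post <- ape::reorder.phylo(tr, "postorder")
      ord <- order(match(tr$edge[, 2], post$edge[, 2]))
      for (e in ord) {
        v <- tr$edge[e, 2]
        if (v <= length(tr$tip.label) || tr$edge.length[e] > 0) next
        kids <- which(tr$edge[, 1] == v)
        slack <- min(tr$edge.length[kids])
        if (slack <= 0) next
        u <- stats::runif(1, 0, 0.5 * slack)
        tr$edge.length[e] <- tr$edge.length[e] + u
        tr$edge.length[kids] <- tr$edge.length[kids] - u
      }
    }
    out[[i]] <- tr
  }
  class(out) <- "multiPhylo"
  out
}

#' Build a range table with planted rarity proportions
#'
#' Constructs a synthetic classified range table whose per-lifeform rare
#' proportions are exact by construction: rare species get metrics halfway
#' below the threshold, non-rare species well above it.
#'
#' @param n Named integer vector: species per lifeform.
#' @param prop_rare_eoo,prop_rare_specimens Named proportions per lifeform.
#' @param thr A [rarity_thresholds()].
#' @return A classified range table.
#' @export
plant_rarity_table <- function(n = c(epiphyte = 20, terrestrial = 20),
                               prop_rare_eoo = c(epiphyte = 0.5,
                                                 terrestrial = 0.25),
                               prop_rare_specimens = prop_rare_eoo,
                               thr = rarity_thresholds()) {
  rows <- list()
  for (lf in names(n)) {
    k <- n[[lf]]
    k_eoo <- round(k * prop_rare_eoo[[lf]])
    k_spc <- round(k * prop_rare_specimens[[lf]])
    rows[[lf]] <- data.frame(
      species = sprintf("%s_sp%03d", lf, seq_len(k)),
      lifeform = factor(lf, levels = c("terrestrial", "epiphyte")),
      family = "FamSynth",
      n_botanical_countries = 1L,
      specimen_count = as.integer(
        c(rep(thr$specimens_max, k_spc), rep(thr$specimens_max + 5, k - k_spc))),
      eoo_km2 = c(rep(thr$eoo_km2_max / 2, k_eoo),
                  rep(thr$eoo_km2_max * 2, k - k_eoo)),
      eligible_le4 = TRUE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("range_table", "data.frame")
  classify_rarity(out, thr)
}
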