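# Shared internal helpers.

# Authalic earth radius, metres. All spherical computations in the package
# (EOO areas, haversine buffers, grid thinning) use this radius.
.EARTH_RADIUS_M <- 6371007.2

#' @noRd
.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x > 0 && x == round(x)

#' @noRd
.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Derive a reproducible child seed from a parent seed and a stage offset.
# Kept below 2^31 so it is always a valid R integer seed.
#' @noRd
.child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}

#' @noRd
.set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
}

# Great-circle distance in metres on the authalic sphere.
#' @noRd
.gc_dist_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .EARTH_RADIUS_M)
}

# Normalize longitudes to (-180, 180].
#' @noRd
.norm_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[!is.na(out) & out == -180] <- 180
  out
}

# Collapse whitespace, trim and case-fold a free-text field.
#' @noRd
.norm_text <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# Locality normalization additionally drops punctuation, so "Mt. Kinabalu
# trail" and "mt  kinabalu  trail" collide as duplicates.
#' @noRd
.norm_locality <- function(x) {
  .norm_text(gsub("[[:punct:]]", "", x))
}
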