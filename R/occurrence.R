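#' Georeferenced presence records
#'
#' A thin data.frame wrapper holding presence points (`species`, `lon`,
#' `lat`) plus a per-point provenance tag (`source`: survey, portal or
#' synthetic). Coordinates must be finite WGS84 lon/lat.
#'
#' @param df data.frame with at least `species`, `lon`, `lat`; an optional
#'   `source` column defaults to "survey".
#' @return an object of classes `occurrence_set` and `data.frame`.
#' @export
occurrence_set <- function(df) {
  need <- c("species", "lon", "lat")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("occurrence data must have columns: %s (missing %s)",
          paste(need, collapse = ", "), paste(missing, collapse = ", "))
  if (!"source" %in% names(df)) df$source <- rep("survey", nrow(df))
  df <- df[, c("species", "lon", "lat", "source")]
  if (nrow(df)) {
    if (any(!is.finite(df$lon)) || any(!is.finite(df$lat)))
      stopf("coordinates must be finite")
    if (any(df$lon < -180 | df$lon > 180) || any(df$lat < -90 | df$lat > 90))
      stopf("lon must lie in [-180, 180] and lat in [-90, 90]")
  }
  rownames(df) <- NULL
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Read occurrences from CSV
#'
#' Expects a UTF-8 CSV with header `species,lon,lat` (a `source` column is
#' honored if present).
#'
#' @param path CSV file path.
#' @return an [occurrence_set()].
#' @export
read_occurrences <- function(path) {
  occurrence_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write occurrences to CSV (`species,lon,lat,source` header)
#' @param occ an [occurrence_set()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spatially thin presence records
#'
#' Two-stage greedy thinning in input order: first at most one point per
#' raster cell (the first point to land in a cell wins), then, if
#' `min_dist_km > 0`, a point is kept only if its great-circle distance to
#' every already-kept point is at least `min_dist_km`. Deterministic given
#' the input order; thinning an already-thinned set is the identity.
#'
#' @param occ an [occurrence_set()].
#' @param stack `raster_stack` defining the cell grid (NULL skips the
#'   one-per-cell stage).
#' @param min_dist_km minimum pairwise great-circle distance in km (>= 0).
#' @return the thinned [occurrence_set()].
#' @export
thin_occurrences <- function(occ, stack = NULL, min_dist_km = 0) {
  if (min_dist_km < 0) stopf("min_dist_km must be >= 0")
  if (nrow(occ) == 0L) return(occ)
  keep <- rep(TRUE, nrow(occ))
  if (!is.null(stack)) {
    cells <- cell_from_lonlat(stack, occ$lon, occ$lat)$cell
    keep <- !duplicated(cells, incomparables = NA)
  }
  idx <- which(keep)
  if (min_dist_km > 0 && length(idx) > 1L) {
    kept <- idx[1L]
    for (i in idx[-1L]) {
      dmin <- min(geosphere::distHaversine(
        cbind(occ$lon[i], occ$lat[i]), cbind(occ$lon[kept], occ$lat[kept])))
      if (dmin >= min_dist_km * 1000) kept <- c(kept, i)
    }
    idx <- kept
  }
  occurrence_set(as.data.frame(occ)[idx, , drop = FALSE])
}
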