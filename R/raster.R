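#' Gridded environmental predictor stack
#'
#' A `raster_stack` holds one or more co-registered single-band layers on a
#' regular lon/lat grid: a named list of numeric matrices (row 1 = northernmost
#' row), an affine georeference (lower-left corner + square cell size, the
#' ESRI ASCII grid convention), a CRS identifier, and a shared nodata mask
#' (`NA` cells). All layers must share shape and mask.
#'
#' @param layers named list of numeric matrices, all the same dimension.
#' @param xll,yll coordinates of the outer corner of the lower-left cell.
#' @param cellsize cell edge length in degrees (square cells).
#' @param crs coordinate reference identifier (default WGS84 lon/lat).
#' @param harmonize_mask if `TRUE` (default) the union of the layers' `NA`
#'   cells becomes the shared mask; if `FALSE`, differing masks are an error.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(layers, xll = 0, yll = 0, cellsize = 1,
                         crs = "EPSG:4326", harmonize_mask = TRUE) {
  if (!is.list(layers) || length(layers) == 0L)
    stopf("`layers` must be a non-empty named list of matrices")
  if (is.null(names(layers)) || anyDuplicated(names(layers)) || any(names(layers) == ""))
    stopf("layer names must be unique and non-empty")
  dims <- lapply(layers, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stopf("all layers must be matrices")
  ref <- dims[[1L]]
  for (i in seq_along(layers)) {
    if (!identical(dims[[i]], ref))
      stopf("layer '%s' has shape %dx%d, expected %dx%d",
            names(layers)[i], dims[[i]][1], dims[[i]][2], ref[1], ref[2])
    storage.mode(layers[[i]]) <- "double"
  }
  mask <- Reduce(`|`, lapply(layers, is.na))
  if (harmonize_mask) {
    layers <- lapply(layers, function(m) { m[mask] <- NA_real_; m })
  } else {
    for (i in seq_along(layers))
      if (!identical(is.na(layers[[i]]), mask))
        stopf("layer '%s' has a different nodata mask", names(layers)[i])
  }
  structure(list(layers = layers, xll = xll, yll = yll,
                 cellsize = cellsize, crs = crs),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$layers[[1L]])
  cat(sprintf("raster_stack: %d layer(s), %d x %d cells, cellsize %g, %s\n",
              length(x$layers), d[1], d[2], x$cellsize, x$crs))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat(sprintf("  valid cells: %d / %d\n", sum(!is.na(x$layers[[1L]])), prod(d)))
  invisible(x)
}

n_layers <- function(stack) length(stack$layers)
stack_dim <- function(stack) dim(stack$layers[[1L]])
stack_mask <- function(stack) !is.na(stack$layers[[1L]])
layer_names <- function(stack) names(stack$layers)

#' Cell-center coordinates for every grid cell
#'
#' @param stack a `raster_stack`.
#' @return data.frame with `cell` (column-major index), `lon`, `lat`.
#' @export
cell_centers <- function(stack) {
  d <- stack_dim(stack)
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  data.frame(cell = seq_len(prod(d)),
             lon = stack$xll + (cols - 0.5) * stack$cellsize,
             lat = stack$yll + (d[1] - rows + 0.5) * stack$cellsize)
}

# Map lon/lat to (row, col); half-open cells, points exactly on an interior
# grid edge assign to the lower-index cell. Returns NA outside the grid.
cell_from_lonlat <- function(stack, lon, lat) {
  d <- stack_dim(stack); cs <- stack$cellsize
  fx <- (lon - stack$xll) / cs
  fy <- (lat - stack$yll) / cs
  col <- floor(fx) + 1
  on_edge_x <- fx == floor(fx) & fx > 0
  col[on_edge_x] <- fx[on_edge_x]            # edge -> lower-index cell
  row_from_bottom <- floor(fy) + 1
  on_edge_y <- fy == floor(fy) & fy > 0
  row_from_bottom[on_edge_y] <- fy[on_edge_y]
  row <- d[1] - row_from_bottom + 1
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1]
  col[bad] <- NA; row[bad] <- NA
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((col - 1) * d[1] + row))
}

#' Extract predictor values at point locations
#'
#' @param stack a `raster_stack`.
#' @param lon,lat coordinate vectors.
#' @param layers layer names to extract (default all).
#' @return data.frame, one column per layer; `NA` outside the grid or on
#'   nodata cells.
#' @export
extract_values <- function(stack, lon, lat, layers = layer_names(stack)) {
  idx <- cell_from_lonlat(stack, lon, lat)
  out <- lapply(layers, function(nm) {
    v <- rep(NA_real_, length(lon))
    ok <- !is.na(idx$cell)
    v[ok] <- stack$layers[[nm]][idx$cell[ok]]
    v
  })
  names(out) <- layers
  as.data.frame(out, optional = TRUE)
}

# ---- ESRI ASCII grid I/O -------------------------------------------------
# Plain-text single-band raster format (the SDM field's standard text
# exchange format). Full-precision "%.17g" serialization makes the
# write -> read round trip value-exact.

write_asc <- function(mat, path, xll, yll, cellsize, nodata = -9999) {
  d <- dim(mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", d[2]),
               sprintf("nrows %d", d[1]),
               sprintf("xllcorner %.17g", xll),
               sprintf("yllcorner %.17g", yll),
               sprintf("cellsize %.17g", cellsize),
               sprintf("NODATA_value %.17g", nodata)), con)
  m <- mat
  m[is.na(m)] <- nodata
  txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(txt, con)
}

read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value"))
    if (!k %in% keys) stopf("'%s': malformed ASCII grid header (missing %s)", path, k)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  body <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(body) != nr * nc)
    stopf("'%s': expected %d values, found %d", path, nr * nc, length(body))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  list(mat = m, xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
       cellsize = vals[["cellsize"]])
}

#' Write a raster stack to a directory
#'
#' One single-band ASCII grid (`<layer>.asc`, nodata -9999) per layer plus a
#' `manifest.json` recording layer order, georeference and CRS.
#'
#' @param stack a `raster_stack`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in layer_names(stack)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_asc(stack$layers[[nm]], p, stack$xll, stack$yll, stack$cellsize)
    paths <- c(paths, p)
  }
  manifest <- list(layers = as.list(layer_names(stack)),
                   xllcorner = stack$xll, yllcorner = stack$yll,
                   cellsize = stack$cellsize, crs = stack$crs,
                   nodata = -9999, format = "esri_ascii_grid")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(dir, "manifest.json")))
}

#' Read a raster stack from ASCII grid files
#'
#' Either a directory written by [write_stack()] (its `manifest.json` fixes
#' layer order and CRS) or an explicit vector of `.asc` paths. All grids must
#' agree on shape and georeference (transform tolerance 1e-6).
#'
#' @param paths directory or character vector of `.asc` files.
#' @param crs CRS identifier used when no manifest is present.
#' @return a `raster_stack`.
#' @export
read_stack <- function(paths, crs = "EPSG:4326") {
  if (length(paths) == 1L && dir.exists(paths)) {
    mf_path <- file.path(paths, "manifest.json")
    if (file.exists(mf_path)) {
      mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
      crs <- mf$crs %||% crs
      files <- file.path(paths, paste0(unlist(mf$layers), ".asc"))
    } else {
      files <- sort(list.files(paths, pattern = "\\.asc$", full.names = TRUE))
    }
  } else files <- paths
  if (length(files) == 0L) stopf("no .asc layers found")
  nm <- sub("\\.asc$", "", basename(files))
  first <- read_asc(files[[1L]])
  layers <- list(first$mat)
  for (i in seq_along(files)[-1L]) {
    g <- read_asc(files[[i]])
    if (!identical(dim(g$mat), dim(first$mat)))
      stopf("layer '%s' grid shape differs from '%s'", nm[i], nm[1])
    if (max(abs(c(g$xll - first$xll, g$yll - first$yll,
                  g$cellsize - first$cellsize))) > 1e-6)
      stopf("layer '%s' georeference differs from '%s'", nm[i], nm[1])
    layers <- c(layers, list(g$mat))
  }
  names(layers) <- nm
  raster_stack(layers, xll = first$xll, yll = first$yll,
               cellsize = first$cellsize, crs = crs)
}

#' Keep a subset of layers
#' @param stack a `raster_stack`.
#' @param keep layer names to retain.
#' @return a `raster_stack` with only the requested layers.
#' @export
subset_stack <- function(stack, keep) {
  missing <- setdiff(keep, layer_names(stack))
  if (length(missing))
    stopf("layer(s) not in stack: %s", paste(missing, collapse = ", "))
  raster_stack(stack$layers[keep], xll = stack$xll, yll = stack$yll,
               cellsize = stack$cellsize, crs = stack$crs)
}
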