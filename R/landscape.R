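#' Generate a synthetic footprint landscape with a protected-area mask
#'
#' Builds a smooth, spatially autocorrelated human-footprint field as a
#' west-to-east base gradient plus a sum of seeded Gaussian bumps, affinely
#' rescaled to `value_range`, on a regular grid of square cells. The
#' protected-area ("park") mask covers the `park_fraction` lowest-footprint
#' cells, emulating a strictly protected park adjoining higher-footprint
#' buffer zones. This is a synthetic stand-in for a real footprint raster:
#' only the value range, resolution and park/non-park contrast are emulated.
#'
#' @param seed integer seed; identical seeds give bit-identical grids.
#' @param n_cells_x,n_cells_y grid dimensions (`>= 2`).
#' @param value_range length-2 numeric, min < max (default `c(2, 16)`).
#' @param park_fraction fraction of cells in the park mask, in (0, 1).
#' @param cell_size cell edge length in km (default 1).
#' @param n_bumps number of Gaussian bumps; bump width is drawn relative to
#'   the grid extent and controls the roughness of the field.
#' @param origin_x,origin_y planar coordinates (km) of the grid's lower-left
#'   corner.
#' @return an object of class `ms_landscape`: list with `origin_x`,
#'   `origin_y`, `cell_size`, `footprint` (matrix, rows = y from south),
#'   `park_mask` (logical matrix), `value_range`, `seed`.
#' @export
#' @examples
#' ls <- make_landscape(1, 40, 40)
#' range(ls$footprint)
make_landscape <- function(seed, n_cells_x, n_cells_y,
                           value_range = c(2, 16), park_fraction = 0.5,
                           cell_size = 1, n_bumps = 25,
                           origin_x = 0, origin_y = 0) {
  if (n_cells_x < 2 || n_cells_y < 2) abort("grid must be at least 2 x 2.")
  if (length(value_range) != 2 || value_range[1] >= value_range[2])
    abort("`value_range` must be an increasing pair.")
  if (park_fraction <= 0 || park_fraction >= 1)
    abort("`park_fraction` must be in (0, 1).")
  if (cell_size <= 0) abort("`cell_size` must be positive.")

  rng <- local_rng(seed)
  cx <- seq_len(n_cells_x) - 0.5
  cy <- seq_len(n_cells_y) - 0.5
  field <- matrix(rep(cx / n_cells_x, each = n_cells_y),
                  nrow = n_cells_y, ncol = n_cells_x)
  ext <- max(n_cells_x, n_cells_y)
  bx <- runif(n_bumps, 0, n_cells_x)
  by <- runif(n_bumps, 0, n_cells_y)
  bw <- runif(n_bumps, 0.06, 0.18) * ext
  ba <- runif(n_bumps, -1, 1)
  for (b in seq_len(n_bumps)) {
    dx2 <- outer(rep(1, n_cells_y), (cx - bx[b])^2)
    dy2 <- outer((cy - by[b])^2, rep(1, n_cells_x))
    field <- field + ba[b] * exp(-(dx2 + dy2) / (2 * bw[b]^2))
  }
  rngk <- range(field)
  field <- value_range[1] +
    (field - rngk[1]) / (rngk[2] - rngk[1]) * diff(value_range)

  n_park <- round(park_fraction * length(field))
  ord <- rank(field, ties.method = "first")
  park <- matrix(ord <= n_park, nrow = n_cells_y, ncol = n_cells_x)

  structure(
    list(origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
         footprint = field, park_mask = park,
         value_range = value_range, seed = seed),
    class = "ms_landscape"
  )
}

#' @export
print.ms_landscape <- function(x, ...) {
  cat(sprintf(
    "Synthetic landscape: %d x %d cells of %.2f km, footprint in [%.2f, %.2f], %.0f%% park\n",
    ncol(x$footprint), nrow(x$footprint), x$cell_size,
    min(x$footprint), max(x$footprint),
    100 * mean(x$park_mask)))
  invisible(x)
}

# Cell indices (row = y, col = x) of planar positions; NA outside extent.
landscape_cell <- function(landscape, x, y) {
  col <- floor((x - landscape$origin_x) / landscape$cell_size) + 1
  row <- floor((y - landscape$origin_y) / landscape$cell_size) + 1
  nx <- ncol(landscape$footprint)
  ny <- nrow(landscape$footprint)
  # points exactly on the top/right edge belong to the last cell
  col[x == landscape$origin_x + nx * landscape$cell_size] <- nx
  row[y == landscape$origin_y + ny * landscape$cell_size] <- ny
  bad <- col < 1 | col > nx | row < 1 | row > ny | !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = row, col = col, outside = bad)
}

# Footprint and park values at planar positions (NA outside the extent).
landscape_lookup <- function(landscape, x, y) {
  idx <- landscape_cell(landscape, x, y)
  lin <- (idx$col - 1) * nrow(landscape$footprint) + idx$row
  list(hfi = landscape$footprint[lin],
       in_park = as.integer(landscape$park_mask[lin]),
       outside = idx$outside)
}

landscape_extent <- function(landscape) {
  c(xmin = landscape$origin_x,
    xmax = landscape$origin_x + ncol(landscape$footprint) * landscape$cell_size,
    ymin = landscape$origin_y,
    ymax = landscape$origin_y + nrow(landscape$footprint) * landscape$cell_size)
}

#' Write a landscape to ESRI ASCII grids
#'
#' Writes `<basename>_footprint.asc`, `<basename>_park.asc` (0/1) and a
#' JSON sidecar `<basename>_meta.json` holding the value range and seed.
#'
#' @param landscape an `ms_landscape`.
#' @param basename path prefix for the three output files.
#' @return the three file paths, invisibly.
#' @export
write_landscape <- function(landscape, basename) {
  dir.create(dirname(basename), recursive = TRUE, showWarnings = FALSE)
  paths <- paste0(basename, c("_footprint.asc", "_park.asc", "_meta.json"))
  write_ascii_grid(landscape$footprint, paths[1], landscape$origin_x,
                   landscape$origin_y, landscape$cell_size)
  write_ascii_grid(landscape$park_mask * 1, paths[2], landscape$origin_x,
                   landscape$origin_y, landscape$cell_size)
  jsonlite::write_json(
    list(value_range = landscape$value_range, seed = landscape$seed),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a landscape written by [write_landscape()]
#'
#' @param basename path prefix used when writing.
#' @return an `ms_landscape`.
#' @export
read_landscape <- function(basename) {
  fp <- read_ascii_grid(paste0(basename, "_footprint.asc"))
  pk <- read_ascii_grid(paste0(basename, "_park.asc"))
  meta_path <- paste0(basename, "_meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(
    list(origin_x = fp$xll, origin_y = fp$yll, cell_size = fp$cellsize,
         footprint = fp$values, park_mask = pk$values > 0.5,
         value_range = as.numeric(unlist(meta$value_range %||% range(fp$values))),
         seed = meta$seed %||% NA_integer_),
    class = "ms_landscape"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ESRI ASCII grid writer; matrix rows are y from the south, the format
# stores rows from the north.
write_ascii_grid <- function(values, path, xll, yll, cellsize) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(values)),
    sprintf("nrows %d", nrow(values)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cellsize),
    "NODATA_value -9999"
  ), con)
  for (r in rev(seq_len(nrow(values))))
    writeLines(paste(format(values[r, ], digits = 17, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]])
  nrows <- as.integer(vals[["nrows"]])
  body <- lapply(lines[7:(6 + nrows)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)
  if (ncol(m) != ncols) abort("malformed ASCII grid body.")
  m[m == vals[["nodata_value"]]] <- NA_real_
  list(values = m[rev(seq_len(nrows)), , drop = FALSE],
       xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
       cellsize = vals[["cellsize"]])
}

# Every stochastic operation takes an explicit seed and calls this first:
# one RNG stream per operation.
local_rng <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    abort("`seed` must be a single integer.")
  set.seed(as.integer(seed))
  invisible(seed)
}
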