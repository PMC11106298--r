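#' Environmental raster stack
#'
#' A minimal in-memory container for co-registered single-band layers: a
#' named list of `n_rows x n_cols` matrices sharing one rectangular grid.
#' Row 1 is the northernmost row; `NA` marks no-data cells.  Coordinates
#' are geographic degrees; cell membership uses half-open intervals
#' `[west, east) x (south, north]`.
#'
#' @param layers Named list of numeric matrices of identical dimension.
#' @param xll,yll Longitude/latitude of the lower-left corner of the grid.
#' @param cellsize Cell edge length in degrees.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, xll = 0, yll = 0, cellsize = 0.05) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("'layers' must be a non-empty named list of matrices")
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("every layer must be named")
  dims <- lapply(layers, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("all layers must share the same grid dimensions")
  structure(list(layers = layers, xll = xll, yll = yll,
                 cellsize = cellsize,
                 n_rows = nrow(layers[[1L]]), n_cols = ncol(layers[[1L]])),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layer(s), %d x %d cells, cellsize %g deg\n",
              length(x$layers), x$n_rows, x$n_cols, x$cellsize))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

# Logical matrix: TRUE where every layer has data.
env_valid_mask <- function(env) {
  m <- !is.na(env$layers[[1L]])
  for (l in env$layers[-1L]) m <- m & !is.na(l)
  m
}

# Linear cell index (column-major over the n_rows x n_cols matrix) of the
# cell containing each lon/lat point; NA for points outside the extent.
cell_from_lonlat <- function(env, lon, lat) {
  col <- floor((lon - env$xll) / env$cellsize) + 1
  row_from_bottom <- ceiling((lat - env$yll) / env$cellsize)
  row <- env$n_rows - row_from_bottom + 1
  ok <- col >= 1 & col <= env$n_cols & row >= 1 & row <= env$n_rows
  idx <- ifelse(ok, (col - 1) * env$n_rows + row, NA_real_)
  as.integer(idx)
}

# Cell-centre coordinates (lon, lat) for linear cell indices.
lonlat_from_cell <- function(env, cells) {
  row <- (cells - 1L) %% env$n_rows + 1L
  col <- (cells - 1L) %/% env$n_rows + 1L
  lon <- env$xll + (col - 0.5) * env$cellsize
  lat <- env$yll + (env$n_rows - row + 0.5) * env$cellsize
  cbind(longitude = lon, latitude = lat)
}

#' Extract predictor values at point locations
#'
#' Maps each point to its containing cell and returns that cell's value in
#' every layer.  Points outside the extent or on no-data cells are dropped
#' with a message reporting how many.
#'
#' @param env An [env_stack()].
#' @param occ Occurrence `data.frame` with `longitude`/`latitude` columns.
#' @return List with `values` (data.frame, one column per layer) and
#'   `kept` (row indices of `occ` that were retained).
#' @export
extract_env <- function(env, occ) {
  stopifnot(inherits(env, "env_stack"))
  cells <- cell_from_lonlat(env, occ$longitude, occ$latitude)
  vals <- sapply(env$layers, function(l) l[cells])
  vals <- matrix(vals, nrow = length(cells),
                 dimnames = list(NULL, names(env$layers)))
  ok <- !is.na(cells) & apply(vals, 1L, function(r) all(!is.na(r)))
  n_drop <- sum(!ok)
  if (n_drop > 0L)
    message(sprintf("dropped %d point(s) outside the extent or on no-data cells",
                    n_drop))
  list(values = as.data.frame(vals[ok, , drop = FALSE]),
       kept = which(ok))
}

#' Read a raster layer from an ESRI ASCII grid file
#'
#' @param path Path to an `.asc` file (headers `ncols`, `nrows`,
#'   `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value`).
#' @return List with `data` (matrix, row 1 = north), `xll`, `yll`,
#'   `cellsize`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  lines <- readLines(path)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1L])) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      n_hdr <- n_hdr + 1L
    } else break
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr)))
    stop(sprintf("malformed ASCII grid header in %s", path))
  vals <- scan(text = lines[-seq_len(n_hdr)], quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("%s: expected %d values, found %d", path, nr * nc,
                 length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(data = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

#' Write a raster layer as an ESRI ASCII grid file
#'
#' Values are printed with 17 significant digits so a write/read round trip
#' is value-identical.
#'
#' @param m Numeric matrix (row 1 = north); `NA` written as the no-data
#'   value.
#' @param path Output path.
#' @param xll,yll Lower-left corner coordinates.
#' @param cellsize Cell size in degrees.
#' @param nodata No-data sentinel (default -9999).
#' @export
write_ascii_grid <- function(m, path, xll = 0, yll = 0, cellsize = 0.05,
                             nodata = -9999) {
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.17g", xll), sprintf("yllcorner %.17g", yll),
           sprintf("cellsize %.17g", cellsize),
           sprintf("NODATA_value %g", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read co-registered ASCII grid layers into a stack
#'
#' @param paths Character vector of `.asc` paths; layer names are taken
#'   from the file names (extension stripped) unless `paths` is named.
#' @return An [env_stack()].  Grids that disagree in size, origin or cell
#'   size raise an error naming the offending layer.
#' @export
read_env <- function(paths) {
  if (length(paths) == 0L) stop("no raster paths given")
  nms <- names(paths)
  if (is.null(nms) || any(nms == ""))
    nms <- sub("\\.[^.]*$", "", basename(paths))
  first <- read_ascii_grid(paths[[1L]])
  layers <- stats::setNames(vector("list", length(paths)), nms)
  layers[[1L]] <- first$data
  if (length(paths) > 1L) for (i in 2:length(paths)) {
    g <- read_ascii_grid(paths[[i]])
    if (!identical(dim(g$data), dim(first$data)) ||
        g$xll != first$xll || g$yll != first$yll ||
        g$cellsize != first$cellsize)
      stop(sprintf("layer '%s' is not co-registered with '%s'",
                   nms[i], nms[1L]))
    layers[[i]] <- g$data
  }
  env_stack(layers, xll = first$xll, yll = first$yll,
            cellsize = first$cellsize)
}

#' Write every layer of a stack to a directory
#'
#' @param env An [env_stack()].
#' @param dir Output directory (created if needed); one `<name>.asc` per
#'   layer.
#' @return Invisibly, the written paths.
#' @export
write_env <- function(env, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(names(env$layers), ".asc"))
  for (i in seq_along(env$layers))
    write_ascii_grid(env$layers[[i]], paths[i], xll = env$xll, yll = env$yll,
                     cellsize = env$cellsize)
  invisible(paths)
}

#' Read an occurrence CSV
#'
#' Expects columns `species`, `longitude`, `latitude`; malformed coordinate
#' fields raise an error naming the first offending data row.
#'
#' @param path CSV path.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop(sprintf("occurrence file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "longitude", "latitude")
  if (!all(req %in% names(df)))
    stop(sprintf("occurrence CSV must have columns %s",
                 paste(req, collapse = ", ")))
  lon <- suppressWarnings(as.numeric(df$longitude))
  lat <- suppressWarnings(as.numeric(df$latitude))
  bad <- which(!is.finite(lon) | !is.finite(lat))
  if (length(bad) > 0L)
    stop(sprintf("malformed coordinates at data row %d of %s", bad[1L], path))
  occurrence_table(df$species, lon, lat)
}

#' Write an occurrence CSV
#'
#' @param occ Occurrence `data.frame`.
#' @param path Output CSV with header `species,longitude,latitude`.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ[, c("species", "longitude", "latitude")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
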