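# Raster I/O.  The primary on-disk format is the ESRI ASCII grid, a plain
# text header (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value)
# followed by rows of values, top row first.  Plain single-band TIFF is
# supported through the 'tiff' package when installed; TIFFs carry no
# georeference here, so `cell_size` must then be given explicitly.

read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing ", paste(setdiff(req, names(hdr)),
         collapse = "/"), "): ", path)
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop("ESRI ASCII grid has ", length(vals), " values, expected ", nc * nr)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(values = m, cell_size = hdr$cellsize,
       xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0)
}

write_ascii_grid <- function(values, path, cell_size, xll = 0, yll = 0,
                             nodata = -9999) {
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", format(xll, scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_raster_any <- function(path, cell_size = NULL) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    if (is.null(cell_size))
      stop("`cell_size` must be given when reading TIFF (no georeference)")
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3) {
      if (dim(m)[3] != 1) stop("expected a single-band TIFF: ", path)
      m <- m[, , 1]
    }
    list(values = m, cell_size = cell_size, xll = 0, yll = 0)
  } else {
    r <- read_ascii_grid(path)
    if (!is.null(cell_size) && !isTRUE(all.equal(cell_size, r$cell_size)))
      stop("cell_size argument (", cell_size, ") contradicts file header (",
           r$cell_size, ")")
    r
  }
}

#' Read a categorical land-use raster
#'
#' Reads an ESRI ASCII grid (`.asc`/`.txt`) or a plain single-band integer
#' TIFF.  Cells whose code is absent from `class_table` are masked with a
#' warning reporting the count.
#'
#' @param path Path to the raster file.
#' @param class_table Class scheme (see [cma_classes()]).
#' @param cell_size Cell size in meters; required for TIFF, optional
#'   cross-check for ASCII grids.
#' @param epoch Epoch label attached to the grid.
#' @return A [land_use_grid()].
#' @export
read_landuse <- function(path, class_table = cma_classes(),
                         cell_size = NULL, epoch = NULL) {
  r <- read_raster_any(path, cell_size)
  v <- r$values
  if (any(abs(v - round(v)) > 1e-9, na.rm = TRUE))
    stop("land-use raster has non-integer values: ", path)
  if (is.null(epoch))
    epoch <- sub("\\.[A-Za-z]+$", "", basename(path))
  land_use_grid(round(v), r$cell_size, class_table, epoch,
                xll = r$xll, yll = r$yll)
}

#' Write a land-use grid as an ESRI ASCII grid
#'
#' @param grid A [land_use_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landuse <- function(grid, path) {
  write_ascii_grid(grid$values, path, grid$cell_size, grid$xll, grid$yll)
}

#' Read a stack of continuous driver rasters
#'
#' @param paths Named character vector of raster paths (names become layer
#'   names).
#' @param grid The [land_use_grid()] the drivers must align to; the grid's
#'   mask is imposed on every layer.
#' @return A [driver_stack()].
#' @export
read_drivers <- function(paths, grid) {
  if (is.null(names(paths))) stop("`paths` must be a named vector")
  layers <- lapply(paths, function(p) {
    r <- read_raster_any(p, cell_size = grid$cell_size)
    if (!identical(dim(r$values), dim(grid$values)))
      stop("driver raster not aligned to grid: ", p)
    r$values
  })
  driver_stack(layers, grid)
}

#' Write a continuous raster as an ESRI ASCII grid
#'
#' @param values Numeric matrix (`NA` = nodata).
#' @param path Output path.
#' @param cell_size Cell size in meters.
#' @param xll,yll Lower-left corner coordinates.
#' @return `path`, invisibly.
#' @export
write_raster <- function(values, path, cell_size, xll = 0, yll = 0) {
  write_ascii_grid(values, path, cell_size, xll, yll)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
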