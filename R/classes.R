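#' Default land-use class scheme
#'
#' The six-class scheme used throughout: 1 cultivated land, 2 forest land,
#' 3 orchard, 4 grassland, 5 water area, 6 construction land.  The
#' vulnerability column ranks how sensitive each class's ecosystem is to
#' disturbance, from 1 (construction, least sensitive once converted) to 5
#' (water, most sensitive).
#'
#' @return A data.frame with columns `code`, `name`, `vulnerability`.
#' @export
#' @examples
#' cma_classes()
cma_classes <- function() {
  data.frame(
    code = 1:6,
    name = c("cultivated", "forest", "orchard", "grassland",
             "water", "construction"),
    vulnerability = c(4L, 2L, 4L, 3L, 5L, 1L)
  )
}

#' Construct a categorical land-use grid
#'
#' @param values Integer matrix of class codes.  `NA` cells are outside the
#'   study region (nodata).  Row 1 is the top (northern) row.
#' @param cell_size Cell edge length in meters (> 0).
#' @param class_table Data.frame with columns `code`, `name`,
#'   `vulnerability` describing the class scheme.
#' @param epoch Free-text epoch label (e.g. `"2000"`).
#' @param xll,yll Coordinates of the lower-left corner (meters); used for
#'   writing ESRI ASCII headers and for unit centroids.
#' @return An object of class `land_use_grid`.
#' @export
land_use_grid <- function(values, cell_size, class_table = cma_classes(),
                          epoch = "epoch", xll = 0, yll = 0) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  stopifnot(all(c("code", "name", "vulnerability") %in% names(class_table)))
  storage.mode(values) <- "integer"
  bad <- !is.na(values) & !(values %in% class_table$code)
  if (any(bad)) {
    warning(sum(bad), " cell(s) carry codes absent from the class table; masked")
    values[bad] <- NA_integer_
  }
  if (all(is.na(values))) stop("grid is fully masked")
  structure(
    list(values = values, cell_size = cell_size,
         class_table = class_table, epoch = as.character(epoch),
         xll = xll, yll = yll),
    class = "land_use_grid"
  )
}

#' @export
print.land_use_grid <- function(x, ...) {
  cat("<land_use_grid> ", nrow(x$values), "x", ncol(x$values),
      " cells @ ", x$cell_size, " m, epoch ", x$epoch, "\n", sep = "")
  tab <- class_areas(x, units = "km2")
  cat("  area ", format(sum(tab), digits = 6), " km2 in ",
      sum(tab > 0), " classes; ", sum(is.na(x$values)),
      " masked cell(s)\n", sep = "")
  invisible(x)
}

#' Test whether two grids share shape, resolution and mask
#'
#' @param a,b `land_use_grid` objects (or driver stacks).
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    identical(is.na(a$values), is.na(b$values))
}

stop_if_misaligned <- function(a, b) {
  if (!grids_aligned(a, b))
    stop("grids are not aligned (shape, cell size and mask must match)")
  invisible(TRUE)
}

#' Per-class and total landscape area
#'
#' @param grid A `land_use_grid`.
#' @param units `"ha"`, `"km2"` or `"cells"`.
#' @return Named numeric vector over all codes in the class table (zero for
#'   absent classes).
#' @export
class_areas <- function(grid, units = c("ha", "km2", "cells")) {
  units <- match.arg(units)
  codes <- grid$class_table$code
  n <- vapply(codes, function(k) sum(grid$values == k, na.rm = TRUE), 0L)
  names(n) <- as.character(codes)
  cell_ha <- grid$cell_size^2 / 1e4
  switch(units,
         cells = as.numeric(n),
         ha    = n * cell_ha,
         km2   = n * cell_ha / 100) -> out
  names(out) <- as.character(codes)
  out
}

#' @rdname class_areas
#' @export
landscape_area <- function(grid, units = c("ha", "km2", "cells")) {
  sum(class_areas(grid, units))
}

#' Bundle continuous driver layers aligned to a land-use grid
#'
#' @param layers Named list of numeric matrices, all with the shape of
#'   `grid` and finite on every unmasked cell.
#' @param grid The `land_use_grid` the layers are aligned to.
#' @return An object of class `driver_stack`.
#' @export
driver_stack <- function(layers, grid) {
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("all driver layers must be named")
  msk <- is.na(grid$values)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!is.matrix(l) || !identical(dim(l), dim(grid$values)))
      stop("driver '", nm, "' is not aligned to the grid")
    if (any(!is.finite(l[!msk])))
      stop("driver '", nm, "' has non-finite values on unmasked cells")
  }
  structure(list(layers = layers, cell_size = grid$cell_size,
                 values = grid$values),  # values only carry the mask
            class = "driver_stack")
}

#' @export
print.driver_stack <- function(x, ...) {
  cat("<driver_stack> ", length(x$layers), " layer(s): ",
      paste(names(x$layers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# driver values of unmasked cells as a data.frame (cells in column-major order)
driver_frame <- function(drivers, cells = NULL) {
  msk <- is.na(drivers$values)
  if (is.null(cells)) cells <- which(!msk)
  as.data.frame(lapply(drivers$layers, function(l) l[cells]))
}
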