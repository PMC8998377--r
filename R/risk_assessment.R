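# Evaluation units, per-unit ERI, and the risk surface pipeline.
#
# Units are squares of `side_km` snapped to whole cells, tiling the grid's
# bounding box from the top-left corner.  Units whose in-mask fraction
# falls below `min_inside_fraction` are dropped (edge handling).

#' Tile the landscape into square evaluation units
#'
#' @param grid A [land_use_grid()].
#' @param side_km Unit edge length in km; snapped to a whole number of
#'   cells (at least one).
#' @param min_inside_fraction Minimum fraction of a unit's cells inside
#'   the mask for the unit to be retained (default 0.5).
#' @return A data.frame of class `eval_units` with one row per retained
#'   unit: `id`, `row0`, `row1`, `col0`, `col1` (cell bounds), `x`, `y`
#'   (centroid, meters, origin at the grid's lower-left corner),
#'   `area_ha` (in-mask area), `inside_frac`.
#' @export
make_units <- function(grid, side_km = 3, min_inside_fraction = 0.5) {
  if (side_km <= 0) stop("side_km must be positive")
  cs <- grid$cell_size
  n_cells <- max(1L, as.integer(round(side_km * 1000 / cs)))
  if (side_km * 1000 < cs)
    stop("unit side smaller than one cell")
  H <- nrow(grid$values); W <- ncol(grid$values)
  row_starts <- seq(1L, H, by = n_cells)
  col_starts <- seq(1L, W, by = n_cells)
  units <- expand.grid(row0 = row_starts, col0 = col_starts)
  units$row1 <- pmin(units$row0 + n_cells - 1L, H)
  units$col1 <- pmin(units$col0 + n_cells - 1L, W)
  cell_ha <- cs^2 / 1e4
  inside <- !is.na(grid$values)
  stats <- t(apply(units, 1, function(u) {
    sub <- inside[u["row0"]:u["row1"], u["col0"]:u["col1"], drop = FALSE]
    c(n_in = sum(sub), n_tot = length(sub))
  }))
  units$inside_frac <- stats[, "n_in"] / (n_cells^2)  # vs nominal unit size
  units$area_ha <- stats[, "n_in"] * cell_ha
  keep <- units$inside_frac >= min_inside_fraction & stats[, "n_in"] > 0
  units <- units[keep, , drop = FALSE]
  # centroids in meters, y measured from the bottom edge (row H bottom)
  units$x <- grid$xll + ((units$col0 + units$col1) / 2 - 0.5) * cs
  units$y <- grid$yll + (H - (units$row0 + units$row1) / 2 + 0.5) * cs
  units$id <- seq_len(nrow(units))
  rownames(units) <- NULL
  units <- units[, c("id", "row0", "row1", "col0", "col1",
                     "x", "y", "area_ha", "inside_frac")]
  message(nrow(units), " evaluation unit(s) retained (",
          n_cells, "x", n_cells, " cells each)")
  class(units) <- c("eval_units", "data.frame")
  units
}

unit_scope <- function(grid, unit) {
  sc <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  sc[unit$row0:unit$row1, unit$col0:unit$col1] <- TRUE
  sc
}

#' Per-unit ecological risk index
#'
#' `ERI_k = sum_i (A_ki / A_k) * R_i`: the area-weighted sum over classes
#' of the loss index, within each evaluation unit.  Two metric scopes are
#' supported: `"landscape"` takes one global loss index per class (the
#' whole-landscape metric table); `"unit"` recomputes fragmentation,
#' separation and fractal dimension inside each unit (vulnerability stays
#' global).
#'
#' @param grid A [land_use_grid()].
#' @param units An [make_units()] table.
#' @param weights A [metric_weights()] object.
#' @param mode `"unit"` (default, for mapping spatial heterogeneity) or
#'   `"landscape"`.
#' @param v_method Vulnerability normalization passed to [metric_table()].
#' @param connectivity Patch connectivity.
#' @return `units` with an added `eri` column.
#' @export
unit_eri <- function(grid, units, weights = metric_weights(),
                     mode = c("unit", "landscape"),
                     v_method = "sum", connectivity = 8) {
  mode <- match.arg(mode)
  codes <- grid$class_table$code
  cell_ha <- grid$cell_size^2 / 1e4
  if (mode == "landscape") {
    mt <- metric_table(grid, weights, connectivity = connectivity,
                       v_method = v_method)
    R_global <- mt$R
    names(R_global) <- as.character(mt$code)
  }
  eri <- vapply(seq_len(nrow(units)), function(j) {
    u <- units[j, ]
    sub <- grid$values[u$row0:u$row1, u$col0:u$col1]
    cnt <- vapply(codes, function(k) sum(sub == k, na.rm = TRUE), 0L)
    A_k <- sum(cnt) * cell_ha
    if (A_k == 0) return(NA_real_)
    if (mode == "landscape") {
      R <- R_global[as.character(codes)]
    } else {
      mtu <- metric_table(grid, weights, scope = unit_scope(grid, u),
                          connectivity = connectivity, v_method = v_method,
                          scope_label = paste0("unit_", u$id))
      R <- mtu$R
    }
    present <- cnt > 0 & !is.na(R)
    if (any(cnt > 0 & is.na(R)))
      stop("loss index missing for class(es) present in unit ", u$id)
    sum((cnt[present] * cell_ha / A_k) * R[present])
  }, 0)
  units$eri <- eri
  units
}

#' Grade-area table across epochs
#'
#' Per-grade areas (km\eqn{^2}) for one or more aligned grade maps and the
#' epoch-to-epoch differences (which sum to zero).
#'
#' @param grade_maps Named list of integer grade matrices (same shape,
#'   `NA` off-mask); names are epoch labels.
#' @param cell_size Cell size in meters.
#' @param n_classes Number of grades.
#' @return A data.frame: one row per grade, one column per epoch, plus
#'   `delta_<a>_<b>` columns for consecutive epoch pairs.
#' @export
grade_area_table <- function(grade_maps, cell_size, n_classes = 5) {
  if (is.null(names(grade_maps)))
    names(grade_maps) <- paste0("epoch", seq_along(grade_maps))
  d <- dim(grade_maps[[1]])
  for (m in grade_maps) if (!identical(dim(m), d)) stop("misaligned grade maps")
  cell_km2 <- cell_size^2 / 1e6
  out <- data.frame(grade = seq_len(n_classes))
  for (nm in names(grade_maps)) {
    out[[nm]] <- vapply(seq_len(n_classes), function(g)
      sum(grade_maps[[nm]] == g, na.rm = TRUE) * cell_km2, 0)
  }
  nms <- names(grade_maps)
  if (length(nms) > 1) {
    for (j in seq_len(length(nms) - 1)) {
      out[[paste0("delta_", nms[j], "_", nms[j + 1])]] <-
        out[[nms[j + 1]]] - out[[nms[j]]]
    }
  }
  out
}

#' Compute a full risk surface for one epoch
#'
#' Pipeline: [make_units()] (unless given), [unit_eri()], ordinary kriging
#' of the unit values to the cell grid ([krige_surface()]), and five-grade
#' classification by Jenks natural breaks ([classify_risk()]).
#'
#' @param grid A [land_use_grid()].
#' @param weights A [metric_weights()] object.
#' @param side_km Evaluation-unit edge length (km).
#' @param mode Metric scope for [unit_eri()].
#' @param units Optional precomputed [make_units()] table (reused across
#'   epochs so surfaces stay comparable).
#' @param n_classes Number of risk grades (default 5).
#' @param breaks Optional frozen breakpoints (length `n_classes - 1`);
#'   `NULL` recomputes Jenks breaks from the interpolated field.
#' @param variogram Variogram options passed to [krige_surface()].
#' @param min_inside_fraction Passed to [make_units()].
#' @param v_method Vulnerability normalization.
#' @return An object of class `risk_surface`: list with `units` (with
#'   `eri`), `field` (interpolated matrix), `grade_map`, `breaks`,
#'   `grade_areas_km2`, `cell_size`, `epoch`.
#' @export
risk_surface <- function(grid, weights = metric_weights(), side_km = 3,
                         mode = "unit", units = NULL, n_classes = 5,
                         breaks = NULL, variogram = list(),
                         min_inside_fraction = 0.5, v_method = "sum") {
  if (is.null(units))
    units <- make_units(grid, side_km, min_inside_fraction)
  units <- unit_eri(grid, units, weights, mode = mode, v_method = v_method)
  field <- do.call(krige_surface,
                   c(list(x = units$x, y = units$y, z = units$eri,
                          grid = grid), variogram))
  cls <- classify_risk(field[!is.na(field)], n_classes, breaks)
  grade_map <- matrix(NA_integer_, nrow(field), ncol(field))
  grade_map[!is.na(field)] <- cls$classes
  ga <- vapply(seq_len(n_classes), function(g)
    sum(grade_map == g, na.rm = TRUE) * grid$cell_size^2 / 1e6, 0)
  structure(list(units = units, field = field, grade_map = grade_map,
                 breaks = cls$breaks, grade_areas_km2 = ga,
                 cell_size = grid$cell_size, epoch = grid$epoch),
            class = "risk_surface")
}

#' @export
print.risk_surface <- function(x, ...) {
  cat("<risk_surface> epoch ", x$epoch, ": ", nrow(x$units),
      " units, ERI ", format(min(x$units$eri, na.rm = TRUE), digits = 4),
      "-", format(max(x$units$eri, na.rm = TRUE), digits = 4), "\n",
      "  breaks: ", paste(format(x$breaks, digits = 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
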