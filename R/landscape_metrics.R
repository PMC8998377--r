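# Per-class landscape pattern indices and their combination into
# disturbance and loss indices.
#
# Conventions that matter for the numbers:
#  * fragmentation and separation use areas in hectares (the published CMA
#    reference values only reproduce under hectares);
#  * the fractal dimension uses class-total perimeter in meters and
#    class-total area in square meters;
#  * metrics of an absent class are NA (absent), never 0 — a zero
#    disturbance would silently lower downstream risk.

#' Metric weights for the disturbance index
#'
#' @param a,b,c Non-negative weights for fragmentation, separation and
#'   fractal dimension; must sum to 1.  Defaults 0.5/0.3/0.2.
#' @return A named list of class `metric_weights`.
#' @export
metric_weights <- function(a = 0.5, b = 0.3, c = 0.2) {
  if (any(c(a, b, c) < 0) || abs(a + b + c - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  structure(list(a = a, b = b, c = c), class = "metric_weights")
}

#' Landscape fragmentation index
#'
#' Patches per hectare of a class: `C_i = n_i / A_i`.  Higher values mean
#' more broken-up cover and lower ecosystem stability.
#'
#' @param n_i Patch count.
#' @param area_ha Class area in hectares.
#' @return `n_i / area_ha`, or `NA` where the class is absent
#'   (`area_ha == 0`).
#' @export
fragmentation <- function(n_i, area_ha) {
  ifelse(area_ha > 0, n_i / area_ha, NA_real_)
}

#' Landscape separation index
#'
#' `N_i = (1/2) * sqrt(n_i / A) * (A / A_i)` with all areas in hectares:
#' the spatial dispersion of a class's patches across the landscape.
#'
#' @param n_i Patch count.
#' @param area_ha Class area (hectares).
#' @param total_ha Total landscape area (hectares).
#' @return Separation index, `NA` for absent classes.
#' @export
separation <- function(n_i, area_ha, total_ha) {
  if (any(total_ha < area_ha)) stop("total area smaller than class area")
  ifelse(area_ha > 0,
         0.5 * sqrt(n_i / total_ha) * (total_ha / area_ha),
         NA_real_)
}

#' Landscape fractal dimension
#'
#' `F_i = 2 * ln(P_i / 4) / ln(A_i)` with the class-total perimeter `P_i`
#' in meters and class-total area `A_i` in square meters.  Values are
#' clipped to the theoretical range \[1, 2\] with a warning.
#'
#' @param perimeter_m Class perimeter (meters).
#' @param area_m2 Class area (square meters).
#' @return Fractal dimension in \[1, 2\]; `NA` for degenerate classes
#'   (`P <= 4` or `A <= 1`).
#' @export
fractal_dimension <- function(perimeter_m, area_m2) {
  out <- ifelse(perimeter_m > 4 & area_m2 > 1,
                2 * log(perimeter_m / 4) / log(area_m2),
                NA_real_)
  bad <- !is.na(out) & (out < 1 | out > 2)
  if (any(bad)) {
    warning(sum(bad), " fractal dimension value(s) outside [1,2]; clipped")
    out <- pmin(pmax(out, 1), 2)
  }
  out
}

#' Normalized landscape vulnerability
#'
#' Converts integer vulnerability ranks (1 = least to 5 = most sensitive)
#' into normalized weights.  `"sum"` divides each rank by the rank total
#' (weights sum to 1); `"max"` divides by the maximum rank.
#'
#' @param levels Named integer vector of ranks (names = class codes or
#'   names), or a class table with a `vulnerability` column.
#' @param method `"sum"` (default) or `"max"`.
#' @return Named numeric vector of vulnerability weights.
#' @export
#' @examples
#' vulnerability(cma_classes())
vulnerability <- function(levels, method = c("sum", "max")) {
  method <- match.arg(method)
  if (is.data.frame(levels)) {
    v <- levels$vulnerability
    names(v) <- as.character(levels$code)
    levels <- v
  }
  if (any(is.na(levels))) stop("missing vulnerability rank")
  if (any(levels < 1 | levels > 5)) stop("ranks must be within 1-5")
  switch(method,
         sum = levels / sum(levels),
         max = levels / max(levels))
}

#' Landscape disturbance index
#'
#' Weighted combination `E_i = a*C_i + b*N_i + c*F_i` of fragmentation,
#' separation and fractal dimension.
#'
#' @param C_i,N_i,F_i Component indices.
#' @param weights A [metric_weights()] object.
#' @return Disturbance index.
#' @export
disturbance <- function(C_i, N_i, F_i, weights = metric_weights()) {
  stopifnot(inherits(weights, "metric_weights"))
  weights$a * C_i + weights$b * N_i + weights$c * F_i
}

#' Landscape loss index
#'
#' `R_i = E_i * V_i`: the per-class contribution to ecological risk.
#'
#' @param E_i Disturbance index.
#' @param V_i Normalized vulnerability.
#' @return Loss index.
#' @export
loss_index <- function(E_i, V_i) {
  if (any(E_i < 0, na.rm = TRUE) || any(V_i < 0, na.rm = TRUE))
    stop("E_i and V_i must be non-negative")
  E_i * V_i
}

#' Full per-class metric table
#'
#' Computes, for every class within the given scope, patch statistics and
#' the indices `C_i`, `N_i`, `F_i`, `V_i`, `E_i`, `R_i`.  Classes absent
#' from the scope carry `NA` metrics and contribute nothing downstream.
#'
#' @param grid A [land_use_grid()].
#' @param weights A [metric_weights()] object.
#' @param scope Optional logical matrix (TRUE = inside scope); cells
#'   outside the scope are treated as masked.  `NULL` = whole landscape.
#' @param connectivity Patch connectivity, 8 or 4.
#' @param v_method Vulnerability normalization, `"sum"` or `"max"`.
#' @param scope_label Label stored with the table.
#' @return A data.frame of class `metric_table` with one row per class:
#'   `code`, `name`, `n`, `area_ha`, `perimeter_m`, `C`, `N`, `F`, `V`,
#'   `E`, `R`, `epoch`, `scope`.
#' @export
metric_table <- function(grid, weights = metric_weights(), scope = NULL,
                         connectivity = 8, v_method = c("sum", "max"),
                         scope_label = "landscape") {
  v_method <- match.arg(v_method)
  if (!is.null(scope)) {
    stopifnot(identical(dim(scope), dim(grid$values)))
    vals <- grid$values
    vals[!scope] <- NA_integer_
    if (all(is.na(vals))) stop("empty scope")
    grid <- land_use_grid(vals, grid$cell_size, grid$class_table,
                          grid$epoch, grid$xll, grid$yll)
  }
  ps <- extract_patches(grid, connectivity)
  tab <- ps$table
  A <- ps$total_area_ha
  tab$C <- fragmentation(tab$n, tab$area_ha)
  tab$N <- separation(tab$n, tab$area_ha, A)
  tab$F <- fractal_dimension(tab$perimeter_m, tab$area_ha * 1e4)
  tab$V <- as.numeric(vulnerability(grid$class_table, v_method))
  tab$E <- disturbance(tab$C, tab$N, tab$F, weights)
  tab$R <- ifelse(is.na(tab$E), NA_real_, loss_index(tab$E, tab$V))
  tab$epoch <- grid$epoch
  tab$scope <- scope_label
  class(tab) <- c("metric_table", "data.frame")
  tab
}

#' Whole-landscape ecological risk index
#'
#' Area-weighted sum of class loss indices over one scope:
#' `ERI = sum_i (A_i / A) * R_i`, the single-unit collapse of the unit ERI.
#'
#' @param mt A [metric_table()].
#' @return Numeric scalar.
#' @export
eri_landscape <- function(mt) {
  present <- !is.na(mt$R) & mt$area_ha > 0
  sum(mt$area_ha[present] / sum(mt$area_ha) * mt$R[present])
}
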