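# Patch delineation: connected components of equal-class cells, computed on
# the cell-adjacency graph.  Perimeters count cardinal cell edges against a
# different class, the nodata mask, or the grid boundary, in meters.

# index pairs of adjacent cells (column-major indices) for a given offset
adjacent_pairs <- function(H, W, dr, dc) {
  I <- matrix(seq_len(H * W), H, W)
  rA <- seq_len(H - abs(dr)); cA <- seq_len(W - abs(dc))
  rB <- rA + abs(dr);        cB <- cA + abs(dc)
  if (dr * dc < 0) { tmp <- cA; cA <- cB; cB <- tmp }  # anti-diagonal
  cbind(as.vector(I[rA, cA, drop = FALSE]),
        as.vector(I[rB, cB, drop = FALSE]))
}

#' Extract per-class patches (connected components)
#'
#' Labels every unmasked cell with a patch id and tallies, per class, the
#' patch count, total area (hectares) and total perimeter (meters).
#' Perimeter follows the convention that edges against the nodata mask or
#' the grid boundary count.
#'
#' @param grid A [land_use_grid()].
#' @param connectivity 8 (default; diagonal neighbors join a patch) or 4.
#' @return An object of class `patch_set`: a list with `labels` (integer
#'   matrix of patch ids, `NA` off-mask), `table` (one row per class:
#'   `code`, `name`, `n`, `area_ha`, `perimeter_m`), `cell_size`, and
#'   `total_area_ha`.
#' @export
#' @examples
#' g <- land_use_grid(matrix(2L, 3, 3), cell_size = 30)
#' extract_patches(g)$table
extract_patches <- function(grid, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  v <- grid$values
  H <- nrow(v); W <- ncol(v)
  offs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  pairs <- do.call(rbind, lapply(offs, function(o)
    adjacent_pairs(H, W, o[1], o[2])))
  same <- !is.na(v[pairs[, 1]]) & !is.na(v[pairs[, 2]]) &
    v[pairs[, 1]] == v[pairs[, 2]]
  g <- igraph::make_empty_graph(n = H * W, directed = FALSE)
  g <- igraph::add_edges(g, t(pairs[same, , drop = FALSE]))
  memb <- igraph::components(g)$membership
  unm <- which(!is.na(v))
  labels <- matrix(NA_integer_, H, W)
  labels[unm] <- match(memb[unm], unique(memb[unm]))

  # perimeter: cardinal edges against different class / mask / boundary
  pad <- function(m, dr, dc) {
    out <- matrix(NA, H, W)
    rs <- seq_len(H); cs <- seq_len(W)
    rs2 <- rs + dr; cs2 <- cs + dc
    ok_r <- rs2 >= 1 & rs2 <= H; ok_c <- cs2 >= 1 & cs2 <= W
    out[rs[ok_r], cs[ok_c]] <- m[rs2[ok_r], cs2[ok_c], drop = FALSE]
    out
  }
  edge_ct <- matrix(0L, H, W)
  for (o in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
    nb <- pad(v, o[1], o[2])
    edge_ct <- edge_ct + (!is.na(v) & (is.na(nb) | nb != v))
  }

  codes <- grid$class_table$code
  cell_ha <- grid$cell_size^2 / 1e4
  tab <- data.frame(
    code = codes,
    name = grid$class_table$name,
    n = vapply(codes, function(k) {
      cells <- unm[v[unm] == k]
      if (!length(cells)) 0L else length(unique(labels[cells]))
    }, 0L),
    area_ha = vapply(codes, function(k)
      sum(v[unm] == k) * cell_ha, 0),
    perimeter_m = vapply(codes, function(k)
      sum(edge_ct[unm][v[unm] == k]) * grid$cell_size, 0)
  )
  structure(list(labels = labels, table = tab,
                 cell_size = grid$cell_size,
                 total_area_ha = length(unm) * cell_ha),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("<patch_set> ", sum(x$table$n), " patches over ",
      format(x$total_area_ha, digits = 6), " ha\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Cross-tabulate land-use change between two epochs
#'
#' Areas (km\eqn{^2}) moving from each class of `grid_a` to each class of
#' `grid_b`.  Row sums equal the first epoch's class areas and column sums
#' the second's.  Transition codes follow the concatenated-digit convention
#' (e.g. `"23"` = forest to orchard).
#'
#' @param grid_a,grid_b Aligned [land_use_grid()] objects.
#' @return A matrix of km\eqn{^2} with class codes as dimnames and
#'   attribute `cell_km2`; see [change_table_df()] for a long form.
#' @export
crosstab_change <- function(grid_a, grid_b) {
  stop_if_misaligned(grid_a, grid_b)
  codes <- grid_a$class_table$code
  cells <- which(!is.na(grid_a$values))
  cell_km2 <- grid_a$cell_size^2 / 1e6
  tab <- table(factor(grid_a$values[cells], levels = codes),
               factor(grid_b$values[cells], levels = codes))
  m <- unclass(tab) * cell_km2
  dimnames(m) <- list(from = as.character(codes), to = as.character(codes))
  attr(m, "cell_km2") <- cell_km2
  m
}

#' Long-form change table with concatenated-digit transition codes
#'
#' @param ct A matrix from [crosstab_change()].
#' @param keep_zero Keep zero-area transitions?
#' @return A data.frame with columns `from`, `to`, `transition`
#'   (e.g. `"23"`), `area_km2`.
#' @export
change_table_df <- function(ct, keep_zero = FALSE) {
  df <- as.data.frame(as.table(ct), stringsAsFactors = FALSE)
  names(df) <- c("from", "to", "area_km2")
  df$transition <- paste0(df$from, df$to)
  df <- df[, c("from", "to", "transition", "area_km2")]
  if (!keep_zero) df <- df[df$area_km2 > 0, ]
  rownames(df) <- NULL
  df
}
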