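# Ordinary kriging with a spherical variogram.
#
# With zero nugget ordinary kriging is an exact interpolator: predicting at
# a sampled location returns that sample (used as a correctness check).
# The variogram sill and range are fitted to the binned empirical
# semivariogram by weighted least squares when not supplied.

spherical_gamma <- function(h, psill, range_, nugget = 0) {
  g <- ifelse(h >= range_, nugget + psill,
              nugget + psill * (1.5 * h / range_ - 0.5 * (h / range_)^3))
  g[h == 0] <- 0
  g
}

#' Fit a spherical variogram to point data
#'
#' @param x,y Coordinates (meters).
#' @param z Values.
#' @param n_bins Number of distance bins (to half the maximum distance).
#' @return List with `psill`, `range`, `empirical` (bin table).
#' @export
fit_variogram <- function(x, y, z, n_bins = 15) {
  n <- length(z)
  d <- as.matrix(stats::dist(cbind(x, y)))
  iu <- upper.tri(d)
  h <- d[iu]
  gam <- 0.5 * (outer(z, z, "-")^2)[iu]
  hmax <- max(h) / 2
  bins <- cut(h, breaks = seq(0, hmax, length.out = n_bins + 1),
              include.lowest = TRUE)
  emp <- data.frame(
    h = tapply(h, bins, mean),
    gamma = tapply(gam, bins, mean),
    n = as.vector(table(bins))
  )
  emp <- emp[!is.na(emp$gamma) & emp$n > 0, ]
  psill0 <- stats::var(z)
  range0 <- hmax / 2
  if (psill0 == 0 || nrow(emp) < 3)
    return(list(psill = max(psill0, .Machine$double.eps),
                range = max(range0, 1), empirical = emp))
  obj <- function(p) {
    g <- spherical_gamma(emp$h, exp(p[1]), exp(p[2]))
    sum(emp$n * (g - emp$gamma)^2)
  }
  fit <- stats::optim(log(c(psill0, range0)), obj, method = "Nelder-Mead")
  list(psill = exp(fit$par[1]), range = exp(fit$par[2]), empirical = emp)
}

#' Ordinary kriging onto a cell grid
#'
#' Interpolates point values (typically evaluation-unit ERI at unit
#' centroids) to every unmasked cell of a target grid.
#'
#' @param x,y,z Sample coordinates (meters, same origin as the grid's
#'   lower-left corner) and values.
#' @param grid A [land_use_grid()] (or any object with `values`,
#'   `cell_size`, `xll`, `yll`) defining the target cells and mask.
#' @param model Variogram model; only `"spherical"` is implemented.
#' @param nugget Nugget variance (default 0, making the interpolator
#'   exact at sample locations).
#' @param psill,range Partial sill and range; fitted from the data when
#'   `NULL`.
#' @param chunk Number of target cells per linear solve (memory control).
#' @return Numeric matrix shaped like `grid$values` (`NA` off-mask).
#' @export
krige_surface <- function(x, y, z, grid, model = "spherical", nugget = 0,
                          psill = NULL, range = NULL, chunk = 5000L) {
  if (model != "spherical") stop("only the spherical model is implemented")
  n <- length(z)
  if (n < 10) stop("kriging needs at least 10 sample points")
  if (length(x) != n || length(y) != n) stop("x, y, z lengths differ")
  if (anyDuplicated(cbind(x, y)))
    stop("duplicate sample locations make the kriging system singular")

  if (stats::var(z) == 0) {         # constant field: exact by convention
    out <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
    out[!is.na(grid$values)] <- z[1]
    return(out)
  }
  if (is.null(psill) || is.null(range)) {
    vf <- fit_variogram(x, y, z)
    if (is.null(psill)) psill <- vf$psill
    if (is.null(range)) range <- vf$range
  }

  D <- as.matrix(stats::dist(cbind(x, y)))
  G <- spherical_gamma(D, psill, range, nugget)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))  # OK system with Lagrange row

  H <- nrow(grid$values); W <- ncol(grid$values)
  cs <- grid$cell_size
  cells <- which(!is.na(grid$values))
  rows <- (cells - 1L) %% H + 1L
  cols <- (cells - 1L) %/% H + 1L
  cx <- grid$xll + (cols - 0.5) * cs
  cy <- grid$yll + (H - rows + 0.5) * cs

  out <- matrix(NA_real_, H, W)
  Ainv <- solve(A)
  for (i0 in seq(1, length(cells), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, length(cells))
    idx <- i0:i1
    dx <- outer(x, cx[idx], "-"); dy <- outer(y, cy[idx], "-")
    g0 <- spherical_gamma(sqrt(dx^2 + dy^2), psill, range, nugget)
    rhs <- rbind(g0, 1)
    w <- Ainv %*% rhs
    out[cells[idx]] <- as.vector(crossprod(w[seq_len(n), , drop = FALSE], z))
  }
  out
}
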