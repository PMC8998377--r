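test_that("unit tiling snaps to cells and honors the retention threshold", {
  g <- land_use_grid(matrix(2L, 30, 30), 30)
  suppressMessages(u <- make_units(g, side_km = 0.3,
                                   min_inside_fraction = 0))
  expect_identical(nrow(u), 9L)
  expect_true(all(u$row1 - u$row0 == 9))
  expect_equal(unique(u$area_ha), 100 * 0.09)

  # mask the right half: those units drop at threshold 0.5
  v <- matrix(2L, 30, 30); v[, 16:30] <- NA_integer_
  gm <- land_use_grid(v, 30)
  suppressMessages(um <- make_units(gm, 0.3, 0.5))
  expect_identical(nrow(um), 6L)   # middle column units are half inside

  # non-multiple side snaps to whole cells
  suppressMessages(u2 <- make_units(g, side_km = 0.25, 0))
  expect_true(all(u2$row1 - u2$row0 <= 7))
  expect_error(make_units(g, side_km = 0.02), "smaller than one cell")
})

test_that("unit ERI is the area-weighted mean of class loss indices", {
  pair <- mini_pair()
  g <- pair$epoch1
  mt <- metric_table(g)
  R <- stats::setNames(mt$R, mt$code)
  suppressMessages(u <- make_units(g, side_km = 0.3))
  ul <- unit_eri(g, u, mode = "landscape")
  # a unit entirely of one class collapses to that class's R
  sub <- vapply(seq_len(nrow(ul)), function(j) {
    s <- unique(na.omit(as.vector(
      g$values[ul$row0[j]:ul$row1[j], ul$col0[j]:ul$col1[j]])))
    if (length(s) == 1) s else NA_integer_
  }, 1L)
  pure <- which(!is.na(sub))
  expect_gt(length(pure), 0)
  for (j in pure)
    expect_equal(ul$eri[j], unname(R[as.character(sub[j])]))
  # convex combination bound for every unit
  expect_true(all(ul$eri <= max(R, na.rm = TRUE) + 1e-12))
  expect_true(all(ul$eri >= 0))
  # hand oracle: recompute one mixed unit from its composition
  j <- which(is.na(sub))[1]
  cnt <- table(factor(g$values[ul$row0[j]:ul$row1[j],
                               ul$col0[j]:ul$col1[j]], levels = 1:6))
  expect_equal(ul$eri[j],
               sum(cnt / sum(cnt) * R[as.character(1:6)], na.rm = TRUE))
})

test_that("degenerate single-unit tiling reproduces the landscape ERI", {
  g <- mini_pair()$epoch1
  suppressMessages(u <- make_units(g, side_km = 3, 0))  # one 100x100 unit
  expect_identical(nrow(u), 1L)
  ul <- unit_eri(g, u, mode = "landscape")
  expect_equal(ul$eri, eri_landscape(metric_table(g)))
  uu <- unit_eri(g, u, mode = "unit")
  expect_equal(uu$eri, ul$eri)  # unit scope == landscape scope here
})

test_that("forest-to-construction conversion raises risk when R_constr > R_forest", {
  # scattered construction fragments the unit, so the construction class
  # carries a higher loss index than intact forest there
  v <- matrix(2L, 40, 40)
  v[cbind(seq(2, 18, 4), rep(seq(2, 18, 4), each = 5))] <- 6L
  g0 <- land_use_grid(matrix(2L, 40, 40), 30)
  g1 <- land_use_grid(v, 30)
  suppressMessages(u <- make_units(g0, 0.6, 0))
  mtu <- metric_table(g1, scope = lersim:::unit_scope(g1, u[1, ]))
  expect_gt(mtu$R[mtu$code == 6], mtu$R[mtu$code == 2])  # precondition
  e0 <- unit_eri(g0, u, mode = "unit")$eri[1]
  e1 <- unit_eri(g1, u, mode = "unit")$eri[1]
  expect_gt(e1, e0)
})

test_that("ordinary kriging is exact at sample locations with zero nugget", {
  set.seed(7)
  g <- land_use_grid(matrix(2L, 50, 50), 30)
  cells <- sample(2500, 40)
  rows <- (cells - 1) %% 50 + 1; cols <- (cells - 1) %/% 50 + 1
  x <- (cols - 0.5) * 30; y <- (50 - rows + 0.5) * 30
  z <- sin(x / 300) + cos(y / 450) + rnorm(40, 0, 0.05)
  f <- krige_surface(x, y, z, g, nugget = 0)
  expect_true(all(abs(f[cbind(rows, cols)] - z) < 1e-6))
  # constants reproduce exactly everywhere
  fc <- krige_surface(x, y, rep(0.4, 40), g)
  expect_true(all(abs(fc - 0.4) < 1e-12, na.rm = TRUE))
  # a linear trend interpolates monotonically along its axis
  zl <- x / max(x)
  fl <- krige_surface(x, y, zl, g)
  colmeans <- colMeans(fl)
  expect_gt(stats::cor(seq_along(colmeans), colmeans), 0.99)
  expect_error(krige_surface(c(x, x[1]), c(y, y[1]), c(z, 1), g),
               "duplicate")
  expect_error(krige_surface(x[1:5], y[1:5], z[1:5], g), "at least 10")
})

test_that("Jenks classification finds the optimal partition", {
  cls <- classify_risk(1:5, 5)
  expect_identical(cls$classes, 1:5)
  # two well-separated clusters split between the clusters
  vals <- c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01))
  cl <- classify_risk(vals, 2)$classes
  expect_true(all(cl[1:10] == 1L) && all(cl[11:20] == 2L))
  # exhaustive-search optimum on random inputs
  set.seed(303)
  for (i in 1:6) {
    v <- round(runif(sample(8:20, 1)) * 100)
    if (length(unique(v)) < 5) next
    k <- sample(2:4, 1)
    br <- jenks_breaks(v, k)
    expect_equal(jenks_sse_of_breaks(v, br), oracle_jenks_sse(v, k),
                 tolerance = 1e-9)
  }
  expect_error(jenks_breaks(c(1, 1, 1, 2), 3), "distinct")
  expect_error(classify_risk(1:10, 5, breaks = c(1, 2)), "length")
  expect_error(classify_risk(1:10, 3, breaks = c(5, 2)), "increase")
})

test_that("grade areas are conserved and deltas cancel", {
  m1 <- matrix(sample(1:5, 100, replace = TRUE), 10, 10)
  ga <- grade_area_table(list(a = m1, b = m1), cell_size = 30)
  expect_equal(ga$delta_a_b, rep(0, 5))
  m2 <- m1
  i <- which(m1 == 1)[1]
  m2[i] <- 5L
  ga2 <- grade_area_table(list(a = m1, b = m2), cell_size = 30)
  expect_equal(sum(ga2$delta_a_b), 0)
  expect_equal(ga2$delta_a_b[1], -9e-4)
  expect_equal(ga2$delta_a_b[5], 9e-4)
  expect_error(grade_area_table(list(m1, matrix(1, 2, 2)), 30),
               "misaligned")
})

test_that("the full risk surface pipeline is consistent", {
  g <- mini_pair()$epoch1
  suppressMessages(rs <- risk_surface(g, side_km = 0.3))
  expect_s3_class(rs, "risk_surface")
  expect_equal(sum(rs$grade_areas_km2), landscape_area(g, "km2"))
  expect_identical(length(rs$breaks), 4L)
  expect_true(!is.unsorted(rs$breaks))
  # grade map consistent with breakpoints
  inside <- !is.na(rs$field)
  expect_identical(
    rs$grade_map[inside],
    findInterval(rs$field[inside], rs$breaks, left.open = TRUE) + 1L)
  # frozen published breaks are accepted
  suppressMessages(rs2 <- risk_surface(g, side_km = 0.3,
                                       breaks = cma_risk_breaks()))
  expect_equal(rs2$breaks, cma_risk_breaks())
})
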