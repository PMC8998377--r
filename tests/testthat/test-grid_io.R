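test_that("ESRI ASCII grids round-trip through read and write", {
  tmp <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(matrix(2, 3, 3), tmp, cell_size = 30)
  g <- read_landuse(tmp, epoch = "t")
  expect_s3_class(g, "land_use_grid")
  expect_identical(sum(g$values == 2L), 9L)
  expect_equal(g$cell_size, 30)

  v <- matrix(sample(c(1:6, NA), 48, replace = TRUE), 6, 8)
  if (all(is.na(v))) v[1] <- 1L
  g2 <- land_use_grid(v, 25, epoch = "rt", xll = 100, yll = 200)
  tmp2 <- withr::local_tempfile(fileext = ".asc")
  write_landuse(g2, tmp2)
  g3 <- read_landuse(tmp2)
  expect_identical(g3$values, g2$values)
  expect_equal(g3$xll, 100)
  expect_equal(g3$yll, 200)
})

test_that("unknown class codes are masked with a warning count", {
  v <- matrix(c(1, 2, 99, 2), 2, 2)
  expect_warning(g <- land_use_grid(v, 30), "1 cell")
  expect_true(is.na(g$values[which(v == 99)]))
  expect_identical(sum(is.na(g$values)), 1L)
})

test_that("malformed rasters are rejected", {
  tmp <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "cellsize 30", "1 2 3"), tmp)
  expect_error(read_landuse(tmp), "expected 4")
  tmp2 <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(matrix(1.5, 2, 2), tmp2, 30)
  expect_error(read_landuse(tmp2), "non-integer")
  expect_error(read_landuse("does/not/exist.asc"), "cannot read")
  expect_error(read_raster_any("x.tif"), "cell_size")
})

test_that("patch extraction matches the closed-form single-patch case", {
  g <- land_use_grid(matrix(2L, 3, 3), 30)
  ps <- extract_patches(g)
  row <- ps$table[ps$table$code == 2, ]
  expect_identical(row$n, 1L)
  expect_equal(row$area_ha, 0.81)
  expect_equal(row$perimeter_m, 360)
  expect_equal(ps$total_area_ha, 0.81)
})

test_that("connectivity controls whether diagonal squares join", {
  v <- matrix(9L, 5, 5)
  v[1:2, 1:2] <- 1L
  v[3:4, 3:4] <- 1L
  ct <- data.frame(code = c(1L, 9L), name = c("a", "bg"),
                   vulnerability = c(3L, 1L))
  g <- land_use_grid(v, 30, ct)
  expect_identical(extract_patches(g, 4)$table$n[1], 2L)
  expect_identical(extract_patches(g, 8)$table$n[1], 1L)

  chk <- (outer(1:4, 1:4, "+") %% 2L) + 1L  # checkerboard
  ct2 <- data.frame(code = 1:2, name = c("a", "b"),
                    vulnerability = c(1L, 2L))
  g2 <- land_use_grid(chk, 30, ct2)
  expect_identical(extract_patches(g2, 4)$table$n[1], 8L)
})

test_that("patch statistics equal the flood-fill oracle on random grids", {
  set.seed(101)
  for (i in 1:8) {
    H <- sample(4:20, 1); W <- sample(4:20, 1)
    conn <- sample(c(4, 8), 1)
    g <- random_grid(H, W, n_classes = sample(2:4, 1))
    ps <- extract_patches(g, conn)
    orc <- oracle_patches(g$values, conn, g$cell_size)
    for (k in orc$table$code) {
      got <- ps$table[ps$table$code == k, ]
      exp <- orc$table[orc$table$code == k, ]
      expect_identical(got$n, exp$n)
      expect_equal(got$area_ha, exp$area_ha)
      expect_equal(got$perimeter_m, exp$perimeter_m)
    }
  }
})

test_that("change cross-tabulation conserves area and codes transitions", {
  pair <- mini_pair()
  ct <- crosstab_change(pair$epoch1, pair$epoch2)
  expect_equal(rowSums(ct), class_areas(pair$epoch1, "km2"),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colSums(ct), class_areas(pair$epoch2, "km2"),
               tolerance = 1e-12, ignore_attr = TRUE)
  # off-diagonal mass equals the programmed change footprint
  off <- sum(ct) - sum(diag(ct))
  expect_equal(off, sum(pair$change_mask) * 30^2 / 1e6)

  ct_self <- crosstab_change(pair$epoch1, pair$epoch1)
  expect_equal(sum(ct_self) - sum(diag(ct_self)), 0)

  # single-cell toy change: 0.0009 km2 at (2,5) for 30 m cells
  v <- matrix(2L, 2, 2)
  a <- land_use_grid(v, 30, epoch = "a")
  v[1, 1] <- 5L
  b <- land_use_grid(v, 30, epoch = "b")
  ctab <- crosstab_change(a, b)
  expect_equal(ctab["2", "5"], 0.0009)
  df <- change_table_df(ctab)
  expect_true("25" %in% df$transition)

  expect_error(crosstab_change(a, land_use_grid(matrix(2L, 3, 3), 30)),
               "aligned")
})
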