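test_that("generated landscapes meet their class budgets exactly", {
  spec <- synth_spec(nrow = 60, ncol = 60, seed = 21)
  syn <- generate_landscape(spec)
  shares <- class_areas(syn$grid, "cells") / (60 * 60)
  expect_true(all(abs(shares - spec$shares) <= 0.02))
  # and the realized budgets are exact up to rounding-residual placement
  budget <- round(spec$shares * 3600)
  budget[which.max(budget)] <- budget[which.max(budget)] +
    3600 - sum(budget)
  expect_equal(unname(class_areas(syn$grid, "cells")), unname(budget))
  # drivers complete and finite
  expect_setequal(names(syn$drivers$layers),
                  c("elevation", "slope", "dist_road", "dist_river",
                    "dist_town", "population", "gdp"))
  expect_true(all(vapply(syn$drivers$layers,
                         function(l) all(is.finite(l)), TRUE)))
})

test_that("generation is deterministic per seed", {
  a <- generate_landscape(synth_spec(nrow = 40, ncol = 40, seed = 8))
  b <- generate_landscape(synth_spec(nrow = 40, ncol = 40, seed = 8))
  expect_identical(a$grid$values, b$grid$values)
  expect_equal(a$drivers$layers, b$drivers$layers)
  c <- generate_landscape(synth_spec(nrow = 40, ncol = 40, seed = 9))
  expect_false(identical(a$grid$values, c$grid$values))
})

test_that("degenerate budgets behave", {
  one <- synth_spec(nrow = 20, ncol = 20,
                    shares = c("2" = 1), patch_seeds = c("2" = 1),
                    seed = 1)
  syn <- generate_landscape(one)
  expect_true(all(syn$grid$values == 2L))
  expect_error(synth_spec(shares = c("1" = 0.5, "2" = 0.4)), "sum to 1")
})

test_that("patch structure mirrors the intended class contrast", {
  syn <- generate_landscape(synth_spec(seed = 13))
  mt <- suppressWarnings(metric_table(syn$grid))
  # forest forms the largest coherent patches (high integrity) and is
  # far less fragmented than the many-seeded cultivated/grassland cover
  present <- mt[mt$area_ha > 0, ]
  mean_patch <- present$area_ha / present$n
  expect_equal(present$code[which.max(mean_patch)], 2)
  expect_lt(present$C[present$code == 2],
            min(present$C[present$code %in% c(1, 4)]) / 2)
})

test_that("programmed change honors budget, drivers and ground truth", {
  pair <- mini_pair()
  expect_identical(nrow(pair$truth), sum(pair$change_mask))
  expect_identical(nrow(pair$truth), as.integer(sum(mini_rules()$n_cells)))
  # road-seeking conversions sit closer to roads than their source class
  d <- pair$drivers$layers$dist_road
  conv <- pair$truth[pair$truth$rule == 1, "cell"]
  src <- which(pair$epoch1$values == 2L)
  expect_lt(mean(d[conv]), mean(d[src]))
  # zero budget is the identity
  z <- generate_change(pair$epoch1, pair$drivers,
                       data.frame(from = 2, to = 6, driver = NA,
                                  coef = NA, n_cells = 0), seed = 1)
  expect_identical(z$grid$values, pair$epoch1$values)
  # infeasible rules fail loudly
  expect_error(generate_change(pair$epoch1, pair$drivers,
    data.frame(from = 6, to = 2, driver = NA, coef = NA,
               n_cells = 1e6), seed = 1), "exceeds")
  expect_error(generate_change(pair$epoch1, pair$drivers,
    data.frame(from = 5, to = 2, driver = NA, coef = NA,
               n_cells = rep(1e9, 1)), seed = 1), "exceeds|empty")
})

test_that("fragmenting forest raises the landscape risk index", {
  pair <- mini_pair()
  eri0 <- eri_landscape(metric_table(pair$epoch1))
  # pepper scattered construction through the forest interior
  frag <- generate_change(pair$epoch1, pair$drivers,
                          data.frame(from = 2, to = 6, driver = NA,
                                     coef = NA, n_cells = 300), seed = 2)
  eri1 <- eri_landscape(suppressWarnings(metric_table(frag$grid)))
  expect_gt(eri1, eri0)
})
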