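test_that("neighborhood effect is the weighted window cover ratio", {
  g <- land_use_grid(matrix(2L, 10, 10), 30)
  om <- neighborhood_effect(g, 2, 3, 1)
  expect_equal(om[5, 5], 1)           # interior of a uniform map
  expect_equal(om[1, 1], 3 / 8)       # corner sees 3 of 8 neighbors
  expect_equal(neighborhood_effect(g, 2, 3, 0)[5, 5], 0)
  # neighbors of an isolated cell see 1/8
  v <- matrix(2L, 10, 10); v[5, 5] <- 6L
  g2 <- land_use_grid(v, 30)
  om6 <- neighborhood_effect(g2, 6, 3, 1)
  expect_equal(om6[5, 6], 1 / 8)
  expect_equal(om6[4, 4], 1 / 8)
  expect_equal(om6[5, 5], 0)          # center excluded
  expect_error(neighborhood_effect(g, 2, 4), "odd")
})

test_that("inertia tracks demand gaps in the prescribed directions", {
  D <- c("1" = 1, "2" = 1, "3" = 1)
  # at demand -> exactly 1
  expect_equal(inertia_coefficient(D, c(5, -5, 0), c(0, 0, 0)),
               c("1" = 1, "2" = 1, "3" = 1))
  # widening gap: up when under-supplied, down when over-supplied
  D2 <- inertia_coefficient(D, c(5, -5, 2), c(10, -10, 1))
  expect_gt(D2[["1"]], 1)
  expect_lt(D2[["2"]], 1)
  expect_equal(D2[["3"]], 1)          # improving: unchanged
  # stalled nonzero gaps get nudged
  D3 <- inertia_coefficient(D, c(5, -5, 0), c(5, -5, 0))
  expect_gt(D3[["1"]], 1)
  expect_lt(D3[["2"]], 1)
  expect_true(all(D3 > 0))
})

test_that("overall probability follows its two branches", {
  P <- matrix(0.8, 2, 2); Om <- matrix(0.5, 2, 2); r <- matrix(0.3, 2, 2)
  expect_equal(overall_probability(P, Om, 1, r, 0.1),
               matrix(0.4, 2, 2))
  # zero seeding threshold kills spontaneous seeds
  expect_equal(overall_probability(P, matrix(0, 2, 2), 1, r, 0),
               matrix(0, 2, 2))
  # Monte-Carlo seeding frequency approaches P
  set.seed(1)
  n <- 1e5
  r <- matrix(runif(n), 1)
  op <- overall_probability(matrix(0.6, 1, n), matrix(0, 1, n), 1, r, 1)
  expect_equal(mean(op > 0), 0.6, tolerance = 0.01)
})

test_that("demand equal to current areas leaves the map unchanged", {
  pair <- mini_pair()
  h <- hindcast(pair, seed = 1)
  dem0 <- demand_from_areas(pair$epoch1, class_areas(pair$epoch1, "km2"))
  res <- cars_simulate(pair$epoch1, h$growth, dem0, seed = 1)
  expect_identical(res$grid$values, pair$epoch1$values)
  expect_identical(nrow(res$log) %||% 0L, 0L)
})

test_that("a constrained transition routes all change through it", {
  pair <- mini_pair()
  h <- hindcast(pair, seed = 2)
  cur <- class_areas(pair$epoch1, "cells")
  dem <- cur; dem[["2"]] <- dem[["2"]] - 100; dem[["6"]] <- dem[["6"]] + 100
  dem <- stats::setNames(as.integer(dem), names(cur))
  # forbid everything except 2 -> 6
  allow <- expand.grid(from = 1:6, to = 1:6)
  allow <- allow[allow$from != allow$to &
                 !(allow$from == 2 & allow$to == 6), ]
  tm <- transition_matrix(forbid = allow)
  res <- cars_simulate(pair$epoch1, h$growth, dem, tm = tm, seed = 2)
  ct <- crosstab_change(pair$epoch1, res$grid)
  off <- ct; diag(off) <- 0
  expect_equal(sum(off > 0), 1L)
  expect_equal(off["2", "6"], 100 * 0.0009, tolerance = 0.011)
  expect_true(res$converged)
})

test_that("simulation is reproducible per seed and stochastic across seeds", {
  pair <- mini_pair()
  h <- hindcast(pair, seed = 3)
  a <- cars_simulate(pair$epoch1, h$growth, h$demand, seed = 77)
  b <- cars_simulate(pair$epoch1, h$growth, h$demand, seed = 77)
  expect_identical(a$grid$values, b$grid$values)
  expect_identical(a$log, b$log)
  c <- cars_simulate(pair$epoch1, h$growth, h$demand, seed = 78)
  expect_false(identical(a$grid$values, c$grid$values))
  # same demand within tolerance regardless of seed
  tol <- max(1, round(0.001 * 1e4))
  expect_true(all(abs(c$gaps) <= tol))
  expect_true(all(abs(a$gaps) <= tol))
})

test_that("restricted cells are frozen and area is conserved", {
  pair <- mini_pair()
  h <- hindcast(pair, seed = 4)
  restr <- matrix(FALSE, 100, 100); restr[1:50, ] <- TRUE
  res <- suppressWarnings(
    cars_simulate(pair$epoch1, h$growth, h$demand, restricted = restr,
                  seed = 4))
  expect_identical(res$grid$values[restr], pair$epoch1$values[restr])
  expect_equal(landscape_area(res$grid, "cells"),
               landscape_area(pair$epoch1, "cells"))
})

test_that("threshold descent decays geometrically on stalled runs", {
  pair <- mini_pair()
  h <- hindcast(pair, seed = 5)
  res <- cars_simulate(pair$epoch1, h$growth, h$demand, seed = 5)
  lg <- res$log
  expect_true(all(diff(lg$d) >= 0))
  expect_equal(lg$tau_base, pmax(0.5^lg$d, 1e-6))
  # wherever the gap improvement fell below the step, d advanced
  imp <- c(NA, -diff(lg$total_gap))
  step <- max(1, round(0.001 * 1e4))
  adv <- diff(lg$d) == 1
  expect_true(all(adv == (imp[-1] < step)))
})

test_that("patch seeding grows the patch count of an expanding class", {
  pair <- mini_pair()
  h <- hindcast(pair, seed = 6)
  # uniform dispersed growth probability for construction
  g2 <- h$growth
  g2$prob[["6"]] <- matrix(0.5, 100, 100)
  cur <- class_areas(pair$epoch1, "cells")
  dem <- cur; dem[["2"]] <- dem[["2"]] - 150; dem[["6"]] <- dem[["6"]] + 150
  dem <- stats::setNames(as.integer(dem), names(cur))
  n0 <- extract_patches(pair$epoch1)$table
  n0 <- n0$n[n0$code == 6]
  grown <- vapply(1:5, function(sd) {
    res <- cars_simulate(pair$epoch1, g2, dem, mu = 0.1, seed = sd)
    tab <- extract_patches(res$grid)$table
    tab$n[tab$code == 6] > n0
  }, TRUE)
  expect_gte(sum(grown), 4)
})
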