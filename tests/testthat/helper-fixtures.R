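# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# 100x100 synthetic two-epoch pair with road-seeking conversion:
# forest -> construction/orchard and grassland -> construction concentrate
# near roads; a small uniform forest gain from orchard.  Change budget
# ~5% of cells, comparable to two decades of gradual land-use change.
mini_rules <- function() {
  data.frame(from = c(2, 2, 4, 3), to = c(6, 3, 6, 2),
             driver = c("dist_road", "dist_road", "dist_road", NA),
             coef = c(-4, -4, -4, NA), n_cells = c(200, 150, 80, 60))
}

mini_pair <- function(seed = 42) {
  key <- paste0("mini_", seed)
  if (is.null(.fixture_cache[[key]])) {
    syn <- generate_landscape(synth_spec(nrow = 100, ncol = 100,
                                         seed = seed))
    chg <- generate_change(syn$grid, syn$drivers, mini_rules(),
                           seed = seed)
    .fixture_cache[[key]] <- list(epoch1 = syn$grid, epoch2 = chg$grid,
                                  drivers = syn$drivers,
                                  change_mask = chg$change_mask,
                                  truth = chg$truth)
  }
  .fixture_cache[[key]]
}

# full-size (200x200) pair for the driver-recovery experiment: same
# change process as mini_pair, scaled so the 1% sampling rate yields a
# realistic sample size (~400 cells).  Not cached: each seed is used once.
recovery_pair <- function(seed) {
  syn <- generate_landscape(synth_spec(seed = seed))
  rules <- mini_rules()
  rules$n_cells <- rules$n_cells * 4L
  chg <- generate_change(syn$grid, syn$drivers, rules, seed = seed)
  list(epoch1 = syn$grid, epoch2 = chg$grid, drivers = syn$drivers,
       change_mask = chg$change_mask, truth = chg$truth)
}

# the 200x200 default-fixture pair used by the CA contract checks
cma_mini <- function(seed = 5) {
  if (is.null(.fixture_cache$cma_mini)) {
    syn <- generate_landscape(synth_spec(seed = seed))
    rules <- data.frame(
      from = c(2, 2, 4), to = c(6, 3, 6),
      driver = c("dist_town", NA, "dist_town"),
      coef = c(-3, NA, -3), n_cells = c(500, 400, 200))
    chg <- generate_change(syn$grid, syn$drivers, rules, seed = seed)
    .fixture_cache$cma_mini <- list(epoch1 = syn$grid, epoch2 = chg$grid,
                                    drivers = syn$drivers)
  }
  .fixture_cache$cma_mini
}

# LEAS + CARS hindcast of epoch 2 from a pair, with demand fixed to the
# true epoch-2 areas
hindcast <- function(pair, seed) {
  s <- expansion_samples(pair$epoch1, pair$epoch2, pair$drivers,
                         rate = 0.01, seed = seed)
  g <- suppressMessages(fit_growth_model(s, pair$drivers, seed = seed,
                                         on_empty = "zero"))
  dem <- demand_from_areas(pair$epoch2, class_areas(pair$epoch2, "km2"))
  sim <- suppressWarnings(cars_simulate(pair$epoch1, g, dem, seed = seed))
  list(growth = g, demand = dem, sim = sim)
}
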