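# CARS: cellular automaton with multi-type random patch seeding.
#
# Each iteration combines, per cell and candidate class, the learned
# growth probability, the neighborhood effect, and a self-adaptive
# inertia coefficient into an overall probability (with a Monte-Carlo
# seeding branch where the neighborhood effect is zero).  A candidate
# class is drawn per cell by roulette wheel over the overall
# probabilities; the cell converts only if the candidate's growth
# probability beats the descending threshold tau = delta^d * r1, the
# transition matrix allows the conversion, the cell is not restricted,
# and the conversion moves both classes toward their demand.  The demand
# guard makes per-class areas approach their targets monotonically and
# conserves total area by construction.
#
# The inertia coefficient is only verbally characterized in the
# literature this follows; here it is 1 while a class's absolute demand
# gap shrinks, is multiplied by the (capped) gap ratio when the gap
# widens -- upward for an under-supplied class, downward for an
# over-supplied one -- and is nudged in the same direction when the gap
# stalls.

#' Neighborhood weights for the six-class scheme
#'
#' Expansion strength from strong to weak: construction 1, forest 0.8,
#' cultivated and grassland 0.5, water 0.1.  Orchard, for which no
#' published weight exists, is set to 0.5 (between cultivated and
#' forest).
#'
#' @return Named numeric vector over class codes.
#' @export
cma_neighborhood_weights <- function() {
  c("1" = 0.5, "2" = 0.8, "3" = 0.5, "4" = 0.5, "5" = 0.1, "6" = 1)
}

#' Binary transition-permission matrix
#'
#' @param class_table Class scheme.
#' @param forbid Optional data.frame with columns `from`, `to` (class
#'   codes): conversions to forbid.  The diagonal is always allowed.
#' @return Integer matrix with 0/1 entries, class codes as dimnames.
#' @export
transition_matrix <- function(class_table = cma_classes(), forbid = NULL) {
  codes <- as.character(class_table$code)
  tm <- matrix(1L, length(codes), length(codes),
               dimnames = list(from = codes, to = codes))
  if (!is.null(forbid)) {
    for (i in seq_len(nrow(forbid))) {
      f <- as.character(forbid$from[i]); t <- as.character(forbid$to[i])
      if (f != t) tm[f, t] <- 0L
    }
  }
  diag(tm) <- 1L
  tm
}

shift_matrix <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Neighborhood effect of a class
#'
#' Cover ratio of class `class_k` in the moving window around each cell
#' (center excluded), scaled by the class's neighborhood weight:
#' `Omega = count / (window^2 - 1) * weight`, in \[0, weight\].  Masked
#' neighbors and off-grid positions count as absent.
#'
#' @param grid A [land_use_grid()].
#' @param class_k Class code.
#' @param window Odd window size >= 3 (default 3).
#' @param weight Neighborhood weight in \[0, 1\].
#' @return Numeric matrix (`NA` off-mask).
#' @export
neighborhood_effect <- function(grid, class_k, window = 3, weight = 1) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  b <- (grid$values == class_k) * 1
  b[is.na(b)] <- 0
  half <- (window - 1) / 2
  cnt <- matrix(0, nrow(b), ncol(b))
  for (dr in -half:half) for (dc in -half:half) {
    if (dr == 0 && dc == 0) next
    cnt <- cnt + shift_matrix(b, dr, dc)
  }
  out <- cnt / (window^2 - 1) * weight
  out[is.na(grid$values)] <- NA
  out
}

#' Self-adaptive inertia update
#'
#' @param D Current inertia coefficients (named by class code).
#' @param gap_prev,gap_cur Previous and current demand gaps
#'   (demand - current area, cells).
#' @param cap Cap on the per-iteration multiplier (default 2).
#' @param stall Nudge factor applied when a nonzero gap does not move.
#' @return Updated positive coefficients; exactly 1 for classes at
#'   demand.
#' @export
inertia_coefficient <- function(D, gap_prev, gap_cur, cap = 2,
                                stall = 1.05) {
  f <- rep(1, length(D))
  a_p <- abs(gap_prev); a_c <- abs(gap_cur)
  widening <- a_c > a_p
  stalled <- a_c == a_p & a_c > 0
  ratio <- ifelse(a_p > 0, pmin(a_c / a_p, cap), cap)
  f[widening & gap_cur > 0] <- ratio[widening & gap_cur > 0]
  f[widening & gap_cur < 0] <- 1 / ratio[widening & gap_cur < 0]
  f[stalled] <- ifelse(gap_cur[stalled] > 0, stall, 1 / stall)
  out <- pmin(pmax(D * f, 0.01), 100)
  out[gap_cur == 0] <- 1
  out
}

#' Overall conversion probability
#'
#' Combines growth probability `P`, neighborhood effect `Omega` and
#' inertia `D`.  Where `Omega == 0` and the Monte-Carlo draw `r < P`, a
#' patch seed may form with probability weight `P * (r * mu) * D`;
#' everywhere else the overall probability is `P * Omega * D`.
#'
#' @param P Growth probability matrix.
#' @param omega Neighborhood-effect matrix.
#' @param D Inertia coefficient (scalar, per class).
#' @param r Uniform(0,1) draw per cell (matrix).
#' @param mu Patch-seeding threshold in \[0, 1\].
#' @return Non-negative matrix.
#' @export
overall_probability <- function(P, omega, D, r, mu) {
  seeding <- !is.na(omega) & omega == 0 & r < P
  out <- P * omega * D
  out[seeding] <- (P * r * mu * D)[seeding]
  out
}

#' Convert class areas (km2) to a whole-cell demand vector
#'
#' @param grid A [land_use_grid()].
#' @param areas_km2 Named vector of target areas per class code.
#' @return Named integer vector of cells summing exactly to the number of
#'   unmasked cells (rounding residual absorbed by the largest class).
#' @export
demand_from_areas <- function(grid, areas_km2) {
  codes <- as.character(grid$class_table$code)
  if (!all(codes %in% names(areas_km2)))
    stop("areas_km2 must name every class code")
  cell_km2 <- grid$cell_size^2 / 1e6
  total <- sum(!is.na(grid$values))
  d <- round(areas_km2[codes] / cell_km2)
  d[which.max(d)] <- d[which.max(d)] + (total - sum(d))
  if (any(d < 0)) stop("infeasible demand (negative cell count)")
  stats::setNames(as.integer(d), codes)
}

#' Simulate land-use change with the patch-generating CA
#'
#' @param grid Starting [land_use_grid()].
#' @param growth A [fit_growth_model()] result (per-class probability
#'   surfaces).
#' @param demand Named integer vector of target cells per class code
#'   (see [demand_from_areas()]); must sum to the unmasked cell count.
#' @param tm Transition-permission matrix ([transition_matrix()]).
#' @param weights Neighborhood weights per class code.
#' @param restricted Optional logical matrix; TRUE cells never change.
#' @param window Neighborhood window (odd, default 3).
#' @param delta Threshold decay factor in \[0, 1\] (default 0.5).
#' @param mu Patch-seeding threshold(s), scalar or named per class
#'   (default 0.1).
#' @param step_frac Improvement step size as a fraction of landscape
#'   cells (default 0.001): when the total absolute demand gap improves
#'   by less than this in an iteration, the decay counter `d` advances.
#' @param tol_frac Demand tolerance as a fraction of landscape cells
#'   (default 0.001).
#' @param max_iter Iteration cap (default 500).
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#' @return An object of class `cars_result`: list with `grid` (final
#'   [land_use_grid()]), `log` (per-iteration data.frame: `iter`,
#'   `total_gap`, `d`, `tau_base`, `n_changes`), `converged`, `gaps`
#'   (final demand - area, cells), `seed`.
#' @export
cars_simulate <- function(grid, growth, demand, tm = transition_matrix(),
                          weights = cma_neighborhood_weights(),
                          restricted = NULL, window = 3, delta = 0.5,
                          mu = 0.1, step_frac = 0.001, tol_frac = 0.001,
                          max_iter = 500, seed = 1L) {
  codes <- as.character(grid$class_table$code)
  K <- length(codes)
  v <- grid$values
  cells <- which(!is.na(v))
  n_land <- length(cells)
  if (!all(codes %in% names(demand)))
    stop("demand must name every class code")
  demand <- demand[codes]
  if (sum(demand) != n_land)
    stop("infeasible demand: targets sum to ", sum(demand),
         " cells but the landscape has ", n_land)
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  if (length(mu) == 1) mu <- stats::setNames(rep(mu, K), codes)
  if (!all(codes %in% names(weights)))
    stop("weights must name every class code")
  if (is.null(restricted))
    restricted <- matrix(FALSE, nrow(v), ncol(v))
  set.seed(seed)

  # per-class growth probabilities at unmasked cells (cells x K)
  Pmat <- matrix(0, n_land, K, dimnames = list(NULL, codes))
  for (k in codes)
    if (!is.null(growth$prob[[k]])) Pmat[, k] <- growth$prob[[k]][cells]
  Pmat[is.na(Pmat)] <- 0
  restr <- restricted[cells]
  code_idx <- stats::setNames(seq_len(K), codes)

  cur <- vapply(codes, function(k) sum(v[cells] == k), 0L)
  gap <- demand - cur
  D <- stats::setNames(rep(1, K), codes)
  tol <- max(1L, round(tol_frac * n_land))
  step <- max(1L, round(step_frac * n_land))
  d_ct <- 0L
  log_rows <- vector("list", max_iter)
  tau_floor <- 1e-6   # keep tau positive once delta^d underflows

  for (it in seq_len(max_iter)) {
    if (all(abs(gap) <= tol)) break
    gap_prev <- gap
    total_prev <- sum(abs(gap))

    gtmp <- land_use_grid(v, grid$cell_size, grid$class_table,
                          grid$epoch, grid$xll, grid$yll)
    r <- matrix(stats::runif(length(v)), nrow(v), ncol(v))
    OP <- matrix(0, n_land, K)
    for (k in codes) {
      om <- neighborhood_effect(gtmp, as.integer(k), window, weights[[k]])
      Pk <- matrix(0, nrow(v), ncol(v)); Pk[cells] <- Pmat[, k]
      OP[, code_idx[k]] <-
        overall_probability(Pk, om, D[[k]], r, mu[[k]])[cells]
    }

    # roulette-wheel candidate class per cell
    rs <- rowSums(OP)
    u <- stats::runif(n_land) * rs
    cum <- rep(0, n_land)
    cand <- rep(NA_integer_, n_land)
    for (j in seq_len(K)) {
      cum <- cum + OP[, j]
      hit <- is.na(cand) & rs > 0 & u <= cum
      cand[hit] <- j
    }

    cur_code <- match(v[cells], as.integer(codes))
    tau <- max(delta^d_ct, tau_floor) * stats::runif(n_land, 0.9, 1.1)
    p_cand <- Pmat[cbind(seq_len(n_land), ifelse(is.na(cand), 1L, cand))]
    ok <- !is.na(cand) & cand != cur_code & !restr &
      tm[cbind(cur_code, cand)] == 1L &
      p_cand > tau &
      gap[cand] > 0 & gap[cur_code] < 0

    n_changes <- 0L
    if (any(ok)) {
      props <- which(ok)
      props <- props[sample.int(length(props))]   # random processing order
      tgt <- cand[props]; don <- cur_code[props]
      rank_t <- stats::ave(seq_along(props), tgt, FUN = seq_along)
      rank_d <- stats::ave(seq_along(props), don, FUN = seq_along)
      keep <- rank_t <= gap[tgt] & rank_d <= -gap[don]
      props <- props[keep]
      if (length(props)) {
        v[cells[props]] <- as.integer(codes)[cand[props]]
        n_changes <- length(props)
        cur <- vapply(codes, function(k) sum(v[cells] == k), 0L)
        gap <- demand - cur
      }
    }

    if (total_prev - sum(abs(gap)) < step) d_ct <- d_ct + 1L
    D <- inertia_coefficient(D, gap_prev, gap)
    log_rows[[it]] <- data.frame(iter = it, total_gap = sum(abs(gap)),
                                 d = d_ct,
                                 tau_base = max(delta^d_ct, tau_floor),
                                 n_changes = n_changes)
  }

  log_df <- do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)])
  converged <- all(abs(gap) <= tol)
  if (!converged)
    warning("CA did not meet demand within tolerance; residual gaps: ",
            paste(codes, gap, sep = "=", collapse = ", "))
  out_grid <- land_use_grid(v, grid$cell_size, grid$class_table,
                            paste0(grid$epoch, "_simulated"),
                            grid$xll, grid$yll)
  structure(list(grid = out_grid, log = log_df, converged = converged,
                 gaps = gap, seed = seed),
            class = "cars_result")
}

#' @export
print.cars_result <- function(x, ...) {
  cat("<cars_result> ", nrow(x$log), " iteration(s), ",
      if (x$converged) "converged" else "NOT converged",
      "; residual |gap| = ", sum(abs(x$gaps)), " cells\n", sep = "")
  invisible(x)
}
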