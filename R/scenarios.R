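# SDG-oriented scenario machinery: conversion-probability multipliers,
# restricted zones, and Markov demand projection.
#
# The three shipped scenarios:
#  * NDS (natural development): no constraints; demand continues the
#    observed trend.
#  * EDS (economic development, SDG 9/12): probability of converting
#    cultivated, orchard, forest, grassland and water into construction
#    land raised by 40%.
#  * EPS (ecological protection, SDG 15): probability of forest
#    converting into cultivated, orchard, water, grassland or
#    construction halved; grassland, orchard and water converting into
#    forest raised by 30%; cultivated, orchard, grassland and water
#    converting into construction reduced by 20%; rivers and lakes
#    become restricted areas.
#
# Multipliers act on the learned growth-probability surfaces (per target
# class, at cells whose current class matches the rule's source), then
# re-clip to [0, 1].  When several rules cover the same (from, to) pair,
# the default resolution is that a later rule overrides an earlier one
# ("most specific wins" when rules are ordered general to specific);
# `combine = "compose"` multiplies all matching rules instead.  Demand is
# scenario-adjusted by applying the same multipliers to the off-diagonal
# transition rates before Markov projection.

#' Build a scenario specification
#'
#' @param name Scenario name.
#' @param rules Data.frame with columns `from`, `to` (class codes) and
#'   `factor` (> 0): each row multiplies the probability of converting
#'   `from` into `to`.
#' @param restricted Class code(s) whose cells become restricted (frozen)
#'   during simulation, or `NULL`.
#' @param combine `"override"` (later rules win on overlap) or
#'   `"compose"` (multiply all matching rules).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, rules = NULL, restricted = NULL,
                          combine = c("override", "compose")) {
  combine <- match.arg(combine)
  if (!is.null(rules)) {
    stopifnot(all(c("from", "to", "factor") %in% names(rules)))
    if (any(rules$factor <= 0)) stop("rule factors must be positive")
  }
  structure(list(name = name, rules = rules, restricted = restricted,
                 combine = combine),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @export
scenario_nds <- function() scenario_spec("NDS")

#' @rdname scenario_spec
#' @export
scenario_eds <- function() {
  scenario_spec("EDS", data.frame(
    from = c(1, 3, 2, 4, 5), to = 6, factor = 1.4))
}

#' @rdname scenario_spec
#' @export
scenario_eps <- function() {
  rules <- rbind(
    data.frame(from = 2, to = c(1, 3, 5, 4, 6), factor = 0.5),
    data.frame(from = c(4, 3, 5), to = 2, factor = 1.3),
    data.frame(from = c(1, 3, 4, 5), to = 6, factor = 0.8))
  scenario_spec("EPS", rules, restricted = 5)
}

# multiplier for every (from, to) pair under a spec's resolution rule
scenario_multipliers <- function(spec, codes) {
  m <- matrix(1, length(codes), length(codes),
              dimnames = list(from = as.character(codes),
                              to = as.character(codes)))
  if (is.null(spec$rules)) return(m)
  for (i in seq_len(nrow(spec$rules))) {
    f <- as.character(spec$rules$from[i])
    t <- as.character(spec$rules$to[i])
    if (!f %in% rownames(m) || !t %in% colnames(m))
      stop("scenario rule references unknown class: ", f, " -> ", t)
    m[f, t] <- if (spec$combine == "compose")
      m[f, t] * spec$rules$factor[i] else spec$rules$factor[i]
  }
  m
}

#' Apply a scenario to growth surfaces, transition matrix and mask
#'
#' @param growth A [fit_growth_model()] result.
#' @param tm A [transition_matrix()].
#' @param spec A [scenario_spec()].
#' @param grid The current-epoch [land_use_grid()] (supplies each cell's
#'   source class and the restricted-class footprint).
#' @return List with modified `growth`, `tm` (unchanged unless rules set
#'   a factor of 0, which forbids the transition), and `restricted`
#'   logical matrix.
#' @export
apply_scenario <- function(growth, tm, spec, grid) {
  codes <- grid$class_table$code
  mult <- scenario_multipliers(spec, codes)
  g2 <- growth
  for (k in names(g2$prob)) {
    P <- g2$prob[[k]]
    fac <- mult[, k][match(grid$values, codes)]  # per-cell source factor
    fac <- matrix(fac, nrow(P), ncol(P))
    fac[is.na(fac)] <- 1
    g2$prob[[k]] <- pmin(pmax(P * fac, 0), 1)
  }
  restricted <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  if (!is.null(spec$restricted))
    restricted <- matrix(grid$values %in% spec$restricted,
                         nrow(grid$values), ncol(grid$values))
  structure(list(growth = g2, tm = tm, restricted = restricted,
                 name = spec$name), class = "scenario_inputs")
}

#' Markov projection of class demand
#'
#' Estimates the per-class transition-rate matrix from two observed
#' epochs (equal-interval assumption) and applies it `steps` times to the
#' later epoch's areas.  Total area is conserved.
#'
#' @param epoch1,epoch2 Aligned [land_use_grid()] objects.
#' @param steps Number of projection steps (default 1 = one more
#'   interval).
#' @param spec Optional [scenario_spec()]: its multipliers are applied to
#'   the off-diagonal transition rates (rows renormalized via the
#'   diagonal) before projection, so scenario policy shifts demand as
#'   well as allocation.
#' @return Named numeric vector of projected areas (km\eqn{^2}).
#' @export
markov_demand <- function(epoch1, epoch2, steps = 1, spec = NULL) {
  ct <- crosstab_change(epoch1, epoch2)
  areas1 <- rowSums(ct)
  if (any(areas1 == 0 & rowSums(ct > 0) > 0))
    stop("zero-area class with outgoing transitions")
  M <- ct / ifelse(areas1 > 0, areas1, 1)
  diag(M)[areas1 == 0] <- 1          # absent classes stay absent
  if (!is.null(spec)) {
    mult <- scenario_multipliers(spec, epoch1$class_table$code)
    off <- M * mult
    diag(off) <- 0
    rs <- rowSums(off)
    scale <- ifelse(rs > 1, 1 / rs, 1)   # keep rows stochastic
    off <- off * scale
    M <- off
    diag(M) <- 1 - rowSums(off)
  }
  areas2 <- class_areas(epoch2, "km2")
  out <- as.numeric(areas2 %*% (Reduce(`%*%`,
         replicate(steps, M, simplify = FALSE))))
  stats::setNames(out, colnames(ct))
}
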