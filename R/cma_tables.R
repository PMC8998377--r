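# Published land-use and landscape-pattern statistics for the central
# mountainous area (CMA) of Hainan Island, 2000-2018 (30 m land-use data).
# Shipped as reference inputs: they anchor the worked examples, give the
# synthetic generator realistic class proportions, and let the metric
# formulas be checked against independently published values.

#' Published CMA land-use areas, 2000-2018
#'
#' Class areas (km\eqn{^2}) of the six land-use classes in the central
#' mountainous area of Hainan Island for 2000, 2010 and 2018.
#'
#' @return A data.frame with columns `year`, `code`, `name`, `area_km2`.
#' @export
#' @examples
#' a <- cma_area_table()
#' xtabs(area_km2 ~ year + name, a)
cma_area_table <- function() {
  cls <- cma_classes()
  data.frame(
    year = rep(c(2000L, 2010L, 2018L), each = 6),
    code = rep(cls$code, 3),
    name = rep(cls$name, 3),
    area_km2 = c(599.16, 5264.29, 733.58, 440.33, 49.47, 28.57,
                 592.63, 5308.71, 716.57, 408.68, 57.41, 31.42,
                 583.70, 5286.44, 707.12, 407.00, 69.74, 61.42)
  )
}

#' Published CMA landscape pattern index table, 2000-2018
#'
#' Patch counts, class areas (hectares) and the published values of the
#' fragmentation (`C`), separation (`N`), fractal dimension (`F`) and
#' disturbance (`E`) indices for the CMA.  `n` and `area_ha` are the
#' inputs from which `C`, `N` and (given `F`) `E` can be recomputed with
#' [fragmentation()], [separation()] and [disturbance()].
#'
#' @return A data.frame with columns `name`, `year`, `n`, `area_ha`,
#'   `C`, `N`, `F`, `E`.
#' @export
cma_pattern_table <- function() {
  cls <- rep(c("cultivated", "forest", "orchard", "grassland",
               "water", "construction"), each = 3)
  data.frame(
    name = cls,
    year = rep(c(2000L, 2010L, 2018L), 6),
    n = c(1398L, 1311L, 1318L, 400L, 380L, 419L, 481L, 490L, 493L,
          1242L, 1216L, 1212L, 172L, 162L, 175L, 224L, 225L, 314L),
    area_ha = c(59916, 59263, 58370, 526429, 530871, 528644,
                73358, 71657, 70712, 44033, 40868, 40700,
                4947, 5741, 6974, 2857, 3142, 6142),
    C = c(0.0233, 0.0221, 0.0226, 0.0008, 0.0007, 0.0008,
          0.0066, 0.0068, 0.0070, 0.0282, 0.0298, 0.0298,
          0.0348, 0.0282, 0.0251, 0.0784, 0.0716, 0.0511),
    N = c(0.2632, 0.2577, 0.2623, 0.0160, 0.0155, 0.0163,
          0.1261, 0.1303, 0.1324, 0.3376, 0.3599, 0.3608,
          1.1181, 0.9351, 0.8000, 2.2092, 2.0133, 1.2168),
    F = c(1.1040, 1.1104, 1.1101, 1.0773, 1.0815, 1.0828,
          1.0901, 1.0884, 1.0906, 1.1031, 1.1043, 1.1036,
          1.1102, 1.1125, 1.1135, 1.0561, 1.0586, 1.0596),
    E = c(0.3114, 0.3104, 0.3120, 0.2206, 0.2213, 0.2219,
          0.2591, 0.2602, 0.2613, 0.3360, 0.3437, 0.3438,
          0.5748, 0.5172, 0.4752, 0.9132, 0.8515, 0.6025)
  )
}

#' Published CMA risk-grade breakpoints
#'
#' The five-grade ERI thresholds published for the CMA (lowest risk below
#' the first value, highest risk above the last).  Useful as frozen breaks
#' in [classify_risk()] when comparability across runs matters more than
#' per-run optimality.
#'
#' @return Numeric vector of 4 increasing thresholds.
#' @export
cma_risk_breaks <- function() {
  c(0.0761, 0.0906, 0.1093, 0.1315)
}
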