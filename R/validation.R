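# Map-agreement statistics and risk-surface comparison.

#' Agreement between a simulated and a reference map
#'
#' Cell-wise confusion matrix, overall accuracy (trace / total), Cohen's
#' kappa (chance agreement from marginal products), and per-class
#' producer/user accuracy.
#'
#' @param simulated,reference Aligned [land_use_grid()] objects.
#' @return An object of class `agreement_report`: list with `confusion`
#'   (cells), `overall_accuracy`, `kappa`, `per_class` (data.frame with
#'   `code`, `producer`, `user`).
#' @export
agreement <- function(simulated, reference) {
  stop_if_misaligned(simulated, reference)
  codes <- reference$class_table$code
  cells <- which(!is.na(reference$values))
  if (!length(cells)) stop("empty overlap")
  cm <- table(factor(simulated$values[cells], levels = codes),
              factor(reference$values[cells], levels = codes))
  cm <- unclass(cm)
  dimnames(cm) <- list(simulated = as.character(codes),
                       reference = as.character(codes))
  total <- sum(cm)
  oa <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-12)
    stop("kappa undefined: degenerate marginals (chance agreement = 1)")
  kappa <- (oa - pe) / (1 - pe)
  per_class <- data.frame(
    code = codes,
    producer = ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), NA),
    user = ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), NA)
  )
  structure(list(confusion = cm, overall_accuracy = oa, kappa = kappa,
                 per_class = per_class),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> OA = ", format(x$overall_accuracy, digits = 4),
      ", kappa = ", format(x$kappa, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Signed change between two risk surfaces
#'
#' @param surface_a,surface_b Aligned [risk_surface()] objects (b minus
#'   a).
#' @return List with `delta` (signed per-cell difference of the
#'   interpolated fields) and `grade_transitions` (crosstab of grades,
#'   cells).
#' @export
risk_delta_map <- function(surface_a, surface_b) {
  if (!identical(dim(surface_a$field), dim(surface_b$field)))
    stop("misaligned risk surfaces")
  delta <- surface_b$field - surface_a$field
  gt <- table(from = factor(surface_a$grade_map, levels = 1:5),
              to = factor(surface_b$grade_map, levels = 1:5))
  list(delta = delta, grade_transitions = unclass(gt))
}
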