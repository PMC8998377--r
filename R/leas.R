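# Land expansion analysis strategy (LEAS): extract where each class
# expanded between two epochs, sample expansion vs background cells, and
# fit a per-class random forest on driver covariates to obtain a growth
# probability surface.
#
# "Non-uniform" sampling is implemented as stratified sampling: every
# expansion cell of a class is an eligible positive, negatives are drawn
# uniformly from non-expansion cells, and the overall rate (default 1% of
# eligible cells) controls the sample size.

#' Cells where a class expanded between two epochs
#'
#' @param epoch1,epoch2 Aligned [land_use_grid()] objects.
#' @param class_k Class code.
#' @return Logical matrix: TRUE where `epoch2` is class `class_k` and
#'   `epoch1` is not (`NA` off-mask).
#' @export
extract_expansion <- function(epoch1, epoch2, class_k) {
  stop_if_misaligned(epoch1, epoch2)
  out <- epoch2$values == class_k & epoch1$values != class_k
  out[is.na(epoch1$values)] <- NA
  out
}

#' Sample expansion and background cells for every class
#'
#' @param epoch1,epoch2 Aligned [land_use_grid()] objects.
#' @param drivers A [driver_stack()] aligned to the grids.
#' @param rate Overall sampling rate (fraction of unmasked cells sampled
#'   per class, default 0.01), split evenly between positives and
#'   negatives where possible.
#' @param seed Integer seed for the draw.
#' @return An object of class `expansion_samples`: per class a
#'   data.frame with `label` (1 expansion / 0 background), `cell`
#'   (column-major index) and one column per driver; plus `rate` and
#'   `seed`.
#' @export
expansion_samples <- function(epoch1, epoch2, drivers, rate = 0.01,
                              seed = 1L) {
  stop_if_misaligned(epoch1, epoch2)
  set.seed(seed)
  codes <- epoch1$class_table$code
  unm <- which(!is.na(epoch1$values))
  n_target <- max(2L, round(rate * length(unm)))
  samples <- lapply(codes, function(k) {
    exp_k <- extract_expansion(epoch1, epoch2, k)
    pos_cells <- which(exp_k)          # TRUE only on unmasked cells
    neg_cells <- unm[!exp_k[unm]]
    n_pos <- min(length(pos_cells), ceiling(n_target / 2))
    n_neg <- min(length(neg_cells), n_target - n_pos)
    pos <- if (n_pos > 0) sample(pos_cells, n_pos) else integer(0)
    neg <- if (n_neg > 0) sample(neg_cells, n_neg) else integer(0)
    cells <- c(pos, neg)
    if (!length(cells)) return(NULL)
    cbind(data.frame(label = rep(c(1L, 0L), c(n_pos, n_neg)), cell = cells),
          driver_frame(drivers, cells))
  })
  names(samples) <- as.character(codes)
  structure(list(samples = samples, rate = rate, seed = seed,
                 codes = codes),
            class = "expansion_samples")
}

#' Fit per-class growth probability surfaces
#'
#' For each land-use class, a probability random forest is trained on the
#' sampled expansion/background cells and evaluated on every unmasked
#' cell, giving the development probability surface used by the cellular
#' automaton.  Driver importances (impurity) are reported per class.
#'
#' @param samples An [expansion_samples()] object.
#' @param drivers The [driver_stack()] used for sampling.
#' @param num_trees Number of trees (default 100).
#' @param seed Integer seed (forest growing and prediction are fully
#'   deterministic given the seed).
#' @param on_empty What to do for a class whose sample has a single label
#'   (no observed expansion): `"error"` (default) or `"zero"` (zero
#'   probability surface, with a message).
#' @return An object of class `growth_probability`: list with `prob`
#'   (named list of probability matrices in \[0,1\]), `importance`
#'   (data.frame class x driver) and `oob` (named out-of-bag prediction
#'   error per fitted class).
#' @export
fit_growth_model <- function(samples, drivers, num_trees = 100, seed = 1L,
                             on_empty = c("error", "zero")) {
  on_empty <- match.arg(on_empty)
  stopifnot(inherits(samples, "expansion_samples"))
  msk <- is.na(drivers$values)
  cells <- which(!msk)
  newdata <- driver_frame(drivers, cells)
  dims <- dim(drivers$values)
  prob <- list(); imp <- list(); oob <- c()
  for (k in names(samples$samples)) {
    s <- samples$samples[[k]]
    if (is.null(s) || length(unique(s$label)) < 2) {
      if (on_empty == "error")
        stop("class ", k, ": sample has a single label; cannot fit a ",
             "growth model (no observed expansion?)")
      message("class ", k, ": no observed expansion; zero growth surface")
      m <- matrix(0, dims[1], dims[2]); m[msk] <- NA
      prob[[k]] <- m
      next
    }
    dat <- s[, setdiff(names(s), "cell")]
    dat$label <- factor(dat$label, levels = c(0, 1))
    fit <- ranger::ranger(label ~ ., data = dat, num.trees = num_trees,
                          probability = TRUE, importance = "impurity",
                          seed = seed, num.threads = 1)
    p <- stats::predict(fit, data = newdata, seed = seed,
                        num.threads = 1)$predictions[, "1"]
    m <- matrix(NA_real_, dims[1], dims[2])
    m[cells] <- p
    prob[[k]] <- m
    imp[[k]] <- fit$variable.importance
    oob[k] <- fit$prediction.error
  }
  importance <- if (length(imp)) {
    data.frame(class = rep(names(imp), each = length(drivers$layers)),
               driver = rep(names(drivers$layers), length(imp)),
               importance = unlist(imp, use.names = FALSE))
  } else data.frame(class = character(), driver = character(),
                    importance = numeric())
  structure(list(prob = prob, importance = importance, oob = oob,
                 seed = seed),
            class = "growth_probability")
}

#' @export
print.growth_probability <- function(x, ...) {
  cat("<growth_probability> ", length(x$prob), " class surface(s)\n",
      sep = "")
  if (length(x$oob))
    cat("  OOB error: ",
        paste(names(x$oob), format(x$oob, digits = 3), sep = "=",
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Top-ranked driver per class
#'
#' @param growth A [fit_growth_model()] result.
#' @return Named character vector: for each fitted class, the driver with
#'   the largest importance.
#' @export
top_driver <- function(growth) {
  imp <- growth$importance
  vapply(split(imp, imp$class), function(d)
    d$driver[which.max(d$importance)], "")
}
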