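# Jenks natural breaks: the 1-D partition of sorted values into k classes
# minimizing total within-class sum of squared deviations, found exactly by
# dynamic programming (Fisher's algorithm, O(k n^2) with prefix sums).
# Inputs above `max_n` values are represented by evenly spaced order
# statistics before the DP (deterministic, order-independent).

jenks_cost_env <- function(v) {
  # prefix sums for O(1) within-class SSE of v[i..j]
  s1 <- c(0, cumsum(v))
  s2 <- c(0, cumsum(v^2))
  function(i, j) {  # vectorized over i
    n <- j - i + 1
    (s2[j + 1] - s2[i]) - (s1[j + 1] - s1[i])^2 / n
  }
}

#' Jenks natural-breaks class boundaries
#'
#' @param values Numeric vector (at least `k` distinct values).
#' @param k Number of classes.
#' @param max_n Values are thinned to at most `max_n` evenly spaced order
#'   statistics before the exact DP (the breaks of large smooth fields are
#'   insensitive to this; the full DP is used below the threshold).
#' @return Numeric vector of `k - 1` increasing breakpoints; class `g` is
#'   the interval (break\[g-1\], break\[g\]\] (lowest class closed below).
#' @export
jenks_breaks <- function(values, k = 5, max_n = 2000L) {
  v <- sort(values[!is.na(values)])
  if (length(unique(v)) < k)
    stop("need at least ", k, " distinct values for ", k, " classes")
  if (length(v) > max_n)
    v <- v[unique(round(seq(1, length(v), length.out = max_n)))]
  n <- length(v)
  cost <- jenks_cost_env(v)
  # D[c, j]: minimal SSE of v[1..j] in c classes; B[c, j]: first index of
  # the last class in that optimum
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  D[1, ] <- vapply(seq_len(n), function(j) cost(1L, j), 0)
  for (cl in 2:k) {
    for (j in cl:n) {
      i <- cl:j                       # candidate start of last class
      tot <- D[cl - 1, i - 1] + cost(i, j)
      best <- which.min(tot)
      D[cl, j] <- tot[best]
      B[cl, j] <- i[best]
    }
  }
  # backtrack break positions: break between classes = max of lower class
  brk <- numeric(k - 1)
  j <- n
  for (cl in k:2) {
    i <- B[cl, j]
    brk[cl - 1] <- v[i - 1]
    j <- i - 1L
  }
  brk
}

#' Classify values into risk grades
#'
#' Assigns each value a grade 1..`n_classes` using Jenks natural breaks
#' (or frozen breakpoints).  Grade `g` covers (break\[g-1\],
#' break\[g\]\], matching the convention that a value exactly on a
#' boundary belongs to the lower grade.
#'
#' @param values Numeric vector.
#' @param n_classes Number of grades (default 5).
#' @param breaks Optional frozen breakpoints of length `n_classes - 1`;
#'   `NULL` computes Jenks breaks from `values`.
#' @return List with `breaks` and `classes` (integer vector).
#' @export
classify_risk <- function(values, n_classes = 5, breaks = NULL) {
  if (is.null(breaks)) {
    breaks <- jenks_breaks(values, n_classes)
  } else {
    if (length(breaks) != n_classes - 1)
      stop("breaks must have length n_classes - 1")
    if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must increase")
  }
  cls <- findInterval(values, breaks, left.open = TRUE) + 1L
  cls[is.na(values)] <- NA_integer_
  list(breaks = breaks, classes = cls)
}
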