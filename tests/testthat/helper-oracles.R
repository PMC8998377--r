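# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# naive flood-fill patch delineation (stack-based) with per-class tallies
oracle_patches <- function(values, connectivity = 4, cell_size = 30) {
  H <- nrow(values); W <- ncol(values)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  lab <- matrix(NA_integer_, H, W)
  nid <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (is.na(values[r, c]) || !is.na(lab[r, c])) next
    nid <- nid + 1L
    stack <- list(c(r, c))
    lab[r, c] <- nid
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        rr <- p[1] + o[1]; cc <- p[2] + o[2]
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        if (is.na(values[rr, cc]) || !is.na(lab[rr, cc])) next
        if (values[rr, cc] != values[p[1], p[2]]) next
        lab[rr, cc] <- nid
        stack[[length(stack) + 1L]] <- c(rr, cc)
      }
    }
  }
  codes <- sort(unique(values[!is.na(values)]))
  tall <- lapply(codes, function(k) {
    cells <- which(values == k)
    per <- 0L
    for (i in cells) {
      r <- (i - 1L) %% H + 1L; c <- (i - 1L) %/% H + 1L
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr < 1 || rr > H || cc < 1 || cc > W ||
            is.na(values[rr, cc]) || values[rr, cc] != k)
          per <- per + 1L
      }
    }
    data.frame(code = k,
               n = length(unique(lab[cells])),
               area_ha = length(cells) * cell_size^2 / 1e4,
               perimeter_m = per * cell_size)
  })
  list(labels = lab, table = do.call(rbind, tall))
}

# exhaustive-search Jenks: minimal within-class SSE over all contiguous
# partitions of the sorted values
oracle_jenks_sse <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  sse <- function(x) sum((x - mean(x))^2)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, j], n)
    tot <- 0
    for (g in seq_len(k)) tot <- tot + sse(v[(cuts[g] + 1):cuts[g + 1]])
    best <- min(best, tot)
  }
  best
}

jenks_sse_of_breaks <- function(values, breaks) {
  cls <- findInterval(values, breaks, left.open = TRUE) + 1L
  sum(unlist(lapply(split(values, cls), function(x) sum((x - mean(x))^2))))
}

# random categorical grid for property tests
random_grid <- function(H, W, n_classes = 3, p_na = 0.1,
                        cell_size = 30) {
  v <- matrix(sample(seq_len(n_classes), H * W, replace = TRUE), H, W)
  v[matrix(stats::runif(H * W) < p_na, H, W)] <- NA_integer_
  if (all(is.na(v))) v[1, 1] <- 1L
  ct <- data.frame(code = seq_len(n_classes),
                   name = paste0("class", seq_len(n_classes)),
                   vulnerability = rep_len(c(3L, 1L, 5L, 2L, 4L),
                                           n_classes))
  land_use_grid(v, cell_size, ct, epoch = "random")
}

# uniform-random change allocator with the same demand (null baseline)
null_allocation <- function(grid, demand, seed) {
  set.seed(seed)
  v <- grid$values
  codes <- as.character(grid$class_table$code)
  gap <- demand[codes] -
    vapply(codes, function(k) sum(v == as.integer(k), na.rm = TRUE), 0L)
  for (k in names(gap)[gap > 0]) {
    donors <- which(!is.na(v) & v %in% as.integer(names(gap)[gap < 0]))
    v[donors[sample.int(length(donors), gap[[k]])]] <- as.integer(k)
  }
  land_use_grid(v, grid$cell_size, grid$class_table, "null_alloc",
                grid$xll, grid$yll)
}
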