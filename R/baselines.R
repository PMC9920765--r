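#' Multiclass ReliefF feature weights
#'
#' For each probe row, finds the k nearest same-class hits and, per other
#' class, the k nearest misses under Manhattan distance on features scaled
#' to `[0, 1]`; a feature's weight accumulates prior-weighted miss
#' differences minus hit differences, averaged over probes and neighbours.
#' By default every training row is a probe (deterministic exhaustive mode).
#'
#' @param data a `feature_matrix`.
#' @param k_neighbors neighbours per hit/miss set.
#' @param n_probes number of sampled probe rows; `NULL` = all rows.
#' @param seed RNG seed (used only when sampling probes).
#' @return named numeric weight vector, one per feature.
#' @export
relieff_weights <- function(data, k_neighbors = 10, n_probes = NULL,
                            seed = 1L) {
  stopifnot(inherits(data, "feature_matrix"), is_count(k_neighbors))
  x <- feature_block(data)
  y <- data$subject
  counts <- table(y)
  if (any(counts < k_neighbors + 1)) {
    stopf("every class needs >= k_neighbors + 1 = %d rows", k_neighbors + 1)
  }
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  xs <- sweep(sweep(x, 2, rng[1, ]), 2, span, `/`)

  n <- nrow(xs)
  probes <- if (is.null(n_probes) || n_probes >= n) {
    seq_len(n)
  } else {
    local_seed(seed, sample.int(n, n_probes))
  }
  priors <- counts / n
  classes <- as.integer(names(counts))
  m <- length(probes)
  k <- k_neighbors
  w <- numeric(ncol(xs))
  for (r in probes) {
    d <- rowSums(abs(sweep(xs, 2, xs[r, ])))
    d[r] <- Inf
    cy <- y[r]
    hit_idx <- which(y == cy)
    hits <- hit_idx[order(d[hit_idx])[seq_len(k)]]
    hit_diff <- colSums(abs(sweep(xs[hits, , drop = FALSE], 2, xs[r, ])))
    w <- w - hit_diff / (m * k)
    for (cls in classes[classes != cy]) {
      miss_idx <- which(y == cls)
      misses <- miss_idx[order(d[miss_idx])[seq_len(k)]]
      miss_diff <- colSums(abs(sweep(xs[misses, , drop = FALSE], 2, xs[r, ])))
      pw <- priors[[as.character(cls)]] / (1 - priors[[as.character(cy)]])
      w <- w + pw * miss_diff / (m * k)
    }
  }
  names(w) <- attr(data, "feature_names")
  w
}

#' Information gain of each feature for the class label
#'
#' Continuous features are discretized by equal-frequency binning;
#' `IG_i = H(Y) - H(Y | bin(X_i))` with Shannon entropy in bits, so
#' `0 <= IG_i <= H(Y)`.
#'
#' @param data a `feature_matrix`.
#' @param n_bins number of equal-frequency bins (>= 2).
#' @return named numeric IG vector in bits.
#' @export
info_gain <- function(data, n_bins = 10) {
  stopifnot(inherits(data, "feature_matrix"), n_bins >= 2)
  y <- data$subject
  x <- feature_block(data)
  ent <- function(labels) {
    p <- table(labels) / length(labels)
    -sum(p * log2(p))
  }
  hy <- ent(y)
  if (hy == 0) {
    warning("single-class data: all information gains are 0")
    return(stats::setNames(numeric(ncol(x)), attr(data, "feature_names")))
  }
  ig <- apply(x, 2, function(col) {
    br <- unique(stats::quantile(col, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2) return(0)
    bins <- cut(col, breaks = br, include.lowest = TRUE)
    hcond <- sum(vapply(levels(bins), function(b) {
      inb <- bins == b
      if (!any(inb)) return(0)
      mean(inb) * ent(y[inb])
    }, numeric(1)))
    max(0, hy - hcond)
  })
  stats::setNames(ig, attr(data, "feature_names"))
}

#' Indices of the k largest feature weights
#'
#' Ties break to the lower feature index.
#'
#' @param weights numeric weight vector.
#' @param k subset size (1 <= k <= length(weights)).
#' @return increasing integer vector of k feature indices.
#' @export
select_top_k <- function(weights, k) {
  stopifnot(is_count(k), k <= length(weights))
  sort(utils::head(order(-weights), k))
}
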