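#' SMOTE class balancing of a training feature matrix
#'
#' Every class is oversampled to the majority-class count. Each synthetic row
#' is `x + u * (x_nn - x)` for a real same-class row `x`, one of its `k`
#' nearest same-class neighbours `x_nn` (Euclidean distance in the feature
#' space as given, i.e. normalize first), and `u ~ Uniform(0, 1)`. Apply to
#' training rows only; held-out rows must never be parents.
#'
#' @param train a `feature_matrix` of training rows (normalized).
#' @param k number of nearest neighbours (SMOTE convention: 5).
#' @param seed RNG seed; output is deterministic given the seed.
#' @return the balanced `feature_matrix`; synthetic rows carry the parent
#'   row's `day` and `synthetic = TRUE` in attribute `synthetic_flag`, with
#'   parent row indices in attribute `smote_parents`.
#' @export
smote <- function(train, k = 5, seed = 1L) {
  stopifnot(inherits(train, "feature_matrix"), is_count(k))
  fn <- attr(train, "feature_names")
  x <- feature_block(train)
  y <- train$subject
  counts <- table(y)
  if (any(counts < k + 1)) {
    stopf("every class needs >= k+1 = %d rows (smallest has %d)",
          k + 1, min(counts))
  }
  target <- max(counts)
  new_rows <- list()
  parents <- integer(0)
  local_seed(seed, {
    for (cls in as.integer(names(counts))) {
      need <- target - counts[[as.character(cls)]]
      if (need == 0) next
      ridx <- which(y == cls)
      xc <- x[ridx, , drop = FALSE]
      d <- as.matrix(stats::dist(xc))
      diag(d) <- Inf
      nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
      pick <- ridx[(seq_len(need) - 1L) %% length(ridx) + 1L]
      for (p in pick) {
        li <- match(p, ridx)
        nb <- nn[li, sample.int(k, 1)]
        u <- stats::runif(1)
        row <- xc[li, ] + u * (xc[nb, ] - xc[li, ])
        new <- train[p, ]
        new[fn] <- as.list(row)
        new_rows[[length(new_rows) + 1L]] <- new
        parents <- c(parents, p)
      }
    }
  })
  if (length(new_rows) == 0) {
    attr(train, "synthetic_flag") <- rep(FALSE, nrow(train))
    attr(train, "smote_parents") <- integer(0)
    return(train)
  }
  out <- rbind(as.data.frame(train), do.call(rbind, new_rows))
  rownames(out) <- NULL
  structure(out, feature_names = fn,
            normalization = attr(train, "normalization"),
            synthetic_flag = c(rep(FALSE, nrow(train)),
                               rep(TRUE, length(new_rows))),
            smote_parents = parents,
            class = c("feature_matrix", "data.frame"))
}
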