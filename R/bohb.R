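#' DQN hyperparameter configuration
#'
#' One point in the tuning search space: number of hidden layers (1--4),
#' shared nodes per layer (16--64), learning rate (0.001--0.1, log scale),
#' optimizer (Adam / SGD / RMSprop) and SGD momentum (0--0.99, active only
#' when the optimizer is SGD). Defaults are the space's center defaults.
#'
#' @param n_layers,nodes_per_layer,learning_rate,optimizer,sgd_momentum see
#'   above.
#' @return object of class `hyperparam_config`.
#' @export
hyperparam_config <- function(n_layers = 2, nodes_per_layer = 32,
                              learning_rate = 0.01, optimizer = "Adam",
                              sgd_momentum = 0.9) {
  sp <- hyperparam_space()
  stopifnot(n_layers >= sp$n_layers[1], n_layers <= sp$n_layers[2],
            nodes_per_layer >= sp$nodes[1], nodes_per_layer <= sp$nodes[2],
            learning_rate >= sp$learning_rate[1],
            learning_rate <= sp$learning_rate[2],
            optimizer %in% sp$optimizers,
            sgd_momentum >= sp$momentum[1], sgd_momentum <= sp$momentum[2])
  structure(list(n_layers = as.integer(n_layers),
                 nodes_per_layer = as.integer(nodes_per_layer),
                 learning_rate = learning_rate, optimizer = optimizer,
                 sgd_momentum = sgd_momentum),
            class = "hyperparam_config")
}

#' Bounds of the DQN hyperparameter search space
#'
#' @return named list of bounds; `learning_rate` is searched on a log scale.
#' @export
hyperparam_space <- function() {
  list(n_layers = c(1L, 4L), nodes = c(16L, 64L),
       learning_rate = c(0.001, 0.1),
       optimizers = c("Adam", "SGD", "RMSprop"), momentum = c(0, 0.99))
}

#' Draw a uniform random configuration from the search space
#'
#' Integer dims uniform over their range, learning rate log-uniform,
#' optimizer uniform; momentum uniform when SGD is drawn (inactive, and set
#' to the space default, otherwise). Uses the caller's RNG stream.
#'
#' @param space bounds list as from [hyperparam_space()].
#' @return a [hyperparam_config()].
#' @export
sample_hyperparam <- function(space = hyperparam_space()) {
  opt <- space$optimizers[sample.int(length(space$optimizers), 1)]
  hyperparam_config(
    n_layers = sample(space$n_layers[1]:space$n_layers[2], 1),
    nodes_per_layer = sample(space$nodes[1]:space$nodes[2], 1),
    learning_rate = 10^stats::runif(1, log10(space$learning_rate[1]),
                                    log10(space$learning_rate[2])),
    optimizer = opt,
    sgd_momentum = if (opt == "SGD") {
      stats::runif(1, space$momentum[1], space$momentum[2])
    } else {
      0.9
    })
}

#' BOHB run configuration
#'
#' @param max_budget maximum budget R per configuration.
#' @param min_budget minimum budget (>= 1).
#' @param eta halving rate (>= 2; conventional default 3).
#' @param n_candidates candidates drawn from l(x) per TPE suggestion.
#' @param random_fraction probability of a pure-random suggestion.
#' @param good_quantile loss quantile splitting good from bad observations.
#' @return object of class `bohb_config` (includes `s_max = ceil(log_eta
#'   (R / min_budget))`).
#' @export
bohb_config <- function(max_budget = 9, min_budget = 1, eta = 3,
                        n_candidates = 24, random_fraction = 1 / 3,
                        good_quantile = 0.15) {
  stopifnot(min_budget >= 1, max_budget >= min_budget, eta >= 2)
  s_max <- as.integer(ceiling(log(max_budget / min_budget) / log(eta)))
  structure(list(max_budget = max_budget, min_budget = min_budget, eta = eta,
                 s_max = s_max, n_candidates = as.integer(n_candidates),
                 random_fraction = random_fraction,
                 good_quantile = good_quantile),
            class = "bohb_config")
}

#' Hyperband successive-halving schedule
#'
#' Bracket `s` starts `ceil((s_max + 1) * eta^s / (s + 1))` configurations at
#' budget `R * eta^(-s)` and keeps the top `1/eta` at each of `s` successive
#' rungs, multiplying the budget by `eta`; budgets never exceed R.
#'
#' @param config a [bohb_config()].
#' @return list of brackets (outermost first); each bracket is a data.frame
#'   with columns `rung`, `n_configs`, `budget`.
#' @export
hyperband_schedule <- function(config) {
  stopifnot(inherits(config, "bohb_config"))
  R <- config$max_budget
  eta <- config$eta
  lapply(config$s_max:0, function(s) {
    n0 <- ceiling((config$s_max + 1) * eta^s / (s + 1))
    b0 <- R * eta^(-s)
    data.frame(rung = 0:s,
               n_configs = floor(n0 * eta^(-(0:s))),
               budget = pmin(R, pmax(config$min_budget, b0 * eta^(0:s))))
  })
}

# flatten a hyperparam_config to a store row
hp_row <- function(hp, budget, loss, bracket, rung, id) {
  data.frame(config_id = id, n_layers = hp$n_layers,
             nodes_per_layer = hp$nodes_per_layer,
             learning_rate = hp$learning_rate, optimizer = hp$optimizer,
             sgd_momentum = hp$sgd_momentum, budget = budget, loss = loss,
             bracket = bracket, rung = rung)
}

# Gaussian KDE density at x over sample centers (Silverman bandwidth,
# floored at 10% of the dimension's span)
kde_dens <- function(x, centers, span) {
  n <- length(centers)
  bw <- max(1.06 * stats::sd(centers) * n^(-1 / 5), 0.1 * span, 1e-6)
  if (!is.finite(bw)) bw <- 0.1 * span
  mean(stats::dnorm(x, centers, bw))
}

kde_draw <- function(centers, span, lo, hi) {
  n <- length(centers)
  bw <- max(1.06 * stats::sd(centers) * n^(-1 / 5), 0.1 * span, 1e-6)
  if (!is.finite(bw)) bw <- 0.1 * span
  min(hi, max(lo, stats::rnorm(1, centers[sample.int(n, 1)], bw)))
}

#' TPE suggestion from a BOHB observation store
#'
#' Splits observations (at the highest budget with enough of them) into good
#' and bad sets at the `good_quantile` loss quantile, fits kernel density
#' estimators l(x) and g(x) (Gaussian kernels for the numeric dims, with the
#' learning rate on a log scale; smoothed frequencies for the optimizer),
#' draws `n_candidates` configurations from l and returns the one maximizing
#' the density ratio l(x)/g(x). Falls back to a uniform random configuration
#' when observations are scarce, and with probability `random_fraction`
#' regardless. Uses the caller's RNG stream.
#'
#' @param store observation data.frame as accumulated by [run_bohb()] (may
#'   be `NULL` or empty).
#' @param space bounds list from [hyperparam_space()].
#' @param config a [bohb_config()].
#' @return a [hyperparam_config()], always within bounds.
#' @export
tpe_suggest <- function(store, space = hyperparam_space(),
                        config = bohb_config()) {
  d <- 5L
  if (stats::runif(1) < config$random_fraction) return(sample_hyperparam(space))
  if (is.null(store) || nrow(store) == 0) return(sample_hyperparam(space))
  budgets <- sort(unique(store$budget), decreasing = TRUE)
  obs <- NULL
  for (b in budgets) {
    cand <- store[store$budget == b & is.finite(store$loss), , drop = FALSE]
    if (nrow(cand) >= d + 2) {
      obs <- cand
      break
    }
  }
  if (is.null(obs)) return(sample_hyperparam(space))

  obs <- obs[order(obs$loss), ]
  n_good <- max(2L, ceiling(config$good_quantile * nrow(obs)))
  if (nrow(obs) - n_good < 2) return(sample_hyperparam(space))
  good <- obs[seq_len(n_good), ]
  bad <- obs[-seq_len(n_good), ]

  num_dims <- list(
    n_layers = list(get = function(o) o$n_layers,
                    lo = space$n_layers[1], hi = space$n_layers[2],
                    int = TRUE),
    nodes_per_layer = list(get = function(o) o$nodes_per_layer,
                           lo = space$nodes[1], hi = space$nodes[2],
                           int = TRUE),
    log_lr = list(get = function(o) log10(o$learning_rate),
                  lo = log10(space$learning_rate[1]),
                  hi = log10(space$learning_rate[2]), int = FALSE)
  )
  opt_levels <- space$optimizers
  freq <- function(o) {
    (tabulate(match(o$optimizer, opt_levels), length(opt_levels)) + 1) /
      (nrow(o) + length(opt_levels))
  }
  fg <- freq(good)
  fb <- freq(bad)

  draw_candidate <- function() {
    vals <- lapply(num_dims, function(dm) {
      v <- kde_draw(dm$get(good), dm$hi - dm$lo, dm$lo, dm$hi)
      if (dm$int) round(v) else v
    })
    opt <- opt_levels[sample.int(length(opt_levels), 1, prob = fg)]
    mom <- if (opt == "SGD") {
      sgd_good <- good$sgd_momentum[good$optimizer == "SGD"]
      if (length(sgd_good) >= 2) {
        kde_draw(sgd_good, diff(space$momentum), space$momentum[1],
                 space$momentum[2])
      } else {
        stats::runif(1, space$momentum[1], space$momentum[2])
      }
    } else {
      0.9
    }
    hyperparam_config(vals$n_layers, vals$nodes_per_layer, 10^vals$log_lr,
                      opt, mom)
  }
  score <- function(hp) {
    v <- c(hp$n_layers, hp$nodes_per_layer, log10(hp$learning_rate))
    r <- 1
    for (k in seq_along(num_dims)) {
      dm <- num_dims[[k]]
      span <- dm$hi - dm$lo
      r <- r * kde_dens(v[k], dm$get(good), span) /
        max(kde_dens(v[k], dm$get(bad), span), 1e-12)
    }
    ko <- match(hp$optimizer, opt_levels)
    r <- r * fg[ko] / fb[ko]
    if (hp$optimizer == "SGD") {
      sg <- good$sgd_momentum[good$optimizer == "SGD"]
      sb <- bad$sgd_momentum[bad$optimizer == "SGD"]
      if (length(sg) >= 2 && length(sb) >= 2) {
        span <- diff(space$momentum)
        r <- r * kde_dens(hp$sgd_momentum, sg, span) /
          max(kde_dens(hp$sgd_momentum, sb, span), 1e-12)
      }
    }
    r
  }
  cands <- replicate(config$n_candidates, draw_candidate(), simplify = FALSE)
  cands[[which.max(vapply(cands, score, numeric(1)))]]
}

#' Run BOHB over an objective
#'
#' Executes every bracket and rung of the hyperband schedule, sourcing new
#' configurations from [tpe_suggest()] (seeded by the accumulating
#' observation store) and advancing the top `1/eta` of each rung by loss
#' (ties by configuration id). A configuration whose objective call errors
#' is marked failed (loss `Inf`) and the run continues. Deterministic under
#' `seed`.
#'
#' @param objective function(config, budget) -> scalar loss.
#' @param space bounds list from [hyperparam_space()].
#' @param config a [bohb_config()].
#' @param seed RNG seed.
#' @return list with `best` (a `hyperparam_config`), `best_loss`, `store`
#'   (all observations: config fields, budget, loss, bracket, rung),
#'   `total_budget` consumed.
#' @export
run_bohb <- function(objective, space = hyperparam_space(),
                     config = bohb_config(), seed = 1L) {
  sched <- hyperband_schedule(config)
  local_seed(seed, {
    store <- NULL
    configs_by_id <- list()
    next_id <- 1L
    total <- 0
    for (bi in seq_along(sched)) {
      bracket <- sched[[bi]]
      ids <- integer(0)
      for (ri in seq_len(nrow(bracket))) {
        n_i <- bracket$n_configs[ri]
        b_i <- bracket$budget[ri]
        if (ri == 1L) {
          ids <- vapply(seq_len(n_i), function(j) {
            hp <- tpe_suggest(store, space, config)
            configs_by_id[[next_id]] <<- hp
            id <- next_id
            next_id <<- next_id + 1L
            id
          }, integer(1))
        } else {
          prev <- store[store$bracket == bi & store$rung == ri - 2L, ]
          prev <- prev[order(prev$loss, prev$config_id), ]
          ids <- utils::head(prev$config_id, n_i)
        }
        for (id in ids) {
          hp <- configs_by_id[[id]]
          loss <- tryCatch(objective(hp, b_i), error = function(e) Inf)
          if (!is.finite(loss)) loss <- Inf
          store <- rbind(store, hp_row(hp, b_i, loss, bi, ri - 1L, id))
          total <- total + b_i
        }
      }
    }
    top_budget <- max(store$budget[is.finite(store$loss)])
    at_top <- store[store$budget == top_budget & is.finite(store$loss), ]
    best_row <- at_top[order(at_top$loss, at_top$config_id), ][1, ]
    list(best = configs_by_id[[best_row$config_id]],
         best_loss = best_row$loss, store = store, total_budget = total)
  })
}
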