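#' Action space of the costly-feature environment
#'
#' Actions `1..n` acquire feature `i`; actions `n+1..n+K` classify as the
#' K-th class label and terminate the episode.
#'
#' @param n_features number of features n.
#' @param classes vector of class labels (subjects).
#' @return object of class `action_space`.
#' @export
action_space <- function(n_features, classes) {
  structure(list(n_features = as.integer(n_features),
                 classes = classes,
                 n_actions = as.integer(n_features + length(classes))),
            class = "action_space")
}

#' Reward configuration of the costly-feature environment
#'
#' A feature action `f_i` pays `-lambda * c(f_i)`; a classification action
#' earns 0 when correct and -1 otherwise. `lambda` trades off precision
#' against average acquisition cost: larger `lambda` shortens episodes.
#'
#' @param n_features number of features.
#' @param lambda trade-off scalar (>= 0).
#' @param costs per-feature acquisition costs (>= 0), default all 1.
#' @return object of class `reward_config`.
#' @export
reward_config <- function(n_features, lambda = 0.01,
                          costs = rep(1, n_features)) {
  stopifnot(lambda >= 0, length(costs) == n_features, all(costs >= 0))
  structure(list(lambda = lambda, costs = costs), class = "reward_config")
}

#' Initial masked state
#'
#' The partially observable state is the pair (x_bar, m): `x_bar` holds the
#' revealed feature values and is 0 wherever the mask `m` is 0. At reset
#' nothing is revealed; the true sample (x, y) stays private to the
#' environment.
#'
#' @param n_features number of features.
#' @return object of class `masked_state` with fields `x_bar`, `m`.
#' @export
cwcf_reset <- function(n_features) {
  structure(list(x_bar = numeric(n_features), m = integer(n_features)),
            class = "masked_state")
}

#' One environment transition
#'
#' @param state current `masked_state`.
#' @param action integer action (see [action_space()]).
#' @param sample list with `x` (full feature vector) and `y` (true label).
#' @param space an `action_space`.
#' @param config a `reward_config`.
#' @return list with `state`, `action`, `reward`, `next_state` (a
#'   `masked_state`, or `NULL` at the terminal state), `done`.
#' @export
cwcf_step <- function(state, action, sample, space, config) {
  stopifnot(inherits(state, "masked_state"), inherits(space, "action_space"))
  n <- space$n_features
  if (action < 1 || action > space$n_actions) stopf("action %d out of range", action)
  if (action <= n) {
    if (state$m[action] == 1) {
      stopf("feature %d already revealed: re-selection is illegal", action)
    }
    nxt <- state
    nxt$m[action] <- 1L
    nxt$x_bar[action] <- sample$x[action]
    list(state = state, action = action,
         reward = -config$lambda * config$costs[action],
         next_state = nxt, done = FALSE)
  } else {
    pred <- space$classes[action - n]
    list(state = state, action = action,
         reward = if (identical(pred, sample$y)) 0 else -1,
         next_state = NULL, done = TRUE)
  }
}

#' Stateful costly-feature environment over a dataset
#'
#' Wraps [cwcf_reset()] / [cwcf_step()] with episode bookkeeping: `reset(i)`
#' (or a random row) starts an episode on row `i` of the feature matrix;
#' `step(action)` advances it. The true sample is held privately.
#'
#' @param fm a `feature_matrix`.
#' @param config a `reward_config` (default unit costs, lambda 0.01).
#' @param classes class labels defining the action space order (default the
#'   sorted unique subjects of `fm`).
#' @return list of functions `reset(i = NULL)`, `step(action)`, `state()`,
#'   plus the `space` used.
#' @export
cwcf_env <- function(fm, config = NULL, classes = sort(unique(fm$subject))) {
  stopifnot(inherits(fm, "feature_matrix"))
  x_all <- feature_block(fm)
  y_all <- fm$subject
  n <- ncol(x_all)
  config <- config %||% reward_config(n)
  space <- action_space(n, classes)
  cur <- NULL
  sample_i <- NULL
  list(
    space = space,
    config = config,
    reset = function(i = NULL) {
      sample_i <<- i %||% sample.int(nrow(x_all), 1)
      cur <<- cwcf_reset(n)
      cur
    },
    step = function(action) {
      if (is.null(cur)) stopf("episode not started; call reset()")
      tr <- cwcf_step(cur, action,
                      list(x = x_all[sample_i, ], y = y_all[sample_i]),
                      space, config)
      cur <<- tr$next_state
      tr
    },
    state = function() cur,
    label = function() y_all[sample_i]
  )
}
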