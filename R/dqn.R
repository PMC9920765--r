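#' Q-learning / DQN training configuration
#'
#' @param alpha tabular learning rate in (0, 1] (tabular updates only).
#' @param gamma discount factor in `[0, 1]`.
#' @param eps_start,eps_end epsilon-greedy schedule endpoints.
#' @param eps_decay_frac fraction of episodes over which epsilon decays
#'   linearly from `eps_start` to `eps_end`.
#' @param episodes number of training episodes M.
#' @param t_max maximum steps per episode (default n_features + 1, the
#'   longest possible episode).
#' @param replay_capacity experience-replay ring capacity.
#' @param batch_size replay batch size.
#' @param target_sync target-network sync period in gradient steps.
#' @param lr_final_frac the optimizer learning rate decays linearly over the
#'   episodes to this fraction of its initial value (1 = constant).
#' @param grad_clip global gradient-norm ceiling per update (`Inf` disables
#'   clipping); keeps aggressive learning rates from diverging.
#' @return object of class `qlearning_config`.
#' @export
qlearning_config <- function(alpha = 0.1, gamma = 1.0, eps_start = 1.0,
                             eps_end = 0.05, eps_decay_frac = 0.5,
                             episodes = 1500, t_max = NULL,
                             replay_capacity = 100000L, batch_size = 64L,
                             target_sync = 500L, lr_final_frac = 0.1,
                             grad_clip = 10) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0, gamma <= 1,
            lr_final_frac > 0, lr_final_frac <= 1, grad_clip > 0)
  structure(list(alpha = alpha, gamma = gamma, eps_start = eps_start,
                 eps_end = eps_end, eps_decay_frac = eps_decay_frac,
                 episodes = as.integer(episodes), t_max = t_max,
                 replay_capacity = as.integer(replay_capacity),
                 batch_size = as.integer(batch_size),
                 target_sync = as.integer(target_sync),
                 lr_final_frac = lr_final_frac, grad_clip = grad_clip),
            class = "qlearning_config")
}

#' Tabular Q-learning update
#'
#' `Q(s,a) <- (1 - alpha) Q(s,a) + alpha (r + gamma max_a' Q(s',a'))`; a
#' terminal next state contributes a zero max term.
#'
#' @param Q numeric matrix, states x actions.
#' @param transition list with integer `s`, `a`, numeric `r`, integer `s2`
#'   (ignored when `done`), logical `done`.
#' @param config a [qlearning_config()] (uses `alpha`, `gamma`).
#' @return the updated Q matrix.
#' @export
q_update_tabular <- function(Q, transition, config) {
  if (!(config$alpha > 0 && config$alpha <= 1)) stopf("alpha must be in (0, 1]")
  target <- transition$r +
    if (transition$done) 0 else config$gamma * max(Q[transition$s2, ])
  Q[transition$s, transition$a] <-
    (1 - config$alpha) * Q[transition$s, transition$a] + config$alpha * target
  Q
}

# ---- dense MLP with manual backprop --------------------------------------

#' Initialize a dense ReLU MLP
#'
#' He-uniform initialization; hidden layers share one width. Uses the
#' caller's RNG stream.
#'
#' @param n_in,n_out input/output dimension.
#' @param n_layers number of hidden layers.
#' @param nodes hidden width.
#' @return list of weight matrices `W` and bias vectors `b`.
#' @export
mlp_init <- function(n_in, n_out, n_layers, nodes) {
  dims <- c(n_in, rep(nodes, n_layers), n_out)
  W <- list()
  b <- list()
  for (l in seq_len(length(dims) - 1)) {
    lim <- sqrt(6 / dims[l])
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -lim, lim),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b)
}

#' Forward pass of the MLP
#'
#' @param params list from [mlp_init()].
#' @param x input matrix (batch x n_in) or a single input vector.
#' @return list with `out` (batch x n_out) and `cache` for backprop.
#' @export
mlp_forward <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  L <- length(params$W)
  hs <- vector("list", L + 1)
  hs[[1]] <- x
  for (l in seq_len(L)) {
    z <- hs[[l]] %*% params$W[[l]]
    z <- sweep(z, 2, params$b[[l]], `+`)
    hs[[l + 1]] <- if (l < L) pmax(z, 0) else z
  }
  list(out = hs[[L + 1]], cache = hs)
}

# gradient of scalar loss wrt params given dL/d(out)
mlp_backward <- function(params, cache, dout) {
  L <- length(params$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dout
  for (l in L:1) {
    gW[[l]] <- crossprod(cache[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(params$W[[l]])) * (cache[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

# rescale all gradients so their global L2 norm is at most max_norm
clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads$W, function(g) sum(g^2), numeric(1))) +
                  sum(vapply(grads$b, function(g) sum(g^2), numeric(1))))
  if (total <= max_norm || total == 0) return(grads)
  sc <- max_norm / total
  grads$W <- lapply(grads$W, `*`, sc)
  grads$b <- lapply(grads$b, `*`, sc)
  grads
}

# optimizer state + update rules (Adam / SGD with momentum / RMSprop)
optimizer_init <- function(hp, params) {
  zeros <- lapply(params$W, function(w) w * 0)
  zerob <- lapply(params$b, function(b) b * 0)
  list(kind = hp$optimizer, lr = hp$learning_rate,
       momentum = hp$sgd_momentum %||% 0, t = 0L,
       mW = zeros, mb = zerob, vW = zeros, vb = zerob)
}

optimizer_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  for (l in seq_along(params$W)) {
    for (part in c("W", "b")) {
      g <- grads[[part]][[l]]
      th <- params[[part]][[l]]
      if (opt$kind == "Adam") {
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        opt[[paste0("m", part)]][[l]] <- b1 * opt[[paste0("m", part)]][[l]] + (1 - b1) * g
        opt[[paste0("v", part)]][[l]] <- b2 * opt[[paste0("v", part)]][[l]] + (1 - b2) * g^2
        mhat <- opt[[paste0("m", part)]][[l]] / (1 - b1^opt$t)
        vhat <- opt[[paste0("v", part)]][[l]] / (1 - b2^opt$t)
        th <- th - opt$lr * mhat / (sqrt(vhat) + eps)
      } else if (opt$kind == "RMSprop") {
        rho <- 0.9; eps <- 1e-8
        opt[[paste0("v", part)]][[l]] <- rho * opt[[paste0("v", part)]][[l]] + (1 - rho) * g^2
        th <- th - opt$lr * g / (sqrt(opt[[paste0("v", part)]][[l]]) + eps)
      } else { # SGD (+ momentum)
        opt[[paste0("m", part)]][[l]] <-
          opt$momentum * opt[[paste0("m", part)]][[l]] - opt$lr * g
        th <- th + opt[[paste0("m", part)]][[l]]
      }
      params[[part]][[l]] <- th
    }
  }
  list(opt = opt, params = params)
}

# ---- acting and TD loss ---------------------------------------------------

# legal-action mask for a state: class actions always, feature i iff m_i == 0
legal_actions <- function(m, space) {
  c(m == 0, rep(TRUE, length(space$classes)))
}

state_input <- function(state) c(state$x_bar, state$m)

#' Epsilon-greedy action with Q-masking
#'
#' Revealed features are excluded by setting their Q-values to -Inf before
#' the argmax; ties break to the lowest action index. With probability
#' `epsilon` a uniform legal action is drawn from the caller's RNG stream.
#'
#' @param state a `masked_state`.
#' @param params MLP Q-network parameters.
#' @param space an `action_space`.
#' @param epsilon exploration probability.
#' @return integer action.
#' @export
dqn_act <- function(state, params, space, epsilon = 0) {
  legal <- legal_actions(state$m, space)
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    cand <- which(legal)
    return(cand[sample.int(length(cand), 1)])
  }
  q <- mlp_forward(params, state_input(state))$out[1, ]
  q[!legal] <- -Inf
  which.max(q)
}

#' Mask-aware TD loss of a transition batch
#'
#' Mean over the batch of `(r + gamma max_a' Q(s', a'; theta-) - Q(s, a;
#' theta))^2`, where the max runs over legal next actions only and terminal
#' transitions contribute target `r`.
#'
#' @param batch list of transitions as returned by [cwcf_step()].
#' @param params online network parameters (theta).
#' @param target_params target network parameters (theta-).
#' @param gamma discount factor.
#' @param space an `action_space`.
#' @return scalar mean-squared TD error.
#' @export
dqn_td_loss <- function(batch, params, target_params, gamma, space) {
  stopifnot(length(batch) > 0)
  errs <- vapply(batch, function(tr) {
    target <- if (tr$done) {
      tr$reward
    } else {
      qn <- mlp_forward(target_params, state_input(tr$next_state))$out[1, ]
      qn[!legal_actions(tr$next_state$m, space)] <- -Inf
      tr$reward + gamma * max(qn)
    }
    q <- mlp_forward(params, state_input(tr$state))$out[1, tr$action]
    (target - q)^2
  }, numeric(1))
  mean(errs)
}

# ---- DQN training ---------------------------------------------------------

#' Train the costly-feature DQN
#'
#' Epsilon-greedy episodes over the labelled feature matrix: each episode
#' samples one training row, rolls it out in the costly-feature environment,
#' stores every transition in the replay ring and performs one gradient step
#' per environment step (once the buffer holds a full batch); the target
#' network is a frozen copy of the online network, re-synced every
#' `target_sync` gradient steps. Deterministic under `seed`.
#'
#' @param data normalized (and, for real use, SMOTE-balanced)
#'   `feature_matrix` of training rows.
#' @param hp a [hyperparam_config()] (architecture + optimizer).
#' @param rl a [qlearning_config()].
#' @param reward a [reward_config()]; default unit costs, lambda 0.01.
#' @param seed RNG seed.
#' @param classes class labels fixing the action-space order.
#' @return object of class `dqn_policy`: list with `params`, `space`,
#'   `reward`, `hp`, `rl`, `classes` and a per-episode `log` (reward, steps,
#'   epsilon, mean loss, correct flag).
#' @export
dqn_train <- function(data, hp = hyperparam_config(), rl = qlearning_config(),
                      reward = NULL, seed = 1L,
                      classes = sort(unique(data$subject))) {
  stopifnot(inherits(data, "feature_matrix"))
  x_all <- feature_block(data)
  y_all <- data$subject
  n <- ncol(x_all)
  space <- action_space(n, classes)
  reward <- reward %||% reward_config(n)
  t_max <- rl$t_max %||% (n + 1L)
  n_act <- space$n_actions
  cap <- min(rl$replay_capacity, rl$episodes * t_max)

  local_seed(seed, {
    net <- mlp_init(2L * n, n_act, hp$n_layers, hp$nodes_per_layer)
    tgt <- net
    opt <- optimizer_init(hp, net)

    S <- matrix(0, cap, 2L * n)
    NS <- matrix(0, cap, 2L * n)
    A <- integer(cap)
    R <- numeric(cap)
    DONE <- logical(cap)
    filled <- 0L
    head <- 0L
    gstep <- 0L

    decay_eps <- max(1L, floor(rl$eps_decay_frac * rl$episodes))
    log <- data.frame(episode = seq_len(rl$episodes), reward = NA_real_,
                      steps = NA_integer_, epsilon = NA_real_,
                      loss = NA_real_, correct = NA)

    lff <- rl$lr_final_frac %||% 1
    for (ep in seq_len(rl$episodes)) {
      epsilon <- max(rl$eps_end,
                     rl$eps_start - (rl$eps_start - rl$eps_end) *
                       (ep - 1) / decay_eps)
      opt$lr <- hp$learning_rate *
        (1 - (1 - lff) * (ep - 1) / max(1L, rl$episodes - 1L))
      i <- sample.int(nrow(x_all), 1)
      sample_i <- list(x = x_all[i, ], y = y_all[i])
      state <- cwcf_reset(n)
      ep_reward <- 0
      losses <- numeric(0)
      correct <- NA
      for (t in seq_len(t_max)) {
        a <- dqn_act(state, net, space, epsilon)
        tr <- cwcf_step(state, a, sample_i, space, reward)
        ep_reward <- ep_reward + tr$reward
        head <- (head %% cap) + 1L
        filled <- min(filled + 1L, cap)
        S[head, ] <- state_input(state)
        A[head] <- a
        R[head] <- tr$reward
        DONE[head] <- tr$done
        NS[head, ] <- if (tr$done) 0 else state_input(tr$next_state)

        if (filled >= rl$batch_size) {
          idx <- sample.int(filled, rl$batch_size)
          qn <- mlp_forward(tgt, NS[idx, , drop = FALSE])$out
          msk <- NS[idx, (n + 1L):(2L * n), drop = FALSE] == 1
          qn[, seq_len(n)][msk] <- -Inf
          maxq <- apply(qn, 1, max)
          targets <- R[idx] + ifelse(DONE[idx], 0, rl$gamma * maxq)
          fw <- mlp_forward(net, S[idx, , drop = FALSE])
          pred <- fw$out[cbind(seq_along(idx), A[idx])]
          diff <- pred - targets
          loss <- mean(diff^2)
          if (!is.finite(loss)) {
            stopf("DQN diverged (non-finite loss) at episode %d, step %d", ep, t)
          }
          losses <- c(losses, loss)
          dout <- matrix(0, length(idx), n_act)
          dout[cbind(seq_along(idx), A[idx])] <- 2 * diff / length(idx)
          grads <- clip_grads(mlp_backward(net, fw$cache, dout),
                              rl$grad_clip %||% Inf)
          res <- optimizer_step(opt, net, grads)
          opt <- res$opt
          net <- res$params
          gstep <- gstep + 1L
          if (gstep %% rl$target_sync == 0L) tgt <- net
        }

        if (tr$done) {
          correct <- tr$reward == 0
          break
        }
        state <- tr$next_state
      }
      log$reward[ep] <- ep_reward
      log$steps[ep] <- t
      log$epsilon[ep] <- epsilon
      log$loss[ep] <- if (length(losses)) mean(losses) else NA_real_
      log$correct[ep] <- correct
    }

    structure(list(params = net, target_params = tgt, space = space,
                   reward = reward, hp = hp, rl = rl, classes = classes,
                   log = log),
              class = "dqn_policy")
  })
}

#' Greedy rollout of a trained policy on one sample
#'
#' @param policy a `dqn_policy`.
#' @param x full feature vector.
#' @return list with `features` (acquired feature indices, in order),
#'   `prediction` (class label), `class_q` (Q-values of the class actions at
#'   the decision step, usable as authentication scores), `steps`.
#' @export
dqn_rollout <- function(policy, x) {
  n <- policy$space$n_features
  state <- cwcf_reset(n)
  acquired <- integer(0)
  class_q <- NULL
  for (t in seq_len(n + 1L)) {
    q <- mlp_forward(policy$params, state_input(state))$out[1, ]
    q[!legal_actions(state$m, policy$space)] <- -Inf
    a <- which.max(q)
    if (a > n) {
      class_q <- q[(n + 1L):length(q)]
      names(class_q) <- policy$space$classes
      return(list(features = acquired,
                  prediction = policy$space$classes[a - n],
                  class_q = class_q, steps = t))
    }
    acquired <- c(acquired, a)
    state$m[a] <- 1L
    state$x_bar[a] <- x[a]
  }
  q <- mlp_forward(policy$params, state_input(state))$out[1, ]
  class_q <- q[(n + 1L):length(q)]
  names(class_q) <- policy$space$classes
  list(features = acquired, prediction = policy$space$classes[which.max(class_q)],
       class_q = class_q, steps = n + 1L)
}

#' Derive the selected-feature subset from a trained policy
#'
#' Greedy (epsilon = 0) rollouts over every row of `data`; records the
#' per-episode acquired set, its mean size (the "average number of selected
#' features" statistic), per-feature selection frequency, and the
#' classifier-facing subset of features whose frequency reaches `threshold`.
#'
#' @param policy a `dqn_policy`.
#' @param data a `feature_matrix`.
#' @param threshold selection-frequency threshold (default 0.5).
#' @return list with `subsets`, `predictions`, `mean_count`, `frequency`,
#'   `subset`, `accuracy`.
#' @export
derive_feature_subset <- function(policy, data, threshold = 0.5) {
  x_all <- feature_block(data)
  rolls <- lapply(seq_len(nrow(x_all)), function(i) {
    dqn_rollout(policy, x_all[i, ])
  })
  subsets <- lapply(rolls, `[[`, "features")
  preds <- vapply(rolls, function(r) as.numeric(r$prediction), numeric(1))
  n <- policy$space$n_features
  freq <- vapply(seq_len(n), function(j) {
    mean(vapply(subsets, function(s) j %in% s, logical(1)))
  }, numeric(1))
  list(subsets = subsets, predictions = preds,
       mean_count = mean(lengths(subsets)), frequency = freq,
       subset = which(freq >= threshold),
       accuracy = mean(preds == data$subject, na.rm = TRUE))
}
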