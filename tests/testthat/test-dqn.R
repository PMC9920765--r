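# ---- tabular Q-learning ---------------------------------------------------

test_that("single tabular updates follow the update rule in edge cases", {
  Q <- matrix(5, 2, 2)
  cfg <- qlearning_config(alpha = 1, gamma = 0)
  Q1 <- q_update_tabular(Q, list(s = 1L, a = 1L, r = -1, s2 = 2L,
                                 done = FALSE), cfg)
  expect_equal(Q1[1, 1], -1)

  cfg0 <- qlearning_config(alpha = 1e-12, gamma = 0.9)
  Q2 <- q_update_tabular(Q, list(s = 1L, a = 1L, r = -1, s2 = 2L,
                                 done = FALSE), cfg0)
  expect_equal(Q2[1, 1], 5, tolerance = 1e-9)
  expect_error(qlearning_config(alpha = 0), "alpha")
  expect_error(qlearning_config(alpha = 1.5), "alpha")
})

test_that("tabular Q-learning converges to the value-iteration fixed point", {
  # 3-state deterministic chain: s1 -a1-> s2 -a1-> s3 (terminal);
  # action 2 self-loops with reward -0.1; reaching s3 pays +1
  gamma <- 0.9
  step_chain <- function(s, a) {
    if (a == 1L) {
      if (s == 1L) list(s2 = 2L, r = 0, done = FALSE)
      else list(s2 = 3L, r = 1, done = TRUE)
    } else {
      list(s2 = s, r = -0.1, done = FALSE)
    }
  }
  # independent value-iteration oracle
  Qstar <- matrix(0, 2, 2)
  for (it in 1:500) {
    Qnew <- Qstar
    for (s in 1:2) for (a in 1:2) {
      tr <- step_chain(s, a)
      Qnew[s, a] <- tr$r + if (tr$done) 0 else gamma * max(Qstar[tr$s2, ])
    }
    Qstar <- Qnew
  }

  Q <- matrix(0, 3, 2)
  cfg <- qlearning_config(alpha = 0.5, gamma = gamma)
  for (sweep in 1:200) {
    for (s in 1:2) for (a in 1:2) {
      tr <- step_chain(s, a)
      Q <- q_update_tabular(Q, list(s = s, a = a, r = tr$r, s2 = tr$s2,
                                    done = tr$done), cfg)
    }
  }
  expect_lt(max(abs(Q[1:2, ] - Qstar)), 1e-6)
})

# ---- TD loss --------------------------------------------------------------

test_that("TD loss matches hand values on terminal transitions", {
  n <- 4
  sp <- action_space(n, 1:2)
  set.seed(1)
  params <- mlp_init(2 * n, sp$n_actions, 1, 8)
  # zero the output layer so Q == 0 everywhere
  L <- length(params$W)
  params$W[[L]] <- params$W[[L]] * 0
  params$b[[L]] <- params$b[[L]] * 0
  s <- cwcf_reset(n)
  term0 <- list(state = s, action = n + 1L, reward = 0, next_state = NULL,
                done = TRUE)
  term1 <- list(state = s, action = n + 2L, reward = -1, next_state = NULL,
                done = TRUE)
  expect_equal(dqn_td_loss(list(term0), params, params, 0.9, sp), 0)
  expect_equal(dqn_td_loss(list(term1), params, params, 0.9, sp), 1)
  expect_equal(dqn_td_loss(list(term0, term1), params, params, 0.9, sp), 0.5)
})

test_that("TD loss equals an element-wise oracle on a random batch", {
  n <- 5
  classes <- 1:3
  sp <- action_space(n, classes)
  cfg <- reward_config(n, lambda = 0.2)
  set.seed(7)
  online <- mlp_init(2 * n, sp$n_actions, 2, 12)
  target <- mlp_init(2 * n, sp$n_actions, 2, 12)
  gamma <- 0.85
  batch <- lapply(1:40, function(i) {
    smp <- list(x = rnorm(n), y = sample(classes, 1))
    s <- cwcf_reset(n)
    for (f in sample(n, sample(0:(n - 1), 1))) {
      s <- cwcf_step(s, f, smp, sp, cfg)$next_state
    }
    legal <- c(which(s$m == 0), n + seq_along(classes))
    cwcf_step(s, sample(legal, 1), smp, sp, cfg)
  })
  oracle <- mean(vapply(batch, function(tr) {
    qs <- mlp_forward(online, c(tr$state$x_bar, tr$state$m))$out[1, ]
    target_v <- if (tr$done) {
      tr$reward
    } else {
      qn <- mlp_forward(target, c(tr$next_state$x_bar, tr$next_state$m))$out[1, ]
      legal <- c(tr$next_state$m == 0, rep(TRUE, length(classes)))
      tr$reward + gamma * max(qn[legal])
    }
    (target_v - qs[tr$action])^2
  }, numeric(1)))
  expect_equal(dqn_td_loss(batch, online, target, gamma, sp), oracle,
               tolerance = 1e-12)
})

# ---- acting ---------------------------------------------------------------

test_that("greedy action takes the unique max and masks revealed features", {
  n <- 3
  sp <- action_space(n, 1:2)
  # linear net whose output is the bias vector regardless of input
  params <- list(W = list(matrix(0, 2 * n, sp$n_actions)),
                 b = list(c(0.1, 0.2, 0.3, 0.9, 0.4)))
  s <- cwcf_reset(n)
  expect_identical(dqn_act(s, params, sp, epsilon = 0), 4L)
  # reveal the would-be best feature: it must be excluded
  params2 <- list(W = params$W, b = list(c(0.1, 2, 0.3, 0.9, 0.4)))
  s2 <- s
  s2$m[2] <- 1L
  expect_identical(dqn_act(s2, params2, sp, epsilon = 0), 4L)
  # ties break to the lowest action index
  params3 <- list(W = params$W, b = list(rep(1, 5)))
  expect_identical(dqn_act(s, params3, sp, epsilon = 0), 1L)
  # all features revealed: only class actions remain
  s3 <- s
  s3$m[] <- 1L
  for (i in 1:20) expect_gt(dqn_act(s3, params2, sp, epsilon = 1), n)
})

test_that("epsilon = 1 explores uniformly over legal actions", {
  n <- 3
  sp <- action_space(n, 1:2)
  set.seed(123)
  params <- mlp_init(2 * n, sp$n_actions, 1, 4)
  s <- cwcf_reset(n)
  s$m[2] <- 1L # 4 legal actions: 1, 3, 4, 5
  draws <- vapply(1:10000, function(i) dqn_act(s, params, sp, epsilon = 1),
                  integer(1))
  counts <- table(factor(draws, levels = c(1, 3, 4, 5)))
  expect_identical(sort(unique(draws)), c(1L, 3L, 4L, 5L))
  # 3 sigma band around 2500 for binomial(10000, 1/4)
  expect_true(all(abs(counts - 2500) < 3 * sqrt(10000 * 0.25 * 0.75)))
})

# ---- training -------------------------------------------------------------

test_that("training is deterministic under a fixed seed", {
  fm <- toy_task(120, 5)
  rl <- qlearning_config(episodes = 60, replay_capacity = 500,
                         target_sync = 50)
  p1 <- dqn_train(fm, rl = rl, seed = 4)
  p2 <- dqn_train(fm, rl = rl, seed = 4)
  expect_identical(p1$log, p2$log)
  expect_identical(p1$params, p2$params)
  p3 <- dqn_train(fm, rl = rl, seed = 5)
  expect_false(identical(p1$log$reward, p3$log$reward))
})

test_that("trained toy policy queries the informative feature", {
  pol <- toy_policy()
  sel <- derive_feature_subset(pol, toy_test())
  expect_gte(sel$frequency[1], 0.9)
  expect_gte(sel$accuracy, 0.95)
  # accounting oracle: mean count equals the mean of per-episode sizes
  expect_equal(sel$mean_count, mean(lengths(sel$subsets)))
  expect_true(1 %in% sel$subset)
})

test_that("an always-classify policy yields zero features", {
  n <- 4
  sp <- action_space(n, 1:2)
  params <- list(W = list(matrix(0, 2 * n, sp$n_actions)),
                 b = list(c(rep(-1, n), 1, 0)))
  pol <- structure(list(params = params, space = sp), class = "dqn_policy")
  sel <- derive_feature_subset(pol, toy_test())
  expect_equal(sel$mean_count, 0)
  expect_length(sel$subset, 0)
})
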