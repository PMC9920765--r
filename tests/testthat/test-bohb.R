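test_that("the hyperband schedule matches the successive-halving formulas", {
  cfg <- bohb_config(max_budget = 9, min_budget = 1, eta = 3)
  expect_identical(cfg$s_max, 2L)
  sched <- hyperband_schedule(cfg)
  expect_length(sched, 3)
  # formula oracle, evaluated independently
  oracle <- lapply(2:0, function(s) {
    n0 <- ceiling((2 + 1) * 3^s / (s + 1))
    data.frame(rung = 0:s, n_configs = floor(n0 * 3^(-(0:s))),
               budget = 9 * 3^(-s) * 3^(0:s))
  })
  for (i in 1:3) {
    expect_equal(sched[[i]]$n_configs, oracle[[i]]$n_configs)
    expect_equal(sched[[i]]$budget, oracle[[i]]$budget)
  }
  # the outermost bracket: 9 @ 1 -> 3 @ 3 -> 1 @ 9
  expect_equal(sched[[1]]$n_configs, c(9, 3, 1))
  expect_equal(sched[[1]]$budget, c(1, 3, 9))
  expect_true(all(unlist(lapply(sched, `[[`, "budget")) <= 9))
})

test_that("max budget equal to min budget degenerates to one rung", {
  cfg <- bohb_config(max_budget = 4, min_budget = 4, eta = 3)
  sched <- hyperband_schedule(cfg)
  expect_length(sched, 1)
  expect_identical(nrow(sched[[1]]), 1L)
  expect_equal(sched[[1]]$budget, 4)
})

test_that("cold-start and random suggestions respect bounds and structure", {
  sp <- hyperparam_space()
  set.seed(2)
  for (i in 1:50) {
    hp <- tpe_suggest(NULL, sp, bohb_config())
    expect_s3_class(hp, "hyperparam_config")
    expect_true(hp$n_layers >= 1 && hp$n_layers <= 4)
    expect_true(hp$nodes_per_layer >= 16 && hp$nodes_per_layer <= 64)
    expect_true(hp$learning_rate >= 0.001 && hp$learning_rate <= 0.1)
    expect_true(hp$optimizer %in% sp$optimizers)
    expect_true(hp$sgd_momentum >= 0 && hp$sgd_momentum <= 0.99)
  }
})

test_that("TPE suggestions concentrate where observed losses are low", {
  set.seed(11)
  n_obs <- 40
  lr <- 10^runif(n_obs, -3, -1)
  store <- data.frame(
    config_id = seq_len(n_obs),
    n_layers = sample(1:4, n_obs, TRUE),
    nodes_per_layer = sample(16:64, n_obs, TRUE),
    learning_rate = lr,
    optimizer = sample(c("Adam", "SGD", "RMSprop"), n_obs, TRUE),
    sgd_momentum = 0.9,
    budget = 9,
    loss = (log10(lr) + 2)^2, # low loss iff lr near 0.01
    bracket = 1, rung = 0
  )
  cfg <- bohb_config(random_fraction = 0) # isolate the model-based path
  hits <- 0
  set.seed(99)
  for (i in 1:100) {
    hp <- tpe_suggest(store, hyperparam_space(), cfg)
    d_good <- abs(log10(hp$learning_rate) - log10(0.01))
    d_bad <- abs(log10(hp$learning_rate) - log10(0.1))
    if (d_good < d_bad) hits <- hits + 1
  }
  expect_gte(hits, 80)
})

test_that("BOHB finds the analytic optimum and accounts its budget exactly", {
  obj <- function(hp, budget) {
    (log10(hp$learning_rate) + 2)^2 + 0.1 * abs(hp$n_layers - 2)
  }
  cfg <- bohb_config()
  res <- run_bohb(obj, config = cfg, seed = 3)
  sched <- hyperband_schedule(cfg)
  expected_budget <- sum(unlist(lapply(sched, function(b) {
    b$n_configs * b$budget
  })))
  expect_equal(res$total_budget, expected_budget)
  expect_equal(sum(res$store$budget), expected_budget)
  # determinism
  res2 <- run_bohb(obj, config = cfg, seed = 3)
  expect_identical(res$store, res2$store)
  expect_identical(res$best, res2$best)
})

test_that("every advanced configuration dominated the ones left behind", {
  obj <- function(hp, budget) (log10(hp$learning_rate) + 2)^2
  res <- run_bohb(obj, config = bohb_config(), seed = 8)
  st <- res$store
  for (b in unique(st$bracket)) {
    rungs <- sort(unique(st$rung[st$bracket == b]))
    for (r in rungs[-length(rungs)]) {
      at <- st[st$bracket == b & st$rung == r, ]
      adv <- st[st$bracket == b & st$rung == r + 1, "config_id"]
      if (length(adv) == 0) next
      kept <- at[at$config_id %in% adv, ]
      left <- at[!at$config_id %in% adv, ]
      if (nrow(left) > 0) expect_lte(max(kept$loss), min(left$loss))
    }
  }
})

test_that("a failing objective is recorded as Inf and the run continues", {
  calls <- 0
  obj <- function(hp, budget) {
    calls <<- calls + 1
    if (calls %% 4 == 0) stop("boom")
    (log10(hp$learning_rate) + 2)^2
  }
  res <- run_bohb(obj, config = bohb_config(), seed = 5)
  expect_true(any(is.infinite(res$store$loss)))
  expect_true(is.finite(res$best_loss))
})
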