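# shared fixtures, generated once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 4-feature sign task: class = sign of feature 1, features 2-4 pure noise
toy_task <- function(n, seed) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * 4), n, 4)
  y <- ifelse(x[, 1] > 0, 1L, 2L)
  as_feature_matrix(x, y)
}

toy_train <- function() cached("toy_train", toy_task(500, 11))
toy_test <- function() cached("toy_test", toy_task(300, 99))

# DQN training configuration used for the toy task throughout the suite
toy_rl <- function(episodes = 4000) {
  qlearning_config(episodes = episodes, eps_end = 0.02, target_sync = 300,
                   replay_capacity = 2000)
}

toy_policy <- function() {
  cached("toy_policy",
         dqn_train(toy_train(), rl = toy_rl(), seed = 1))
}

# small multi-subject cohort (1-minute records) shared across feature /
# protocol tests; filtered and featurized once
small_cohort <- function() {
  cached("small_cohort", {
    coh <- make_cohort(n_subjects = 3, n_days = 6, duration = 60, fs = 1000,
                       drift = 0.05, noise_sd = 0.02, seed = 5)
    lapply(coh, apply_filter)
  })
}

small_fm <- function() {
  cached("small_fm", build_feature_matrix(small_cohort()))
}

# noise-free, drift-free pair of subjects for separability checks
clean_pair <- function() {
  cached("clean_pair", {
    coh <- make_cohort(n_subjects = 2, n_days = 1, duration = 120, fs = 1000,
                       drift = 0, noise_sd = 0, seed = 21, baseline_amp = 0)
    lapply(coh, apply_filter)
  })
}
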