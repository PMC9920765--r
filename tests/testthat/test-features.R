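hand_beat <- function(fs = 1000) {
  # fiducials at explicit times/amplitudes for arithmetic checks
  data.frame(P = 101L, Q = 251L, R = 281L, S = 321L, T = 601L,
             P_amp = 0.15, Q_amp = -0.1, R_amp = 1.0, S_amp = -0.2,
             T_amp = 0.3)
}

test_that("the extractor emits exactly 31 named finite features", {
  fv <- extract_features(hand_beat(), next_r = 1281L, next_t = 1601L,
                         fs = 1000)
  expect_length(fv, 31)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_length(feature_names(), 31)
  expect_identical(anyDuplicated(feature_names()), 0L)
})

test_that("interval, slope and ratio arithmetic matches hand computation", {
  b <- hand_beat()
  fv <- extract_features(b, next_r = 1281L, next_t = 1601L, fs = 1000)
  # R at 281, S at 321: R-S slope = (-0.2 - 1.0) / 0.040 = -30 mV/s
  expect_equal(unname(fv["R-S Slope"]), -30)
  expect_equal(unname(fv["R-R Interval"]), 1000)
  expect_equal(unname(fv["R-Tnext Interval"]), 1601 - 281)
  expect_equal(unname(fv["R-P Interval"]), 180)
  expect_equal(unname(fv["P-Q Interval"]), 150)
  # amplitude ratios: R-S = 1.0 / -0.2 = -5; Q-S floored denominator intact
  expect_equal(unname(fv["R-S Amplitude"]), 1.0 / -0.2)
  expect_equal(unname(fv["R-Q Amplitude"]), 1.0 / -0.1)
  # denominator flooring at 0.01 mV
  b2 <- b
  b2$Q_amp <- -0.001
  fv2 <- extract_features(b2, 1281L, 1601L, fs = 1000)
  expect_equal(unname(fv2["R-Q Amplitude"]), 1.0 / -0.01)
})

test_that("vertex angles equal an independent two-vector arccos computation", {
  b <- hand_beat()
  fv <- extract_features(b, 1281L, 1601L, fs = 1000, mV_scale = 100)
  oracle_angle <- function(A, W, B) {
    u <- A - W
    v <- B - W
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  # plane: 1 unit per ms, 100 units per mV
  p <- c(100, 15); q <- c(250, -10); r <- c(280, 100); s <- c(320, -20)
  t <- c(600, 30)
  expect_equal(unname(fv["Q Angle"]), oracle_angle(p, q, r))
  expect_equal(unname(fv["R Angle"]), oracle_angle(q, r, s))
  expect_equal(unname(fv["S Angle"]), oracle_angle(r, s, t))
  # symmetric hand-built vertex from explicit coordinates
  b3 <- data.frame(P = 1L, Q = 1L, R = 31L, S = 61L, T = 91L,
                   P_amp = 0, Q_amp = -0.1, R_amp = 1.0, S_amp = -0.1,
                   T_amp = 0)
  b3$P <- 1L; b3$Q <- 1L # degenerate P==Q rejected
  expect_null(extract_features(b3, 1031L, 1091L, fs = 1000))
})

test_that("amplitude ratios are scale invariant and slopes scale linearly", {
  b <- hand_beat()
  k <- 1.7
  bk <- b
  for (col in c("P_amp", "Q_amp", "R_amp", "S_amp", "T_amp")) {
    bk[[col]] <- b[[col]] * k
  }
  f1 <- extract_features(b, 1281L, 1601L, fs = 1000)
  fk <- extract_features(bk, 1281L, 1601L, fs = 1000)
  amp_idx <- grep("Amplitude", feature_names())
  slope_idx <- grep("Slope", feature_names())
  expect_equal(fk[amp_idx], f1[amp_idx], tolerance = 1e-12)
  expect_equal(unname(fk[slope_idx]), unname(k * f1[slope_idx]),
               tolerance = 1e-12)
})

test_that("feature matrix rows track the generator's beat ledger", {
  fm <- small_fm()
  expect_identical(attr(fm, "feature_names"), feature_names())
  truth_total <- sum(vapply(small_cohort(), function(r) {
    nrow(r$truth_fiducials)
  }, numeric(1)))
  # minus one edge beat per record (no next-R) and boundary skips
  n_rec <- length(small_cohort())
  expect_lt(abs(nrow(fm) - (truth_total - n_rec)) / truth_total, 0.10)
  expect_true(all(is.finite(feature_block(fm))))
  expect_true(all(fm[["R-R Interval"]] > 0))
})

test_that("identical records produce identical feature rows", {
  rec <- small_cohort()[[1]]
  fm2 <- build_feature_matrix(list(rec, rec))
  half <- nrow(fm2) / 2
  expect_equal(feature_block(fm2)[seq_len(half), ],
               feature_block(fm2)[half + seq_len(half), ],
               ignore_attr = TRUE)
})

test_that("z-scoring with training-day statistics is exact on training rows", {
  fm <- normalize_features(small_fm(), train_days = 1:5)
  tr <- fm$day %in% 1:5
  x <- feature_block(fm)[tr, ]
  expect_true(all(abs(colMeans(x)) < 1e-9))
  expect_true(all(abs(apply(x, 2, sd) - 1) < 1e-9))
  # test-day columns are scaled by the same stats, not re-centered
  xte <- feature_block(fm)[!tr, ]
  expect_false(all(abs(colMeans(xte)) < 1e-6))
})

test_that("two clean subjects separate by far more than their within-subject spread", {
  fm <- build_feature_matrix(clean_pair())
  x <- feature_block(fm)
  s1 <- x[fm$subject == 1, ]
  s2 <- x[fm$subject == 2, ]
  gap <- abs(colMeans(s1) - colMeans(s2))
  spread <- pmax(apply(s1, 2, sd), apply(s2, 2, sd), 1e-12)
  expect_true(any(gap > 10 * spread))
})

test_that("feature matrices round-trip through CSV", {
  fm <- small_fm()[1:20, ]
  attr(fm, "feature_names") <- feature_names()
  class(fm) <- c("feature_matrix", "data.frame")
  path <- file.path(tempdir(), "fm.csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_identical(attr(back, "feature_names"), feature_names())
  expect_equal(feature_block(back), feature_block(fm), tolerance = 1e-9,
               ignore_attr = TRUE)
})
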