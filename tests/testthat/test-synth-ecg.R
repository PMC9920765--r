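test_that("cohort generation is deterministic under a fixed seed", {
  a <- make_cohort(n_subjects = 2, n_days = 1, duration = 60, fs = 1000,
                   drift = 0, noise_sd = 0, seed = 7)
  b <- make_cohort(n_subjects = 2, n_days = 1, duration = 60, fs = 1000,
                   drift = 0, noise_sd = 0, seed = 7)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  expect_identical(lapply(a, `[[`, "truth_fiducials"),
                   lapply(b, `[[`, "truth_fiducials"))
  c2 <- make_cohort(n_subjects = 2, n_days = 1, duration = 60, fs = 1000,
                    drift = 0, noise_sd = 0, seed = 8)
  expect_false(identical(a[[1]]$samples, c2[[1]]$samples))
})

test_that("RR intervals equal mean_rr exactly when rr_sd is zero", {
  waves <- data.frame(wave = c("P", "Q", "R", "S", "T"),
                      amp = c(0.15, -0.1, 1.2, -0.2, 0.3),
                      mu = c(-160, -20, 0, 20, 300),
                      width = c(25, 8, 10, 8, 55))
  tpl <- subject_template(1, waves, mean_rr = 1000, rr_sd = 0)
  rec <- make_record(tpl, 1, duration = 60, fs = 1000, drift = 0,
                     noise_sd = 0, seed = 3)
  expect_true(all(diff(rec$truth_fiducials$R) == 1000L))
})

test_that("per-record truth beat count tracks duration / mean_rr", {
  tpls <- sample_templates(4, seed = 1)
  for (tpl in tpls) {
    rec <- make_record(tpl, 1, duration = 120, fs = 1000, drift = 0.05,
                       noise_sd = 0.02, seed = 1)
    expected <- 120000 / tpl$mean_rr
    expect_lt(abs(nrow(rec$truth_fiducials) - expected) / expected, 0.10)
  }
})

test_that("truth R indices are local maxima of the clean signal", {
  rec <- make_record(sample_templates(1, seed = 9)[[1]], 1, duration = 30,
                     fs = 1000, drift = 0, noise_sd = 0, seed = 9,
                     baseline_amp = 0)
  half <- 50L
  # bump centers fall on fractional sample positions, so the argmax may sit
  # on the neighbouring sample
  for (r in rec$truth_fiducials$R) {
    lo <- max(1L, r - half)
    hi <- min(length(rec$samples), r + half)
    expect_lte(abs(lo + which.max(rec$samples[lo:hi]) - 1L - r), 1L)
  }
})

test_that("truth fiducials are strictly increasing within each beat and record", {
  for (rec in small_cohort()[1:3]) {
    tf <- rec$truth_fiducials
    expect_true(all(tf$P < tf$Q & tf$Q < tf$R & tf$R < tf$S & tf$S < tf$T))
    expect_true(all(diff(tf$R) > 0))
    expect_true(all(tf$P >= 1 & tf$T <= length(rec$samples)))
  }
})

test_that("invalid templates and too-short records are rejected", {
  waves <- data.frame(wave = c("P", "Q", "R", "S", "T"),
                      amp = c(0.15, -0.1, 1.2, -0.2, 0.3),
                      mu = c(-160, -20, 0, 20, 300),
                      width = c(25, 8, 10, 8, 55))
  bad <- waves
  bad$mu[4] <- -5 # S before R
  expect_error(subject_template(1, bad, 900, 20), "mu_P < mu_Q")
  bad2 <- waves
  bad2$amp[3] <- -1
  expect_error(subject_template(1, bad2, 900, 20), "R amplitude")
  tpl <- subject_template(1, waves, 900, 20)
  expect_error(make_record(tpl, 1, duration = 0.5, fs = 1000, seed = 1),
               "too short")
})

test_that("day drift is deterministic and bounded in magnitude", {
  tpl <- sample_templates(1, seed = 4)[[1]]
  r1 <- make_record(tpl, 3, duration = 20, fs = 1000, drift = 0.1,
                    noise_sd = 0, seed = 6)
  r2 <- make_record(tpl, 3, duration = 20, fs = 1000, drift = 0.1,
                    noise_sd = 0, seed = 6)
  expect_identical(r1$samples, r2$samples)
  # different days differ when drift > 0
  r3 <- make_record(tpl, 4, duration = 20, fs = 1000, drift = 0.1,
                    noise_sd = 0, seed = 6)
  expect_false(identical(r1$samples, r3$samples))
  # peak R amplitude perturbed by at most the drift fraction (plus wander)
  a_r <- tpl$waves$amp[3]
  expect_lt(abs(max(r1$samples) - a_r) / a_r, 0.1 + 0.12)
})

test_that("CSV + JSON sidecar round-trips a record", {
  rec <- make_record(sample_templates(1, seed = 2)[[1]], 1, duration = 12,
                     fs = 500, drift = 0, noise_sd = 0.01, seed = 2)
  path <- file.path(tempdir(), "rec.csv")
  write_ecg_record(rec, path)
  back <- read_ecg_record(path)
  expect_equal(back$samples, rec$samples, tolerance = 1e-9)
  expect_equal(back$fs, rec$fs)
  expect_identical(back$subject_id, rec$subject_id)
  expect_equal(as.data.frame(back$truth_fiducials),
               as.data.frame(rec$truth_fiducials))
})
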