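#' Subject morphology template for the synthetic ECG generator
#'
#' A template fixes one subject's beat morphology as five Gaussian bumps, one
#' per canonical ECG wave (P, Q, R, S, T), plus the subject's RR-interval
#' distribution. Each wave `w` carries an amplitude `amp` (mV), a center
#' offset `mu` (ms relative to the R peak; negative = before R) and a width
#' `width` (Gaussian sd, ms).
#'
#' @param subject_id integer subject label.
#' @param waves data.frame with columns `wave` (exactly "P","Q","R","S","T"),
#'   `amp`, `mu`, `width`.
#' @param mean_rr mean RR interval in ms.
#' @param rr_sd RR interval standard deviation in ms.
#' @return object of class `subject_template`.
#' @export
subject_template <- function(subject_id, waves, mean_rr, rr_sd) {
  stopifnot(is.data.frame(waves), nrow(waves) == 5)
  waves <- waves[match(c("P", "Q", "R", "S", "T"), waves$wave), ]
  if (anyNA(waves$wave)) stopf("waves must contain exactly P,Q,R,S,T")
  mu <- waves$mu
  if (!(mu[1] < mu[2] && mu[2] < 0 && mu[3] == 0 && 0 < mu[4] && mu[4] < mu[5])) {
    stopf("wave centers must satisfy mu_P < mu_Q < 0 = mu_R < mu_S < mu_T")
  }
  if (any(waves$width <= 0)) stopf("wave widths must be positive")
  if (waves$amp[3] <= 0) stopf("R amplitude must be positive")
  if (waves$amp[2] > 0 || waves$amp[4] > 0) stopf("Q and S amplitudes must be <= 0")
  if (!(mean_rr > 0 && rr_sd >= 0)) stopf("mean_rr > 0 and rr_sd >= 0 required")
  structure(
    list(subject_id = as.integer(subject_id), waves = waves,
         mean_rr = mean_rr, rr_sd = rr_sd),
    class = "subject_template"
  )
}

#' Default physiologic ranges for random subject templates
#'
#' Amplitudes in mV, centers/widths in ms. Each entry is a (min, max) pair
#' sampled uniformly per subject.
#'
#' @return named list of ranges.
#' @export
template_ranges <- function() {
  list(
    P_amp = c(0.10, 0.25),  P_mu = c(-180, -140), P_width = c(20, 30),
    Q_amp = c(-0.15, -0.05), Q_mu = c(-30, -18),  Q_width = c(6, 10),
    R_amp = c(0.8, 1.6),                          R_width = c(8, 12),
    S_amp = c(-0.35, -0.10), S_mu = c(18, 30),    S_width = c(6, 10),
    T_amp = c(0.20, 0.45),  T_mu = c(280, 340),   T_width = c(45, 65),
    mean_rr = c(700, 1100), rr_sd = c(15, 40)
  )
}

#' Draw random subject templates within physiologic ranges
#'
#' @param n_subjects number of subjects.
#' @param seed RNG seed.
#' @param ranges ranges list as from [template_ranges()].
#' @return list of [subject_template()] objects.
#' @export
sample_templates <- function(n_subjects, seed, ranges = template_ranges()) {
  stopifnot(is_count(n_subjects))
  local_seed(derive_seed(seed, 101L), {
    lapply(seq_len(n_subjects), function(i) {
      u <- function(nm) stats::runif(1, ranges[[nm]][1], ranges[[nm]][2])
      waves <- data.frame(
        wave = c("P", "Q", "R", "S", "T"),
        amp = c(u("P_amp"), u("Q_amp"), u("R_amp"), u("S_amp"), u("T_amp")),
        mu = c(u("P_mu"), u("Q_mu"), 0, u("S_mu"), u("T_mu")),
        width = c(u("P_width"), u("Q_width"), u("R_width"), u("S_width"),
                  u("T_width"))
      )
      subject_template(i, waves, mean_rr = u("mean_rr"), rr_sd = u("rr_sd"))
    })
  })
}

# Deterministic per-(subject, day) multiplicative perturbation of wave
# amplitudes and timings, magnitude <= drift. A day is reproducible in
# isolation because the perturbation depends only on (seed, subject, day).
day_drift_factors <- function(template, day, drift, seed) {
  local_seed(derive_seed(seed, template$subject_id, day, 977L), {
    list(amp = 1 + stats::runif(5, -drift, drift),
         mu = 1 + stats::runif(5, -drift, drift))
  })
}

#' Generate one synthetic single-lead ECG record
#'
#' Beats are sums of five Gaussian bumps placed on an RR sequence drawn from
#' the subject template, plus a low-frequency baseline-wander sinusoid and
#' white noise. Ground-truth fiducials are the exact bump-center sample
#' indices.
#'
#' @param template a [subject_template()].
#' @param day recording day (1-based); drives the deterministic day drift.
#' @param duration record length in seconds.
#' @param fs sampling rate in Hz.
#' @param drift relative magnitude of the per-day perturbation of wave
#'   amplitudes and timings (0 <= drift < 0.3).
#' @param noise_sd white-noise sd in mV.
#' @param seed RNG seed (cohort-level; the record stream is derived from it).
#' @param baseline_amp baseline-wander amplitude in mV.
#' @param baseline_freq baseline-wander frequency in Hz (<= 0.5).
#' @return object of class `ecg_record`: list with `samples` (mV), `fs`,
#'   `subject_id`, `day`, and `truth_fiducials` (data.frame with one row per
#'   beat and columns `P`, `Q`, `R`, `S`, `T` of sample indices).
#' @export
make_record <- function(template, day, duration, fs, drift = 0, noise_sd = 0,
                        seed = 1L, baseline_amp = 0.1, baseline_freq = 0.33) {
  stopifnot(inherits(template, "subject_template"), fs > 0,
            day >= 1, drift >= 0, drift < 0.3, baseline_freq <= 0.5)
  dur_ms <- duration * 1000
  fac <- day_drift_factors(template, day, drift, seed)
  amp <- template$waves$amp * fac$amp
  mu <- template$waves$mu * fac$mu
  width <- template$waves$width

  rec_seed <- derive_seed(seed, template$subject_id, day)
  local_seed(rec_seed, {
    # place R centers; each beat needs its T bump inside the record
    first_r <- 400
    tail_ms <- max(mu[5] + 3 * width[5], 500)
    r_centers <- numeric(0)
    t_r <- first_r
    while (t_r + tail_ms < dur_ms) {
      r_centers <- c(r_centers, t_r)
      rr <- if (template$rr_sd > 0) {
        max(400, stats::rnorm(1, template$mean_rr, template$rr_sd))
      } else {
        template$mean_rr
      }
      t_r <- t_r + rr
    }
    if (length(r_centers) == 0) {
      stopf("duration %.3g s too short to contain one full beat", duration)
    }

    n <- round(duration * fs)
    tms <- (seq_len(n) - 1) / fs * 1000
    samples <- numeric(n)
    for (t_r in r_centers) {
      for (w in 1:5) {
        c_w <- t_r + mu[w]
        lo <- max(1L, floor((c_w - 4 * width[w]) / 1000 * fs) + 1L)
        hi <- min(n, ceiling((c_w + 4 * width[w]) / 1000 * fs) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        samples[idx] <- samples[idx] +
          amp[w] * exp(-((tms[idx] - c_w)^2) / (2 * width[w]^2))
      }
    }
    phase <- stats::runif(1, 0, 2 * pi)
    if (baseline_amp > 0) {
      samples <- samples +
        baseline_amp * sin(2 * pi * baseline_freq * tms / 1000 + phase)
    }
    if (noise_sd > 0) samples <- samples + stats::rnorm(n, 0, noise_sd)

    truth <- as.data.frame(lapply(1:5, function(w) {
      pmin(n, pmax(1L, round(outer(r_centers, mu[w], `+`)[, 1] / 1000 * fs) + 1L))
    }))
    names(truth) <- c("P", "Q", "R", "S", "T")

    structure(
      list(samples = samples, fs = fs, subject_id = template$subject_id,
           day = as.integer(day), truth_fiducials = truth),
      class = "ecg_record"
    )
  })
}

#' Generate a multi-subject multi-day synthetic ECG cohort
#'
#' Emulates a repeated-measures acquisition design: `n_subjects` subjects,
#' each recorded on `n_days` consecutive days. Per-subject morphology is
#' stable across days up to a deterministic multiplicative day drift of
#' magnitude at most `drift`. Defaults mirror an 11-subject, 6-day, 10-minute
#' design sampled at 1000 Hz.
#'
#' @inheritParams make_record
#' @param n_subjects number of subjects (>= 2).
#' @param n_days number of recording days per subject.
#' @param templates optional list of [subject_template()]; drawn with
#'   [sample_templates()] when `NULL`.
#' @return list of `ecg_record`, one per (subject, day), with the templates
#'   attached as attribute `templates`. Identical seeds give bit-identical
#'   cohorts.
#' @export
make_cohort <- function(n_subjects = 11, n_days = 6, duration = 600, fs = 1000,
                        drift = 0.05, noise_sd = 0.02, seed = 1L,
                        templates = NULL, baseline_amp = 0.1,
                        baseline_freq = 0.33) {
  stopifnot(n_subjects >= 2 || !is.null(templates), n_days >= 1)
  templates <- templates %||% sample_templates(n_subjects, seed)
  records <- list()
  for (tpl in templates) {
    for (d in seq_len(n_days)) {
      records[[length(records) + 1L]] <-
        make_record(tpl, d, duration, fs, drift = drift, noise_sd = noise_sd,
                    seed = seed, baseline_amp = baseline_amp,
                    baseline_freq = baseline_freq)
    }
  }
  attr(records, "templates") <- templates
  records
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> subject %d, day %d: %d samples @ %g Hz (%.1f s), %d truth beats\n",
    x$subject_id, x$day, length(x$samples), x$fs, length(x$samples) / x$fs,
    nrow(x$truth_fiducials)))
  invisible(x)
}

#' Write / read an ECG record as CSV plus JSON sidecar
#'
#' The CSV holds columns `sample_index`, `mV`; the sidecar (same path with
#' extension `.json`) holds `fs`, `subject_id`, `day` and the truth fiducial
#' indices (if any).
#'
#' @param record an `ecg_record`.
#' @param path CSV file path.
#' @return `write_ecg_record` returns `path` invisibly; `read_ecg_record`
#'   returns the reconstructed `ecg_record`.
#' @export
write_ecg_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  utils::write.csv(
    data.frame(sample_index = seq_along(record$samples), mV = record$samples),
    path, row.names = FALSE)
  side <- list(fs = record$fs, subject_id = record$subject_id,
               day = record$day)
  if (!is.null(record$truth_fiducials)) {
    side$truth_fiducials <- record$truth_fiducials
  }
  jsonlite::write_json(side, sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ecg_record
#' @export
read_ecg_record <- function(path) {
  dat <- utils::read.csv(path)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  truth <- side$truth_fiducials
  if (!is.null(truth)) truth <- as.data.frame(truth)
  structure(
    list(samples = dat$mV, fs = side$fs,
         subject_id = as.integer(side$subject_id), day = as.integer(side$day),
         truth_fiducials = truth),
    class = "ecg_record"
  )
}
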