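#' Names of the 31 fiducial features, in canonical order
#'
#' Ten amplitude ratios, twelve intervals (ms), six slopes (mV/s) and three
#' angles (degrees), all derived from the P, Q, R, S, T peak points. Two
#' R-to-T interval slots exist: the intra-beat R to T and the cross-beat R to
#' the next beat's T (named `R-Tnext Interval` here); together with the R-R
#' interval these are the only features that look across beats.
#'
#' @return character vector of length 31.
#' @export
feature_names <- function() {
  c(
    paste(c("R-P", "R-S", "R-T", "P-S", "P-T", "S-T", "R-Q", "Q-T", "Q-S",
            "P-Q"), "Amplitude"),
    paste(c("R-P", "R-Q", "R-S", "R-T", "P-Q", "P-S", "P-T", "Q-S", "Q-T",
            "S-T", "R-R", "R-Tnext"), "Interval"),
    paste(c("P-R", "R-S", "S-T", "Q-R", "P-Q", "Q-S"), "Slope"),
    paste(c("Q", "R", "S"), "Angle")
  )
}

# sign-preserving denominator floor for amplitude ratios (mV)
floor_den <- function(a, eps = 0.01) {
  s <- ifelse(a < 0, -1, 1)
  s * pmax(abs(a), eps)
}

#' Estimate the isoelectric baseline before one beat
#'
#' Median of the 40 ms window ending 20 ms before the P peak.
#'
#' @param x signal vector (mV).
#' @param p_index P-peak sample index.
#' @param fs sampling rate in Hz.
#' @return baseline estimate in mV.
#' @export
estimate_baseline <- function(x, p_index, fs) {
  lo <- max(1L, p_index - round(0.060 * fs))
  hi <- max(1L, p_index - round(0.020 * fs))
  stats::median(x[lo:hi])
}

#' Extract the 31 fiducial features of one beat
#'
#' Amplitudes are baseline-corrected peak values `a_w = signal(w) - baseline`.
#' An "X-Y Amplitude" feature is the ratio `a_X / a_Y` with `|a_Y|` floored at
#' `amp_floor` (sign preserved) so near-zero denominators stay finite; set
#' `amplitude_mode = "difference"` for plain `a_X - a_Y` instead. An "X-Y
#' Interval" is the unsigned duration `|index_Y - index_X| / fs` in ms; the
#' R-R interval uses the next beat's R and the `R-Tnext` slot the next beat's
#' T. An "X-Y Slope" is `(a_Y - a_X)` over the signed time difference, in
#' mV/s. A "W Angle" is the interior angle at W between its flanking
#' fiducials (Q: P-Q-R; R: Q-R-S; S: R-S-T), measured in a plane scaled to 1
#' unit per ms and `mV_scale` units per mV, in degrees.
#'
#' @param beat one-row fiducial data.frame as from [locate_pqst()].
#' @param next_r next beat's R sample index.
#' @param next_t next beat's T sample index.
#' @param fs sampling rate in Hz.
#' @param baseline isoelectric baseline in mV (see [estimate_baseline()]).
#' @param amplitude_mode `"ratio"` (default) or `"difference"`.
#' @param amp_floor denominator floor in mV for ratio mode.
#' @param mV_scale vertical plane scaling for angles (units per mV).
#' @return named numeric vector of length 31, or `NULL` when any value is
#'   non-finite (coincident indices).
#' @export
extract_features <- function(beat, next_r, next_t, fs, baseline = 0,
                             amplitude_mode = c("ratio", "difference"),
                             amp_floor = 0.01, mV_scale = 100) {
  amplitude_mode <- match.arg(amplitude_mode)
  idx <- c(P = beat$P, Q = beat$Q, R = beat$R, S = beat$S, T = beat$T)
  if (!(idx["P"] < idx["Q"] && idx["Q"] < idx["R"] && idx["R"] < idx["S"] &&
        idx["S"] < idx["T"]) || next_r <= idx["R"]) {
    return(NULL)
  }
  a <- c(P = beat$P_amp, Q = beat$Q_amp, R = beat$R_amp, S = beat$S_amp,
         T = beat$T_amp) - baseline

  amp_pairs <- list(c("R", "P"), c("R", "S"), c("R", "T"), c("P", "S"),
                    c("P", "T"), c("S", "T"), c("R", "Q"), c("Q", "T"),
                    c("Q", "S"), c("P", "Q"))
  amps <- vapply(amp_pairs, function(p) {
    if (amplitude_mode == "ratio") {
      a[p[1]] / floor_den(a[p[2]], amp_floor)
    } else {
      a[p[1]] - a[p[2]]
    }
  }, numeric(1))

  int_pairs <- list(c("R", "P"), c("R", "Q"), c("R", "S"), c("R", "T"),
                    c("P", "Q"), c("P", "S"), c("P", "T"), c("Q", "S"),
                    c("Q", "T"), c("S", "T"))
  ints <- vapply(int_pairs, function(p) {
    abs(idx[p[2]] - idx[p[1]]) / fs * 1000
  }, numeric(1))
  ints <- c(ints, (next_r - idx[["R"]]) / fs * 1000,
            (next_t - idx[["R"]]) / fs * 1000)

  slope_pairs <- list(c("P", "R"), c("R", "S"), c("S", "T"), c("Q", "R"),
                      c("P", "Q"), c("Q", "S"))
  slopes <- vapply(slope_pairs, function(p) {
    (a[p[2]] - a[p[1]]) / ((idx[p[2]] - idx[p[1]]) / fs)
  }, numeric(1))

  pt <- function(w) c(idx[[w]] / fs * 1000, a[[w]] * mV_scale)
  vertex_angle <- function(aw, w, bw) {
    u <- pt(aw) - pt(w)
    v <- pt(bw) - pt(w)
    cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
    acos(max(-1, min(1, cosang))) * 180 / pi
  }
  angles <- c(vertex_angle("P", "Q", "R"), vertex_angle("Q", "R", "S"),
              vertex_angle("R", "S", "T"))

  out <- c(amps, ints, slopes, angles)
  names(out) <- feature_names()
  if (!all(is.finite(out))) return(NULL)
  out
}

#' Build a labelled feature matrix from filtered records
#'
#' Runs R detection, P/Q/S/T localization and feature extraction per record.
#' The final beat of each record contributes the RR-derived features of its
#' predecessor but no row of its own (it has no next beat).
#'
#' @param records list of filtered `ecg_record`s.
#' @param windows P/Q/S/T search windows, see [pqst_windows()].
#' @param ... passed to [extract_features()].
#' @return object of class `feature_matrix`: data.frame with columns
#'   `subject`, `day`, then the 31 features (attribute `feature_names`);
#'   rejected-beat counts in attribute `rejected`.
#' @export
build_feature_matrix <- function(records, windows = pqst_windows(), ...) {
  rows <- list()
  rejected <- integer(0)
  for (rec in records) {
    beats <- extract_beats(rec, windows)
    nb <- nrow(beats)
    n_rej <- attr(beats, "n_skipped") %||% 0L
    if (nb < 2) {
      warning(sprintf("record subject %d day %d yielded %d usable beats; skipped",
                      rec$subject_id, rec$day, nb))
      next
    }
    for (i in seq_len(nb - 1L)) {
      bl <- estimate_baseline(rec$samples, beats$P[i], rec$fs)
      fv <- extract_features(beats[i, ], next_r = beats$R[i + 1L],
                             next_t = beats$T[i + 1L], fs = rec$fs,
                             baseline = bl, ...)
      if (is.null(fv)) {
        n_rej <- n_rej + 1L
        next
      }
      rows[[length(rows) + 1L]] <-
        c(subject = rec$subject_id, day = rec$day, fv)
    }
    rejected[sprintf("s%d_d%d", rec$subject_id, rec$day)] <- n_rej
  }
  if (length(rows) == 0) stopf("no usable beats in any record")
  mat <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  mat$subject <- as.integer(mat$subject)
  mat$day <- as.integer(mat$day)
  structure(mat, feature_names = feature_names(), rejected = rejected,
            class = c("feature_matrix", "data.frame"))
}

#' Z-score a feature matrix using training-day statistics only
#'
#' Per-feature mean/sd are computed from rows whose `day` is in `train_days`
#' and applied to every row, so held-out days never influence the scaling.
#'
#' @param fm a `feature_matrix`.
#' @param train_days integer days that constitute the training set.
#' @return the normalized `feature_matrix`; the statistics are stored in
#'   attribute `normalization` (list with `mean`, `sd`, `train_days`).
#' @export
normalize_features <- function(fm, train_days) {
  stopifnot(inherits(fm, "feature_matrix"))
  fn <- attr(fm, "feature_names")
  tr <- fm$day %in% train_days
  if (!any(tr)) stopf("no rows in train_days")
  mu <- vapply(fn, function(f) mean(fm[[f]][tr]), numeric(1))
  sd_ <- vapply(fn, function(f) stats::sd(fm[[f]][tr]), numeric(1))
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  for (f in fn) fm[[f]] <- (fm[[f]] - mu[[f]]) / sd_[[f]]
  attr(fm, "normalization") <- list(mean = mu, sd = sd_,
                                    train_days = train_days)
  fm
}

#' Extract the bare numeric feature block of a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @return numeric matrix (rows = beats, columns = the 31 features).
#' @export
feature_block <- function(fm) {
  as.matrix(fm[, attr(fm, "feature_names"), drop = FALSE])
}

#' Assemble a feature matrix from a plain numeric matrix and labels
#'
#' Useful for toy tasks and for feeding externally computed features into the
#' selection/evaluation machinery.
#'
#' @param x numeric matrix (rows = samples).
#' @param subject integer class labels, one per row.
#' @param day integer day labels, one per row (default 1).
#' @param names feature names (default from `colnames(x)` or `f1..fn`).
#' @return a `feature_matrix`.
#' @export
as_feature_matrix <- function(x, subject, day = rep(1L, nrow(x)),
                              names = NULL) {
  x <- as.matrix(x)
  names <- names %||% colnames(x) %||% paste0("f", seq_len(ncol(x)))
  colnames(x) <- names
  out <- data.frame(subject = as.integer(subject), day = as.integer(day),
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(x, check.names = FALSE))
  structure(out, feature_names = names,
            class = c("feature_matrix", "data.frame"))
}

#' Write / read a feature matrix as CSV
#'
#' Header is the 31 feature names plus `subject` and `day`.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.csv(as.data.frame(fm), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  dat <- utils::read.csv(path, check.names = FALSE)
  dat$subject <- as.integer(dat$subject)
  dat$day <- as.integer(dat$day)
  structure(dat, feature_names = setdiff(names(dat), c("subject", "day")),
            class = c("feature_matrix", "data.frame"))
}
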