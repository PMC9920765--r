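#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic Pan-Tompkins stages: 5--15 Hz bandpass (zero-phase FIR), 5-point
#' derivative, squaring, 150 ms moving-window integration, then dual adaptive
#' thresholds with search-back and a 200 ms refractory period. Detections are
#' refined to the local maximum of the input signal within +/- 50 ms.
#'
#' @param record an `ecg_record` (already bandpass filtered; >= 2 s long for
#'   meaningful threshold adaptation).
#' @param refractory_ms refractory period in ms.
#' @param refine_ms half-width of the local-maximum refinement window in ms.
#' @return strictly increasing integer vector of R-peak sample indices
#'   (empty for flat/energy-free signals).
#' @export
detect_r_peaks <- function(record, refractory_ms = 200, refine_ms = 50) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  if (n < 2 * fs || max(abs(x)) == 0) return(integer(0))

  # QRS-band emphasis
  taps <- 2L * floor(0.3 * fs) + 1L
  bp <- fir_zero_phase(x, design_fir(filter_spec(5, 15, order = taps, fs = fs)))
  # centered 5-point derivative
  d <- c(0, 0, (1 / 8) * (2 * bp[5:n] + bp[4:(n - 1)] -
                            bp[2:(n - 3)] - 2 * bp[1:(n - 4)]), 0, 0)
  sq <- d^2
  mwi_len <- max(3L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / mwi_len, mwi_len), sides = 2))
  mwi[is.na(mwi)] <- 0

  refr <- round(refractory_ms / 1000 * fs)
  cand <- local_maxima(mwi, min_sep = refr)
  if (length(cand) == 0) return(integer(0))

  # adaptive dual thresholds (Pan-Tompkins running estimates)
  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  rr_hist <- numeric(0)
  peaks <- integer(0)
  skipped <- integer(0)
  for (i in cand) {
    thr1 <- npki + 0.25 * (spki - npki)
    p <- mwi[i]
    accepted <- FALSE
    if (p > thr1) {
      accepted <- TRUE
    } else if (length(peaks) > 0 && length(rr_hist) > 0) {
      # search-back: missed-beat window at half threshold
      rr_avg <- mean(utils::tail(rr_hist, 8))
      if ((i - peaks[length(peaks)]) > 1.66 * rr_avg && length(skipped) > 0) {
        gap <- skipped[skipped > peaks[length(peaks)]]
        if (length(gap) > 0) {
          best <- gap[which.max(mwi[gap])]
          if (mwi[best] > 0.5 * thr1) {
            spki <- 0.25 * mwi[best] + 0.75 * spki
            if (length(peaks) > 0) {
              rr_hist <- c(rr_hist, best - peaks[length(peaks)])
            }
            peaks <- c(peaks, best)
            skipped <- integer(0)
          }
        }
      }
    }
    if (accepted) {
      spki <- 0.125 * p + 0.875 * spki
      if (length(peaks) > 0) rr_hist <- c(rr_hist, i - peaks[length(peaks)])
      peaks <- c(peaks, i)
      skipped <- integer(0)
    } else {
      npki <- 0.125 * p + 0.875 * npki
      skipped <- c(skipped, i)
    }
  }
  if (length(peaks) == 0) return(integer(0))
  peaks <- sort(peaks)

  # refine to the local signal maximum
  half <- round(refine_ms / 1000 * fs)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, as.integer(i - half))
    hi <- min(n, as.integer(i + half))
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce refractory after refinement: keep the larger of any close pair
  keep <- rep(TRUE, length(refined))
  last <- 1L
  for (j in seq_along(refined)[-1]) {
    if (refined[j] - refined[last] < refr) {
      if (x[refined[j]] > x[refined[last]]) {
        keep[last] <- FALSE
        last <- j
      } else {
        keep[j] <- FALSE
      }
    } else {
      last <- j
    }
  }
  refined[keep]
}

# indices of strict local maxima of v, greedily thinned to min_sep spacing
local_maxima <- function(v, min_sep) {
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- which(diff(sign(diff(v))) < 0) + 1L
  idx <- idx[v[idx] > 0]
  if (length(idx) <= 1) return(idx)
  ord <- idx[order(v[idx], decreasing = TRUE)]
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(taken - i) >= min_sep)) taken <- c(taken, i)
  }
  sort(taken)
}

#' Default P/Q/S/T search windows (ms)
#'
#' Window-based extrema search around a detected R peak: Q is the minimum
#' shortly before R, S the minimum shortly after, P the maximum in a window
#' before Q, T the maximum in a window after S.
#'
#' @return named list of window bounds in ms.
#' @export
pqst_windows <- function() {
  list(q_before = 80, s_after = 80, p_lo = 250, p_hi = 20, t_lo = 60, t_hi = 450)
}

#' Localize P, Q, S and T around one detected R peak
#'
#' @param record an `ecg_record` (filtered).
#' @param r_index detected R-peak sample index; needs >= 300 ms of context
#'   before and >= 500 ms after, otherwise the beat is skipped.
#' @param windows search windows as from [pqst_windows()].
#' @return one-row data.frame with columns `P`, `Q`, `R`, `S`, `T` (sample
#'   indices) and `P_amp` .. `T_amp` (raw signal values), or `NULL` when the
#'   beat lacks context or the fiducial ordering cannot be established.
#' @export
locate_pqst <- function(record, r_index, windows = pqst_windows()) {
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  ms <- function(v) round(v / 1000 * fs)
  if (r_index - ms(300) < 1 || r_index + ms(500) > n) {
    return(NULL)
  }
  q_rng <- (r_index - ms(windows$q_before)):(r_index - 1L)
  q <- q_rng[which.min(x[q_rng])]
  s_rng <- (r_index + 1L):(r_index + ms(windows$s_after))
  s <- s_rng[which.min(x[s_rng])]
  p_rng <- max(1L, q - ms(windows$p_lo)):(q - ms(windows$p_hi))
  p <- p_rng[which.max(x[p_rng])]
  t_rng <- (s + ms(windows$t_lo)):min(n, s + ms(windows$t_hi))
  t <- t_rng[which.max(x[t_rng])]
  if (!(p < q && q < r_index && r_index < s && s < t)) {
    return(NULL)
  }
  data.frame(P = p, Q = q, R = r_index, S = s, T = t,
             P_amp = x[p], Q_amp = x[q], R_amp = x[r_index], S_amp = x[s],
             T_amp = x[t])
}

#' Detect and localize all complete beats of a record
#'
#' Runs [detect_r_peaks()] then [locate_pqst()] per beat; beats at the record
#' edges (insufficient context) are dropped rather than padded.
#'
#' @param record a filtered `ecg_record`.
#' @param windows search windows as from [pqst_windows()].
#' @return data.frame of beat fiducials (columns as in [locate_pqst()]);
#'   attribute `n_skipped` counts dropped beats.
#' @export
extract_beats <- function(record, windows = pqst_windows()) {
  r_peaks <- detect_r_peaks(record)
  rows <- lapply(r_peaks, function(r) locate_pqst(record, r, windows))
  ok <- !vapply(rows, is.null, logical(1))
  out <- if (any(ok)) do.call(rbind, rows[ok]) else
    data.frame(P = integer(0), Q = integer(0), R = integer(0), S = integer(0),
               T = integer(0), P_amp = numeric(0), Q_amp = numeric(0),
               R_amp = numeric(0), S_amp = numeric(0), T_amp = numeric(0))
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Score detected R peaks against ground truth
#'
#' Greedy one-to-one matching of detections to truth indices within a
#' tolerance; reports precision, recall and F1.
#'
#' @param detected integer detections.
#' @param truth integer ground-truth indices.
#' @param fs sampling rate in Hz.
#' @param tol_ms matching tolerance in ms.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
detection_score <- function(detected, truth, fs, tol_ms = 50) {
  tol <- tol_ms / 1000 * fs
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol)
    if (length(j) > 0) {
      used[j[which.min(abs(truth[j] - d))]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}
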