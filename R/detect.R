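#' Band-pass filter specification for pulse detection
#'
#' Defaults follow the detector's published configuration for 100 Hz
#' PPG: fourth-order low-pass at 10 Hz and third-order Butterworth
#' high-pass at 0.05 Hz (both applied zero-phase), followed by a
#' 38-sample moving average whose output drives the peak threshold.
#'
#' @param lp_order,lp_cutoff Low-pass order and cutoff (Hz).
#' @param hp_order,hp_cutoff High-pass order and cutoff (Hz).
#' @param ma_length Moving-average length in samples.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(lp_order = 4, lp_cutoff = 10,
                        hp_order = 3, hp_cutoff = 0.05,
                        ma_length = 38) {
  stopifnot(lp_order >= 1, hp_order >= 1, ma_length >= 1,
            lp_cutoff > 0, hp_cutoff > 0, hp_cutoff < lp_cutoff)
  structure(list(lp_order = lp_order, lp_cutoff = lp_cutoff,
                 hp_order = hp_order, hp_cutoff = hp_cutoff,
                 ma_length = ma_length),
            class = "filter_spec")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the low-pass then the high-pass stage of `spec`, each
#' forward-backward (`signal::filtfilt`), so pulse timings are not
#' phase-shifted. Output length equals input length.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, spec = filter_spec()) {
  nyq <- fs / 2
  if (spec$lp_cutoff >= nyq || spec$hp_cutoff >= nyq)
    stop("filter cutoff at or above the Nyquist frequency (", nyq, " Hz)")
  if (length(x) < 3 * 3 * max(spec$lp_order, spec$hp_order))
    stop("signal too short for stable zero-phase filtering")
  lp <- signal::butter(spec$lp_order, spec$lp_cutoff / nyq, type = "low")
  hp <- signal::butter(spec$hp_order, spec$hp_cutoff / nyq, type = "high")
  y <- signal::filtfilt(lp, x)
  as.numeric(signal::filtfilt(hp, y))
}

#' Causal moving average
#'
#' `y[k]` is the mean of the `length`-sample window ending at `k`; at the
#' start of the signal the window shrinks to the samples available.
#'
#' @param x Numeric signal.
#' @param length Window length in samples.
#' @return Smoothed signal, same length as `x`.
#' @export
moving_average <- function(x, length = 38) {
  n <- base::length(x)
  if (length < 1) stop("`length` must be >= 1")
  if (length > n) stop("`length` exceeds the signal length")
  cs <- cumsum(x)
  y <- numeric(n)
  k <- seq_len(n)
  full <- k >= length
  y[!full] <- cs[!full] / k[!full]
  y[full] <- (cs[k[full]] - c(0, cs)[k[full] - length + 1]) / length
  y
}

# rolling quantile approximated on non-overlapping blocks, linearly
# interpolated back to per-sample resolution (adaptive threshold track)
.rolling_quantile <- function(x, w, p) {
  n <- length(x)
  w <- max(1L, min(w, n))
  starts <- seq(1L, n, by = w)
  q <- vapply(starts, function(s) {
    stats::quantile(x[s:min(n, s + w - 1L)], p, names = FALSE)
  }, numeric(1))
  centers <- pmin(starts + (w - 1) / 2, n)
  if (length(q) == 1) return(rep(q, n))
  stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
}

# local maxima above a per-sample threshold track, thinned by a
# refractory interval (the taller of two close candidates wins)
.thresholded_maxima <- function(sig, thr_sig, thr, fs, refractory_s) {
  n <- length(sig)
  if (n < 3) return(integer(0))
  core <- 2:(n - 1)
  is_max <- sig[core] > sig[core - 1] & sig[core] >= sig[core + 1]
  cand <- core[is_max & thr_sig[core] > thr[core]]
  if (length(cand) == 0) return(integer(0))
  ref_n <- round(refractory_s * fs)
  keep <- integer(0)
  for (k in cand) {
    if (length(keep) == 0 || k - keep[length(keep)] > ref_n) {
      keep <- c(keep, k)
    } else if (sig[k] > sig[keep[length(keep)]]) {
      keep[length(keep)] <- k
    }
  }
  keep
}

#' Detect pulse peaks and troughs in a PPG recording
#'
#' Modified Pan-Tompkins style detector: the signal is band-pass
#' filtered ([bandpass()]), smoothed with a moving average, and peaks
#' are taken as local maxima of the filtered signal whose smoothed
#' amplitude exceeds an adaptive threshold (a fraction of the rolling
#' 75th percentile of the moving-average output), subject to a
#' refractory interval. Troughs are found by running the same detector
#' on the inverted signal, thinned so at most one trough lies between
#' consecutive peaks, and any peak-to-peak gap the inversion pass missed
#' is filled with the signal minimum between the two peaks.
#'
#' @param x A `ppg_recording` or a numeric signal (then give `fs`).
#' @param fs Sampling rate (Hz), ignored when `x` is a recording.
#' @param spec A [filter_spec()].
#' @param threshold_frac Threshold as a fraction of the rolling
#'   percentile of the moving-average output.
#' @param threshold_quantile Percentile used for the adaptive threshold.
#' @param threshold_window_s Window (s) of the rolling percentile.
#' @param refractory_s Minimum peak-to-peak separation (s); 0.3 s caps
#'   detection at 200 beats/min.
#' @return An object of class `beat_annotations` with `peak_times`,
#'   `trough_times` (s) and `fs`. If nothing crosses the threshold an
#'   empty annotation is returned with a warning.
#' @export
detect_peaks <- function(x, fs = NULL, spec = filter_spec(),
                         threshold_frac = 0.5,
                         threshold_quantile = 0.75,
                         threshold_window_s = 5,
                         refractory_s = 0.3) {
  if (inherits(x, "ppg_recording")) { fs <- x$fs; x <- x$ppg }
  if (is.null(fs)) stop("`fs` is required when `x` is a plain vector")
  if (length(x) / fs < 10) stop("recording shorter than 10 s")
  bp <- bandpass(x, fs, spec)
  w <- round(threshold_window_s * fs)
  ann_for <- function(sig) {
    ma <- moving_average(sig, spec$ma_length)
    # causal MA delays the waveform by ~ (L-1)/2 samples; re-align so the
    # threshold track is compared at the right samples
    d <- floor((spec$ma_length - 1) / 2)
    ma_al <- c(ma[(d + 1):length(ma)], rep(ma[length(ma)], d))
    thr <- threshold_frac * .rolling_quantile(ma_al, w, threshold_quantile)
    .thresholded_maxima(sig, ma_al, thr, fs, refractory_s)
  }
  pk <- ann_for(bp)
  tr <- ann_for(-bp)
  if (length(pk) == 0)
    warning("no peaks found: returning an empty annotation")
  # interleave: keep the single deepest trough between consecutive peaks,
  # plus at most one before the first peak and one after the last
  if (length(pk) > 0 && length(tr) > 0) {
    bins <- findInterval(tr, pk)
    keep <- unlist(lapply(split(seq_along(tr), bins), function(idx) {
      idx[which.min(bp[tr[idx]])]
    }), use.names = FALSE)
    tr <- sort(tr[keep])
  }
  # the trough between two detected peaks exists by continuity; where the
  # inversion pass missed it (filter edge transients bury the shallower
  # trough prominence), take the signal minimum between the peaks
  if (length(pk) > 1) {
    for (i in seq_len(length(pk) - 1)) {
      if (!any(tr > pk[i] & tr < pk[i + 1])) {
        gap <- (pk[i] + 1):(pk[i + 1] - 1)
        tr <- c(tr, gap[which.min(bp[gap])])
      }
    }
    tr <- sort(tr)
  }
  structure(list(peak_times = (pk - 1) / fs,
                 trough_times = (tr - 1) / fs,
                 fs = fs),
            class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d peaks, %d troughs @ %g Hz\n",
              length(x$peak_times), length(x$trough_times), x$fs))
  invisible(x)
}

#' Inter-beat-interval series from beat annotations
#'
#' Successive peak-time differences in ms. Intervals outside the
#' plausibility window are flagged (not dropped); downstream feature
#' extraction excludes flagged intervals.
#'
#' @param ann A `beat_annotations` (needs at least 3 peaks).
#' @param plausibility_ms Two-element plausible-interval window (ms).
#' @return An object of class `ibi_series` with `beat_times` (s),
#'   `intervals` (ms, length `beats - 1`) and logical `flagged`.
#' @export
to_ibi <- function(ann, plausibility_ms = c(300, 2000)) {
  t <- if (inherits(ann, "beat_annotations")) ann$peak_times else as.numeric(ann)
  if (length(t) < 3) stop("need at least 3 peaks to form an IBI series")
  intervals <- diff(t) * 1000
  flagged <- intervals < plausibility_ms[1] | intervals > plausibility_ms[2]
  structure(list(beat_times = t, intervals = intervals, flagged = flagged),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d intervals (mean %.0f ms, %d flagged)\n",
              length(x$intervals), mean(x$intervals), sum(x$flagged)))
  invisible(x)
}

#' Restrict an IBI series to a time window
#' @param ibi An `ibi_series`.
#' @param window Two-element `c(start, end)` in seconds.
#' @return An `ibi_series` with only the beats inside the window.
#' @export
window_ibi <- function(ibi, window) {
  keep <- ibi$beat_times >= window[1] & ibi$beat_times <= window[2]
  t <- ibi$beat_times[keep]
  if (length(t) < 3) stop("fewer than 3 beats inside the window")
  to_ibi_raw(t, ibi)
}

to_ibi_raw <- function(t, parent) {
  intervals <- diff(t) * 1000
  # intervals spanning the original gaps keep their original flags where
  # the pairs are unchanged; recompute from the plausibility of values
  flagged <- intervals < 300 | intervals > 2000
  structure(list(beat_times = t, intervals = intervals, flagged = flagged),
            class = "ibi_series")
}

#' Beat-detection accuracy against ground truth
#'
#' Greedy one-to-one matching of detected beat times to true beat times
#' within `tol_s`; reports precision, recall and F1.
#'
#' @param detected,truth Beat times in seconds.
#' @param tol_s Matching tolerance (s).
#' @return List with `f1`, `precision`, `recall`, `n_matched`.
#' @export
detection_f1 <- function(detected, truth, tol_s = 0.05) {
  used <- rep(FALSE, length(truth))
  matched <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol_s)
    if (length(j) > 0) {
      used[j[which.min(abs(truth[j] - d))]] <- TRUE
      matched <- matched + 1L
    }
  }
  precision <- if (length(detected) > 0) matched / length(detected) else NA_real_
  recall <- if (length(truth) > 0) matched / length(truth) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) 2 * precision * recall / (precision + recall) else 0
  list(f1 = f1, precision = precision, recall = recall, n_matched = matched)
}
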