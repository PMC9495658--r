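#' One trough-to-trough pulse segment
#'
#' @param samples Numeric waveform samples of one beat.
#' @param fs Sampling rate (Hz).
#' @param start_time Absolute time (s) of the first sample.
#' @return Object of class `pulse_segment`.
#' @export
pulse_segment <- function(samples, fs, start_time = 0) {
  stopifnot(is.numeric(samples), fs > 0)
  if (length(samples) / fs < 0.3)
    stop("pulse segment shorter than 0.3 s")
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_time = start_time),
            class = "pulse_segment")
}

#' Split a recording into trough-to-trough pulse segments
#'
#' Uses the detector's troughs; segments that do not contain exactly one
#' detected peak, or that are shorter than 0.3 s, are dropped.
#'
#' @param x A `ppg_recording` or numeric signal (then give `fs`).
#' @param ann [detect_peaks()] annotations for the same signal.
#' @param fs Sampling rate when `x` is a plain vector.
#' @param filtered Optional pre-filtered signal to segment instead of
#'   band-passing `x` again.
#' @return List of `pulse_segment` objects.
#' @export
segment_pulses <- function(x, ann, fs = NULL, filtered = NULL) {
  if (inherits(x, "ppg_recording")) { fs <- x$fs; x <- x$ppg }
  sig <- if (is.null(filtered)) bandpass(x, fs) else filtered
  tr <- ann$trough_times
  pk <- ann$peak_times
  out <- list()
  if (length(tr) < 2) return(out)
  for (i in seq_len(length(tr) - 1)) {
    npk <- sum(pk > tr[i] & pk < tr[i + 1])
    len_s <- tr[i + 1] - tr[i]
    if (npk != 1 || len_s < 0.3) next
    i0 <- round(tr[i] * fs) + 1
    i1 <- round(tr[i + 1] * fs) + 1
    out[[length(out) + 1]] <- pulse_segment(sig[i0:i1], fs, start_time = tr[i])
  }
  out
}

# centred 5-point moving-average smoother (edges shrink)
.smooth5 <- function(x) {
  n <- length(x)
  if (n < 5) return(x)
  y <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  y <- as.numeric(y)
  y[1:2] <- c(mean(x[1:3]), mean(x[1:4]))
  y[(n - 1):n] <- c(mean(x[(n - 3):n]), mean(x[(n - 2):n]))
  y
}

# central difference, one-sided at the edges, scaled to units/s
.cdiff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d * fs
}

#' Smoothed first and second derivatives of a pulse
#'
#' Each differencing pass is preceded by a 5-point smoother, since raw
#' second differences at 100 Hz are noise-dominated.
#'
#' @param pulse A [pulse_segment()].
#' @return List with `d1` and `d2`, each the same length as the pulse.
#' @export
pulse_derivatives <- function(pulse) {
  stopifnot(inherits(pulse, "pulse_segment"))
  d1 <- .cdiff(.smooth5(pulse$samples), pulse$fs)
  d2 <- .cdiff(.smooth5(d1), pulse$fs)
  list(d1 = d1, d2 = d2)
}

#' Locate the systolic and diastolic peaks of one pulse
#'
#' The systolic peak is the global maximum. The reflected (diastolic)
#' peak is found from derivative landmarks: the most prominent local
#' maximum of the second derivative after the systolic peak marks the
#' dicrotic notch region, and the next down-going zero crossing of the
#' first derivative after that landmark (a local maximum of the
#' waveform) is the diastolic peak. The landmark search is confined to
#' a physiologically plausible window after the systolic peak
#' (`max_rptt_frac` of the segment) so that noise wiggles in the
#' late-diastolic tail are not mistaken for a reflected wave. When no
#' landmark exists (e.g. no visible reflected wave) the measurement is
#' returned with a missing R-PTT and a degraded quality flag rather
#' than a fabricated value. The rule is isolated here so an alternative
#' landmark scheme can be swapped in.
#'
#' @param pulse A [pulse_segment()].
#' @param max_rptt_frac Latest admissible diastolic peak, as a fraction
#'   of the segment length after the systolic peak.
#' @return Object of class `rptt_measurement`: `rptt` (s),
#'   `systolic_peak_time`, `diastolic_peak_time` (absolute s) and
#'   `quality` ("ok" or "degraded").
#' @export
locate_peaks_in_pulse <- function(pulse, max_rptt_frac = 0.6) {
  stopifnot(inherits(pulse, "pulse_segment"))
  x <- pulse$samples
  fs <- pulse$fs
  n <- length(x)
  sys_i <- which.max(x)
  der <- pulse_derivatives(pulse)
  fail <- function() {
    structure(list(rptt = NA_real_,
                   systolic_peak_time = pulse$start_time + (sys_i - 1) / fs,
                   diastolic_peak_time = NA_real_,
                   quality = "degraded"),
              class = "rptt_measurement")
  }
  if (sys_i >= n - 3) return(fail())
  d2 <- der$d2
  d1 <- der$d1
  hi <- min(n - 1, sys_i + round(max_rptt_frac * n))
  rng <- (sys_i + 1):hi
  if (length(rng) < 3) return(fail())
  loc <- rng[d2[rng] > d2[rng - 1] & d2[rng] >= d2[rng + 1]]
  if (length(loc) == 0) return(fail())
  lm2 <- loc[which.max(d2[loc])]
  # next down-going zero crossing of d1 = the diastolic local maximum
  zc <- which(d1[lm2:(hi - 1)] > 0 & d1[(lm2 + 1):hi] <= 0)
  if (length(zc) == 0) return(fail())
  dia_i <- lm2 + zc[1] - 1
  # refine to the nearest sample where d1 changes sign
  if (abs(d1[dia_i + 1]) < abs(d1[dia_i])) dia_i <- dia_i + 1
  # sub-sample refinement: parabolic vertex through the sample and its
  # neighbours on the (unsmoothed) segment, for both peaks
  sys_t <- sys_i + .parabolic_offset(x, sys_i)
  dia_t <- dia_i + .parabolic_offset(x, dia_i)
  structure(list(rptt = (dia_t - sys_t) / fs,
                 systolic_peak_time = pulse$start_time + (sys_t - 1) / fs,
                 diastolic_peak_time = pulse$start_time + (dia_t - 1) / fs,
                 quality = "ok"),
            class = "rptt_measurement")
}

# vertex offset (in samples, clamped to +/- 0.5) of the parabola through
# (i-1, i, i+1); 0 at the edges or when the points are collinear
.parabolic_offset <- function(x, i) {
  n <- length(x)
  if (i <= 1 || i >= n) return(0)
  den <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (den == 0) return(0)
  off <- 0.5 * (x[i - 1] - x[i + 1]) / den
  max(-0.5, min(0.5, off))
}

#' Measure R-PTT for every beat of a recording
#'
#' Segments the recording trough-to-trough and applies
#' [locate_peaks_in_pulse()] to each segment.
#'
#' @inheritParams segment_pulses
#' @return Data frame with one row per usable beat: `time` (systolic
#'   peak, s), `rptt_s`, `quality`.
#' @export
measure_rptt <- function(x, ann, fs = NULL, filtered = NULL) {
  segs <- segment_pulses(x, ann, fs = fs, filtered = filtered)
  if (length(segs) == 0)
    return(data.frame(time = numeric(0), rptt_s = numeric(0),
                      quality = character(0)))
  rows <- lapply(segs, function(s) {
    m <- locate_peaks_in_pulse(s)
    data.frame(time = m$systolic_peak_time, rptt_s = m$rptt,
               quality = m$quality)
  })
  do.call(rbind, rows)
}

#' Windowed mean R-PTT (mPTP calibration average)
#'
#' Arithmetic mean of the non-degraded R-PTT values whose systolic peak
#' falls inside the window; averaging over a window (rather than using
#' a single beat) is what makes the calibration robust.
#'
#' @param measurements Data frame from [measure_rptt()].
#' @param window Two-element `c(start, end)` window in seconds
#'   (default: first 30 s).
#' @param min_beats Minimum number of usable beats required.
#' @return Mean R-PTT in seconds.
#' @export
mptp_average <- function(measurements, window = c(0, 30), min_beats = 5) {
  ok <- measurements$quality == "ok" & !is.na(measurements$rptt_s) &
    measurements$time >= window[1] & measurements$time <= window[2]
  if (sum(ok) < min_beats)
    stop("only ", sum(ok), " usable beats in the window; need at least ",
         min_beats, " - use a longer calibration window")
  mean(measurements$rptt_s[ok])
}
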