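#' Configuration for the synthetic PPG generator
#'
#' Generates quasi-periodic PPG pulses with a systolic and a delayed
#' reflected (diastolic) component, beat-to-beat interval variability
#' with LF/HF oscillatory structure, baseline wander, mains
#' interference and broadband noise, plus a ground-truth SBP/DBP
#' trajectory coupled to the reflected-wave delay through the pressure
#' model. Defaults emulate a clean operating-room pulse-oximeter
#' recording: 100 Hz sampling, ~75 beats/min with 40/20 ms LF/HF
#' oscillations and 10 ms white jitter, a 0.25 s reflected-wave delay
#' with slow physiological drift, 2% broadband noise, slow baseline
#' wander and a trace of 50 Hz mains.
#'
#' @param sampling_rate Hz.
#' @param duration Seconds of signal.
#' @param mean_ibi Mean inter-beat interval (ms).
#' @param lf_osc `c(frequency_hz, amplitude_ms)` low-frequency IBI
#'   oscillation (vasomotor band).
#' @param hf_osc `c(frequency_hz, amplitude_ms)` high-frequency IBI
#'   oscillation (respiratory band).
#' @param ibi_jitter_sd White beat-to-beat jitter SD (ms).
#' @param rptt Reflected-wave delay: a constant (s) or a function of
#'   time returning seconds.
#' @param reflected_amplitude_ratio Reflected/primary amplitude, in (0,1).
#' @param noise_sd Broadband noise SD in units of the (unit) pulse
#'   amplitude.
#' @param wander `c(frequency_hz, amplitude)` baseline wander
#'   (frequency at or below 0.04 Hz).
#' @param mains `c(frequency_hz, amplitude)` mains interference (50 or
#'   60 Hz).
#' @param bp_noise_sd Per-beat pressure offset noise added to the true
#'   SBP/DBP trajectory (mmHg; same offset on both so SBP > DBP is
#'   preserved).
#' @param cal_bp_error_sd SD (mmHg) of a per-recording offset applied
#'   to the reference BP channel inside the calibration window only,
#'   emulating noninvasive cuff measurement error at calibration time.
#' @param cal_window_s End of the calibration window (s) for that
#'   offset.
#' @param true_params A [bp_model_params()] coupling R-PTT to BP.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(sampling_rate = 100, duration = 660,
                         mean_ibi = 800,
                         lf_osc = c(0.1, 40), hf_osc = c(0.25, 20),
                         ibi_jitter_sd = 10,
                         rptt = function(t) 0.25 * (1 + 0.08 * sin(2 * pi * t / 300)),
                         reflected_amplitude_ratio = 0.4,
                         noise_sd = 0.02,
                         wander = c(0.03, 0.3),
                         mains = c(50, 0.02),
                         bp_noise_sd = 2,
                         cal_bp_error_sd = 0,
                         cal_window_s = 30,
                         true_params = bp_model_params(2.5, 280 / 3, 0.25),
                         seed = 1) {
  stopifnot(sampling_rate > 0, duration > 0, mean_ibi > 0,
            reflected_amplitude_ratio > 0, reflected_amplitude_ratio < 1,
            ibi_jitter_sd >= 0, noise_sd >= 0, bp_noise_sd >= 0,
            length(lf_osc) == 2, length(hf_osc) == 2,
            length(wander) == 2, length(mains) == 2)
  if (wander[1] > 0.04) stop("baseline wander frequency must be <= 0.04 Hz")
  if (!mains[1] %in% c(50, 60)) stop("mains frequency must be 50 or 60 Hz")
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 mean_ibi = mean_ibi, lf_osc = lf_osc, hf_osc = hf_osc,
                 ibi_jitter_sd = ibi_jitter_sd, rptt = rptt,
                 reflected_amplitude_ratio = reflected_amplitude_ratio,
                 noise_sd = noise_sd, wander = wander, mains = mains,
                 bp_noise_sd = bp_noise_sd,
                 cal_bp_error_sd = cal_bp_error_sd,
                 cal_window_s = cal_window_s,
                 true_params = true_params, seed = seed),
            class = "synth_config")
}

#' Generate a beat-time / IBI series
#'
#' `IBI(k) = mean_ibi + lf_amp*sin(2*pi*f_lf*t_k) +
#' hf_amp*sin(2*pi*f_hf*t_k) + jitter`, with beat times the cumulative
#' sum of the intervals.
#'
#' @param config A [synth_config()].
#' @return List with `beat_times` (s) and `ibi_ms` (length
#'   `length(beat_times) - 1`).
#' @export
generate_ibi_series <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  t <- 0
  beat_times <- 0
  ibi_ms <- numeric(0)
  repeat {
    ibi <- config$mean_ibi +
      config$lf_osc[2] * sin(2 * pi * config$lf_osc[1] * t) +
      config$hf_osc[2] * sin(2 * pi * config$hf_osc[1] * t) +
      (if (config$ibi_jitter_sd > 0) stats::rnorm(1, 0, config$ibi_jitter_sd) else 0)
    if (ibi <= 0)
      stop("rejected configuration: realised IBI <= 0 (oscillation ",
           "amplitudes/jitter too large for mean_ibi)")
    t_next <- t + ibi / 1000
    if (t_next > config$duration + 1e-9) break
    beat_times <- c(beat_times, t_next)
    ibi_ms <- c(ibi_ms, ibi)
    t <- t_next
  }
  list(beat_times = beat_times, ibi_ms = ibi_ms)
}

# fraction of the interval at which the systolic peak sits, and the
# Gaussian widths of the two component waves. Widths scale with the
# interval up to a 0.8 s reference beat and saturate beyond it
# (ejection duration does not lengthen proportionally at slow rates;
# strict proportionality would merge the two peaks on slow beats).
.PULSE_T0 <- 0.18
.PULSE_SIGMA1 <- 0.08
.PULSE_SIGMA2 <- 0.12
.PULSE_IBI_CAP <- 0.8

.pulse_widths <- function(ibi) {
  w <- min(ibi, .PULSE_IBI_CAP)
  c(s1 = .PULSE_SIGMA1 * w, s2 = .PULSE_SIGMA2 * w)
}

# peak separation of the continuous two-Gaussian pulse: locate both
# local maxima of the noiseless waveform to sub-ms precision; errors
# if the reflected wave does not form a distinct diastolic peak
.realized_rptt <- function(delay, ibi, ratio) {
  t0 <- .PULSE_T0 * ibi
  s <- .pulse_widths(ibi)
  f <- function(t) exp(-(t - t0)^2 / (2 * s[1]^2)) +
    ratio * exp(-(t - t0 - delay)^2 / (2 * s[2]^2))
  sys <- stats::optimize(f, c(t0 - s[1], t0 + s[1]), maximum = TRUE,
                         tol = 1e-7)$maximum
  dia <- stats::optimize(f, c(t0 + delay - s[2], t0 + delay + s[2]),
                         maximum = TRUE, tol = 1e-7)$maximum
  out <- dia - sys
  # reject configurations whose pulses are effectively unimodal: a
  # distinct diastolic peak requires a genuine valley between the peaks
  valley <- if (out > 0) stats::optimize(f, c(sys, dia), tol = 1e-7)$objective else Inf
  if (out < 0.5 * delay || valley >= f(dia) - 1e-9)
    stop("rejected configuration: no distinct reflected (diastolic) peak ",
         "for delay ", signif(delay, 3), " s at IBI ", signif(ibi, 3), " s")
  out
}

#' Synthesise one PPG pulse
#'
#' Sum of two smooth unimodal (Gaussian) bumps: a unit-amplitude
#' primary (systolic) wave and a reflected (diastolic) wave of relative
#' amplitude `reflected_ratio` whose peak lags the primary peak by
#' `rptt` seconds. Gaussian widths scale with the interval (primary
#' sigma 0.08 IBI, reflected 0.12 IBI, saturating at a 0.8 s beat) so
#' the two peaks stay unambiguous for the second-derivative landmark
#' method.
#'
#' @param rptt Reflected-wave delay (s), `0 < rptt < ibi`.
#' @param ibi Beat interval (s).
#' @param reflected_ratio Reflected amplitude in (0, 1); 0 gives a
#'   single-peaked pulse.
#' @param sampling_rate Hz.
#' @return Numeric waveform of length `round(ibi * sampling_rate)`.
#' @export
synth_pulse <- function(rptt, ibi, reflected_ratio, sampling_rate) {
  if (!is.na(rptt) && (rptt <= 0 || rptt >= ibi))
    stop("rptt must lie strictly inside (0, ibi): the reflection would ",
         "fall into the next beat")
  n <- round(ibi * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  t0 <- .PULSE_T0 * ibi
  s <- .pulse_widths(ibi)
  w <- exp(-(t - t0)^2 / (2 * s[1]^2))
  if (reflected_ratio > 0 && !is.na(rptt))
    w <- w + reflected_ratio * exp(-(t - t0 - rptt)^2 / (2 * s[2]^2))
  w
}

#' Generate a full synthetic recording with ground truth
#'
#' Concatenates one pulse per generated interval, evaluates the true
#' per-beat SBP/DBP from the true R-PTT through [predict_bp()] with
#' `config$true_params` (plus optional per-beat pressure-offset noise),
#' then adds baseline wander, mains interference and broadband noise to
#' the waveform. The reference BP channel carries the true per-beat
#' pressures, with an optional calibration-window measurement offset
#' (`cal_bp_error_sd`).
#'
#' @param config A [synth_config()].
#' @return Object of class `synth_recording`: `recording` (a
#'   [ppg_recording()] including the reference BP channel),
#'   `true_beat_times` (systolic peak times, s), `true_ibi` (ms),
#'   `true_rptt` (s per beat), `true_sbp`, `true_dbp` (mmHg per beat),
#'   `true_params`, `cal_bp_offset` and the `config`.
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  series <- generate_ibi_series(config)   # seeds the RNG
  nb <- length(series$ibi_ms)
  if (nb < 2) stop("configuration yields fewer than 2 beats")
  fs <- config$sampling_rate
  rptt_fun <- if (is.function(config$rptt)) config$rptt else
    function(t) rep(config$rptt, length(t))
  seg_start_t <- series$beat_times[seq_len(nb)]
  true_rptt <- rptt_fun(seg_start_t)
  ibi_s <- series$ibi_ms / 1000
  if (any(true_rptt <= 0) || any(true_rptt >= ibi_s))
    stop("rejected configuration: R-PTT must stay inside (0, IBI) for every beat")
  pulses <- vector("list", nb)
  peak_sample <- integer(nb)
  offset <- 0L
  for (k in seq_len(nb)) {
    p <- synth_pulse(true_rptt[k], ibi_s[k],
                     config$reflected_amplitude_ratio, fs)
    pulses[[k]] <- p
    peak_sample[k] <- offset + round(.PULSE_T0 * ibi_s[k] * fs) + 1L
    offset <- offset + length(p)
  }
  # ground-truth R-PTT is the realised systolic-to-diastolic peak
  # separation of the noiseless pulse (R-PTT is defined on the
  # waveform's peaks; wave superposition shifts them slightly relative
  # to the configured component delay)
  true_rptt <- vapply(seq_len(nb), function(k) {
    .realized_rptt(true_rptt[k], ibi_s[k], config$reflected_amplitude_ratio)
  }, numeric(1))
  ppg <- unlist(pulses, use.names = FALSE)
  n <- length(ppg)
  tt <- (seq_len(n) - 1) / fs
  # remaining RNG draws, in a fixed order, off the same seeded stream
  phase_w <- stats::runif(1, 0, 2 * pi)
  phase_m <- stats::runif(1, 0, 2 * pi)
  bp_noise <- if (config$bp_noise_sd > 0) stats::rnorm(nb, 0, config$bp_noise_sd) else numeric(nb)
  cal_off <- if (config$cal_bp_error_sd > 0) stats::rnorm(1, 0, config$cal_bp_error_sd) else 0
  wn <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)
  ppg <- ppg +
    config$wander[2] * sin(2 * pi * config$wander[1] * tt + phase_w) +
    config$mains[2] * sin(2 * pi * config$mains[1] * tt + phase_m) +
    wn
  bp <- predict_bp(true_rptt, config$true_params)
  true_sbp <- bp$sbp + bp_noise
  true_dbp <- bp$dbp + bp_noise
  true_beat_times <- (peak_sample - 1) / fs
  ref <- data.frame(time = true_beat_times, sbp = true_sbp, dbp = true_dbp)
  in_cal <- ref$time <= config$cal_window_s
  ref$sbp[in_cal] <- ref$sbp[in_cal] + cal_off
  ref$dbp[in_cal] <- ref$dbp[in_cal] + cal_off
  rec <- ppg_recording(ppg, fs, ref_bp = ref)
  structure(list(recording = rec,
                 true_beat_times = true_beat_times,
                 true_ibi = diff(true_beat_times) * 1000,
                 true_rptt = true_rptt,
                 true_sbp = true_sbp, true_dbp = true_dbp,
                 true_params = config$true_params,
                 cal_bp_offset = cal_off,
                 config = config),
            class = "synth_recording")
}

#' @export
print.synth_recording <- function(x, ...) {
  cat(sprintf("<synth_recording> %d beats, %.0f s @ %g Hz  (ka=%.3g kb=%.3g kc=%.3g)\n",
              length(x$true_rptt), recording_duration(x$recording),
              x$recording$fs, x$true_params$ka, x$true_params$kb,
              x$true_params$kc))
  invisible(x)
}

#' Generate a synthetic study cohort
#'
#' Draws subject-specific model parameters and heart-rate baselines,
#' then generates one recording per subject. `ka` is uniform on 1-5
#' mmHg s^2, `kc` equals the subject's baseline R-PTT (uniform on
#' 0.23-0.30 s) and `kb` is normal around 90 mmHg; the mean IBI is
#' coupled (negatively) to `kb` so that subjects with higher pressure
#' run faster heart rates, as in resting physiology. All randomness
#' descends from `seed` through per-subject sub-seeds.
#'
#' @param n Number of subjects (>= 2; leave-one-out is undefined below
#'   that).
#' @param config Template [synth_config()]; per-subject fields
#'   (`mean_ibi`, `rptt`, `true_params`, oscillation amplitudes,
#'   `seed`) are overridden per subject.
#' @param seed Master seed.
#' @param cal_bp_error_sd Calibration-window cuff-error SD (mmHg).
#' @param dir Optional directory: recordings and a manifest table are
#'   written there as delimited text.
#' @return Object of class `synth_cohort`: list of `synth_recording`s
#'   and a `manifest` data frame (subject id, file, true parameters).
#' @export
generate_cohort <- function(n = 30, config = synth_config(), seed = 1,
                            cal_bp_error_sd = 4, dir = NULL) {
  if (n < 2) stop("need at least 2 subjects (leave-one-out undefined)")
  set.seed(seed)
  ka <- stats::runif(n, 1, 5)
  rptt_base <- stats::runif(n, 0.23, 0.30)
  kb <- stats::rnorm(n, 90, 5)
  mean_ibi <- 800 - 6 * (kb - 90) + stats::rnorm(n, 0, 15)
  lf_amp <- stats::runif(n, 25, 55)
  hf_amp <- stats::runif(n, 10, 30)
  jit <- stats::runif(n, 5, 15)
  sub_seed <- sample.int(1e7, n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    base <- rptt_base[i]
    cfg <- config
    cfg$mean_ibi <- mean_ibi[i]
    cfg$lf_osc[2] <- lf_amp[i]
    cfg$hf_osc[2] <- hf_amp[i]
    cfg$ibi_jitter_sd <- jit[i]
    cfg$rptt <- local({
      b <- base
      function(t) b * (1 + 0.08 * sin(2 * pi * t / 300))
    })
    cfg$true_params <- bp_model_params(ka[i], kb[i], base,
                                       config$true_params$constants)
    cfg$cal_bp_error_sd <- cal_bp_error_sd
    cfg$seed <- sub_seed[i]
    recs[[i]] <- generate_recording(cfg)
    recs[[i]]$recording$subject <- sprintf("s%02d", i)
  }
  manifest <- data.frame(subject = sprintf("s%02d", seq_len(n)),
                         file = NA_character_,
                         ka = ka, kb = kb, kc = rptt_base,
                         mean_ibi = mean_ibi,
                         cal_bp_offset = vapply(recs, `[[`, numeric(1), "cal_bp_offset"),
                         seed = sub_seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      f <- file.path(dir, sprintf("%s.csv", manifest$subject[i]))
      write_recording(recs[[i]]$recording, f)
      manifest$file[i] <- f
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(recordings = recs, manifest = manifest, seed = seed),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d subjects (seed %d)\n",
              length(x$recordings), x$seed))
  invisible(x)
}
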