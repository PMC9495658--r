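#' Spectral band definition for IBI frequency analysis
#'
#' Default bands: VLF 0.0033-0.05 Hz, LF 0.05-0.15 Hz, HF 0.15-0.5 Hz.
#'
#' @param vlf,lf,hf Two-element Hz intervals; must be increasing and
#'   non-overlapping.
#' @return An object of class `spectral_bands`.
#' @export
spectral_bands <- function(vlf = c(0.0033, 0.05),
                           lf = c(0.05, 0.15),
                           hf = c(0.15, 0.5)) {
  b <- rbind(vlf, lf, hf)
  if (any(b[, 2] <= b[, 1]) || vlf[2] > lf[1] || lf[2] > hf[1])
    stop("bands must be increasing, non-overlapping intervals")
  structure(list(vlf = vlf, lf = lf, hf = hf), class = "spectral_bands")
}

.ibi_values <- function(ibi) {
  if (inherits(ibi, "ibi_series")) ibi$intervals[!ibi$flagged] else as.numeric(ibi)
}

.ibi_times <- function(ibi) {
  if (inherits(ibi, "ibi_series")) ibi$beat_times[-1][!ibi$flagged]
  else stop("beat times unavailable: supply an `ibi_series`")
}

#' Time-domain IBI statistics
#'
#' Mean IBI, SDNN (sample SD of all intervals), SDANN (SD over
#' non-overlapping segment means, with the 1/(M-1) normalisation),
#' RMSSD, NNx and pNNx. NNx counts successive differences whose
#' absolute value exceeds the threshold (default 10 ms); pNNx is its
#' percentage of all successive differences.
#'
#' @param ibi An `ibi_series` or numeric intervals (ms).
#' @param nnx_threshold_ms NNx threshold in ms.
#' @param sdann_segment_s Segment length in seconds for SDANN.
#' @return Named list: `mean_ibi`, `sdnn`, `sdann`, `rmssd`, `nnx`,
#'   `pnnx`. `sdann` is `NA` (with a warning) when fewer than two
#'   segments fit.
#' @export
time_domain <- function(ibi, nnx_threshold_ms = 10, sdann_segment_s = 60) {
  x <- .ibi_values(ibi)
  if (length(x) < 2) stop("need at least 2 intervals")
  d <- diff(x)
  nnx <- sum(abs(d) > nnx_threshold_ms)
  sdann <- NA_real_
  if (inherits(ibi, "ibi_series")) {
    t <- .ibi_times(ibi)
    seg <- floor((t - t[1]) / sdann_segment_s)
    means <- tapply(x, seg, mean)
    if (length(means) >= 2) {
      sdann <- sqrt(sum((means - mean(means))^2) / (length(means) - 1))
    } else {
      warning("fewer than 2 SDANN segments: sdann is NA")
    }
  } else {
    warning("SDANN needs beat times: supply an `ibi_series`")
  }
  list(mean_ibi = mean(x),
       sdnn = stats::sd(x),
       sdann = sdann,
       rmssd = sqrt(mean(d^2)),
       nnx = nnx,
       pnnx = 100 * nnx / length(d))
}

#' Geometric IBI histogram measures
#'
#' The triangular index PRVti is the total interval count divided by the
#' height of the histogram mode. TINN is `M - N` for the triangle
#' `q(t)` with apex at the mode that minimises the squared deviation
#' from the histogram, found by exhaustive search of `(N, M)` over the
#' bin-centre grid (extended beyond the occupied range so an exact
#' triangular histogram is recovered).
#'
#' @param ibi An `ibi_series` or numeric intervals (ms).
#' @param bin_width_ms Histogram bin width; the default 7.8125 ms is the
#'   conventional 1/128 s discretisation.
#' @return List with `prvti` and `tinn` (ms).
#' @export
histogram_geometry <- function(ibi, bin_width_ms = 7.8125) {
  x <- .ibi_values(ibi)
  if (length(x) < 1) stop("empty series")
  bw <- bin_width_ms
  lo <- floor(min(x) / bw)
  hi <- floor(max(x) / bw)
  counts <- tabulate(floor(x / bw) - lo + 1L, nbins = hi - lo + 1L)
  centers <- (seq(lo, hi) + 0.5) * bw
  Y <- max(counts)
  prvti <- length(x) / Y
  if (length(counts) == 1) return(list(prvti = prvti, tinn = 0))
  apex_i <- which.max(counts)
  # candidate triangle feet on the bin grid, one bin beyond each end
  left_c <- c(centers[1] - bw, centers[centers < centers[apex_i]])
  right_c <- c(centers[centers > centers[apex_i]], centers[length(centers)] + bw)
  best <- Inf; best_nm <- c(centers[apex_i], centers[apex_i])
  for (Nf in left_c) for (Mf in right_c) {
    q <- numeric(length(centers))
    upl <- centers > Nf & centers <= centers[apex_i]
    q[upl] <- Y * (centers[upl] - Nf) / (centers[apex_i] - Nf)
    dnl <- centers > centers[apex_i] & centers < Mf
    q[dnl] <- Y * (Mf - centers[dnl]) / (Mf - centers[apex_i])
    sse <- sum((counts - q)^2)
    if (sse < best - 1e-12) { best <- sse; best_nm <- c(Nf, Mf) }
  }
  list(prvti = prvti, tinn = best_nm[2] - best_nm[1])
}

#' Lomb-Scargle periodogram of an unevenly sampled IBI series
#'
#' Least-squares spectral estimate for arbitrary sample times, with the
#' frequency-dependent offset `tau` that makes the estimate invariant to
#' a shift of the time origin. Returns both the classical normalised
#' power (power divided by `2 * var(x)`-style normalisation) and a
#' one-sided power spectral density in ms^2/Hz scaled so that its
#' integral over all frequencies approximates the series variance; band
#' powers are trapezoidal integrals of that density.
#'
#' @param ibi An `ibi_series`, or numeric intervals (then give `times`).
#' @param times Sample times in s (one per interval) when `ibi` is a
#'   plain vector.
#' @param freq Frequency grid in Hz (default 0.001-0.5 Hz, step 0.001).
#' @param bands A [spectral_bands()].
#' @return List with `freq`, `power` (normalised), `psd` (ms^2/Hz),
#'   `vlf`, `lf`, `hf` (ms^2) and `lf_hf` (`NA` when the HF power is 0).
#' @export
lomb_scargle <- function(ibi, times = NULL,
                         freq = seq(0.001, 0.5, by = 0.001),
                         bands = spectral_bands()) {
  if (inherits(ibi, "ibi_series")) {
    x <- ibi$intervals[!ibi$flagged]
    t <- ibi$beat_times[-1][!ibi$flagged]
  } else {
    x <- as.numeric(ibi); t <- times
    if (is.null(t)) stop("`times` required for a plain interval vector")
  }
  n <- length(x)
  if (n < 10) stop("need at least 10 points")
  xc <- x - mean(x)
  s2 <- stats::var(x)
  pow <- numeric(length(freq))
  for (i in seq_along(freq)) {
    w <- 2 * pi * freq[i]
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    th <- w * (t - tau)
    ct <- cos(th); st <- sin(th)
    pow[i] <- 0.5 * (sum(xc * ct)^2 / sum(ct^2) + sum(xc * st)^2 / sum(st^2))
  }
  power_norm <- pow / s2
  fs_eff <- (n - 1) / (t[n] - t[1])
  psd <- 2 * pow / fs_eff   # one-sided density, ms^2/Hz
  band_power <- function(b) {
    sel <- freq >= b[1] & freq <= b[2]
    f <- freq[sel]; p <- psd[sel]
    if (sum(sel) < 2) return(0)
    sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
  }
  vlf <- band_power(bands$vlf); lf <- band_power(bands$lf); hf <- band_power(bands$hf)
  list(freq = freq, power = power_norm, psd = psd,
       vlf = vlf, lf = lf, hf = hf,
       lf_hf = if (hf > 0) lf / hf else NA_real_)
}

#' Poincare-plot descriptors SD1 and SD2
#'
#' SD1 (minor semi-axis) is `sqrt(2)/2` times the SD of successive
#' differences; SD2 (major) is `sqrt(2*SD(x)^2 - SD1-term)`. A negative
#' radicand yields `NA` with a warning rather than a fabricated value.
#'
#' @param ibi An `ibi_series` or numeric intervals (ms).
#' @return List with `sd1` and `sd2` (ms).
#' @export
poincare <- function(ibi) {
  x <- .ibi_values(ibi)
  if (length(x) < 3) stop("need at least 3 intervals")
  sdd <- stats::sd(diff(x))
  sd1 <- sqrt(2) / 2 * sdd
  rad <- 2 * stats::sd(x)^2 - 0.5 * sdd^2
  if (rad < 0) {
    warning("SD2 radicand negative: sd2 is NA")
    sd2 <- NA_real_
  } else sd2 <- sqrt(rad)
  list(sd1 = sd1, sd2 = sd2)
}

#' Sample entropy of an IBI series
#'
#' `-log(A/B)` where `B` and `A` count pairs of length-`m` and
#' length-`m+1` templates (Chebyshev distance, self-matches excluded)
#' within tolerance `r`. Zero means consecutive sequences are identical;
#' larger values mean higher complexity.
#'
#' @param ibi An `ibi_series` or numeric intervals (ms).
#' @param m Embedding dimension.
#' @param r Tolerance; defaults to `r_factor * sd(x)`.
#' @param r_factor Tolerance as a fraction of the series SD.
#' @return Sample entropy (nats); `NA` with a warning when no templates
#'   match at either length.
#' @export
sample_entropy <- function(ibi, m = 2, r = NULL, r_factor = 0.2) {
  x <- .ibi_values(ibi)
  n <- length(x)
  if (n < m + 2) stop("series too short for m = ", m)
  if (n < 50) warning("fewer than 50 intervals: SampEn estimate is unstable")
  if (is.null(r)) r <- r_factor * stats::sd(x)
  nt <- n - m          # number of templates compared at both lengths
  count_pairs <- function(len) {
    # Chebyshev distance between all template pairs, accumulated one
    # embedding lag at a time
    d <- matrix(0, nt, nt)
    for (k in 0:(len - 1)) {
      v <- x[(1 + k):(nt + k)]
      d <- pmax(d, abs(outer(v, v, "-")))
    }
    (sum(d <= r) - nt) / 2   # exclude self-matches, count unordered pairs
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1)
  if (A == 0 || B == 0) {
    warning("no matching templates: SampEn is NA")
    return(NA_real_)
  }
  -log(A / B)
}

#' Detrended fluctuation analysis scaling exponents
#'
#' Integrates the mean-removed series into a profile, detrends it with a
#' per-segment least-squares line at each window size, and fits the
#' log-log slope of the RMS fluctuation over the short (`alpha1`) and
#' long (`alpha2`) window ranges.
#'
#' @param ibi An `ibi_series` or numeric intervals (ms).
#' @param short_range,long_range Integer window-size ranges in beats.
#' @return List with `alpha1`, `alpha2` and the `n`/`f` fluctuation
#'   table. An exponent is `NA` with a warning when the series is too
#'   short for its range.
#' @export
dfa <- function(ibi, short_range = 4:16, long_range = 16:64) {
  x <- .ibi_values(ibi)
  N <- length(x)
  y <- cumsum(x - mean(x))
  fluct <- function(n) {
    segs <- floor(N / n)
    if (segs < 1) return(NA_real_)
    idx <- seq_len(segs * n)
    seg <- rep(seq_len(segs), each = n)
    k <- rep(seq_len(n), segs)
    res2 <- vapply(seq_len(segs), function(s) {
      yy <- y[((s - 1) * n + 1):(s * n)]
      kk <- seq_len(n)
      fit <- stats::lm.fit(cbind(1, kk), yy)
      sum(fit$residuals^2)
    }, numeric(1))
    sqrt(sum(res2) / (segs * n))
  }
  slope_over <- function(range) {
    ns <- unique(round(exp(seq(log(min(range)), log(max(range)),
                               length.out = min(10, length(range))))))
    ns <- ns[ns >= 4 & N >= 4 * ns]
    if (length(ns) < 3) {
      warning("series too short for DFA range [", min(range), ",",
              max(range), "]: alpha is NA")
      return(list(alpha = NA_real_, n = ns, f = rep(NA_real_, length(ns))))
    }
    f <- vapply(ns, fluct, numeric(1))
    if (any(f <= 0)) {
      warning("zero fluctuation (perfectly linear profile): alpha is NA")
      return(list(alpha = NA_real_, n = ns, f = f))
    }
    list(alpha = unname(stats::coef(stats::lm(log(f) ~ log(ns)))[2]), n = ns, f = f)
  }
  s <- slope_over(short_range)
  l <- slope_over(long_range)
  list(alpha1 = s$alpha, alpha2 = l$alpha,
       table = list(n = c(s$n, l$n), f = c(s$f, l$f)))
}

#' All cardiovascular-dynamics features for one analysis window
#'
#' Aggregates the time-domain, geometric, Lomb-Scargle frequency-domain
#' and nonlinear (Poincare, sample entropy, DFA) features into a single
#' named row. Flagged intervals are excluded throughout; missing values
#' propagate as `NA`, never fabricated.
#'
#' @param ibi An `ibi_series` for the analysis window.
#' @param nnx_threshold_ms,sdann_segment_s See [time_domain()].
#' @param bin_width_ms See [histogram_geometry()].
#' @param bands See [spectral_bands()].
#' @param freq Lomb-Scargle frequency grid.
#' @param sampen_m,sampen_r_factor See [sample_entropy()].
#' @param dfa_short,dfa_long See [dfa()].
#' @param min_intervals Smallest window accepted (intervals).
#' @return A one-row data frame with 17 feature columns (`mean_ibi`,
#'   `sdnn`, `sdann`, `rmssd`, `nnx`, `pnnx`, `prvti`, `tinn`, `vlf`,
#'   `lf`, `hf`, `lf_hf`, `sd1`, `sd2`, `sampen`, `alpha1`, `alpha2`).
#' @export
extract_all <- function(ibi,
                        nnx_threshold_ms = 10, sdann_segment_s = 60,
                        bin_width_ms = 7.8125,
                        bands = spectral_bands(),
                        freq = seq(0.001, 0.5, by = 0.001),
                        sampen_m = 2, sampen_r_factor = 0.2,
                        dfa_short = 4:16, dfa_long = 16:64,
                        min_intervals = 30) {
  stopifnot(inherits(ibi, "ibi_series"))
  if (sum(!ibi$flagged) < min_intervals)
    stop("analysis window has fewer than ", min_intervals, " usable intervals")
  td <- time_domain(ibi, nnx_threshold_ms, sdann_segment_s)
  gm <- histogram_geometry(ibi, bin_width_ms)
  ls <- lomb_scargle(ibi, freq = freq, bands = bands)
  pc <- poincare(ibi)
  se <- suppressWarnings(sample_entropy(ibi, m = sampen_m,
                                        r_factor = sampen_r_factor))
  df <- suppressWarnings(dfa(ibi, dfa_short, dfa_long))
  data.frame(mean_ibi = td$mean_ibi, sdnn = td$sdnn, sdann = td$sdann,
             rmssd = td$rmssd, nnx = td$nnx, pnnx = td$pnnx,
             prvti = gm$prvti, tinn = gm$tinn,
             vlf = ls$vlf, lf = ls$lf, hf = ls$hf, lf_hf = ls$lf_hf,
             sd1 = pc$sd1, sd2 = pc$sd2,
             sampen = se, alpha1 = df$alpha1, alpha2 = df$alpha2)
}
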