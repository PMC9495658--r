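# Independent oracles and small builders shared across the tests.
# These deliberately re-derive quantities from their definitions rather
# than calling the implementation under test.

# brute-force O(N^2) sample-entropy template counter
sampen_bf <- function(x, m, r) {
  n <- length(x)
  cnt <- function(len) {
    s <- 0L
    for (i in seq_len(n - m)) for (j in seq_len(n - m)) {
      if (i < j && max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r)
        s <- s + 1L
    }
    s
  }
  B <- cnt(m); A <- cnt(m + 1)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# build an ibi_series fixture carrying the interval values exactly
# (cumulating times and re-differencing would add float noise that
# breaks exact-degeneracy contracts)
make_ibi <- function(intervals_ms, start_s = 0) {
  structure(list(beat_times = start_s + c(0, cumsum(intervals_ms)) / 1000,
                 intervals = as.numeric(intervals_ms),
                 flagged = intervals_ms < 300 | intervals_ms > 2000),
            class = "ibi_series")
}

# squared-magnitude gain of the zero-phase band-pass cascade at f Hz
# (filtfilt applies |H|^2 per stage), from the transfer functions
bandpass_gain <- function(f, fs, spec = filter_spec()) {
  hmag <- function(flt) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(flt$b * z^(0:(length(flt$b) - 1))) /
          sum(flt$a * z^(0:(length(flt$a) - 1))))
  }
  lp <- signal::butter(spec$lp_order, spec$lp_cutoff / (fs / 2), "low")
  hp <- signal::butter(spec$hp_order, spec$hp_cutoff / (fs / 2), "high")
  (hmag(lp) * hmag(hp))^2
}

# quiet noise-free generator settings for deterministic-signal tests
clean_config <- function(...) {
  synth_config(noise_sd = 0, wander = c(0.03, 0), mains = c(50, 0),
               bp_noise_sd = 0, ...)
}
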