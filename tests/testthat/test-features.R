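test_that("time-domain statistics match hand arithmetic", {
  x <- c(800, 820, 790, 810)
  td <- suppressWarnings(time_domain(x))
  expect_equal(td$mean_ibi, 805)
  expect_equal(td$rmssd, sqrt((400 + 900 + 400) / 3))
  expect_equal(td$nnx, 3)
  expect_equal(td$pnnx, 100)

  const <- suppressWarnings(time_domain(rep(800, 20)))
  expect_equal(const$sdnn, 0)
  expect_equal(const$rmssd, 0)
  expect_equal(const$nnx, 0)
})

test_that("SDANN uses segment means with the 1/(M-1) normalisation", {
  # two 60-s segments with interval means 810 and 800 ms
  ibi <- make_ibi(c(rep(810, 74), rep(800, 76)))
  td <- time_domain(ibi, sdann_segment_s = 60)
  expect_equal(td$sdann, sqrt(((5)^2 + (-5)^2) / (2 - 1)), tolerance = 0.2)

  # a single segment cannot yield SDANN
  short <- make_ibi(rep(800, 20))
  expect_warning(td2 <- time_domain(short, sdann_segment_s = 60), "SDANN")
  expect_true(is.na(td2$sdann))
  expect_false(is.na(td2$sdnn))
})

test_that("histogram geometry recovers exact triangles and degenerates safely", {
  ident <- rep(800, 100)
  g <- histogram_geometry(ident, bin_width_ms = 7.8125)
  expect_equal(g$prvti, 1)
  expect_equal(g$tinn, 0)

  # an exactly triangular histogram: counts 1,2,3,2,1 over 5 bins of 10 ms.
  # The squared-error-minimising triangle has its feet one bin beyond each
  # end bin (it reproduces the counts exactly), so TINN spans 6 bins.
  tri <- rep(c(805, 815, 825, 835, 845), c(1, 2, 3, 2, 1))
  g <- histogram_geometry(tri, bin_width_ms = 10)
  expect_equal(g$prvti, 9 / 3)
  expect_equal(g$tinn, 60)

  set.seed(31)
  for (k in 1:5) {
    x <- rnorm(200, 800, 30)
    expect_gte(histogram_geometry(x)$prvti, 1)
  }
})

test_that("the Lomb-Scargle estimate matches the classical periodogram and is shift-invariant", {
  set.seed(5)
  n <- 256
  t <- (0:(n - 1)) * 0.8
  x <- rnorm(n, 800, 30)
  fj <- (1:80) / (n * 0.8)          # interior Fourier frequencies
  ls <- lomb_scargle(x, times = t, freq = fj)
  per <- (Mod(fft(x - mean(x)))^2 / n)[2:81] / var(x)
  expect_equal(ls$power, per, tolerance = 1e-6)

  ls2 <- lomb_scargle(x, times = t + 137.31, freq = fj)
  expect_equal(ls2$power, ls$power, tolerance = 1e-10)
})

test_that("an LF oscillation produces an LF spectral peak and dominant LF power", {
  cfg <- clean_config(duration = 600, lf_osc = c(0.1, 40),
                      hf_osc = c(0.25, 0), ibi_jitter_sd = 0, seed = 8)
  s <- generate_ibi_series(cfg)
  ls <- lomb_scargle(s$ibi_ms, times = s$beat_times[-1])
  expect_lt(abs(ls$freq[which.max(ls$power)] - 0.1), 0.0015)
  expect_gt(ls$lf, 10 * ls$hf)
  expect_gt(ls$lf_hf, 10)
})

test_that("Poincare descriptors follow their closed forms and guard the radicand", {
  const <- poincare(rep(800, 10))
  expect_equal(const$sd1, 0)
  expect_equal(const$sd2, 0)

  lin <- poincare(c(800, 810, 820, 830, 840))
  expect_equal(lin$sd1, 0, tolerance = 1e-9)
  expect_equal(lin$sd2, sqrt(2) * sd(c(800, 810, 820, 830, 840)))

  expect_warning(alt <- poincare(c(800, 900, 800, 900, 800)), "radicand")
  expect_true(is.na(alt$sd2))

  # identity sd1^2 + sd2^2 = 2 SD^2 wherever sd2 is defined
  set.seed(77)
  for (k in 1:20) {
    x <- rnorm(100, 800, 25)
    p <- poincare(x)
    if (!is.na(p$sd2))
      expect_equal(p$sd1^2 + p$sd2^2, 2 * sd(x)^2, tolerance = 1e-9)
  }
})

test_that("sample entropy matches the brute-force template counter", {
  expect_equal(suppressWarnings(sample_entropy(rep(800, 60))), 0)

  # 12-point alternating series, m = 2, r = 0.5
  x12 <- rep(c(1, 2), 6)
  expect_equal(suppressWarnings(sample_entropy(x12, m = 2, r = 0.5)),
               sampen_bf(x12, 2, 0.5))

  set.seed(9)
  for (k in 1:20) {
    x <- rnorm(60, 800, 30)
    r <- 0.3 * sd(x)
    mine <- suppressWarnings(sample_entropy(x, m = 2, r = r))
    ref <- sampen_bf(x, 2, r)
    if (is.na(ref)) expect_true(is.na(mine))
    else expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("sample entropy grows with added noise", {
  set.seed(13)
  base <- 800 + 50 * sin(2 * pi * (1:300) / 25)
  prev <- -Inf
  for (amp in c(1, 10, 40)) {
    se <- suppressWarnings(sample_entropy(base + rnorm(300, 0, amp)))
    expect_gte(se, prev)
    prev <- se
  }
})

test_that("DFA recovers the theoretical scaling exponents", {
  set.seed(42)
  w <- rnorm(1000)
  a_white <- dfa(w)$alpha1
  expect_gt(a_white, 0.4); expect_lt(a_white, 0.6)

  a_brown <- dfa(cumsum(w))$alpha1
  expect_gt(a_brown, 1.4); expect_lt(a_brown, 1.6)

  # scale invariance of the log-log slope
  d1 <- dfa(w); d2 <- dfa(w * 37.5)
  expect_equal(d1$alpha1, d2$alpha1, tolerance = 1e-9)
  expect_equal(d1$alpha2, d2$alpha2, tolerance = 1e-9)
})

test_that("feature aggregation respects contracts on degenerate and flagged input", {
  # constant series: variability features are zero or missing, never invented
  const <- make_ibi(rep(800, 100))
  row <- suppressWarnings(extract_all(const))
  expect_equal(row$sdnn, 0)
  expect_equal(row$rmssd, 0)
  expect_equal(row$sd1, 0)
  expect_equal(row$sampen, 0)
  expect_equal(row$prvti, 1)
  expect_true(is.na(row$alpha1))

  # features are invariant to prepending flagged (implausible) intervals
  set.seed(21)
  base <- rnorm(400, 800, 25)
  a <- make_ibi(base)
  b <- make_ibi(c(rep(100, 10), base))   # 100 ms intervals are flagged
  expect_true(all(b$flagged[1:10]))
  ra <- suppressWarnings(extract_all(a))
  rb <- suppressWarnings(extract_all(b))
  for (col in setdiff(names(ra), "sdann"))
    expect_equal(ra[[col]], rb[[col]], tolerance = 1e-12, label = col)

  expect_error(extract_all(make_ibi(rep(800, 10))), "fewer than")
})

test_that("band powers never exceed the total integrated spectrum", {
  set.seed(55)
  for (k in 1:5) {
    x <- rnorm(300, 800, 30)
    t <- cumsum(x) / 1000
    ls <- lomb_scargle(x, times = t)
    total <- sum(diff(ls$freq) * (ls$psd[-1] + ls$psd[-length(ls$psd)]) / 2)
    expect_lte(ls$vlf + ls$lf + ls$hf, total + 1e-9)
  }
})
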