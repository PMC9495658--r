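---
title: "Methods: calibrated cardiovascular dynamics for cuffless blood pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated cardiovascular dynamics for cuffless blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Continuous blood-pressure monitoring without a cuff is attractive because
the cuff is intermittent, uncomfortable, and unusable for some patients,
while the intra-arterial gold standard is invasive. `pulsecal` implements a
single-sensor approach: everything is derived from one photoplethysmogram
(PPG) channel plus a short initial window of ordinary noninvasive BP
readings used for calibration. Two independent sources of pressure
information are extracted from the PPG and then fused:

1. **Reflective pulse transit time (R-PTT).** Each arterial pulse shows a
   systolic peak followed by a smaller reflected (diastolic) peak; the
   delay between them is a within-beat surrogate for arterial transit
   time and falls as pressure rises.
2. **Cardiovascular dynamics.** The beat-to-beat variability of the
   inter-beat-interval (IBI) series carries autonomic information related
   to pressure level that is independent of within-beat morphology.

## The pressure model

Pulse-wave velocity relates to pressure through the Bramwell–Hill
relation $PWV = \sqrt{V\,\Delta P / (\rho\,\Delta V)}$ and the
Moens–Korteweg relation $PWV = \sqrt{E_{in} h / (2 \rho r)}$ with an
exponential pressure dependence of the arterial elastic modulus,
$E_{in} = E_0 e^{\gamma\,MBP}$ ($E_0 = 1428.7$, $\gamma = 0.031$
mmHg$^{-1}$, brachial-artery population averages, both exposed in
`calibration_constants()`). Folding the per-subject anatomical constants
into three calibration parameters gives the working model

$$SBP - DBP = K_a / RPTT^2, \qquad
  MBP \equiv \tfrac13 SBP + \tfrac23 DBP = K_b +
  \tfrac{2}{\gamma}\ln\!\frac{K_c}{RPTT}.$$

**Calibration closure.** One calibration window yields one equation for
the two mean-pressure parameters $(K_b, K_c)$, so they are not separately
identifiable: any pair with $K_b - (2/\gamma)\ln K_c$ constant predicts
identically. `calibrate_bp_model()` closes the system by pinning
$K_c$ at the calibration R-PTT (the log term vanishes at calibration) and
$K_b$ at the calibration mean pressure, which makes the calibration point
an exact fixed point of the model and keeps all three parameters
identifiable from a single window. `calibrate_bp_model_multi()` offers a
least-squares alternative when several calibration windows exist.
Recovery tests therefore compare *predictions*, not raw $(K_b, K_c)$.

**mPTP averaging.** Calibration uses the R-PTT averaged over the first
30 s (`mptp_average()`), not a single beat; single-beat pairing is
fragile against beat-level measurement noise. Prediction for a test
window likewise uses the window-averaged R-PTT.

## Signal processing choices

* **Filtering.** Fourth-order low-pass at 10 Hz and third-order
  Butterworth high-pass at 0.05 Hz (the low-pass family is also
  Butterworth, for a uniformly maximally-flat cascade), both applied
  forward–backward. Zero-phase filtering matters because the quantities
  of interest are *timings*; phase distortion would bias them. The
  zero-phase 0.05 Hz high-pass has a long edge transient (on the order
  of 90 s to fall below $10^{-6}$); the detectors tolerate it, but the
  first seconds of a record should not be trusted for shallow landmarks.
* **Peak detection.** Local maxima of the filtered signal gated by an
  adaptive threshold: 0.5 times the rolling 75th percentile (5 s window)
  of a 38-sample moving-average trace, with a 0.3 s refractory interval
  (caps detection at 200 beats/min). The percentile, fraction, window
  and refractory interval are conventional values, exposed in
  `detect_peaks()`. Troughs come from running the same detector on the
  inverted signal; where the inversion pass misses a trough (shallow
  prominence inside the edge transient) the between-peak minimum is
  used, so peaks and troughs always interleave.
* **IBI plausibility.** Intervals outside 300–2000 ms are flagged and
  excluded from feature windows, guarding against double detections and
  dropouts.
* **R-PTT landmarks.** Within each trough-to-trough segment the systolic
  peak is the global maximum; the most prominent local maximum of the
  (5-point-smoothed) second derivative after it marks the dicrotic
  region, and the next down-going zero crossing of the first derivative
  is the diastolic peak. The search is confined to 0.6 of the segment
  after the systolic peak so late-diastolic noise cannot masquerade as a
  reflected wave, and both peak times get parabolic sub-sample
  refinement. A pulse with no such landmark yields a missing value with
  a degraded quality flag — never a fabricated number. The rule lives in
  one function (`locate_peaks_in_pulse()`) so alternative landmark
  schemes can be swapped in.

## The sixteen dynamics features

`extract_all()` computes, per analysis window: mean IBI, SDNN, SDANN,
RMSSD, NNx, pNNx (time domain); PRVti and TINN (histogram geometry);
VLF, LF, HF power and LF/HF (Lomb–Scargle); SD1, SD2 (Poincaré), sample
entropy and DFA $\alpha_1/\alpha_2$ (nonlinear). Conventions that the
source descriptions leave open are fixed as follows:

* Sample standard deviation ($n-1$) everywhere, except where a formula
  prints its own normalisation: SDANN uses $1/(M-1)$ over segment means
  (segments default to 60 s — a 5-min convention cannot give two
  segments inside a 10-min window), and the error metric SDE uses $1/n$.
* Both SDNN (plain SD) and SDANN (segment means) are reported, since the
  two names are used interchangeably in parts of the source literature.
* NNx counts successive differences with $|\Delta IBI| >$ 10 ms — the
  NN50-family definition — not "intervals longer than a threshold".
* The VLF band is 0.0033–0.05 Hz (a printed "0.098–0.05 Hz" bound is
  inverted and unusable); LF 0.05–0.15 Hz and HF 0.15–0.5 Hz as printed.
* The Lomb–Scargle periodogram is evaluated on a 0.001–0.5 Hz grid
  (step 0.001 Hz) with the frequency-dependent offset $\tau$ that makes
  it invariant to the time origin. Band powers integrate a one-sided
  density scaled so that its integral approximates the series variance
  (ms$^2$); on uniformly sampled data the normalised estimate equals
  the classical periodogram at Fourier frequencies.
* TINN minimises the squared deviation between the IBI histogram
  (7.8125 ms = 1/128 s bins) and a triangle with its apex at the mode,
  by exhaustive search of the feet over the bin-centre grid extended one
  bin beyond the occupied range; an exactly triangular histogram is
  reproduced with zero error, and its recovered base is therefore two
  bins wider than the occupied span.
* SampEn uses $m = 2$, $r = 0.2\,SD$, Chebyshev distance, self-matches
  excluded; DFA fits $\alpha_1$ over 4–16 beats and $\alpha_2$ over
  16–64 beats. All defaults are arguments.

## Regression and evaluation

The regressor is the classical small network for this task: one sigmoid
hidden layer (ten neurons) and a linear output, trained per target (SBP,
DBP). Training approximates Bayesian-regularised backpropagation with
explicitly validated L2 weight decay: the 29-subject training pool is
split 85/15 into training and validation, features and target are
z-scored with training-split statistics only, and for each candidate
decay (0.001, 0.01, 0.1) the network trains in 10-epoch increments until
the validation loss stops improving for 20 epochs. The decay and weight
snapshot with the lowest validation loss win. The trainer sits behind a
plain interface so a literal evidence-based implementation could be
dropped in.

Evaluation is leave-one-subject-out: each subject is predicted by a
model that never saw its row — not in training, not in standardisation,
not in selection (asserted by an instrumentation test). Pooled held-out
errors are summarised as ME, MAE, and SDE (population $1/n$ form). Three
estimator variants are compared: dynamics features only, the calibrated
model only (no network), and dynamics plus the model estimates as
features. Feature subsets default to the published frozen presets
(`preset_features()`); `forward_select()` re-runs wrapper selection
(forward-greedy on 5-fold cross-validated MAE, lexicographic
tie-breaking, stopping at < 1% relative improvement — the source method
leaves the evaluator and stopping rule open) when a fresh search is
wanted.

## Sensitivity analysis

`sobol_indices()` estimates first-order ($S_i$) and total ($ST_i$)
variance-based indices with Saltelli pick-and-freeze sampling and
Jansen's estimators, on an unscrambled Sobol' sequence (Joe–Kuo
direction numbers, generated in-package since no installed library
provides one); $N$ must be a power of two. Bootstrap resampling of the
sample rows gives confidence half-widths, and the quasi-random design
makes results seed-independent except for those intervals.

The default problem (`bp_sa_problem()`) perturbs the calibrated
parameters around a nominal calibration ($K_a = 2.5$ mmHg s$^2$,
$K_b = 93.3$ mmHg, $K_c = 0.25$ s, output evaluated at R-PTT 0.22 s).
The ranges deliberately represent *calibration uncertainty* rather than
a uniform relative band: $K_a$ spans its full physiological range (1–5
mmHg s$^2$) because a single-window calibration pins it down least
reliably, $K_b$ carries cuff-level uncertainty (±5 mmHg), and $K_c$
carries one-sample timing uncertainty (±0.01 s). A uniform ±25% band
would make the result a statement about $K_b$'s larger absolute scale
rather than about calibration risk — under it $K_b$ trivially dominates
— whereas under uncertainty-weighted ranges $K_a$ ranks first and $K_c$
last for both the systolic and diastolic outputs, and the ranking is
stable across halved and doubled range widths. The model is additive in
the three parameters at fixed R-PTT, so $S_i \approx ST_i$ throughout.

## The synthetic cohort

`generate_recording()` builds PPG with known ground truth: IBIs are a
mean plus LF (0.1 Hz, 40 ms) and HF (0.25 Hz, 20 ms) sinusoidal
modulation plus 10 ms white jitter; each beat is a unit Gaussian
systolic wave plus a 0.4-amplitude reflected Gaussian delayed by the
R-PTT trajectory (default: slow ±8% drift with a 300 s period); baseline
wander (0.03 Hz), 50 Hz mains and broadband noise (2% of pulse
amplitude) are added on top. Per-beat SBP/DBP follow from the true
R-PTT through the same pressure model (plus a 2 mmHg per-beat offset
noise), so the full pipeline can be scored against exact truth.

Choices worth knowing about:

* **Ground-truth R-PTT is the realised peak separation** of the
  noiseless pulse, found by continuous optimisation — not the configured
  component delay. Superposition shifts the waveform's peaks off the
  component centres by about 1%, and R-PTT is defined on the peaks.
* **Pulse widths saturate.** Widths scale with the interval
  ($\sigma_1 = 0.08\,IBI$, $\sigma_2 = 0.12\,IBI$) up to a 0.8 s beat
  and are constant beyond, reflecting the weak rate-dependence of
  ejection duration; strictly proportional widths would merge the two
  peaks on slow beats. Configurations whose pulses have no distinct
  diastolic peak are rejected with an error rather than silently given
  fabricated truth.
* **Cohorts** (default 30 subjects, 660 s each: 30 s calibration, 600 s
  test window with a 30 s separation) draw $K_a \sim U(1, 5)$ mmHg s$^2$,
  baseline R-PTT $= K_c \sim U(0.23, 0.30)$ s, $K_b \sim N(90, 5)$
  mmHg, with mean IBI negatively coupled to $K_b$ (higher-pressure
  subjects run faster heart rates, $\approx -6$ ms/mmHg with 15 ms
  scatter) and per-subject oscillation amplitudes. A per-subject
  calibration-window reference offset ($SD = 4$ mmHg) emulates
  noninvasive cuff error at calibration time; the test-window reference
  is the clean trajectory. This is what gives the fused estimator
  something real to correct: the model inherits each subject's
  calibration error, while the dynamics features carry population-level
  pressure information.
* All randomness descends from one seed through per-subject sub-seeds;
  identical seeds give byte-identical recordings.

**What the generator does not emulate** — and what passing tests
therefore do not show about clinical data: motion and perfusion
artifacts, arrhythmia, non-stationary autonomic state, pulse-morphology
changes other than the reflected-wave delay, drifts between the
calibration and test windows that are uncoupled from R-PTT, and any
real relation between HRV indices and pressure beyond the built-in
heart-rate coupling. On the synthetic cohort the calibrated model is
substantially more accurate than it is on clinical recordings; the
three-way comparison should be read as an ordering, not as attainable
clinical error.

## Problem sizes

The shipped evaluation uses a 30-subject cohort at 660 s per subject
(100 Hz), Sobol estimation at $N = 1024$ base samples (5120 model
evaluations per output), and 1000-draw round-trip property checks; the
whole acceptance computation completes in well under a minute of CPU
after cohort feature extraction (~15 s).

## Known limitations

* The $(K_b, K_c)$ closure is one defensible choice among a
  one-parameter family; only predictions are identifiable from a single
  calibration window.
* The diastolic-landmark rule is a concrete reading of the
  second-derivative method; heavily damped reflected waves yield missing
  values, and subjects with baseline R-PTT near the bimodality limit
  measure with a few-ms positive bias.
* SDANN over 60 s segments is not comparable to 5-min-segment SDANN
  from long recordings.
* The ANN operates on 29-row training sets; its LOSO variance is
  non-trivial, and with an already-accurate model path the fused
  estimator is a near-tie with the model-only estimator rather than a
  uniform improvement.
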