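#' Fixed arterial elasticity constants
#'
#' Population-average brachial-artery values: elastic modulus at zero
#' pressure `e0 = 1428.7` (model units) and pressure coefficient
#' `gamma = 0.031` 1/mmHg. They are config-visible because they are
#' population averages, not universal constants.
#'
#' @param e0 Elastic modulus at zero pressure (> 0).
#' @param gamma Vessel pressure coefficient (1/mmHg, > 0).
#' @return Object of class `calibration_constants`.
#' @export
calibration_constants <- function(e0 = 1428.7, gamma = 0.031) {
  stopifnot(e0 > 0, gamma > 0)
  structure(list(e0 = e0, gamma = gamma), class = "calibration_constants")
}

#' Calibrated blood-pressure model parameters
#'
#' @param ka Pulse-pressure coefficient (mmHg s^2, > 0).
#' @param kb Mean-pressure offset (mmHg).
#' @param kc Reference R-PTT (s, > 0).
#' @param constants A [calibration_constants()].
#' @return Object of class `bp_model_params`.
#' @export
bp_model_params <- function(ka, kb, kc, constants = calibration_constants()) {
  stopifnot(ka > 0, kc > 0)
  structure(list(ka = ka, kb = kb, kc = kc, constants = constants),
            class = "bp_model_params")
}

#' @export
print.bp_model_params <- function(x, ...) {
  cat(sprintf("<bp_model_params> ka=%.4g mmHg.s^2  kb=%.4g mmHg  kc=%.4g s  (e0=%g, gamma=%g)\n",
              x$ka, x$kb, x$kc, x$constants$e0, x$constants$gamma))
  invisible(x)
}

#' Calibrate the pressure model from one initial window
#'
#' Inverts the pulse-pressure relation `SBP - DBP = ka / rptt^2` to get
#' `ka = (sbp - dbp) * rptt^2`, and closes the under-determined mean
#' pressure relation by fixing `kc` at the calibration R-PTT (so the
#' log term vanishes at calibration) and `kb` at the calibration mean
#' pressure `(sbp + 2*dbp)/3`. Predictions at the calibration R-PTT
#' then reproduce the calibration pressures exactly.
#'
#' @param sbp_cal,dbp_cal Window-averaged noninvasive SBP/DBP (mmHg),
#'   `sbp_cal > dbp_cal > 0`.
#' @param rptt_cal Window-averaged R-PTT (s, > 0); see [mptp_average()].
#' @param constants A [calibration_constants()].
#' @return A [bp_model_params()].
#' @export
calibrate_bp_model <- function(sbp_cal, dbp_cal, rptt_cal,
                               constants = calibration_constants()) {
  if (!is.finite(sbp_cal) || !is.finite(dbp_cal) || sbp_cal <= dbp_cal || dbp_cal <= 0)
    stop("calibration requires sbp_cal > dbp_cal > 0")
  if (!is.finite(rptt_cal) || rptt_cal <= 0)
    stop("calibration requires rptt_cal > 0")
  bp_model_params(ka = (sbp_cal - dbp_cal) * rptt_cal^2,
                  kb = (sbp_cal + 2 * dbp_cal) / 3,
                  kc = rptt_cal,
                  constants = constants)
}

#' Multi-window least-squares calibration
#'
#' When several calibration windows with paired (SBP, DBP, R-PTT)
#' averages are available: `ka` from a no-intercept regression of the
#' pulse pressure on `1/rptt^2`, `kc` as the geometric-mean R-PTT, and
#' `kb` from the mean-pressure residual at that `kc`.
#'
#' @param sbp,dbp,rptt Equal-length vectors of window averages.
#' @param constants A [calibration_constants()].
#' @return A [bp_model_params()].
#' @export
calibrate_bp_model_multi <- function(sbp, dbp, rptt,
                                     constants = calibration_constants()) {
  stopifnot(length(sbp) == length(dbp), length(dbp) == length(rptt),
            length(sbp) >= 2, all(rptt > 0), all(sbp > dbp))
  z <- 1 / rptt^2
  ka <- sum((sbp - dbp) * z) / sum(z^2)
  kc <- exp(mean(log(rptt)))
  mbp <- (sbp + 2 * dbp) / 3
  kb <- mean(mbp - (2 / constants$gamma) * log(kc / rptt))
  bp_model_params(ka = ka, kb = kb, kc = kc, constants = constants)
}

#' Predict SBP, DBP and MBP from R-PTT
#'
#' Mean pressure `mbp = kb + (2/gamma) * log(kc/rptt)`; diastolic
#' pressure subtracts one third of the pulse pressure,
#' `dbp = mbp - ka/(3*rptt^2)`; systolic adds the full pulse pressure,
#' `sbp = dbp + ka/rptt^2`. The identity `mbp = (sbp + 2*dbp)/3` holds
#' by construction.
#'
#' @param rptt R-PTT values in seconds (vectorised, all > 0).
#' @param params A [bp_model_params()].
#' @return Data frame with columns `sbp`, `dbp`, `mbp` (mmHg).
#' @export
predict_bp <- function(rptt, params) {
  stopifnot(inherits(params, "bp_model_params"))
  if (any(!is.finite(rptt)) || any(rptt <= 0))
    stop("rptt must be positive and finite")
  g <- params$constants$gamma
  mbp <- params$kb + (2 / g) * log(params$kc / rptt)
  dbp <- mbp - params$ka / (3 * rptt^2)
  sbp <- dbp + params$ka / rptt^2
  data.frame(sbp = sbp, dbp = dbp, mbp = mbp)
}

#' Pulse wave velocity reference relations
#'
#' Reference implementations of the physical relations whose constants
#' the calibrated parameters absorb: the Bramwell-Hill form
#' `PWV = sqrt(V * dP / (rho * dV))` and the Moens-Korteweg form
#' `PWV = sqrt(Ein * h / (2 * rho * r))` with the exponential
#' pressure-dependent elastic modulus `Ein = e0 * exp(gamma * MBP)`.
#' They document the model's physical basis; none of them is needed for
#' calibration or prediction, whose units are absorbed into
#' `ka`, `kb`, `kc`.
#'
#' @param volume Arterial blood volume.
#' @param density Blood density.
#' @param dp Pulse pressure (SBP - DBP).
#' @param dv Corresponding volume change.
#' @return Pulse wave velocity.
#' @export
pwv_bramwell_hill <- function(volume, density, dp, dv) {
  stopifnot(volume > 0, density > 0, dp > 0, dv > 0)
  sqrt(volume * dp / (density * dv))
}

#' @rdname pwv_bramwell_hill
#' @param ein Incremental elastic modulus.
#' @param h Arterial wall thickness.
#' @param radius Arterial radius.
#' @export
pwv_moens_korteweg <- function(ein, h, density, radius) {
  stopifnot(ein > 0, h > 0, density > 0, radius > 0)
  sqrt(ein * h / (2 * density * radius))
}

#' @rdname pwv_bramwell_hill
#' @param mbp Mean blood pressure (mmHg).
#' @param constants A [calibration_constants()].
#' @export
elastic_modulus <- function(mbp, constants = calibration_constants()) {
  constants$e0 * exp(constants$gamma * mbp)
}
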