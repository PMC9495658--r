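#' Full-run configuration
#'
#' Gathers every stage's tunables with their defaults: a 30 s initial
#' calibration window, a 600 s test window taken from the end of the
#' recording (maximally separated from calibration), and the filter,
#' feature, model and ANN settings of the individual modules.
#'
#' @param cal_window_s Calibration window length from record start (s).
#' @param test_window_s Test window length, taken from the record end (s).
#' @param filter A [filter_spec()].
#' @param bands A [spectral_bands()].
#' @param nnx_threshold_ms,sdann_segment_s,bin_width_ms,sampen_m,sampen_r_factor
#'   Feature-extraction tunables (see [extract_all()]).
#' @param plausibility_ms IBI plausibility window (ms), see [to_ibi()].
#' @param ann An [ann_spec()].
#' @param constants A [calibration_constants()].
#' @param min_cal_beats Minimum usable beats for [mptp_average()].
#' @param seed Master seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cal_window_s = 30, test_window_s = 600,
                       filter = filter_spec(), bands = spectral_bands(),
                       nnx_threshold_ms = 10, sdann_segment_s = 60,
                       bin_width_ms = 7.8125,
                       sampen_m = 2, sampen_r_factor = 0.2,
                       plausibility_ms = c(300, 2000),
                       ann = ann_spec(),
                       constants = calibration_constants(),
                       min_cal_beats = 5,
                       seed = 1) {
  stopifnot(cal_window_s > 0, test_window_s > 0)
  structure(list(cal_window_s = cal_window_s, test_window_s = test_window_s,
                 filter = filter, bands = bands,
                 nnx_threshold_ms = nnx_threshold_ms,
                 sdann_segment_s = sdann_segment_s,
                 bin_width_ms = bin_width_ms,
                 sampen_m = sampen_m, sampen_r_factor = sampen_r_factor,
                 plausibility_ms = plausibility_ms,
                 ann = ann, constants = constants,
                 min_cal_beats = min_cal_beats, seed = seed),
            class = "run_config")
}

.stage <- function(name, subject, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] stage '%s' failed: %s", subject, name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Process one subject end to end
#'
#' Detect beats, build the IBI series, extract the dynamics features
#' over the test window, measure per-beat R-PTT, calibrate the pressure
#' model from the window-averaged R-PTT and reference BP over the
#' calibration window, and predict model SBP/DBP at the window-averaged
#' R-PTT of the test window. The targets are the reference SBP/DBP
#' averaged over the whole test window.
#'
#' @param rec A `ppg_recording` with a reference BP channel, covering
#'   both windows.
#' @param config A [run_config()].
#' @return One-row data frame: `subject`, the 17 feature columns,
#'   `model_sbp`, `model_dbp`, `true_sbp`, `true_dbp`; the stage log
#'   (beats detected/flagged, R-PTT yield, calibration values) is in
#'   the `"log"` attribute.
#' @export
run_subject <- function(rec, config = run_config()) {
  stopifnot(inherits(rec, "ppg_recording"), inherits(config, "run_config"))
  subject <- rec$subject
  dur <- recording_duration(rec)
  if (dur < config$cal_window_s + config$test_window_s)
    stop(sprintf("[%s] recording (%.0f s) shorter than calibration + test windows (%.0f s)",
                 subject, dur, config$cal_window_s + config$test_window_s))
  if (is.null(rec$ref_bp))
    stop(sprintf("[%s] no reference BP channel: cannot calibrate", subject))
  cal_win <- c(0, config$cal_window_s)
  test_win <- c(dur - config$test_window_s, dur)

  ann <- .stage("detect", subject, detect_peaks(rec, spec = config$filter))
  ibi <- .stage("ibi", subject, to_ibi(ann, config$plausibility_ms))
  ibi_test <- .stage("ibi", subject, window_ibi(ibi, test_win))
  feats <- .stage("features", subject, extract_all(
    ibi_test,
    nnx_threshold_ms = config$nnx_threshold_ms,
    sdann_segment_s = config$sdann_segment_s,
    bin_width_ms = config$bin_width_ms,
    bands = config$bands,
    sampen_m = config$sampen_m, sampen_r_factor = config$sampen_r_factor))
  rpt <- .stage("rptt", subject, measure_rptt(rec, ann))
  rptt_cal <- .stage("calibrate", subject,
                     mptp_average(rpt, cal_win, config$min_cal_beats))
  ref <- rec$ref_bp
  in_cal <- ref$time >= cal_win[1] & ref$time <= cal_win[2]
  if (sum(in_cal) < 1)
    stop(sprintf("[%s] no reference BP inside the calibration window", subject))
  params <- .stage("calibrate", subject, calibrate_bp_model(
    mean(ref$sbp[in_cal]), mean(ref$dbp[in_cal]), rptt_cal,
    config$constants))
  rptt_test <- .stage("predict", subject,
                      mptp_average(rpt, test_win, config$min_cal_beats))
  est <- predict_bp(rptt_test, params)
  in_test <- ref$time >= test_win[1] & ref$time <= test_win[2]
  if (sum(in_test) < 1)
    stop(sprintf("[%s] no reference BP inside the test window", subject))
  row <- cbind(data.frame(subject = subject), feats,
               data.frame(model_sbp = est$sbp, model_dbp = est$dbp,
                          true_sbp = mean(ref$sbp[in_test]),
                          true_dbp = mean(ref$dbp[in_test])))
  attr(row, "log") <- list(
    subject = subject,
    n_peaks = length(ann$peak_times),
    n_flagged = sum(ibi$flagged),
    rptt_yield = mean(rpt$quality == "ok"),
    rptt_cal = rptt_cal, rptt_test = rptt_test,
    params = params)
  row
}

#' Build the cohort feature table
#'
#' Applies [run_subject()] to every recording; per-subject failures are
#' logged and excluded, and the run continues while at least 3 subjects
#' remain.
#'
#' @param cohort A `synth_cohort`, or a list of `ppg_recording`s.
#' @param config A [run_config()].
#' @return Feature table (one row per subject) with the per-subject
#'   stage logs in the `"logs"` attribute and any failures in
#'   `"failures"`.
#' @export
cohort_feature_table <- function(cohort, config = run_config()) {
  recs <- if (inherits(cohort, "synth_cohort"))
    lapply(cohort$recordings, `[[`, "recording") else cohort
  rows <- list(); logs <- list(); failures <- character(0)
  for (i in seq_along(recs)) {
    r <- tryCatch(run_subject(recs[[i]], config), error = function(e) e)
    if (inherits(r, "error")) {
      failures <- c(failures, conditionMessage(r))
      message("skipping subject ", i, ": ", conditionMessage(r))
    } else {
      logs[[length(logs) + 1]] <- attr(r, "log")
      attr(r, "log") <- NULL
      rows[[length(rows) + 1]] <- r
    }
  }
  if (length(rows) < 3)
    stop("fewer than 3 subjects processed successfully")
  tab <- do.call(rbind, rows)
  attr(tab, "logs") <- logs
  attr(tab, "failures") <- failures
  tab
}

#' Run the three-way cohort comparison
#'
#' Evaluates SBP and DBP under the three estimation modes -- dynamics
#' features only, calibrated model only, and dynamics plus model -- by
#' leave-one-subject-out cross-validation.
#'
#' @param cohort A `synth_cohort`, list of recordings, or a
#'   pre-computed feature table from [cohort_feature_table()].
#' @param config A [run_config()].
#' @return Object of class `cohort_results`: the feature `table` and a
#'   named list `results` of six `eval_result`s
#'   (`sbp_dynamics`, ..., `dbp_dynamics+model`).
#' @export
run_cohort <- function(cohort, config = run_config()) {
  tab <- if (is.data.frame(cohort)) cohort else cohort_feature_table(cohort, config)
  modes <- c("dynamics", "model", "dynamics+model")
  results <- list()
  for (target in c("sbp", "dbp")) {
    for (mode in modes) {
      spec <- config$ann
      spec$seed <- config$seed
      results[[paste(target, mode, sep = "_")]] <-
        loso_evaluate(tab, target, mode, spec)
    }
  }
  structure(list(table = tab, results = results, config = config),
            class = "cohort_results")
}

#' @export
print.cohort_results <- function(x, ...) {
  cat(sprintf("<cohort_results> %d subjects\n", nrow(x$table)))
  df <- comparison_table(x)
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Three-way comparison table
#' @param x A `cohort_results`.
#' @return Data frame: target, mode, ME, SDE, MAE (mmHg).
#' @export
comparison_table <- function(x) {
  stopifnot(inherits(x, "cohort_results"))
  do.call(rbind, lapply(x$results, function(r)
    data.frame(target = toupper(r$target), mode = r$mode,
               me = r$me, sde = r$sde, mae = r$mae)))
}
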