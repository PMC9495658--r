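#' Blood-pressure error metrics
#'
#' Mean error, mean absolute error, and the standard deviation of the
#' error with the population (1/n) normalisation.
#'
#' @param predictions,truths Equal-length mmHg vectors.
#' @return List with `me`, `mae`, `sde` and the per-case `errors`.
#' @export
bp_metrics <- function(predictions, truths) {
  if (length(predictions) == 0 || length(predictions) != length(truths))
    stop("predictions and truths must be equal-length, non-empty")
  e <- predictions - truths
  list(me = mean(e),
       mae = mean(abs(e)),
       sde = sqrt(mean((e - mean(e))^2)),
       errors = e)
}

#' ANN regressor specification
#'
#' Two-layer feed-forward network: one sigmoid hidden layer (default
#' ten neurons) and a linear output. Trained with L2 weight decay whose
#' strength is chosen on the validation split, plus validation-based
#' early stopping; this regularised training stands behind the same
#' interface as any other trainer, so a different weight-penalty scheme
#' can be dropped in.
#'
#' @param hidden_units Hidden-layer size.
#' @param decay_grid Candidate L2 weight-decay strengths.
#' @param max_epochs Training-epoch budget.
#' @param patience Early-stopping patience in epochs.
#' @param chunk Epochs between validation checks.
#' @param seed Seed controlling the split and the initial weights.
#' @return Object of class `ann_spec`.
#' @export
ann_spec <- function(hidden_units = 10, decay_grid = c(0.001, 0.01, 0.1),
                     max_epochs = 300, patience = 20, chunk = 10, seed = 1) {
  stopifnot(hidden_units >= 1, max_epochs >= 1, patience >= 1, chunk >= 1)
  structure(list(hidden_units = hidden_units, decay_grid = decay_grid,
                 max_epochs = max_epochs, patience = patience,
                 chunk = chunk, seed = seed),
            class = "ann_spec")
}

#' Train the ANN regressor
#'
#' Splits rows into training and validation (default 85/15), z-scores
#' features and target with training-split statistics only, and for
#' each candidate weight decay trains the network incrementally,
#' checking the validation loss every few epochs and stopping once it
#' has failed to improve within the patience window. The decay (and
#' weight snapshot) with the lowest validation loss wins. Deterministic
#' under the spec seed.
#'
#' @param X Numeric feature matrix (rows = cases).
#' @param y Numeric target.
#' @param spec An [ann_spec()].
#' @param validation_fraction Fraction of rows held out for validation.
#' @return Object of class `pulsecal_ann` with a `predict` method;
#'   `$history` records the per-check validation loss.
#' @export
train_ann <- function(X, y, spec = ann_spec(), validation_fraction = 0.15) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 10) stop("need at least 10 rows to train")
  if (stats::sd(y) == 0) {
    warning("degenerate target (zero variance): returning a constant predictor")
    return(structure(list(constant = y[1], history = NULL,
                          features = colnames(X)),
                     class = "pulsecal_ann"))
  }
  set.seed(spec$seed)
  n_val <- max(1L, round(validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  mu <- colMeans(X[tr_idx, , drop = FALSE])
  sg <- apply(X[tr_idx, , drop = FALSE], 2, stats::sd)
  sg[sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  ym <- mean(y[tr_idx]); ys <- stats::sd(y[tr_idx]); if (ys == 0) ys <- 1
  yz <- (y - ym) / ys
  nw <- (ncol(X) + 1) * spec$hidden_units + (spec$hidden_units + 1)
  best <- list(loss = Inf)
  history <- list()
  for (decay in spec$decay_grid) {
    wts <- stats::runif(nw, -0.5, 0.5)
    best_d <- Inf; stale <- 0; epochs <- 0
    losses <- numeric(0)
    while (epochs < spec$max_epochs) {
      fit <- nnet::nnet(Z[tr_idx, , drop = FALSE], yz[tr_idx],
                        size = spec$hidden_units, linout = TRUE,
                        decay = decay, maxit = spec$chunk, Wts = wts,
                        trace = FALSE)
      wts <- fit$wts
      epochs <- epochs + spec$chunk
      vloss <- mean((stats::predict(fit, Z[val_idx, , drop = FALSE]) - yz[val_idx])^2)
      losses <- c(losses, vloss)
      if (vloss < best_d - 1e-10) {
        best_d <- vloss; stale <- 0
        if (vloss < best$loss) {
          best <- list(loss = vloss, fit = fit, decay = decay)
        }
      } else {
        stale <- stale + spec$chunk
        if (stale >= spec$patience) break
      }
    }
    history[[as.character(decay)]] <- losses
  }
  structure(list(fit = best$fit, decay = best$decay,
                 center = mu, scale = sg, y_center = ym, y_scale = ys,
                 val_loss = best$loss, history = history,
                 features = colnames(X)),
            class = "pulsecal_ann")
}

#' @export
predict.pulsecal_ann <- function(object, newdata, ...) {
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(as.matrix(newdata))))
  Z <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  as.numeric(stats::predict(object$fit, Z)) * object$y_scale + object$y_center
}

# k-fold cross-validated MAE of an evaluator on a candidate feature set
.cv_mae <- function(X, y, folds, evaluator) {
  preds <- numeric(length(y))
  for (f in unique(folds)) {
    te <- which(folds == f); tr <- which(folds != f)
    preds[te] <- evaluator(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE])
  }
  mean(abs(preds - y))
}

# default wrapper evaluator: ordinary least squares
.lm_evaluator <- function(Xtr, ytr, Xte) {
  df <- as.data.frame(Xtr); df$.y <- ytr
  fit <- stats::lm(.y ~ ., data = df)
  as.numeric(stats::predict(fit, as.data.frame(Xte)))
}

#' Wrapper forward-greedy feature selection
#'
#' Starts from the empty set and at each step adds the candidate whose
#' addition most reduces the k-fold cross-validated MAE of the
#' evaluator, stopping when no addition improves the running best by
#' more than `tol` (a fraction of the intercept-only baseline MAE).
#' Candidates are scanned in lexicographic order, which also breaks
#' ties; the fold assignment is drawn once under `seed`, so reruns with
#' the same seed reproduce the same subset.
#'
#' @param table Data frame containing candidate columns and the target.
#' @param target Name of the target column.
#' @param candidates Candidate feature names (default: every numeric
#'   column except the target and any `true_*` column).
#' @param evaluator `function(Xtrain, ytrain, Xtest) -> predictions`;
#'   defaults to an ordinary least-squares fit.
#' @param k_folds Cross-validation folds.
#' @param tol Minimum relative improvement to accept a feature.
#' @param seed Seed for the fold assignment.
#' @return Character vector of selected features, in selection order,
#'   with the per-step MAE as the `"mae_path"` attribute.
#' @export
forward_select <- function(table, target, candidates = NULL,
                           evaluator = .lm_evaluator,
                           k_folds = 5, tol = 0.01, seed = 1) {
  if (is.null(candidates)) {
    candidates <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          c(target, grep("^true_", names(table), value = TRUE)))
  }
  if (length(candidates) < 2) stop("need at least 2 candidate features")
  candidates <- sort(candidates)
  y <- table[[target]]
  complete <- stats::complete.cases(table[, c(candidates, target)])
  if (!all(complete)) {
    message(sum(!complete), " row(s) with missing candidate features excluded")
    table <- table[complete, ]; y <- y[complete]
  }
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k_folds), length(y)))
  baseline <- .cv_mae(matrix(1, length(y), 1), y, folds,
                      function(Xtr, ytr, Xte) rep(mean(ytr), nrow(Xte)))
  selected <- character(0)
  best_mae <- baseline
  path <- numeric(0)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    maes <- vapply(remaining, function(cand) {
      .cv_mae(as.matrix(table[, c(selected, cand), drop = FALSE]), y,
              folds, evaluator)
    }, numeric(1))
    i <- which.min(maes)  # lexicographic tie-break: remaining is sorted
    if (maes[i] >= best_mae - tol * baseline) break
    selected <- c(selected, remaining[i])
    best_mae <- maes[i]
    path <- c(path, best_mae)
  }
  attr(selected, "mae_path") <- path
  attr(selected, "baseline_mae") <- baseline
  selected
}

#' Published feature presets
#'
#' The frozen feature subsets selected by the original wrapper search
#' on the clinical data, reusable on new data without re-running
#' selection: SBP dynamics-only NNx, alpha1, LF, HF; DBP dynamics-only
#' SDNN, RMSSD, SD1, LF, alpha1; with the model estimate added, SampEn,
#' alpha1 and the systolic model estimate for SBP, and SampEn, HF and
#' the diastolic model estimate for DBP.
#'
#' @param target `"sbp"` or `"dbp"`.
#' @param mode `"dynamics"` or `"dynamics+model"`.
#' @return Character vector of column names.
#' @export
preset_features <- function(target = c("sbp", "dbp"),
                            mode = c("dynamics", "dynamics+model")) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  switch(paste(target, mode),
         "sbp dynamics" = c("nnx", "alpha1", "lf", "hf"),
         "dbp dynamics" = c("sdnn", "rmssd", "sd1", "lf", "alpha1"),
         "sbp dynamics+model" = c("sampen", "alpha1", "model_sbp"),
         "dbp dynamics+model" = c("sampen", "hf", "model_dbp"))
}

#' Leave-one-subject-out evaluation
#'
#' For each subject: hold that subject out, train the ANN on the
#' remaining rows (with its internal 85/15 train/validation split and
#' early stopping), predict the held-out subject, and pool all held-out
#' errors into [bp_metrics()]. Mode `"model"` bypasses the ANN and
#' scores the calibrated-model estimates (`model_sbp`/`model_dbp`)
#' directly. The held-out row never contributes to standardisation,
#' selection or training.
#'
#' @param table Feature table: one row per subject with the dynamics
#'   features, `model_sbp`/`model_dbp` and targets
#'   `true_sbp`/`true_dbp`.
#' @param target `"sbp"` or `"dbp"`.
#' @param mode `"dynamics"`, `"model"` or `"dynamics+model"`.
#' @param spec An [ann_spec()].
#' @param features Feature columns to use; defaults to the
#'   [preset_features()] for the target/mode.
#' @param select If `TRUE`, re-run [forward_select()] inside each
#'   training fold instead of using `features`.
#' @return Object of class `eval_result`: `me`, `mae`, `sde`,
#'   per-subject `errors` and `predictions`, `features`, `mode`,
#'   `target`.
#' @export
loso_evaluate <- function(table, target = c("sbp", "dbp"),
                          mode = c("dynamics", "model", "dynamics+model"),
                          spec = ann_spec(), features = NULL,
                          select = FALSE) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  n <- nrow(table)
  if (n < 3) stop("need at least 3 subjects")
  truth_col <- paste0("true_", target)
  model_col <- paste0("model_", target)
  if (!truth_col %in% names(table)) stop("missing column ", truth_col)
  y <- table[[truth_col]]
  if (mode == "model") {
    if (!model_col %in% names(table)) stop("missing column ", model_col)
    preds <- table[[model_col]]
    m <- bp_metrics(preds, y)
    return(structure(c(m, list(predictions = preds, features = model_col,
                               mode = mode, target = target, n = n)),
                     class = "eval_result"))
  }
  if (is.null(features))
    features <- preset_features(target, if (mode == "dynamics") "dynamics" else "dynamics+model")
  missing_cols <- setdiff(features, names(table))
  if (length(missing_cols) > 0)
    stop("feature mode references missing columns: ",
         paste(missing_cols, collapse = ", "))
  drop <- !stats::complete.cases(table[, c(features, truth_col)])
  if (any(drop)) {
    message("excluding ", sum(drop), " subject(s) with missing features: ",
            paste(rownames(table)[drop], collapse = ", "))
    table <- table[!drop, ]; y <- y[!drop]; n <- nrow(table)
    if (n < 3) stop("fewer than 3 subjects remain after exclusions")
  }
  preds <- numeric(n)
  used <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    feats_i <- features
    if (select) {
      feats_i <- forward_select(table[rest, ], truth_col,
                                candidates = features, seed = spec$seed + i)
      if (length(feats_i) == 0) feats_i <- features
    }
    fold_spec <- spec
    fold_spec$seed <- spec$seed + i
    fit <- train_ann(table[rest, feats_i, drop = FALSE], y[rest], fold_spec)
    preds[i] <- predict(fit, table[i, feats_i, drop = FALSE])
    used[[i]] <- feats_i
  }
  m <- bp_metrics(preds, y)
  structure(c(m, list(predictions = preds, features = features,
                      features_per_fold = if (select) used else NULL,
                      mode = mode, target = target, n = n)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s / %s (n=%d): ME %.2f  MAE %.2f  SDE %.2f mmHg\n",
              toupper(x$target), x$mode, x$n, x$me, x$mae, x$sde))
  invisible(x)
}
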