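test_that("error metrics match hand arithmetic and their identities", {
  z <- bp_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(z$me, z$mae, z$sde), c(0, 0, 0))

  off <- bp_metrics(c(4, 5, 6), c(1, 2, 3))
  expect_equal(c(off$me, off$mae, off$sde), c(3, 3, 0))

  m <- bp_metrics(c(120, 130, 110), c(118, 135, 111))
  expect_equal(m$me, -4 / 3, tolerance = 1e-9)
  expect_equal(m$mae, 8 / 3, tolerance = 1e-9)
  expect_equal(m$sde, sqrt((sum(c(2, -5, -1)^2) - 3 * (4 / 3)^2) / 3),
               tolerance = 1e-9)
  expect_equal(round(m$sde, 4), 2.8674)

  expect_error(bp_metrics(numeric(0), numeric(0)), "non-empty")
  expect_error(bp_metrics(1:3, 1:4), "equal-length")

  # |me| <= mae and sde^2 + me^2 = MSE under the 1/n convention
  set.seed(66)
  for (k in 1:100) {
    p <- rnorm(20, 100, 10); tr <- rnorm(20, 100, 10)
    m <- bp_metrics(p, tr)
    expect_lte(abs(m$me), m$mae)
    expect_equal(m$sde^2 + m$me^2, mean((p - tr)^2), tolerance = 1e-9)
  }
})

test_that("the ANN learns a noiseless linear map and is deterministic", {
  set.seed(3)
  X <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  y <- 2 * X[, 1]
  fit <- train_ann(X, y, ann_spec(seed = 4))
  set.seed(99)
  Xn <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  rmse <- sqrt(mean((predict(fit, Xn) - 2 * Xn[, 1])^2))
  expect_lt(rmse, 0.05 * sd(y))

  fit2 <- train_ann(X, y, ann_spec(seed = 4))
  expect_identical(fit$fit$wts, fit2$fit$wts)
  expect_identical(predict(fit, Xn), predict(fit2, Xn))

  # early stopping leaves a bounded training history
  spec <- ann_spec(seed = 4, max_epochs = 200, patience = 20, chunk = 10)
  fit3 <- train_ann(X, y + rnorm(50, 0, 0.5), spec)
  for (h in fit3$history)
    expect_lte(length(h), spec$max_epochs / spec$chunk)

  expect_warning(cfit <- train_ann(X, rep(5, 50)), "degenerate")
  expect_equal(predict(cfit, Xn), rep(5, 30))
  expect_error(train_ann(X[1:5, ], y[1:5]), "at least 10")
})

test_that("forward selection finds the informative feature and stops on noise", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    tab <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60),
                      d = rnorm(60), e = rnorm(60))
    tab$y <- 3 * tab$a + rnorm(60, 0, 0.3)
    sel <- forward_select(tab, "y", candidates = c("a", "b", "c", "d", "e"),
                          seed = s)
    if (length(sel) > 0 && sel[1] == "a") hits <- hits + 1
  }
  expect_gte(hits, 18)

  # pure noise: empty or single-feature selection
  for (s in 1:5) {
    set.seed(s + 100)
    tab <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50),
                      y = rnorm(50))
    sel <- forward_select(tab, "y", candidates = c("a", "b", "c"), seed = s)
    expect_lte(length(sel), 1)
  }

  # reproducibility under the seed
  set.seed(1)
  tab <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  tab$y <- tab$a - 2 * tab$b + rnorm(60, 0, 0.2)
  s1 <- forward_select(tab, "y", candidates = c("a", "b", "c"), seed = 5)
  s2 <- forward_select(tab, "y", candidates = c("a", "b", "c"), seed = 5)
  expect_identical(as.character(s1), as.character(s2))
})

test_that("leave-one-subject-out evaluation honours its partition contract", {
  set.seed(12)
  n <- 12
  tab <- data.frame(
    sampen = rnorm(n, 1.5, 0.3), hf = rnorm(n, 200, 50),
    alpha1 = rnorm(n, 1, 0.2),
    model_sbp = rnorm(n, 120, 10), model_dbp = rnorm(n, 80, 6))
  tab$true_sbp <- tab$model_sbp + rnorm(n, 0, 2)
  tab$true_dbp <- tab$model_dbp + rnorm(n, 0, 2)

  r <- loso_evaluate(tab, "sbp", "model")
  expect_length(r$errors, n)
  expect_equal(r$predictions, tab$model_sbp)

  spec <- ann_spec(seed = 2, max_epochs = 60)
  r2 <- loso_evaluate(tab, "dbp", "dynamics+model", spec)
  expect_length(r2$predictions, n)
  expect_equal(r2$features, preset_features("dbp", "dynamics+model"))

  expect_error(loso_evaluate(tab[1:2, ], "sbp", "model"), "at least 3")
  expect_error(loso_evaluate(tab, "sbp", "dynamics"), "missing columns")
})

test_that("held-out subjects never leak into training or standardisation", {
  set.seed(40)
  n <- 15
  tab <- data.frame(sampen = rnorm(n), hf = rnorm(n),
                    model_dbp = rnorm(n, 80, 5))
  tab$true_dbp <- tab$model_dbp + rnorm(n)
  spec <- ann_spec(seed = 3, max_epochs = 40)
  base <- loso_evaluate(tab, "dbp", "dynamics+model", spec)
  # the held-out subject's target is only ever used for scoring: changing
  # it must leave that subject's own prediction untouched (it would not
  # if the row leaked into training or standardisation)
  for (i in c(1, 8)) {
    tab2 <- tab
    tab2$true_dbp[i] <- tab2$true_dbp[i] + 500
    r <- loso_evaluate(tab2, "dbp", "dynamics+model", spec)
    expect_equal(r$predictions[i], base$predictions[i], tolerance = 1e-12)
    expect_false(isTRUE(all.equal(r$errors[i], base$errors[i])))
  }
})

test_that("preset feature sets match the published selections", {
  expect_setequal(preset_features("sbp", "dynamics"),
                  c("nnx", "alpha1", "lf", "hf"))
  expect_setequal(preset_features("dbp", "dynamics"),
                  c("sdnn", "rmssd", "sd1", "lf", "alpha1"))
  expect_setequal(preset_features("sbp", "dynamics+model"),
                  c("sampen", "alpha1", "model_sbp"))
  expect_setequal(preset_features("dbp", "dynamics+model"),
                  c("sampen", "hf", "model_dbp"))
})
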