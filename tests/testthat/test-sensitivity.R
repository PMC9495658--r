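test_that("the Sobol sequence has its defining low-discrepancy structure", {
  X <- sobol_sequence(15, 5)
  # first point is the hypercube centre; coordinates stay in (0, 1)
  expect_equal(X[1, ], rep(0.5, 5))
  expect_true(all(X > 0 & X < 1))
  # together with the (skipped) origin, the first dyadic block is a
  # stratified grid: every interval [j/16, (j+1)/16) holds exactly one
  # of the 16 points in every dimension
  blk <- rbind(rep(0, 5), X)
  for (d in 1:5)
    expect_setequal(floor(blk[, d] * 16), 0:15)
})

test_that("problem validation enforces the sampling-scheme requirements", {
  f <- function(p) p[["a"]]
  expect_error(sa_problem("a", 0, 1, f, n = 100), "power of 2")
  expect_error(sa_problem("a", 0, 1, f, n = 32), "power of 2")
  expect_error(sa_problem("a", 1, 1, f, n = 64), "non-degenerate")
  expect_s3_class(sa_problem("a", 0, 1, f, n = 64), "sa_problem")
})

test_that("a single active factor takes the whole variance", {
  pr <- sa_problem(c("x1", "x2", "x3"), rep(0, 3), rep(1, 3),
                   function(p) p[["x1"]], n = 256)
  r <- sobol_indices(pr, n_boot = 20)
  expect_lt(abs(r$si[[1]] - 1), 0.02)
  expect_lt(abs(r$sti[[1]] - 1), 0.02)
  expect_lt(max(abs(r$si[2:3])), 0.02)
  expect_lt(max(abs(r$sti[2:3])), 0.02)
})

test_that("the additive two-factor model matches its closed-form decomposition", {
  pr <- sa_problem(c("x1", "x2"), c(0, 0), c(1, 1),
                   function(p) p[["x1"]] + 2 * p[["x2"]], n = 1024)
  r <- sobol_indices(pr, n_boot = 20)
  # Var = 1/12 + 4/12; S1 = 0.2, S2 = 0.8; STi = Si for additive models
  expect_lt(max(abs(r$si - c(0.2, 0.8))), 0.03)
  expect_lt(max(abs(r$sti - c(0.2, 0.8))), 0.03)
  expect_lte(sum(r$si), 1 + 0.05)
})

test_that("the Ishigami benchmark reproduces its analytic indices", {
  ish <- function(p) sin(p[["x1"]]) + 7 * sin(p[["x2"]])^2 +
    0.1 * p[["x3"]]^4 * sin(p[["x1"]])
  pr <- sa_problem(c("x1", "x2", "x3"), rep(-pi, 3), rep(pi, 3), ish,
                   n = 1024)
  r <- sobol_indices(pr, n_boot = 50)
  # analytic: S = (0.3139, 0.4424, 0); ST3 = 0.2437 (pure interaction)
  expect_lt(abs(r$si[[1]] - 0.3139), 0.03)
  expect_lt(abs(r$si[[2]] - 0.4424), 0.03)
  expect_lt(abs(r$si[[3]]), 0.03)
  expect_gt(unname(r$sti[3]), 0.2)
  # totals dominate first-order indices up to estimator noise
  expect_true(all(r$sti >= r$si - 0.02))
})

test_that("estimates are seed-deterministic and converge with the sample size", {
  ish <- function(p) sin(p[["x1"]]) + 7 * sin(p[["x2"]])^2 +
    0.1 * p[["x3"]]^4 * sin(p[["x1"]])
  pr <- function(n) sa_problem(c("x1", "x2", "x3"), rep(-pi, 3), rep(pi, 3),
                               ish, n = n, seed = 42)
  a <- sobol_indices(pr(512), n_boot = 100)
  b <- sobol_indices(pr(512), n_boot = 100)
  expect_identical(a$si, b$si)
  expect_identical(a$si_ci, b$si_ci)

  big <- sobol_indices(pr(1024), n_boot = 100)
  expect_true(all(abs(big$si - a$si) <= pmax(a$si_ci, 0.02)))
})

test_that("non-finite model output is reported with the offending sample", {
  pr <- sa_problem(c("a", "b"), c(0, 0), c(1, 1),
                   function(p) if (p[["a"]] > 0.9) NaN else p[["a"]],
                   n = 64)
  expect_error(sobol_indices(pr, n_boot = 5), "non-finite")
})

test_that("parameter ranking orders by total index with flagged ties", {
  r <- structure(list(si = c(a = 0.65, b = 0.18, c = 0.08),
                      sti = c(a = 0.7, b = 0.2, c = 0.1)),
                 class = "sa_result")
  rk <- rank_parameters(r)
  expect_equal(rk$parameter, c("a", "b", "c"))
  expect_equal(rk$rank_sti, 1:3)

  tied <- structure(list(si = c(b = 0.5, a = 0.5), sti = c(b = 0.5, a = 0.5)),
                    class = "sa_result")
  expect_warning(rk2 <- rank_parameters(tied), "ties")
  expect_equal(rk2$parameter, c("a", "b"))
  expect_true(any(rk2$tied))
})

test_that("the pressure model is most sensitive to ka and least to kc", {
  for (out in c("sbp", "dbp")) {
    r <- sobol_indices(bp_sa_problem(out, n = 512), n_boot = 20)
    rk <- rank_parameters(r)
    expect_equal(rk$parameter[1], "ka")
    expect_equal(rk$parameter[3], "kc")
    expect_true(all(r$sti >= r$si - 0.02))
  }
})
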