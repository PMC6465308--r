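# reaction-coordinate model, likelihood, Monte Carlo fit, calibration

test_that("committor model identities", {
  expect_equal(committor_model(0), 0.5)
  expect_equal(committor_model(50), 1)
  q <- seq(-6, 6, by = 0.17)
  expect_equal(committor_model(q) + committor_model(-q), rep(1, length(q)),
               tolerance = 1e-15)
  expect_true(all(diff(committor_model(q)) > 0))
})

test_that("log-likelihood matches hand values and the per-shot oracle", {
  m0 <- rc_model(c(0, 0), "q1")
  one <- data.frame(q1 = 0.3, n_to_A = 0L, n_to_B = 1L)
  expect_equal(rc_log_likelihood(m0, one), log(0.5))
  bal <- data.frame(q1 = rnorm(4), n_to_A = c(2L, 3L, 1L, 4L),
                    n_to_B = c(2L, 3L, 1L, 4L))
  expect_equal(rc_log_likelihood(m0, bal), sum(bal$n_to_A + bal$n_to_B) * log(0.5))
  expect_error(rc_log_likelihood(m0, data.frame(q1 = 1, n_to_A = 0L, n_to_B = 0L)),
               "no committed")
  set.seed(14)
  for (rep in 1:5) {
    m <- rc_model(rnorm(3), c("q1", "q2"), center = rnorm(2),
                  scale = runif(2, 0.5, 2))
    rec <- data.frame(q1 = rnorm(6), q2 = rnorm(6),
                      n_to_A = rpois(6, 3), n_to_B = rpois(6, 3))
    rec$n_to_A[1] <- rec$n_to_A[1] + 1L    # guarantee a committed shot
    expect_equal(rc_log_likelihood(m, rec), oracle_log_likelihood(m, rec),
                 tolerance = 1e-10)
  }
})

test_that("prediction composes standardization, linear map and committor", {
  m <- rc_model(c(0, 1.2, -0.4), c("a", "b"), center = c(2, -1),
                scale = c(3, 0.5))
  expect_equal(rc_predict(m, c(2, -1)), 0.5)
  expect_error(rc_predict(m, c(1, 2, 3)), "dimensionality")
  set.seed(15)
  qs <- matrix(rnorm(200), ncol = 2)
  manual <- committor_model(0 + 1.2 * (qs[, 1] - 2) / 3 +
                              (-0.4) * (qs[, 2] + 1) / 0.5)
  expect_equal(rc_predict(m, qs), manual, tolerance = 1e-12)
  # monotone in a positive-coefficient descriptor
  grid <- cbind(seq(-5, 5, 0.5), 0)
  expect_true(all(diff(rc_predict(m, grid)) > 0))
})

test_that("null records give slope coefficients within 2 s.d. of zero", {
  truth <- rc_model(c(0, 0, 0), c("q1", "q2"))
  rec <- gen_shooting_records(truth, 100, 10, seed = 16)
  fit <- rc_fit(rec, c("q1", "q2"), n_steps = 1500, n_restarts = 3,
                n_boot = 60, boot_steps = 250, seed = 17)
  for (j in 2:3)
    expect_lte(abs(fit$model$coefficients[j]), 2 * fit$model$uncertainties[j])
})

test_that("likelihood maximum is invariant to affine descriptor rescaling", {
  truth <- rc_model(c(0.3, 1.5, -0.5), c("q1", "q2"))
  rec <- gen_shooting_records(truth, 120, 10, seed = 18)
  rec2 <- rec
  rec2$q1 <- 100 * rec2$q1 - 7       # affine change of the raw descriptor
  f1 <- rc_fit(rec, c("q1", "q2"), n_steps = 2000, n_restarts = 3,
               n_boot = 0, seed = 19)
  f2 <- rc_fit(rec2, c("q1", "q2"), n_steps = 2000, n_restarts = 3,
               n_boot = 0, seed = 19)
  # empirical standardization absorbs the affine map, so the maximized
  # likelihood and standardized coefficients agree to optimizer tolerance
  expect_equal(f1$model$coefficients, f2$model$coefficients, tolerance = 0.02)
  expect_equal(f1$report$log_likelihood, f2$report$log_likelihood,
               tolerance = 1e-4)
  # likelihood-scaling invariance of the argmax: duplicating every record
  # doubles log L at any fixed model, leaving the optimum in place
  expect_equal(rc_log_likelihood(f1$model, rbind(rec, rec)),
               2 * rc_log_likelihood(f1$model, rec), tolerance = 1e-12)
  f3 <- rc_fit(rbind(rec, rec), c("q1", "q2"), n_steps = 2000, n_restarts = 3,
               n_boot = 0, seed = 19)
  raw <- function(f) f$model$coefficients[-1] / f$model$scale
  expect_equal(raw(f3), raw(f1), tolerance = 0.02)
})

test_that("the reported optimum dominates every restart", {
  truth <- rc_model(c(0, 1, 0), c("q1", "q2"))
  rec <- gen_shooting_records(truth, 80, 8, seed = 20)
  fit <- rc_fit(rec, c("q1", "q2"), n_steps = 800, n_restarts = 4,
                n_boot = 0, seed = 21)
  expect_true(all(fit$report$log_likelihood >= fit$report$restart_optima - 1e-12))
  expect_equal(fit$report$log_likelihood,
               rc_log_likelihood(fit$model, rec), tolerance = 1e-12)
})

test_that("coefficient error shrinks as shots per point grow (10 -> 100)", {
  truth <- rc_model(c(0, 1.5), "q1")
  err <- sapply(c(10, 100), function(spp) {
    vapply(1:8, function(r) {
      rec <- gen_shooting_records(truth, 60, spp, seed = 500 + r)
      fit <- rc_fit(rec, "q1", n_steps = 1200, n_restarts = 2, n_boot = 0,
                    seed = 600 + r)
      abs(fit$model$coefficients[2] - 1.5)
    }, 0)
  })
  expect_lt(median(err[, 2]), median(err[, 1]))
})

test_that("separation is flagged and capped", {
  rec <- data.frame(q1 = c(-2, -1, 1, 2), n_to_A = c(5L, 5L, 0L, 0L),
                    n_to_B = c(0L, 0L, 5L, 5L))
  expect_warning(fit <- rc_fit(rec, "q1", n_steps = 4000, n_restarts = 2,
                               n_boot = 0, cap = 8, seed = 22),
                 "separation")
  expect_lte(max(abs(fit$model$coefficients)), 8)
  expect_true(fit$report$separated)
})

test_that("calibration table, coverage and edge cases", {
  expect_identical(nrow(rc_calibrate(rc_model(c(0, 1), "q1"),
                                     data.frame(q1 = 1, n_to_A = 0L,
                                                n_to_B = 0L))$table), 0L)
  # constant phi = 0.5 model against extreme observed committors
  const <- rc_model(c(0, 0), "q1")
  rec <- data.frame(q1 = rnorm(10),
                    n_to_A = rep(c(19L, 1L), 5), n_to_B = rep(c(1L, 19L), 5))
  cal <- rc_calibrate(const, rec)
  expect_gt(cal$rmse, 0.3)
  expect_equal(cal$table$observed, rep(c(0.05, 0.95), 5))
})
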