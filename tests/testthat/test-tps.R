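# two-segment shooting: commitment, conjugate pairs, stitching, committor

test_that("commitment detection is first-passage with the contracted edge cases", {
  eng <- toy_engine()
  r <- run_until_committed(engine_state(c(-1, 0)), eng$potential, eng$states,
                           100, eng$dt, eng$friction, eng$temperature)
  expect_identical(r$outcome, "to_A")
  expect_identical(r$steps_to_commit, 0L)
  expect_identical(nrow(r$segment), 1L)
  # one step from the saddle cannot reach a basin 0.8 away
  r1 <- run_until_committed(engine_state(c(0, 0), c(0.5, 0)), eng$potential,
                            eng$states, 1, eng$dt, 0, 0)
  expect_identical(r1$outcome, "uncommitted")
  expect_true(is.na(r1$steps_to_commit))
})

test_that("deep-well starts at low temperature return home", {
  eng <- toy_engine()
  outcomes <- vapply(1:100, function(i) {
    v0 <- draw_mb_velocities(1, 0.2, n = 2, seed = 100 + i)
    run_until_committed(engine_state(c(-1, 0), v0), eng$potential,
                        eng$states, 2000, eng$dt, eng$friction,
                        temperature = 0.2, seed = 200 + i,
                        record = FALSE)$outcome
  }, "")
  expect_gte(mean(outcomes == "to_A"), 0.99)
})

test_that("conjugate pairs stitch into continuous A-to-B paths", {
  eng <- toy_engine()
  n_path <- 0; max_seam <- 0; max_intra <- 0
  for (i in 1:40) {
    res <- shoot_pair(engine_state(c(0, 0)), eng$potential, eng$states,
                      eng$max_steps, eng$dt, eng$friction, eng$temperature,
                      seed = i)
    oo <- c(res$forward$outcome, res$backward$outcome)
    if (is.null(res$path)) {
      expect_false(all(c("to_A", "to_B") %in% oo))
      next
    }
    n_path <- n_path + 1
    p <- res$path
    m <- sum(p$provenance == "backward"); n <- sum(p$provenance == "forward")
    expect_identical(nrow(p$frames), m + n + 1L)
    expect_identical(p$provenance[p$shooting_index], "shooting_point")
    expect_true(all(diff(p$times) > 0))
    expect_identical(p$endpoints, c("A", "B"))
    expect_lte(p$frames[1, 1], -0.8)
    expect_gte(p$frames[nrow(p$frames), 1], 0.8)
    expect_true(p$shooting_index > 1 && p$shooting_index < nrow(p$frames))
    # interior frames reach neither basin before the terminal frames
    interior <- p$frames[-c(1, nrow(p$frames)), 1]
    expect_true(all(interior > -0.8 & interior < 0.8))
    # stitched continuity: the seam jump is an ordinary integration step
    jumps <- sqrt(rowSums((p$frames[-1, , drop = FALSE] -
                             p$frames[-nrow(p$frames), , drop = FALSE])^2))
    seam <- jumps[c(p$shooting_index - 1L, p$shooting_index)]
    max_seam <- max(max_seam, seam)
    max_intra <- max(max_intra, jumps[-c(p$shooting_index - 1L,
                                         p$shooting_index)])
    # every toy transition path crosses the barrier window (shooting range)
    expect_true(any(abs(p$frames[, 1]) <= 0.5))
  }
  expect_gt(n_path, 5)
  expect_lte(max_seam, max_intra)
})

test_that("stitching validates its contract", {
  eng <- toy_engine()
  res <- shoot_pair(engine_state(c(-0.95, 0)), eng$potential, eng$states,
                    500, eng$dt, eng$friction, temperature = 0.3, seed = 1)
  # at low temperature near the A basin both segments return to A
  expect_identical(res$forward$outcome, "to_A")
  expect_identical(res$backward$outcome, "to_A")
  expect_null(res$path)
  expect_error(stitch(res$forward, res$backward, engine_state(c(-0.95, 0))),
               "opposite")
})

test_that("committor estimation applies the exclusion rule", {
  mk <- function(nB, nA, nU) c(rep("to_B", nB), rep("to_A", nA),
                               rep("uncommitted", nU))
  est <- estimate_committor(mk(15, 15, 0))
  expect_equal(est$phi_B, 0.5)
  expect_identical(est$n_committed, 30L)
  est <- estimate_committor(mk(10, 10, 10))
  expect_equal(est$phi_B, 0.5)
  expect_identical(est$n_committed, 20L)
  expect_identical(est$n_uncommitted, 10L)
  expect_error(estimate_committor(mk(0, 0, 5)), "no committed")
})

test_that("shooting range is the union of occluded and connected", {
  expect_identical(in_shooting_range(c("occluded", "inward", "connected",
                                       "outward")),
                   c(TRUE, FALSE, TRUE, FALSE))
  expect_error(in_shooting_range("limbo"), "unknown")
})

test_that("path weights are exact rationals with exact chaining", {
  expect_identical(path_weight_ratio(4, 2), 2)
  expect_identical(path_weight_ratio(7, 7), 1)
  expect_error(path_weight_ratio(1, 0), "degenerate")
  set.seed(13)
  for (rep in 1:20) {
    ns <- sample(1:50, 8, replace = TRUE)
    ratios <- path_weight_ratio(ns[-length(ns)], ns[-1])
    expect_lt(abs(sum(log(ratios)) - log(prod(ratios))), 1e-12)
    expect_equal(prod(ratios), ns[1] / ns[length(ns)], tolerance = 1e-14)
  }
})

test_that("shooting-point selection: uniform draw and model-targeted argmin", {
  eng <- toy_engine()
  res <- NULL
  for (i in 1:50) {
    res <- shoot_pair(engine_state(c(0, 0)), eng$potential, eng$states,
                      eng$max_steps, eng$dt, eng$friction, eng$temperature,
                      seed = 1000 + i)
    if (!is.null(res$path)) break
  }
  p <- res$path
  in_range <- abs(p$frames[, 1]) <= 0.5
  s1 <- select_shooting_points(p, in_range, 5, seed = 3)
  s2 <- select_shooting_points(p, in_range, 5, seed = 3)
  expect_identical(s1, s2)
  expect_length(s1, 5L)
  expect_true(all(in_range[s1]))
  expect_warning(empty <- select_shooting_points(p, rep(FALSE, nrow(p$frames)), 3),
                 "no frames")
  expect_length(empty, 0L)
  # model route: exhaustive |Q| scan oracle
  model <- rc_model(c(0.2, 1.5), "x")
  sel <- select_shooting_points(p, in_range, 3, model = model,
                                descriptor_fn = function(x) c(x = x[1]))
  Q <- 0.2 + 1.5 * p$frames[, 1]
  Q[!in_range] <- Inf
  expect_identical(sort(sel), sort(which(in_range)[order(abs(Q[in_range]))[1:3]]))
})
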