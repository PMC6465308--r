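# rigid-body superposition, rotation angle/axis extraction, domain motion

test_that("superposition recovers exact rigid transforms", {
  expect_fit <- function(fit, R, t) {
    expect_lt(max(abs(fit$rotation - R)), 1e-8)
    expect_lt(max(abs(fit$translation - t)), 1e-8)
  }
  set.seed(1)
  X <- matrix(runif(30, -5, 5), ncol = 3)
  fit <- superpose(X, X)
  expect_fit(fit, diag(3), c(0, 0, 0))
  expect_lt(fit$rmsd, 1e-12)

  fit <- superpose(X, sweep(X, 2, c(1, 2, 3), `+`))
  expect_fit(fit, diag(3), c(1, 2, 3))
  expect_lt(fit$rmsd, 1e-12)

  R <- oracle_rodrigues(c(0, 0, 1), 30); t <- c(-2, 0.5, 7)
  fit <- superpose(X, sweep(X %*% t(R), 2, t, `+`))
  expect_fit(fit, R, t)
  expect_lt(fit$rmsd, 1e-10)
})

test_that("degenerate point sets and reflection-optimal cases are handled", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line + 1), "degenerate|collinear")
  # reference is a mirror image: best orthogonal map is a reflection, but
  # the fit must still return a proper rotation
  set.seed(2)
  X <- matrix(rnorm(24), ncol = 3)
  Y <- X; Y[, 3] <- -Y[, 3]
  fit <- superpose(X, Y)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("fitted transforms are local RMSD minima", {
  set.seed(3)
  for (case in 1:10) {
    X <- matrix(runif(30, -5, 5), ncol = 3)
    Y <- sweep(X %*% t(random_rotation()), 2, rnorm(3), `+`) +
      matrix(rnorm(30, sd = 0.1), ncol = 3)
    fit <- superpose(X, Y)
    for (p in 1:20) {
      Rp <- fit$rotation %*% oracle_rodrigues(rnorm(3), runif(1, 0.1, 1))
      tp <- fit$translation + rnorm(3, sd = 0.01)
      expect_gte(transform_rmsd(X, Y, Rp, tp), fit$rmsd - 1e-12)
    }
  }
})

test_that("angle/axis extraction inverts the axis-angle construction", {
  expect_equal(rotation_angle(diag(3)), 0)
  expect_equal(rotation_angle(oracle_rodrigues(c(0, 0, 1), 10)), 10,
               tolerance = 1e-10)
  expect_equal(rotation_angle(oracle_rodrigues(c(0, 0, 1), -10)), 10,
               tolerance = 1e-10)
  expect_equal(rotation_axis(oracle_rodrigues(c(0, 0, 1), -10)),
               c(0, 0, -1), tolerance = 1e-10)
  expect_equal(rotation_axis(oracle_rodrigues(c(1, 1, 1), 90)),
               rep(1, 3) / sqrt(3), tolerance = 1e-8)
  expect_error(rotation_axis(diag(3)), "undefined")
  expect_error(rotation_axis(oracle_rodrigues(c(1, 0, 0), 180)), "undefined")
  expect_error(rotation_angle(matrix(2 * diag(3), 3)), "not a proper rotation")

  set.seed(4)
  for (i in 1:200) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 1, 179)
    R <- oracle_rodrigues(ax, ang)
    expect_lt(abs(rotation_angle(R) - ang), 1e-8)
    expect_lt(max(abs(rotation_axis(R) - ax)), 1e-8)
  }
})

test_that("rotation_matrix agrees with the independent Rodrigues oracle", {
  set.seed(5)
  for (i in 1:50) {
    ax <- rnorm(3); ang <- runif(1, 0, 180)
    expect_lt(max(abs(rotation_matrix(ax, ang) - oracle_rodrigues(ax, ang))),
              1e-12)
  }
})

test_that("domain motion honours its averaging conventions", {
  f <- gen_fixture(fixture_spec(2, 8, "occluded", 6, 6))
  sel <- f$selections
  # frame vs itself as both references: everything zero
  dm <- domain_motion(f$frame, f$frame, f$frame, sel$dimer, sel$transporter)
  expect_lt(abs(dm$dphi_in), 1e-8)
  expect_lt(abs(dm$dz_in), 1e-12)
  expect_equal(dm$dphi, 0)
  # identical references: dphi = (x - x)/2 = 0 whatever the frame
  dm2 <- domain_motion(f$frame, f$ref_in, f$ref_in, sel$dimer, sel$transporter)
  expect_equal(dm2$dphi, 0)
  expect_equal(dm2$dz, dm2$dz_in)
  # averaging identities
  dm3 <- domain_motion(f$frame, f$ref_in, f$ref_out, sel$dimer, sel$transporter)
  expect_equal(dm3$dphi, (dm3$dphi_in - dm3$dphi_out) / 2)
  expect_equal(dm3$dz, (dm3$dz_in + dm3$dz_out) / 2)
  # both rotation routes agree on rigid fixtures
  dm4 <- domain_motion(f$frame, f$ref_in, f$ref_out, sel$dimer,
                       sel$transporter, rotation_route = "direct")
  expect_equal(dm4$dphi_in, dm3$dphi_in, tolerance = 1e-8)
})

test_that("domain motion is invariant to consistent atom permutations", {
  f <- gen_fixture(fixture_spec(3.1, 12, "occluded", 6, 6))
  sel <- f$selections
  dm <- domain_motion(f$frame, f$ref_in, f$ref_out, sel$dimer, sel$transporter)
  set.seed(6)
  perm <- sample(nrow(f$frame$coordinates))
  permute <- function(fr) {
    fr$coordinates <- fr$coordinates[perm, , drop = FALSE]
    fr$atoms <- fr$atoms[perm, ]
    fr
  }
  inv <- order(perm)
  psel <- function(s) atom_selection(s$name, inv[s$indices])
  dmp <- domain_motion(permute(f$frame), permute(f$ref_in), permute(f$ref_out),
                       psel(sel$dimer), psel(sel$transporter))
  expect_equal(dmp$dphi, dm$dphi, tolerance = 1e-10)
  expect_equal(dmp$dz, dm$dz, tolerance = 1e-10)
})

test_that("average_structure averages after superposition", {
  f <- gen_fixture(fixture_spec(0, 0, "occluded", 6, 6))
  fr <- f$frame
  expect_equal(average_structure(list(fr), 1)$coordinates, fr$coordinates)
  shifted <- fr; shifted$coordinates <- sweep(fr$coordinates, 2, c(3, -1, 2), `+`)
  avg <- average_structure(list(fr, shifted), 1:2)
  expect_equal(avg$coordinates, fr$coordinates, tolerance = 1e-10)
  expect_error(average_structure(list(fr), integer(0)), "non-empty")
  # Monte Carlo: noisy copies average towards the truth
  set.seed(7)
  noisy <- lapply(1:10, function(i) {
    g <- fr; g$coordinates <- fr$coordinates + matrix(rnorm(length(fr$coordinates), sd = 0.1),
                                                     ncol = 3)
    g
  })
  avg <- average_structure(noisy, 1:10)
  fitted <- apply_fit(avg$coordinates, superpose(avg$coordinates, fr$coordinates))
  rms <- sqrt(mean(rowSums((fitted - fr$coordinates)^2)))
  expect_lt(rms, 3 * 0.1 * sqrt(3) / sqrt(10))
})
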