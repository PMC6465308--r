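#' Tanh committor model
#'
#' \eqn{\phi_B(Q) = [1 + \tanh(Q)]/2}: the assumed committor to the
#' outward-open state B as a function of the linear reaction coordinate Q.
#' Strictly increasing, with \eqn{\phi_B(0) = 1/2} and
#' \eqn{\phi_B(Q) + \phi_B(-Q) = 1}.
#'
#' @param Q reaction-coordinate value(s).
#' @return probability in (0, 1).
#' @export
committor_model <- function(Q) (1 + tanh(Q)) / 2

#' Linear reaction-coordinate model
#'
#' \eqn{Q = a_0 + \sum_i a_i q_i} on standardized descriptors: each raw
#' descriptor is centred and scaled by the stored constants before the
#' coefficients apply, so coefficient magnitudes are comparable across
#' descriptors.
#'
#' @param coefficients numeric length K+1: intercept a0 then one slope per
#'   descriptor.
#' @param descriptors character names of the K descriptors.
#' @param center,scale standardization constants per descriptor
#'   (`scale > 0`).
#' @param uncertainties optional s.d. per coefficient (length K+1).
#' @return object of class `rc_model`.
#' @export
rc_model <- function(coefficients, descriptors,
                     center = rep(0, length(descriptors)),
                     scale = rep(1, length(descriptors)),
                     uncertainties = NULL) {
  k <- length(descriptors)
  if (length(coefficients) != k + 1L)
    stop("need K+1 coefficients for K descriptors")
  if (length(center) != k || length(scale) != k)
    stop("standardization constants must match the descriptors")
  if (any(scale <= 0)) stop("scales must be positive")
  if (!is.null(uncertainties) && length(uncertainties) != k + 1L)
    stop("uncertainties must match the coefficients")
  structure(list(coefficients = as.numeric(coefficients),
                 descriptors = as.character(descriptors),
                 center = as.numeric(center), scale = as.numeric(scale),
                 uncertainties = uncertainties),
            class = "rc_model")
}

#' @export
print.rc_model <- function(x, ...) {
  cat("<rc_model> Q = a0 + sum a_i q_i (standardized descriptors)\n")
  u <- if (is.null(x$uncertainties)) rep(NA_real_, length(x$coefficients))
       else x$uncertainties
  lab <- c("(intercept)", x$descriptors)
  for (i in seq_along(x$coefficients))
    cat(sprintf("  %-14s a%-2d = %8.4f  (s.d. %s)\n", lab[i], i - 1L,
                x$coefficients[i],
                if (is.na(u[i])) "-" else sprintf("%.4f", u[i])))
  invisible(x)
}

# internal: standardized descriptor matrix from a records data.frame
rc_design <- function(model, records) {
  q <- as.matrix(records[, model$descriptors, drop = FALSE])
  sweep(sweep(q, 2, model$center), 2, model$scale, `/`)
}

#' Reaction-coordinate value of descriptor vectors
#'
#' @param model an [rc_model()].
#' @param q descriptor vector, matrix (rows = points) or data.frame with
#'   the model's descriptor columns.
#' @return Q value(s).
#' @export
rc_value <- function(model, q) {
  if (is.data.frame(q)) {
    Z <- rc_design(model, q)
  } else {
    q <- if (is.matrix(q)) q else matrix(q, nrow = 1)
    if (ncol(q) != length(model$descriptors))
      stop("descriptor dimensionality does not match the model")
    Z <- sweep(sweep(q, 2, model$center), 2, model$scale, `/`)
  }
  as.numeric(model$coefficients[1] + Z %*% model$coefficients[-1])
}

#' Predicted committor of descriptor vectors
#'
#' @inheritParams rc_value
#' @return probability of reaching B first.
#' @export
rc_predict <- function(model, q) committor_model(rc_value(model, q))

# probability floor inside logs: keeps the likelihood finite under
# (near-)complete separation while preserving the ordering of models
RC_PROB_FLOOR <- 1e-12

#' Log-likelihood of shooting outcomes
#'
#' Eq.-style binomial log-likelihood of committed shooting outcomes under
#' the tanh committor model:
#' \eqn{\log L = \sum_{r \to B} \log \phi_B[Q(r)] +
#'      \sum_{r \to A} \log\{1 - \phi_B[Q(r)]\}}.
#' Uncommitted shots are excluded; the per-record counts `n_to_A`,
#' `n_to_B` expand shot multiplicities. Probabilities are clipped at
#' 1e-12 inside the logs.
#'
#' @param model an [rc_model()].
#' @param records data.frame with the model's descriptor columns plus
#'   `n_to_A` and `n_to_B`.
#' @return scalar log-likelihood.
#' @export
rc_log_likelihood <- function(model, records) {
  if (sum(records$n_to_A + records$n_to_B) < 1)
    stop("records contain no committed shots")
  p <- committor_model(rc_value(model, records))
  p <- pmin(1 - RC_PROB_FLOOR, pmax(RC_PROB_FLOOR, p))
  sum(records$n_to_B * log(p) + records$n_to_A * log(1 - p))
}

# internal: greedy Monte Carlo maximization with adaptive Gaussian proposals,
# optionally followed by a Metropolis phase at unit "temperature"
rc_mc_search <- function(obj, a0, n_steps, step0, cap, metropolis_steps = 0L) {
  a <- a0; best <- a; f <- obj(a); fbest <- f; s <- step0
  trace_len <- 0L
  for (i in seq_len(n_steps)) {
    prop <- a + stats::rnorm(length(a), sd = s)
    prop <- pmax(-cap, pmin(cap, prop))
    fp <- obj(prop)
    if (fp >= f) {
      a <- prop; f <- fp; s <- min(s * 1.1, 2)
      trace_len <- trace_len + 1L
      if (f > fbest) { fbest <- f; best <- a }
    } else {
      s <- max(s * 0.98, 1e-4)
    }
  }
  for (i in seq_len(metropolis_steps)) {
    prop <- pmax(-cap, pmin(cap, a + stats::rnorm(length(a), sd = s)))
    fp <- obj(prop)
    if (log(stats::runif(1)) < fp - f) { a <- prop; f <- fp }
    if (f > fbest) { fbest <- f; best <- a }
  }
  list(par = best, value = fbest, accepted = trace_len)
}

#' Fit the reaction coordinate by Monte Carlo likelihood maximization
#'
#' Standardizes the chosen descriptors (empirical mean / s.d.), then runs a
#' restarted greedy Monte Carlo search with adaptive Gaussian proposals in
#' coefficient space to maximize [rc_log_likelihood()]. Coefficient
#' uncertainties are, by default, standard deviations over bootstrap
#' resamples of the shooting records (warm-started refits).
#'
#' @param records data.frame of shooting records: descriptor columns plus
#'   `n_to_A`, `n_to_B` (and optionally `n_uncommitted`, ignored here).
#' @param descriptors character subset of descriptor column names.
#' @param n_steps greedy MC steps per restart.
#' @param n_restarts independent restarts (>= 1; default 5).
#' @param step0 initial proposal s.d.
#' @param metropolis_steps optional Metropolis phase length after the
#'   greedy phase of each restart.
#' @param cap coefficient magnitude bound; hitting it flags (near-)complete
#'   separation.
#' @param n_boot bootstrap resamples for the uncertainties (0 disables).
#' @param boot_steps greedy steps per bootstrap refit.
#' @param seed integer seed.
#' @return list with `model` (an [rc_model()] including uncertainties) and
#'   `report`: final log-likelihood, per-restart optima, accepted-move
#'   counts, separation flag.
#' @export
rc_fit <- function(records, descriptors, n_steps = 3000, n_restarts = 5,
                   step0 = 0.3, metropolis_steps = 0L, cap = 20,
                   n_boot = 200, boot_steps = 400, seed = NULL) {
  if (nrow(records) < 2) stop("need at least two shooting records")
  if (all(records$n_to_B == 0) || all(records$n_to_A == 0))
    warning("all committed shots share one outcome; fit is weakly determined")
  ctr <- vapply(records[descriptors], mean, 0)
  scl <- vapply(records[descriptors], stats::sd, 0)
  degenerate <- !is.finite(scl) | scl <= 0
  if (any(degenerate)) {
    warning("descriptor(s) with zero variance standardized with scale 1: ",
            paste(descriptors[degenerate], collapse = ", "))
    scl[degenerate] <- 1
  }
  base <- rc_model(rep(0, length(descriptors) + 1L), descriptors, ctr, scl)
  make_obj <- function(rec) {
    Z <- rc_design(base, rec); nB <- rec$n_to_B; nA <- rec$n_to_A
    function(a) {
      p <- committor_model(a[1] + as.numeric(Z %*% a[-1]))
      p <- pmin(1 - RC_PROB_FLOOR, pmax(RC_PROB_FLOOR, p))
      sum(nB * log(p) + nA * log(1 - p))
    }
  }
  with_seed_or_current(seed, {
    obj <- make_obj(records)
    fits <- lapply(seq_len(max(1L, n_restarts)), function(r) {
      a0 <- stats::rnorm(length(descriptors) + 1L, sd = 0.5)
      rc_mc_search(obj, a0, n_steps, step0, cap, metropolis_steps)
    })
    vals <- vapply(fits, `[[`, 0, "value")
    best <- fits[[which.max(vals)]]
    separated <- any(abs(best$par) >= cap - 1e-9)
    if (separated)
      warning("coefficients capped at |a| = ", cap,
              ": (near-)complete separation of outcomes")
    unc <- NULL
    if (n_boot > 0) {
      boots <- matrix(NA_real_, nrow = n_boot, ncol = length(best$par))
      for (b in seq_len(n_boot)) {
        idx <- sample.int(nrow(records), replace = TRUE)
        rb <- records[idx, , drop = FALSE]
        if (sum(rb$n_to_A) == 0 || sum(rb$n_to_B) == 0) {
          idx <- sample.int(nrow(records), replace = TRUE)
          rb <- records[idx, , drop = FALSE]
        }
        boots[b, ] <- rc_mc_search(make_obj(rb), best$par, boot_steps,
                                   step0 / 3, cap)$par
      }
      unc <- apply(boots, 2, stats::sd, na.rm = TRUE)
    }
    model <- rc_model(best$par, descriptors, ctr, scl, uncertainties = unc)
    list(model = model,
         report = list(log_likelihood = best$value,
                       restart_optima = vals,
                       accepted_moves = vapply(fits, `[[`, 0L, "accepted"),
                       separated = separated))
  })
}

#' Predicted-vs-observed committor calibration
#'
#' For validation shooting points with repeated shots, compares the model's
#' predicted committor with the observed fraction of committed shots
#' reaching B, with a binomial 95% check: the observed count is covered
#' when it lies within the central 0.95 mass of
#' Binomial(n_committed, predicted).
#'
#' @param model an [rc_model()].
#' @param records validation records (descriptor columns, `n_to_A`,
#'   `n_to_B`); rows without committed shots are dropped.
#' @return list with `table` (point_id, predicted, observed, n_committed,
#'   se, covered) and summary `rmse` and `n_covered`.
#' @export
rc_calibrate <- function(model, records) {
  n_comm <- records$n_to_A + records$n_to_B
  keep <- which(n_comm >= 1)
  if (length(keep) == 0L)
    return(list(table = data.frame(point_id = integer(0), predicted = numeric(0),
                                   observed = numeric(0), n_committed = integer(0),
                                   se = numeric(0), covered = logical(0)),
                rmse = NA_real_, n_covered = 0L))
  rec <- records[keep, , drop = FALSE]
  n <- rec$n_to_A + rec$n_to_B
  pred <- rc_predict(model, rec)
  obs <- rec$n_to_B / n
  lo <- stats::qbinom(0.025, n, pred)
  hi <- stats::qbinom(0.975, n, pred)
  covered <- rec$n_to_B >= lo & rec$n_to_B <= hi
  tab <- data.frame(
    point_id = if ("point_id" %in% names(rec)) rec$point_id else keep,
    predicted = pred, observed = obs, n_committed = n,
    se = sqrt(pmax(obs * (1 - obs), 0) / n), covered = covered
  )
  list(table = tab, rmse = sqrt(mean((pred - obs)^2)),
       n_covered = sum(covered))
}

#' Synthetic shooting records from a known committor model
#'
#' Draws descriptor vectors from independent Gaussians, computes the true
#' reaction coordinate through `true_model`, and simulates
#' `shots_per_point` outcomes per point: uncommitted with probability
#' `uncommitted_rate` (independently of Q, the least-structured choice),
#' otherwise reaching B with probability \eqn{[1+\tanh(Q)]/2}.
#'
#' @param true_model an [rc_model()]; by default its standardization
#'   constants define the raw descriptor distribution (mean = center,
#'   s.d. = scale).
#' @param n_points number of shooting points.
#' @param shots_per_point shots simulated per point (>= 1).
#' @param uncommitted_rate probability in [0, 1) that a shot commits to
#'   neither state.
#' @param descriptor_center,descriptor_scale override the raw descriptor
#'   distribution (`descriptor_scale` may contain zeros; a distribution
#'   with zero variance in every descriptor is flagged degenerate with a
#'   warning).
#' @param seed integer seed.
#' @return data.frame: `point_id`, one column per descriptor (raw scale),
#'   `n_to_A`, `n_to_B`, `n_uncommitted`, plus attributes `Q_true` and
#'   `degenerate` (TRUE when every descriptor has zero scale).
#' @export
gen_shooting_records <- function(true_model, n_points, shots_per_point,
                                 uncommitted_rate = 0,
                                 descriptor_center = true_model$center,
                                 descriptor_scale = true_model$scale,
                                 seed = NULL) {
  stopifnot(inherits(true_model, "rc_model"))
  if (shots_per_point < 1) stop("shots_per_point must be >= 1")
  if (uncommitted_rate < 0 || uncommitted_rate >= 1)
    stop("uncommitted_rate must lie in [0, 1)")
  k <- length(true_model$descriptors)
  degenerate <- all(descriptor_scale <= 0)
  if (degenerate) warning("degenerate descriptor distribution: zero variance everywhere")
  with_seed_or_current(seed, {
    Z <- matrix(stats::rnorm(n_points * k), ncol = k)
    raw <- sweep(sweep(Z, 2, descriptor_scale, `*`), 2, descriptor_center, `+`)
    Q <- true_model$coefficients[1] + as.numeric(Z %*% true_model$coefficients[-1])
    pB <- committor_model(Q)
    n_unc <- stats::rbinom(n_points, shots_per_point, uncommitted_rate)
    n_comm <- shots_per_point - n_unc
    nB <- stats::rbinom(n_points, n_comm, pB)
    out <- data.frame(point_id = seq_len(n_points))
    for (j in seq_len(k)) out[[true_model$descriptors[j]]] <- raw[, j]
    out$n_to_A <- n_comm - nB
    out$n_to_B <- nB
    out$n_uncommitted <- n_unc
    attr(out, "Q_true") <- Q
    attr(out, "degenerate") <- degenerate
    out
  })
}
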