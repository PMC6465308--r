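#' Metastable-state definition
#'
#' @param name state label (`"A"` = inward-open, `"B"` = outward-open by
#'   convention).
#' @param predicate function of a position vector returning TRUE when the
#'   state is reached.
#' @return object of class `state_definition`.
#' @export
state_definition <- function(name, predicate) {
  stopifnot(is.function(predicate))
  structure(list(name = name, predicate = predicate),
            class = "state_definition")
}

#' Toy basin definitions on the double-well x coordinate
#'
#' A: x <= `x_A` (inward-open analogue); B: x >= `x_B` (outward-open).
#' Mutually exclusive for `x_A < x_B`.
#'
#' @param x_A,x_B basin thresholds along the first coordinate.
#' @return named list of two [state_definition()]s.
#' @export
toy_states <- function(x_A = -0.8, x_B = 0.8) {
  if (x_A >= x_B) stop("x_A must be below x_B")
  list(A = state_definition("A", function(x) x[1] <= x_A),
       B = state_definition("B", function(x) x[1] >= x_B))
}

#' Propagate until commitment to a basin
#'
#' Runs Langevin dynamics from `state` until the A or B predicate first
#' holds (first-passage criterion) or `max_steps` is exhausted.
#'
#' @param state initial [engine_state()] (positions and velocities).
#' @param potential a [potential_spec()].
#' @param states list with [state_definition()]s `A` and `B`.
#' @param max_steps step budget (>= 1): shots exceeding it are
#'   `"uncommitted"`.
#' @param dt,friction,temperature,masses engine parameters, see
#'   [langevin_propagate()].
#' @param seed integer seed for the thermostat noise.
#' @param record keep the visited positions (default TRUE).
#' @return object of class `shot_result`: `outcome` (`"to_A"`, `"to_B"`,
#'   `"uncommitted"`), `steps_to_commit` (NA if uncommitted), `segment`
#'   (positions matrix incl. the initial state, if recorded), `final`
#'   ([engine_state()]).
#' @export
run_until_committed <- function(state, potential, states, max_steps,
                                dt, friction, temperature, masses = 1,
                                seed = NULL, record = TRUE) {
  if (max_steps < 1) stop("max_steps must be >= 1")
  d <- length(state$positions)
  masses <- rep_len(as.numeric(masses), d)
  predA <- states$A$predicate; predB <- states$B$predicate
  mk <- function(outcome, steps, seg, x, v, t)
    structure(list(outcome = outcome, steps_to_commit = steps,
                   segment = seg, final = engine_state(x, v, t)),
              class = "shot_result")
  x <- state$positions; v <- state$velocities
  if (predA(x)) return(mk("to_A", 0L, if (record) matrix(x, 1) else NULL,
                          x, v, state$time))
  if (predB(x)) return(mk("to_B", 0L, if (record) matrix(x, 1) else NULL,
                          x, v, state$time))
  with_seed_or_current(seed, {
    step <- baoab_stepper(potential, dt, friction, temperature, masses)
    seg <- if (record) matrix(NA_real_, nrow = max_steps + 1L, ncol = d)
    if (record) seg[1L, ] <- x
    outcome <- "uncommitted"; steps <- NA_integer_
    for (i in seq_len(max_steps)) {
      s <- step(x, v); x <- s$x; v <- s$v
      if (!all(is.finite(x)))
        stop(sprintf("integration blow-up: non-finite coordinates at step %d", i))
      if (record) seg[i + 1L, ] <- x
      if (predA(x)) { outcome <- "to_A"; steps <- i; break }
      if (predB(x)) { outcome <- "to_B"; steps <- i; break }
    }
    n_kept <- if (is.na(steps)) max_steps + 1L else steps + 1L
    mk(outcome, steps, if (record) seg[seq_len(n_kept), , drop = FALSE],
       x, v, state$time + (n_kept - 1L) * dt)
  })
}

#' Conjugate shooting pair with stitching
#'
#' Draws Maxwell-Boltzmann velocities at the shooting point, runs a
#' forward segment with them and a conjugate backward segment with their
#' sign inverse (each with its own thermostat noise stream), and stitches
#' the pair into a continuous transition path when the two segments commit
#' to opposite states. Random draws are consumed in a fixed order
#' (velocities, forward noise, backward noise) so runs are
#' seed-reproducible.
#'
#' @param point shooting-point [engine_state()] (positions used;
#'   velocities drawn fresh).
#' @param potential,states,max_steps,dt,friction,temperature,masses see
#'   [run_until_committed()].
#' @param seed integer seed.
#' @return list with `forward`, `backward` ([run_until_committed()]
#'   results) and `path` (a `transition_path` or NULL when the outcomes do
#'   not pair A with B).
#' @export
shoot_pair <- function(point, potential, states, max_steps, dt, friction,
                       temperature, masses = 1, seed = NULL) {
  d <- length(point$positions)
  masses <- rep_len(as.numeric(masses), d)
  with_seed_or_current(seed, {
    v0 <- draw_mb_velocities(masses, temperature, n = d)
    fw <- run_until_committed(engine_state(point$positions, v0),
                              potential, states, max_steps, dt, friction,
                              temperature, masses)
    bw <- run_until_committed(engine_state(point$positions, -v0),
                              potential, states, max_steps, dt, friction,
                              temperature, masses)
    path <- NULL
    oo <- c(fw$outcome, bw$outcome)
    if (all(c("to_A", "to_B") %in% oo))
      path <- stitch(fw, bw, point, dt = dt)
    list(forward = fw, backward = bw, path = path)
  })
}

#' Stitch two conjugate committed segments into a transition path
#'
#' The segment that committed to A is reversed in time and prepended to
#' the segment that committed to B; the shared shooting point appears
#' exactly once and times are remapped to a strictly increasing axis.
#'
#' @param forward,backward `shot_result`s with recorded segments that
#'   committed to opposite states.
#' @param point the shooting-point [engine_state()].
#' @param dt frame spacing for the remapped time axis.
#' @return object of class `transition_path`: `frames` (positions matrix,
#'   one row per time point), `times`, `shooting_index`, `provenance`
#'   (per-frame `"backward"` / `"shooting_point"` / `"forward"` labels),
#'   `endpoints` (state labels of first and last frame).
#' @export
stitch <- function(forward, backward, point, dt = 1) {
  oo <- c(forward$outcome, backward$outcome)
  if (!all(c("to_A", "to_B") %in% oo))
    stop("stitching requires conjugate segments committed to opposite states")
  if (is.null(forward$segment) || is.null(backward$segment))
    stop("stitching requires recorded segments")
  # orient so the path runs A -> B
  seg_to_A <- if (forward$outcome == "to_A") forward else backward
  seg_to_B <- if (forward$outcome == "to_B") forward else backward
  a <- seg_to_A$segment   # starts at shooting point, ends in A
  b <- seg_to_B$segment   # starts at shooting point, ends in B
  m <- nrow(a) - 1L; n <- nrow(b) - 1L
  frames <- rbind(a[rev(seq_len(m + 1L))[seq_len(m)], , drop = FALSE],
                  b)
  structure(list(
    frames = frames,
    times = dt * (0:(m + n)),
    shooting_index = m + 1L,
    provenance = c(rep("backward", m), "shooting_point", rep("forward", n)),
    endpoints = c("A", "B")
  ), class = "transition_path")
}

#' Committor estimate from repeated shots
#'
#' \eqn{\hat\phi_B = n_B / (n_A + n_B)} over committed shots only, with
#' the binomial standard error.
#'
#' @param results list of `shot_result`s (or a character vector of
#'   outcomes).
#' @return list: `phi_B`, `se`, `n_committed`, `n_uncommitted`.
#' @export
estimate_committor <- function(results) {
  outcomes <- if (is.character(results)) results
              else vapply(results, `[[`, "", "outcome")
  nB <- sum(outcomes == "to_B"); nA <- sum(outcomes == "to_A")
  n <- nA + nB
  if (n == 0L) stop("committor undefined: no committed shots")
  p <- nB / n
  list(phi_B = p, se = sqrt(p * (1 - p) / n), n_committed = n,
       n_uncommitted = sum(outcomes == "uncommitted"))
}

#' Shooting-range membership of an access state
#'
#' The shooting range is the union of the occluded and connected
#' water-access states: every transport transition path must contain at
#' least one configuration in it.
#'
#' @param access_state character vector of access states.
#' @return logical vector.
#' @export
in_shooting_range <- function(access_state) {
  if (!all(access_state %in% c("inward", "outward", "occluded", "connected")))
    stop("unknown access state")
  access_state %in% c("occluded", "connected")
}

#' Detailed-balance path weight ratio
#'
#' For the recursive shooting scheme, the weight ratio of a new path to
#' the existing path it was shot from is `p_new / p_old = n_old / n_new`,
#' the ratio of the numbers of uniformly saved configurations in the
#' shooting range on the old and new paths.
#'
#' @param n_old,n_new shooting-range configuration counts (both >= 1; a
#'   valid transition path always contains at least one).
#' @return the exact quotient `n_old / n_new`.
#' @export
path_weight_ratio <- function(n_old, n_new) {
  if (any(n_old < 1) || any(n_new < 1))
    stop("degenerate path: shooting-range configuration counts must be >= 1")
  n_old / n_new
}

#' Select shooting points from a transition path
#'
#' Without a reaction-coordinate model, draws uniformly at random from the
#' frames inside the shooting range. With a model, picks the frames whose
#' predicted committor is closest to 1/2 (smallest |Q|).
#'
#' @param path a `transition_path`.
#' @param in_range logical vector, one entry per path frame (from
#'   [in_shooting_range()] on the frames' access states, or a toy barrier
#'   window).
#' @param n_points number of frames to select.
#' @param model optional [rc_model()]; `descriptor_fn` must then map a
#'   frame (position row) to the model's descriptor vector.
#' @param descriptor_fn function(position row) -> named descriptor vector.
#' @param seed integer seed for the uniform draw.
#' @return integer frame indices into the path (empty, with a warning,
#'   when no frame is in range).
#' @export
select_shooting_points <- function(path, in_range, n_points, model = NULL,
                                   descriptor_fn = NULL, seed = NULL) {
  stopifnot(inherits(path, "transition_path"))
  idx <- which(in_range)
  if (length(idx) == 0L) {
    warning("no frames in the shooting range: empty selection")
    return(integer(0))
  }
  n_points <- min(n_points, length(idx))
  if (is.null(model)) {
    with_seed_or_current(seed, sort(sample(idx, n_points)))
  } else {
    if (is.null(descriptor_fn))
      stop("descriptor_fn is required when selecting with a model")
    Q <- vapply(idx, function(i)
      rc_value(model, matrix(descriptor_fn(path$frames[i, ]), nrow = 1)), 0)
    idx[order(abs(Q))][seq_len(n_points)]
  }
}
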