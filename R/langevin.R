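#' Phase-space state of the toy engine
#'
#' @param positions numeric vector, length units.
#' @param velocities numeric vector, same length; defaults to zeros.
#' @param time time stamp, engine units.
#' @return object of class `engine_state`.
#' @export
engine_state <- function(positions, velocities = NULL, time = 0) {
  positions <- as.numeric(positions)
  if (is.null(velocities)) velocities <- numeric(length(positions))
  velocities <- as.numeric(velocities)
  if (length(velocities) != length(positions))
    stop("positions and velocities must have identical dimensionality")
  structure(list(positions = positions, velocities = velocities, time = time),
            class = "engine_state")
}

#' Maxwell-Boltzmann velocity draw
#'
#' Each velocity component is an independent zero-mean Gaussian with
#' variance `temperature / mass` (kT units, mass units of the engine).
#'
#' @param masses positive mass per degree of freedom (recycled).
#' @param temperature temperature in kT units, >= 0.
#' @param n number of degrees of freedom; defaults to `length(masses)`.
#' @param seed optional integer seed (same seed, same draw).
#' @return numeric velocity vector.
#' @export
draw_mb_velocities <- function(masses, temperature, n = length(masses),
                               seed = NULL) {
  if (any(masses <= 0)) stop("masses must be positive")
  if (temperature < 0) stop("temperature must be >= 0")
  masses <- rep_len(as.numeric(masses), n)
  with_seed_or_current(seed, {
    if (temperature == 0) numeric(n)
    else stats::rnorm(n, mean = 0, sd = sqrt(temperature / masses))
  })
}

# internal BAOAB stepper shared by the propagators. Returns a function of
# (x, v) performing one step and returning list(x, v). friction = 0 and
# temperature = 0 reduce exactly to velocity Verlet.
baoab_stepper <- function(potential, dt, friction, temperature, masses) {
  c1 <- exp(-friction * dt)
  c2 <- sqrt(pmax(0, (1 - c1^2) * temperature / masses))
  half_dt <- dt / 2
  inv_m <- 1 / masses
  function(x, v) {
    v <- v - half_dt * potential_gradient(potential, x) * inv_m   # B
    x <- x + half_dt * v                                          # A
    if (friction > 0 && temperature > 0) {                        # O
      v <- c1 * v + c2 * stats::rnorm(length(v))
    } else if (friction > 0) {
      v <- c1 * v
    }
    x <- x + half_dt * v                                          # A
    v <- v - half_dt * potential_gradient(potential, x) * inv_m   # B
    list(x = x, v = v)
  }
}

#' Langevin propagation on an analytic potential
#'
#' Integrates underdamped Langevin dynamics with a BAOAB splitting: velocity
#' Verlet with the Ornstein-Uhlenbeck friction/noise step applied
#' symmetrically mid-step. With `friction = 0` and `temperature = 0` the
#' scheme is plain velocity Verlet (deterministic, energy-conserving).
#'
#' @param state initial [engine_state()].
#' @param potential a [potential_spec()] matching the state dimensionality.
#' @param n_steps number of integration steps (>= 1).
#' @param dt time step, > 0.
#' @param friction friction coefficient, 1/time, >= 0.
#' @param temperature temperature, kT units, >= 0.
#' @param masses mass per degree of freedom (recycled), default 1.
#' @param seed optional integer seed; identical seeds give identical
#'   trajectories.
#' @param thin keep every `thin`-th step in the returned arrays (the initial
#'   state is always kept); default 1 keeps everything.
#' @return list with `positions` and `velocities` (kept-steps x dim
#'   matrices, first row the initial state), `times`, and `final` (an
#'   [engine_state()] after the last step, kept or not).
#' @export
langevin_propagate <- function(state, potential, n_steps, dt, friction = 0,
                               temperature = 0, masses = 1, seed = NULL,
                               thin = 1L) {
  stopifnot(inherits(state, "engine_state"), inherits(potential, "potential_spec"))
  if (dt <= 0) stop("dt must be positive")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (friction < 0) stop("friction must be >= 0")
  d <- length(state$positions)
  if (d != potential$dimensionality)
    stop("state dimensionality does not match potential")
  masses <- rep_len(as.numeric(masses), d)
  thin <- max(1L, as.integer(thin))
  kept <- c(0L, seq_len(n_steps)[seq_len(n_steps) %% thin == 0L])
  pos <- matrix(NA_real_, nrow = length(kept), ncol = d)
  vel <- matrix(NA_real_, nrow = length(kept), ncol = d)
  pos[1L, ] <- state$positions; vel[1L, ] <- state$velocities
  with_seed_or_current(seed, {
    step <- baoab_stepper(potential, dt, friction, temperature, masses)
    x <- state$positions; v <- state$velocities
    row <- 2L
    for (i in seq_len(n_steps)) {
      s <- step(x, v); x <- s$x; v <- s$v
      if (!all(is.finite(x)))
        stop(sprintf("integration blow-up: non-finite coordinates at step %d", i))
      if (i %% thin == 0L) { pos[row, ] <- x; vel[row, ] <- v; row <- row + 1L }
    }
    list(
      positions = pos, velocities = vel,
      times = state$time + kept * dt,
      final = engine_state(x, v, time = state$time + n_steps * dt)
    )
  })
}

#' Total energy of a state
#' @param state an [engine_state()].
#' @param potential a [potential_spec()].
#' @param masses mass per degree of freedom (recycled).
#' @return kinetic plus potential energy, kT units.
#' @export
total_energy <- function(state, potential, masses = 1) {
  m <- rep_len(as.numeric(masses), length(state$positions))
  0.5 * sum(m * state$velocities^2) + potential_energy(potential, state$positions)
}
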