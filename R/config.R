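# Run configuration: a JSON file with one section per pipeline stage.
# jsonlite round-trips it losslessly; validation happens at load.

#' Default run configuration
#'
#' @return nested list with the documented defaults for every stage:
#'   `seed`, `engine` (dt, friction, temperature, max_steps, masses),
#'   `potential`, `states` (toy basin thresholds), `hydration`,
#'   `fixture`, `records` (synthetic shooting-ledger generator), `fit`
#'   (Monte Carlo optimizer).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    engine = list(dt = 0.01, friction = 1, temperature = 1,
                  max_steps = 10000L, masses = 1),
    potential = list(kind = "double_well_2d", barrier_height = 5,
                     well_separation = 1, stiffness = 5),
    states = list(x_A = -0.8, x_B = 0.8),
    hydration = list(alpha = 10, beta = 5, gamma = 5, cutoff = 3,
                     slab_width = 10, contact_cutoff = 3),
    fixture = list(delta_z_true = 3.5, delta_phi_true = 10,
                   access_state_true = "inward", n_waters_inward = 13L,
                   n_waters_outward = 13L, box = c(40, 40, 70)),
    records = list(n_points = 200L, shots_per_point = 10L,
                   uncommitted_rate = 0.1,
                   descriptors = c("dz", "gate_dist"),
                   true_coefficients = c(0, 2, 0)),
    fit = list(n_steps = 3000L, n_restarts = 5L, n_boot = 200L,
               boot_steps = 400L)
  )
}

#' Read and validate a run configuration
#'
#' Missing sections fall back to [default_config()]; present values are
#' range-checked.
#'
#' @param path JSON configuration file.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Write a run configuration
#'
#' @param cfg configuration list.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Validate a configuration list
#'
#' @param cfg configuration list.
#' @return `cfg`, invisibly; errors name the offending parameter.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("config validation: ", what)
  chk(cfg$engine$dt > 0, "engine.dt must be > 0")
  chk(cfg$engine$friction >= 0, "engine.friction must be >= 0")
  chk(cfg$engine$temperature >= 0, "engine.temperature must be >= 0")
  chk(cfg$engine$max_steps >= 1, "engine.max_steps must be >= 1")
  chk(cfg$potential$kind %in% c("double_well_1d", "double_well_2d", "harmonic"),
      "potential.kind unknown")
  chk(cfg$states$x_A < cfg$states$x_B, "states.x_A must be below states.x_B")
  chk(all(unlist(cfg$hydration[c("alpha", "beta", "gamma", "cutoff")]) > 0),
      "hydration parameters must be positive")
  chk(cfg$records$shots_per_point >= 1, "records.shots_per_point must be >= 1")
  chk(cfg$records$uncommitted_rate >= 0 && cfg$records$uncommitted_rate < 1,
      "records.uncommitted_rate must lie in [0, 1)")
  chk(length(cfg$records$true_coefficients) ==
        length(cfg$records$descriptors) + 1L,
      "records.true_coefficients must have one entry more than descriptors")
  invisible(cfg)
}

# internal: potential_spec from a config section
config_potential <- function(cfg) {
  p <- cfg$potential
  potential_spec(p$kind, barrier_height = p$barrier_height,
                 well_separation = p$well_separation,
                 stiffness = p$stiffness,
                 dimensionality = p$dimensionality)
}
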