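# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# Rodrigues rotation construction, written out element-wise (independent of
# transpath::rotation_matrix).
oracle_rodrigues <- function(axis, angle_deg) {
  e <- axis / sqrt(sum(axis^2))
  p <- angle_deg * pi / 180
  c1 <- cos(p); s1 <- sin(p); v <- 1 - c1
  matrix(c(
    c1 + e[1]^2 * v,        e[2] * e[1] * v + e[3] * s1, e[3] * e[1] * v - e[2] * s1,
    e[1] * e[2] * v - e[3] * s1, c1 + e[2]^2 * v,        e[3] * e[2] * v + e[1] * s1,
    e[1] * e[3] * v + e[2] * s1, e[2] * e[3] * v - e[1] * s1, c1 + e[3]^2 * v
  ), nrow = 3)
}

# Brute-force single-linkage partition by boolean transitive closure of the
# minimum-image adjacency matrix (O(N^2) distances, O(N^3) closure).
oracle_single_linkage <- function(coords, box, cutoff) {
  n <- nrow(coords)
  adj <- diag(n) > 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- coords[i, ] - coords[j, ]
    if (!is.null(box)) d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) <= cutoff) adj[i, j] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0 | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  # canonical partition labels: index of first member of each block
  apply(adj, 1, function(r) which(r)[1])
}

# partitions equal as equivalences (labels may differ)
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(as.integer(factor(a, levels = unique(a))),
              as.integer(factor(b, levels = unique(b))))
}

# per-shot brute-force log-likelihood: expand counts into individual shots
oracle_log_likelihood <- function(model, records, floor = 1e-12) {
  total <- 0
  for (i in seq_len(nrow(records))) {
    p <- (1 + tanh(rc_value(model, records[i, , drop = FALSE]))) / 2
    p <- min(1 - floor, max(floor, p))
    if (records$n_to_B[i] > 0)
      for (s in seq_len(records$n_to_B[i])) total <- total + log(p)
    if (records$n_to_A[i] > 0)
      for (s in seq_len(records$n_to_A[i])) total <- total + log(1 - p)
  }
  total
}

# random proper rotation via QR with det fix (independent of the package)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# RMSD of mobile mapped by (R, t) onto reference
transform_rmsd <- function(X, Y, R, t) {
  Z <- sweep(X %*% t(R), 2, t, `+`)
  sqrt(mean(rowSums((Z - Y)^2)))
}

# random feasible fixture spec; states cycle so all four are covered
random_fixture_spec <- function(i) {
  states <- c("inward", "outward", "occluded", "connected")
  st <- states[(i - 1L) %% 4L + 1L]
  fixture_spec(
    delta_z_true = stats::runif(1, -4, 4),
    delta_phi_true = stats::runif(1, 0.5, 25),
    access_state_true = st,
    n_waters_inward = sample(11:16, 1),
    n_waters_outward = sample(11:16, 1),
    n_waters_pore = if (st == "connected") sample(1:3, 1) else 0L,
    seed = i
  )
}

# default toy engine settings shared by the TPS tests
toy_engine <- function() {
  list(potential = potential_spec("double_well_2d", barrier_height = 5,
                                  well_separation = 1, stiffness = 5),
       states = toy_states(-0.8, 0.8),
       dt = 0.01, friction = 1, temperature = 1, max_steps = 5000)
}
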