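#' Synthetic fixture specification
#'
#' Describes a protein-like test frame with known ground truth: a static
#' scaffold ("dimerization") domain, a mobile ("transporter") domain
#' displaced by `delta_z_true` along the membrane normal and rotated by
#' `delta_phi_true` about an in-plane axis relative to the stored
#' inward-open reference, one probe atom standing in for the
#' proton-carrying aspartate carboxyl oxygen, and water oxygens arranged
#' in 2.9 Angstrom-spaced chains so that the requested water-access state
#' is certain by construction under the 3.0 Angstrom clustering rule.
#'
#' @param delta_z_true transporter-domain z displacement, Angstrom.
#' @param delta_phi_true transporter-domain rotation, degrees, in [0, 180).
#' @param access_state_true one of `"inward"`, `"outward"`, `"occluded"`,
#'   `"connected"`.
#' @param n_waters_inward,n_waters_outward,n_waters_pore water counts for
#'   the inward bulk chain, outward bulk chain, and the pore bridge
#'   (pore > 0 only for `"connected"`).
#' @param box orthorhombic box edges, Angstrom.
#' @param seed integer seed (reserved for randomized placements; the
#'   default construction is deterministic).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(delta_z_true = 3.5, delta_phi_true = 10,
                         access_state_true = c("inward", "outward",
                                               "occluded", "connected"),
                         n_waters_inward = 13, n_waters_outward = 13,
                         n_waters_pore = NULL, box = c(40, 40, 70),
                         seed = 1L) {
  access_state_true <- match.arg(access_state_true)
  if (is.null(n_waters_pore))
    n_waters_pore <- if (access_state_true == "connected") 1L else 0L
  if (delta_phi_true < 0 || delta_phi_true >= 180)
    stop("delta_phi_true must lie in [0, 180)")
  if (any(c(n_waters_inward, n_waters_outward, n_waters_pore) < 0))
    stop("water counts must be >= 0")
  if (any(box <= 0)) stop("box edges must be positive")
  structure(list(delta_z_true = delta_z_true, delta_phi_true = delta_phi_true,
                 access_state_true = access_state_true,
                 n_waters_inward = as.integer(n_waters_inward),
                 n_waters_outward = as.integer(n_waters_outward),
                 n_waters_pore = as.integer(n_waters_pore),
                 box = as.numeric(box), seed = as.integer(seed)),
            class = "fixture_spec")
}

# internal: rigid template point sets (relative to their geometric centres)
fixture_templates <- function() {
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  dimer <- rbind(
    cbind(12 * cos(ang), 12 * sin(ang), rep(-5, 8)),
    cbind(8 * cos(ang[c(1, 3, 5, 7)] + 0.4),
          8 * sin(ang[c(1, 3, 5, 7)] + 0.4), rep(5, 4))
  )
  trans <- rbind(
    cbind(4 * cos(ang[1:6]), 4 * sin(ang[1:6]), seq(-6, 6, length.out = 6)),
    cbind(2.5 * cos(ang[1:4] + 0.7), 2.5 * sin(ang[1:4] + 0.7),
          c(-3, 3, -1, 1))
  )
  # centre the mobile template on its geometric mean so rotation about the
  # template origin is rotation about the domain centre (keeps the centre
  # displacement equal to the requested translation)
  trans <- sweep(trans, 2, colMeans(trans))
  list(dimer = dimer, trans = trans)
}

# internal: water columns realizing a requested access state; returns an
# n x 3 matrix. All geometry is anchored to the probe z (z0) and the
# retained-region faces implied by the default 10 A slab at z = 0.
fixture_waters <- function(spec, z0, face_in, face_out) {
  st <- spec$access_state_true
  xy <- c(spec$box[1] / 2, spec$box[2] / 2)   # pore column
  need_in <- 11L; need_out_conn <- 10L; need_out <- 11L
  if (st %in% c("inward", "connected") && spec$n_waters_inward < need_in)
    stop(sprintf("infeasible: state '%s' needs >= %d inward waters", st, need_in))
  if (st == "outward" && spec$n_waters_outward < need_out)
    stop(sprintf("infeasible: state 'outward' needs >= %d outward waters", need_out))
  if (st == "connected" && spec$n_waters_outward < need_out_conn)
    stop(sprintf("infeasible: state 'connected' needs >= %d outward waters",
                 need_out_conn))
  if (st == "connected" && spec$n_waters_pore < 1L)
    stop("infeasible: connected state needs at least one pore water")
  if (st != "connected" && spec$n_waters_pore > 0L)
    stop("infeasible: pore waters are only placed in the connected state")

  col_up <- function(k) cbind(xy[1], xy[2], face_in + 0.5 + 2.9 * (seq_len(k) - 1))
  col_down <- function(k) cbind(xy[1], xy[2], face_out - 0.5 - 2.9 * (seq_len(k) - 1))
  # face-level extras on a 2.9 A grid adjacent to the column anchor
  extras <- function(n, zface) {
    if (n <= 0L) return(NULL)
    g <- expand.grid(a = 0:7, b = 0:7)
    g <- g[g$a + g$b > 0, ]
    g <- g[order(pmax(g$a, g$b), g$a, g$b), ][seq_len(n), , drop = FALSE]
    if (anyNA(g$a)) stop("infeasible: too many waters for the face grid")
    cbind(xy[1] + 2.9 * g$a, xy[2] + 2.9 * g$b, zface)
  }
  stub <- 7L   # non-contacting columns stop ~10 A short of the probe
  place <- function(n_tot, n_col, col_fun, zface) {
    n_col <- min(n_tot, n_col)
    rbind(col_fun(n_col), extras(n_tot - n_col, zface))
  }
  w_in <- switch(st,
    inward = place(spec$n_waters_inward, need_in, col_up, face_in + 0.5),
    connected = place(spec$n_waters_inward, need_in, col_up, face_in + 0.5),
    place(spec$n_waters_inward, stub, col_up, face_in + 0.5)
  )
  w_out <- switch(st,
    outward = place(spec$n_waters_outward, need_out, col_down, face_out - 0.5),
    connected = place(spec$n_waters_outward, need_out_conn, col_down,
                      face_out - 0.5),
    place(spec$n_waters_outward, stub, col_down, face_out - 0.5)
  )
  w_pore <- if (st == "connected") {
    bridge <- cbind(xy[1], xy[2], z0 + 1)
    if (spec$n_waters_pore > 1L)
      bridge <- rbind(bridge,
                      cbind(xy[1], xy[2] + 2.9 * seq_len(spec$n_waters_pore - 1L),
                            z0 + 1))
    bridge
  } else NULL
  rbind(w_in, w_out, w_pore)
}

#' Generate a synthetic fixture frame with ground truth
#'
#' Builds the frame described by a [fixture_spec()] together with
#' inward-open and outward-open reference frames, the atom selections the
#' analysis modules need, and a ground-truth record. The transporter
#' template is rotated by `delta_phi_true` about the in-plane x axis
#' through its geometric centre and displaced by `delta_z_true` along z,
#' relative to the inward-open reference; the outward-open reference uses
#' a fixed displacement of +3.5 Angstrom and +10 degrees. Waters realize
#' the requested access state by construction (2.9 Angstrom chains vs the
#' 3.0 Angstrom clustering cutoff).
#'
#' @param spec a [fixture_spec()].
#' @return list with `frame`, `ref_in`, `ref_out` ([tp_frame()]s),
#'   `selections` (named list: `dimer`, `transporter`, `probe`, `water`),
#'   `params` (a [hydration_params()] centred on the probe) and `truth`
#'   (the requested ground-truth values plus the reference transform).
#' @export
gen_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  box <- spec$box
  centre <- box / 2
  z0 <- centre[3]
  face_in <- 5; face_out <- box[3] - 5   # default 10 A slab at z = 0
  tpl <- fixture_templates()
  dimer <- sweep(tpl$dimer, 2, c(centre[1] - 6, centre[2], z0), `+`)
  trans_centre_ref <- c(centre[1] + 7, centre[2], z0)
  trans_ref <- sweep(tpl$trans, 2, trans_centre_ref, `+`)
  probe <- matrix(c(centre[1] + 1.5, centre[2], z0), nrow = 1)

  move_domain <- function(dz, phi) {
    R <- rotation_matrix(c(1, 0, 0), phi)
    sweep(tpl$trans %*% t(R), 2, trans_centre_ref + c(0, 0, dz), `+`)
  }
  trans_frame <- move_domain(spec$delta_z_true, spec$delta_phi_true)
  out_dz <- 3.5; out_phi <- 10
  trans_out <- move_domain(out_dz, out_phi)
  waters <- fixture_waters(spec, z0, face_in, face_out)

  n_d <- nrow(dimer); n_t <- nrow(trans_ref); n_w <- nrow(waters)
  atoms <- data.frame(
    serial = seq_len(n_d + n_t + 1L + n_w),
    name = c(rep("CA", n_d + n_t), "OD1", rep("O", n_w)),
    resname = c(rep("GLY", n_d + n_t), "ASP", rep("HOH", n_w)),
    chain = c(rep("A", n_d), rep("B", n_t), "P", rep("W", n_w)),
    resid = c(seq_len(n_d), seq_len(n_t), 1L, seq_len(n_w)),
    element = c(rep("C", n_d + n_t), "O", rep("O", n_w)),
    stringsAsFactors = FALSE
  )
  build <- function(trans_pts) {
    tp_frame(rbind(dimer, trans_pts, probe, waters), box = box, atoms = atoms)
  }
  sel <- list(
    dimer = atom_selection("dimer", seq_len(n_d)),
    transporter = atom_selection("transporter", n_d + seq_len(n_t)),
    probe = atom_selection("probe", n_d + n_t + 1L),
    water = atom_selection("water", n_d + n_t + 1L + seq_len(n_w))
  )
  list(
    frame = build(trans_frame),
    ref_in = build(trans_ref),
    ref_out = build(trans_out),
    selections = sel,
    params = hydration_params(r0 = probe[1, ]),
    truth = list(delta_z_true = spec$delta_z_true,
                 delta_phi_true = spec$delta_phi_true,
                 access_state_true = spec$access_state_true,
                 axis_true = c(1, 0, 0),
                 ref_out_delta_z = out_dz, ref_out_delta_phi = out_phi,
                 spec = spec)
  )
}
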