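#' Rotation matrix from axis and angle
#'
#' Rodrigues construction
#' \deqn{R = \cos\phi \, I + (1-\cos\phi)\, e e^T + \sin\phi \, [e]_\times}
#' for a unit axis \eqn{e} and angle \eqn{\phi}.
#'
#' @param axis length-3 axis vector (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  e <- as.numeric(axis)
  nrm <- sqrt(sum(e^2))
  if (nrm == 0) stop("axis must be non-zero")
  e <- e / nrm
  phi <- angle_deg * pi / 180
  ex <- matrix(c(0, e[3], -e[2],
                 -e[3], 0, e[1],
                 e[2], -e[1], 0), nrow = 3)  # column-major: [e]_x
  cos(phi) * diag(3) + (1 - cos(phi)) * tcrossprod(e) + sin(phi) * ex
}

# internal: check R is a proper rotation
assert_rotation <- function(R, tol = 1e-6) {
  R <- as.matrix(R)
  if (!identical(dim(R), c(3L, 3L))) stop("R must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("input is not a proper rotation matrix")
  R
}

#' Rotation angle from a rotation matrix
#'
#' \eqn{\Delta\phi = \cos^{-1}[(\mathrm{tr}\,R - 1)/2]}, with the trace
#' argument clamped to \eqn{[-1, 1]} against floating-point overshoot. The
#' angle is non-negative by convention; a rotation by \eqn{-\phi} about an
#' axis is reported as \eqn{+\phi} about the inverted axis.
#'
#' @param R 3 x 3 proper rotation matrix.
#' @return angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(R) {
  R <- assert_rotation(R)
  arg <- (R[1, 1] + R[2, 2] + R[3, 3] - 1) / 2
  arg <- max(-1, min(1, arg))
  # evaluate acos(arg) through atan2 with the antisymmetric part supplying
  # sin(phi): mathematically identical on [0, 180] but numerically stable
  # near 0 and 180 degrees, where acos of the clamped trace loses ~1e-6 deg
  s <- 0.5 * sqrt((R[3, 2] - R[2, 3])^2 + (R[1, 3] - R[3, 1])^2 +
                    (R[2, 1] - R[1, 2])^2)
  atan2(s, arg) * 180 / pi
}

#' Rotation axis from a rotation matrix
#'
#' \eqn{e = (R_{32}-R_{23},\; R_{13}-R_{31},\; R_{21}-R_{12}) / (2\sin\phi)}.
#' Undefined at 0 and 180 degrees where \eqn{\sin\phi = 0}.
#'
#' @param R 3 x 3 proper rotation matrix.
#' @param angle_deg the rotation angle in degrees (from [rotation_angle()]).
#' @param tol angle tolerance (degrees) for the degenerate cases.
#' @return unit axis vector.
#' @export
rotation_axis <- function(R, angle_deg = rotation_angle(R), tol = 1e-9) {
  R <- assert_rotation(R)
  if (angle_deg <= tol || angle_deg >= 180 - tol)
    stop("rotation axis undefined at 0 or 180 degrees")
  s <- 2 * sin(angle_deg * pi / 180)
  c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / s
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-RMSD proper rotation and translation mapping `mobile` onto
#' `reference` over a fit selection, via SVD of the coordinate covariance
#' with reflection correction (det +1 enforced). The fit satisfies
#' `y ~ R x + t` for mobile coordinates `x` and reference `y`.
#'
#' @param mobile,reference [tp_frame()]s (or bare n x 3 matrices).
#' @param fit_selection [atom_selection()] applied to both frames; `NULL`
#'   uses all atoms. At least 3 non-collinear points are required.
#' @return object of class `rigid_body_fit`: list with `rotation` (3 x 3),
#'   `translation` (length 3, Angstrom), `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, reference, fit_selection = NULL) {
  X <- if (inherits(mobile, "tp_frame")) frame_coords(mobile, fit_selection)
       else as.matrix(mobile)
  Y <- if (inherits(reference, "tp_frame")) frame_coords(reference, fit_selection)
       else as.matrix(reference)
  if (!identical(dim(X), dim(Y))) stop("selections differ in size between frames")
  if (nrow(X) < 3L) stop("superposition needs at least 3 points")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set: rotation is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cy - as.numeric(R %*% cx)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd),
            class = "rigid_body_fit")
}

#' Apply a rigid-body fit to a frame
#'
#' @param frame a [tp_frame()] (or n x 3 matrix).
#' @param fit a [superpose()] result.
#' @return transformed frame (same class as input).
#' @export
apply_fit <- function(frame, fit) {
  stopifnot(inherits(fit, "rigid_body_fit"))
  if (inherits(frame, "tp_frame")) {
    frame$coordinates <- sweep(frame$coordinates %*% t(fit$rotation), 2,
                               fit$translation, `+`)
    if (!is.null(frame$velocities))
      frame$velocities <- frame$velocities %*% t(fit$rotation)
    frame
  } else {
    sweep(as.matrix(frame) %*% t(fit$rotation), 2, fit$translation, `+`)
  }
}

#' Domain translation and rotation relative to two references
#'
#' For each reference (inward-open, outward-open): the frame is first
#' aligned to the reference by superposing the static scaffold
#' (`fit_selection`, the dimerization domains); the domain translation is
#' then the difference of the geometric centre of `domain_selection` from
#' the reference's, and the domain rotation comes from an optimal
#' domain-on-domain superposition. The two references are combined by the
#' conventions \eqn{\Delta\phi = (\Delta\phi_{in} - \Delta\phi_{out})/2}
#' and \eqn{\Delta z = (\Delta z_{in} + \Delta z_{out})/2}. z is the
#' membrane normal (box z axis).
#'
#' @param frame frame to analyse.
#' @param ref_in,ref_out inward-open and outward-open reference frames.
#' @param fit_selection scaffold (dimerization-domain) [atom_selection()].
#' @param domain_selection mobile (transporter) domain [atom_selection()].
#' @param rotation_route `"domain_on_domain"` (default): rotation from a
#'   direct domain-on-domain fit after the scaffold alignment;
#'   `"direct"`: domain-on-domain fit without prior scaffold alignment.
#' @return list of class `domain_motion` with fields `dphi_in`, `dphi_out`
#'   (degrees, >= 0), `dz_in`, `dz_out`, `dx_in`, `dy_in`, `dx_out`,
#'   `dy_out` (Angstrom), averaged `dphi`, `dz`, rotation axes `axis_in`,
#'   `axis_out` (unit vectors or NULL when the angle is degenerate), and
#'   the `rotation_route` used.
#' @export
domain_motion <- function(frame, ref_in, ref_out, fit_selection,
                          domain_selection,
                          rotation_route = c("domain_on_domain", "direct")) {
  rotation_route <- match.arg(rotation_route)
  one_ref <- function(ref) {
    aligned <- if (rotation_route == "domain_on_domain")
      apply_fit(frame, superpose(frame, ref, fit_selection)) else frame
    dcen <- colMeans(frame_coords(aligned, domain_selection)) -
            colMeans(frame_coords(ref, domain_selection))
    dfit <- superpose(frame_coords(aligned, domain_selection),
                      frame_coords(ref, domain_selection))
    # rotation of the domain relative to the reference: the fit maps the
    # frame's domain onto the reference's, so the domain's own rotation is
    # the inverse of the fitted rotation
    Rdom <- t(dfit$rotation)
    ang <- rotation_angle(Rdom)
    ax <- tryCatch(rotation_axis(Rdom, ang), error = function(e) NULL)
    list(d = dcen, phi = ang, axis = ax)
  }
  a_in <- one_ref(ref_in); a_out <- one_ref(ref_out)
  structure(list(
    dphi_in = a_in$phi, dphi_out = a_out$phi,
    dx_in = a_in$d[1], dy_in = a_in$d[2], dz_in = a_in$d[3],
    dx_out = a_out$d[1], dy_out = a_out$d[2], dz_out = a_out$d[3],
    dphi = (a_in$phi - a_out$phi) / 2,
    dz = (a_in$d[3] + a_out$d[3]) / 2,
    axis_in = a_in$axis, axis_out = a_out$axis,
    rotation_route = rotation_route
  ), class = "domain_motion")
}

#' Domain-motion series over a trajectory
#'
#' @param frames list of [tp_frame()]s.
#' @inheritParams domain_motion
#' @return data.frame with one row per frame: time, dphi_in, dphi_out,
#'   dz_in, dz_out, dphi, dz.
#' @export
domain_motion_series <- function(frames, ref_in, ref_out, fit_selection,
                                 domain_selection,
                                 rotation_route = "domain_on_domain") {
  rows <- lapply(frames, function(fr) {
    dm <- domain_motion(fr, ref_in, ref_out, fit_selection, domain_selection,
                        rotation_route)
    data.frame(time = fr$time, dphi_in = dm$dphi_in, dphi_out = dm$dphi_out,
               dz_in = dm$dz_in, dz_out = dm$dz_out, dphi = dm$dphi,
               dz = dm$dz)
  })
  do.call(rbind, rows)
}

#' Average structure over a trajectory window
#'
#' Frames in the window are superposed onto the first window frame using
#' `fit_selection`, then coordinates are averaged per atom.
#'
#' @param trajectory list of [tp_frame()]s.
#' @param window integer indices into `trajectory` (non-empty).
#' @param fit_selection [atom_selection()] for the superposition; `NULL`
#'   uses all atoms.
#' @return a [tp_frame()] with the averaged coordinates.
#' @export
average_structure <- function(trajectory, window = seq_along(trajectory),
                              fit_selection = NULL) {
  window <- as.integer(window)
  if (length(window) == 0L) stop("window must be non-empty")
  ref <- trajectory[[window[1]]]
  acc <- matrix(0, nrow = nrow(ref$coordinates), ncol = 3)
  for (i in window) {
    fr <- trajectory[[i]]
    fit <- superpose(fr, ref, fit_selection)
    acc <- acc + apply_fit(fr$coordinates, fit)
  }
  out <- ref
  out$coordinates <- acc / length(window)
  out$velocities <- NULL
  out
}
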