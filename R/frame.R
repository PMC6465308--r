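#' Single-time-point coordinate frame
#'
#' A frame holds an N x 3 coordinate matrix in Angstrom, optionally matching
#' velocities, an orthorhombic box, a time stamp, and a per-atom metadata
#' table (chain, residue, atom name) used by selection patterns and PDB
#' output.
#'
#' @param coordinates numeric N x 3 matrix, Angstrom.
#' @param velocities optional numeric N x 3 matrix, Angstrom per time unit.
#' @param box optional length-3 numeric, orthorhombic box edges in Angstrom.
#' @param time time stamp (engine units or ps).
#' @param atoms optional data.frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resid`, `element`; defaults are generated when omitted.
#' @return object of class `tp_frame`.
#' @export
tp_frame <- function(coordinates, velocities = NULL, box = NULL, time = 0,
                     atoms = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be an N x 3 matrix")
  n <- nrow(coordinates)
  if (n < 1L) stop("frame must contain at least one atom")
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!identical(dim(velocities), dim(coordinates)))
      stop("velocities must have the same shape as coordinates")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be three positive edge lengths")
  }
  if (is.null(atoms)) {
    atoms <- data.frame(
      serial = seq_len(n), name = rep("CA", n), resname = rep("GLY", n),
      chain = rep("A", n), resid = seq_len(n), element = rep("C", n),
      stringsAsFactors = FALSE
    )
  } else if (nrow(atoms) != n) {
    stop("atoms metadata must have one row per coordinate")
  }
  structure(
    list(coordinates = coordinates, velocities = velocities, box = box,
         time = time, atoms = atoms),
    class = "tp_frame"
  )
}

#' @export
print.tp_frame <- function(x, ...) {
  cat(sprintf("<tp_frame> %d atoms, time %g%s\n", nrow(x$coordinates), x$time,
              if (is.null(x$box)) "" else
                sprintf(", box %.1f x %.1f x %.1f A", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Named atom selection
#'
#' @param name label for the selection.
#' @param indices 1-based atom indices into a frame.
#' @return object of class `atom_selection`.
#' @export
atom_selection <- function(name, indices) {
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 1L)) stop("indices must be positive integers")
  if (anyDuplicated(indices)) stop("indices must be unique")
  structure(list(name = name, indices = indices), class = "atom_selection")
}

#' Extract selected coordinates from a frame
#'
#' @param frame a [tp_frame()].
#' @param selection an [atom_selection()] or integer indices; `NULL` selects
#'   all atoms.
#' @return numeric n x 3 matrix.
#' @export
frame_coords <- function(frame, selection = NULL) {
  stopifnot(inherits(frame, "tp_frame"))
  if (is.null(selection)) return(frame$coordinates)
  idx <- if (inherits(selection, "atom_selection")) selection$indices
         else as.integer(selection)
  if (any(idx > nrow(frame$coordinates)))
    stop(sprintf("selection '%s' exceeds frame size",
                 if (inherits(selection, "atom_selection")) selection$name else "<indices>"))
  frame$coordinates[idx, , drop = FALSE]
}

# internal: run expr under a fixed RNG seed without disturbing the caller's
# RNG state; seed = NULL uses the current stream.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Derive a stage seed from a master seed
#'
#' A single master seed deterministically yields one sub-seed per named
#' pipeline stage, so any stage can be re-run in isolation. The result is
#' always a non-negative integer below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"shoot"`, `"fit-rc"`).
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483647)
}
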