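# Minimal fixed-width PDB support for fixture frames: ATOM/HETATM, MODEL/
# ENDMDL, CRYST1. No pre-installed R package provides PDB parsing, and the
# fixtures only need these records; anything else is passed over silently
# except malformed coordinate fields, which raise with the line number.

#' Write frames to a PDB file
#'
#' Multi-frame input produces a multi-model PDB. Waters are written as
#' their metadata says (single O pseudo-atoms in fixtures); an optional
#' CRYST1 record stores the orthorhombic box.
#'
#' @param frames a [tp_frame()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frames, path) {
  if (inherits(frames, "tp_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  box <- frames[[1]]$box
  if (!is.null(box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       box[1], box[2], box[3]), con)
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- fr$atoms; xyz <- fr$coordinates
    rec <- ifelse(a$resname %in% c("HOH", "WAT"), "HETATM", "ATOM  ")
    name4 <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                    sprintf("%-4s", a$name))
    writeLines(sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       rec, a$serial %% 100000L, name4, a$resname, a$chain,
                       a$resid %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3],
                       a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read frames from a PDB file
#'
#' Parses ATOM/HETATM records (fixed columns), MODEL/ENDMDL boundaries and
#' CRYST1. Coordinates are returned in Angstrom with 1-based internal
#' indices; PDB serials are kept as metadata only.
#'
#' @param path PDB file.
#' @return a [tp_frame()] for single-model files, otherwise a list of
#'   frames (one per model).
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("parse error: empty PDB file ", path)
  box <- NULL
  cry <- grep("^CRYST1", lines)
  if (length(cry) > 0) {
    b <- suppressWarnings(as.numeric(c(substr(lines[cry[1]], 7, 15),
                                       substr(lines[cry[1]], 16, 24),
                                       substr(lines[cry[1]], 25, 33))))
    if (!anyNA(b)) box <- b
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("parse error: no ATOM/HETATM records in ", path)
  model_starts <- grep("^MODEL", lines)
  bounds <- if (length(model_starts) == 0L) {
    list(which(is_atom))
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts))
      stop("parse error: unmatched MODEL/ENDMDL records")
    lapply(seq_along(model_starts), function(i) {
      w <- which(is_atom)
      w[w > model_starts[i] & w < ends[i]]
    })
  }
  parse_block <- function(rows) {
    ln <- lines[rows]
    num <- function(from, to, what) {
      v <- suppressWarnings(as.numeric(substr(ln, from, to)))
      bad <- which(!is.finite(v))
      if (length(bad) > 0)
        stop(sprintf("parse error: bad %s field at line %d", what,
                     rows[bad[1]]))
      v
    }
    xyz <- cbind(num(31, 38, "x"), num(39, 46, "y"), num(47, 54, "z"))
    atoms <- data.frame(
      serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
      name = trimws(substr(ln, 13, 16)),
      resname = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      resid = suppressWarnings(as.integer(substr(ln, 23, 26))),
      element = trimws(substr(ln, 77, 78)),
      stringsAsFactors = FALSE
    )
    tp_frame(xyz, box = box, atoms = atoms)
  }
  frames <- lapply(bounds, parse_block)
  if (length(frames) == 1L) frames[[1]] else frames
}

#' Select atoms of a frame by metadata patterns
#'
#' @param frame a [tp_frame()].
#' @param chain,resname,name optional exact-match filters on the atom
#'   metadata; all given filters must hold.
#' @param label selection name.
#' @return an [atom_selection()].
#' @export
select_atoms <- function(frame, chain = NULL, resname = NULL, name = NULL,
                         label = "selection") {
  a <- frame$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  atom_selection(label, which(keep))
}
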