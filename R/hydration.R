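#' Hydration order-parameter settings
#'
#' Parameters of the continuous hydration order parameter
#' \eqn{n_{access} = \sum_i \sigma_r(|r_i - r_0|)\,\sigma_z(z_i - z_0)}:
#' a radial sigmoid selects waters within ~`alpha` of the ion-path centre
#' `r0`, and an antisymmetric axial weight counts outward-side waters
#' (z > z0) positively and inward-side waters negatively.
#'
#' @param r0 length-3 centre of the ion path (3D geometric centre of the
#'   inside and gate residues), Angstrom.
#' @param alpha radial cutoff scale, Angstrom (default 10).
#' @param beta radial steepness, 1/Angstrom (default 5).
#' @param gamma axial scale, Angstrom (default 5).
#' @return object of class `hydration_params`; `z0` is the z component of
#'   `r0`.
#' @export
hydration_params <- function(r0, alpha = 10, beta = 5, gamma = 5) {
  if (alpha <= 0 || beta <= 0 || gamma <= 0)
    stop("alpha, beta and gamma must be positive")
  r0 <- as.numeric(r0)
  if (length(r0) != 3L) stop("r0 must be a length-3 point")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 r0 = r0, z0 = r0[3]),
            class = "hydration_params")
}

#' Radial counting sigmoid
#'
#' \eqn{\sigma_r(x) = 1 / (1 + \exp[\beta (x - \alpha)])}: ~1 well inside
#' the radial cutoff `alpha`, 0.5 at `alpha`, ~0 outside.
#'
#' @param x radial distance(s), Angstrom, >= 0.
#' @param params a [hydration_params()].
#' @return weight(s) in (0, 1).
#' @export
sigma_r <- function(x, params) {
  1 / (1 + exp(pmin(700, params$beta * (x - params$alpha))))
}

#' Signed axial weight
#'
#' \eqn{\sigma_z(x) = (x/\gamma) \exp(1/2 - x^2 / 2\gamma^2)}:
#' antisymmetric, with extrema +1 at \eqn{x = +\gamma} and -1 at
#' \eqn{x = -\gamma}; inward-side waters (x < 0) get negative weight.
#'
#' @param x signed axial offset(s) z - z0, Angstrom.
#' @param params a [hydration_params()].
#' @return signed weight(s) in [-1, 1].
#' @export
sigma_z <- function(x, params) {
  g <- params$gamma
  (x / g) * exp(0.5 - x^2 / (2 * g^2))
}

#' Continuous hydration order parameter
#'
#' Signed water count around the binding site: positive when hydration is
#' outward-weighted (site connected towards the outside), negative when
#' inward-weighted.
#'
#' @param frame a [tp_frame()].
#' @param water_selection [atom_selection()] of water oxygens.
#' @param params a [hydration_params()].
#' @return scalar n_access; 0 with a warning when the selection is empty.
#' @export
n_access <- function(frame, water_selection, params) {
  idx <- if (inherits(water_selection, "atom_selection"))
    water_selection$indices else as.integer(water_selection)
  if (length(idx) == 0L) {
    warning("empty water selection: n_access = 0")
    return(0)
  }
  w <- frame_coords(frame, water_selection)
  dr <- sweep(w, 2, params$r0)
  r <- sqrt(rowSums(dr^2))
  sum(sigma_r(r, params) * sigma_z(w[, 3] - params$z0, params))
}

# internal: pairwise minimum-image distance matrix for an orthorhombic box
min_image_dist <- function(coords, box = NULL) {
  n <- nrow(coords)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(coords[, k], coords[, k], `-`)
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Single-linkage water clustering with slab exclusion
#'
#' Waters inside the exclusion slab (a z interval cutting the periodic bulk
#' solvent phase in two) are removed; the rest are clustered by
#' single-linkage under the minimum-image oxygen-oxygen distance with the
#' given cutoff. Clusters reaching within `attach` (in z) of the retained
#' region's lower face are flagged inward bulk; of the upper face, outward
#' bulk. A membrane-spanning cluster can be both.
#'
#' @param frame a [tp_frame()] with an orthorhombic `box`.
#' @param water_selection [atom_selection()] of water oxygens.
#' @param cutoff clustering distance cutoff, Angstrom (default 3.0).
#' @param slab length-2 z interval `c(lo, hi)` to exclude; `lo > hi` wraps
#'   through the periodic boundary. `NULL` defaults to a 10 Angstrom slab
#'   centred on the periodic boundary z = 0 (the bulk mid-plane of the
#'   fixtures).
#' @param attach bulk-face attachment distance in z, Angstrom (default 3.0).
#' @return object of class `water_clustering`: `labels` (cluster id per
#'   retained water, NA for slab-excluded), `retained` (indices into the
#'   water selection), `bulk_in`, `bulk_out` (cluster-id sets), `faces`
#'   (inward/outward z of the retained region), `cutoff`, `slab`.
#' @export
cluster_waters <- function(frame, water_selection, cutoff = 3.0, slab = NULL,
                           attach = 3.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  box <- frame$box
  if (is.null(slab)) {
    if (is.null(box)) stop("slab must be given when the frame has no box")
    hw <- 5
    slab <- c(box[3] - hw, hw)   # wraps through z = 0
  }
  w <- frame_coords(frame, water_selection)
  z <- w[, 3]
  if (!is.null(box)) z <- z %% box[3]
  in_slab <- if (slab[1] <= slab[2]) z >= slab[1] & z <= slab[2]
             else z >= slab[1] | z <= slab[2]
  retained <- which(!in_slab)
  face_in <- if (slab[1] <= slab[2]) slab[2] else slab[2]
  face_out <- slab[1]
  labels <- rep(NA_integer_, length(z))
  bulk_in <- integer(0); bulk_out <- integer(0)
  if (length(retained) > 0L) {
    wr <- w[retained, , drop = FALSE]
    dm <- min_image_dist(wr, box)
    adj <- dm <= cutoff
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    labels[retained] <- comp
    zr <- z[retained]
    # faces are z values of the retained region boundary; attachment in z
    near_in <- zr <= face_in + attach & zr >= face_in
    near_out <- zr >= face_out - attach & zr <= face_out
    bulk_in <- sort(unique(comp[near_in]))
    bulk_out <- sort(unique(comp[near_out]))
  }
  structure(list(labels = labels, retained = retained,
                 bulk_in = bulk_in, bulk_out = bulk_out,
                 faces = c(inward = face_in, outward = face_out),
                 cutoff = cutoff, slab = slab),
            class = "water_clustering")
}

#' Water-access state of the binding site
#'
#' Classifies the probe atom (proton-carrying aspartate carboxyl oxygen
#' stand-in) by the bulk character of the water clusters it contacts:
#' `inward` / `outward` if it touches only inward / outward bulk water,
#' `connected` if it touches both sides (including one membrane-spanning
#' cluster), `occluded` if it touches no bulk water at all.
#'
#' @param frame a [tp_frame()].
#' @param probe single-atom [atom_selection()].
#' @param clustering a [cluster_waters()] result for the same frame.
#' @param water_selection the water selection used for the clustering.
#' @param contact_cutoff probe-water contact distance, Angstrom (default 3.0).
#' @return one of `"inward"`, `"outward"`, `"occluded"`, `"connected"`.
#' @export
classify_access <- function(frame, probe, clustering, water_selection,
                            contact_cutoff = 3.0) {
  pidx <- if (inherits(probe, "atom_selection")) probe$indices
          else as.integer(probe)
  if (length(pidx) != 1L) stop("probe selection must contain exactly one atom")
  p <- frame_coords(frame, pidx)
  ret <- clustering$retained
  if (length(ret) == 0L) return("occluded")
  w <- frame_coords(frame, water_selection)[ret, , drop = FALSE]
  dvec <- sweep(w, 2, as.numeric(p))
  if (!is.null(frame$box))
    for (k in 1:3) dvec[, k] <- dvec[, k] -
      frame$box[k] * round(dvec[, k] / frame$box[k])
  d <- sqrt(rowSums(dvec^2))
  touched <- unique(clustering$labels[ret][d <= contact_cutoff])
  has_in <- any(touched %in% clustering$bulk_in)
  has_out <- any(touched %in% clustering$bulk_out)
  if (has_in && has_out) "connected"
  else if (has_in) "inward"
  else if (has_out) "outward"
  else "occluded"
}

#' Hydration series over a trajectory
#'
#' @param frames list of [tp_frame()]s.
#' @param water_selection,probe selections shared by all frames.
#' @param params a [hydration_params()].
#' @param cutoff,slab,attach,contact_cutoff see [cluster_waters()] and
#'   [classify_access()].
#' @return data.frame: time, n_access, access_state, n_clusters.
#' @export
hydration_series <- function(frames, water_selection, probe, params,
                             cutoff = 3.0, slab = NULL, attach = 3.0,
                             contact_cutoff = 3.0) {
  rows <- lapply(frames, function(fr) {
    cl <- cluster_waters(fr, water_selection, cutoff, slab, attach)
    data.frame(
      time = fr$time,
      n_access = n_access(fr, water_selection, params),
      access_state = classify_access(fr, probe, cl, water_selection,
                                     contact_cutoff),
      n_clusters = length(unique(stats::na.omit(cl$labels))),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
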