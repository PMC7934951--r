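#' Bin index of a point projected onto the vessel surface
#'
#' Radially projects 3-D points onto the cylindrical vessel surface
#' (preserving the axial coordinate and the azimuth) and returns the index of
#' the fixed 0.5 um x 0.5 um surface patch hit. Used to build the sensory
#' map: VEGFR activations on filopodia far from the cell body are credited to
#' the surface patch directly beneath them, which can belong to the
#' neighbouring cell's territory.
#'
#' @param pos matrix of points (one per row, um) or a single 3-vector.
#' @param geom cylinder geometry list with `yc`, `zc` (axis centre), `radius`,
#'   `Lx_um` (vessel length, periodic), `site_um`, `nbin_ax`, `nbin_ci`
#'   (as stored in an `msm_state$geom`).
#' @return integer vector of 1-based bin indices (length `nbin_ax * nbin_ci`
#'   linearised, axial index fastest).
#' @export
surface_bin <- function(pos, geom) {
  pos <- rbind(pos)
  dimnames(pos) <- NULL
  dy <- geom$yc - pos[, 2]
  dz <- pos[, 3] - geom$zc
  if (any(abs(dy) < 1e-12 & abs(dz) < 1e-12))
    stop("point on the cylinder axis: azimuth undefined")
  th <- atan2(dz, dy) %% (2 * pi)
  ax <- floor((pos[, 1] %% geom$Lx_um) / geom$site_um)
  ax[ax >= geom$nbin_ax] <- geom$nbin_ax - 1L
  ci <- floor(th / (2 * pi) * geom$nbin_ci)
  ci[ci >= geom$nbin_ci] <- geom$nbin_ci - 1L
  as.integer(1L + ax + geom$nbin_ax * ci)
}

#' Project a point radially onto the vessel surface
#'
#' The displacement vector from the point to the cylinder axis (in the
#' cross-sectional plane) is normalised and scaled to the vessel radius,
#' yielding the closest surface point with the same axial coordinate and
#' azimuth. Points already on the surface map to themselves.
#'
#' @inheritParams surface_bin
#' @param point a 3-vector (um).
#' @return list with `surface_point` (3-vector on the cylinder) and `bin`
#'   (its sensory-map bin index).
#' @export
project_activation <- function(point, geom) {
  dy <- point[2] - geom$yc
  dz <- point[3] - geom$zc
  r <- sqrt(dy^2 + dz^2)
  if (r < 1e-12) stop("point on the cylinder axis: projection undefined")
  sp <- c(point[1], geom$yc + dy / r * geom$radius,
          geom$zc + dz / r * geom$radius)
  list(surface_point = sp, bin = surface_bin(rbind(sp), geom))
}

#' Sensory-map intensity
#'
#' The sum of VEGFR activations across the sensory map. Because the radial
#' projection conserves activation counts, this equals the total activated
#' receptor count of all cells at that step.
#'
#' @param counts numeric vector (or matrix) of per-bin activation counts.
#' @return total intensity (activations).
#' @export
map_intensity <- function(counts) sum(counts)

#' Shannon entropy of the sensory map (bits)
#'
#' The spatial distribution of VEGFR activations is turned into a probability
#' distribution by Laplace smoothing, p_i = (v_i + alpha) / (sum(v) + N *
#' alpha), and the Shannon entropy H = -sum p_i log2 p_i is returned in bits.
#' H is bounded by log2(N), attained only for the exactly uniform smoothed
#' distribution.
#'
#' @param counts numeric vector (or matrix) of per-bin activation counts.
#' @param alpha Laplace smoothing pseudo-count (> 0); default 1.
#' @return entropy in bits.
#' @examples
#' map_entropy(c(1, 1, 1, 1), alpha = 1e-9)   # ~2 bits, uniform over 4 bins
#' @export
map_entropy <- function(counts, alpha = 1) {
  stopifnot(alpha > 0)
  v <- as.numeric(counts)
  p <- (v + alpha) / (sum(v) + length(v) * alpha)
  -sum(p * log2(p))
}

#' Run the two-cell active-perception testbed
#'
#' Simulates the minimal two-cell vessel with the sensory map recorded each
#' step, and scores the patterning time by the Dll4-advantage criterion (one
#' cell holding a lead of at least `dll4_advantage` ligands for
#' `dll4_window` consecutive steps; the waiting window is subtracted from the
#' reported time).
#'
#' @param params an [msm_params()] list.
#' @param seed integer seed.
#' @param steps run length (default: `params$max_steps` by VEGF mode).
#' @param mesh_density optional mesh density override.
#' @return list with the `msm_trace` (`$trace`, including `I` and `H` per
#'   step) and the [dll4_advantage_time()] result (`$pattern`).
#' @export
ap_signature_run <- function(params = msm_params(), seed = 1, steps = NULL,
                             mesh_density = NULL) {
  tr <- msm_run(params, n_cells = 2, seed = seed, steps = steps,
                record_ap = TRUE, mesh_density = mesh_density)
  list(trace = tr, pattern = dll4_advantage_time(tr))
}
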