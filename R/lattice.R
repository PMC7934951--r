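#' VEGF field over the simulation lattice
#'
#' The environment is a 3-D lattice of 0.5 um cubic sites carrying a static
#' VEGF concentration: either a linear gradient rising along y and anchored at
#' zero concentration at y = 0, or a uniform level everywhere.
#'
#' @param mode "gradient" (I = V * y) or "uniform" (I = V everywhere).
#' @param V slope of the gradient, or the flat concentration in uniform mode.
#' @param y_units whether y in the gradient formula is the lattice site index
#'   ("site", default) or the physical coordinate in micrometres ("um").
#' @param site_um physical edge length of one lattice site (0.5 um).
#' @return object of class `vegf_field`.
#' @examples
#' f <- vegf_field("gradient", V = 0.04)
#' vegf_at(f, c(0, 10, 0))   # 0.4
#' @export
vegf_field <- function(mode = c("gradient", "uniform"), V = 0.04,
                       y_units = "site", site_um = 0.5) {
  mode <- match.arg(mode)
  stopifnot(V >= 0, y_units %in% c("site", "um"))
  structure(list(mode = mode, V = V, y_units = y_units, site_um = site_um),
            class = "vegf_field")
}

#' VEGF concentration at a lattice site
#'
#' @param field a [vegf_field()].
#' @param site integer site index triple (x, y, z), 0-based, or a matrix with
#'   one site per row.
#' @param dims optional lattice dimensions (number of sites per axis); when
#'   given, out-of-bounds sites raise an error.
#' @return concentration value(s), always >= 0.
#' @export
vegf_at <- function(field, site, dims = NULL) {
  site <- rbind(site)
  dimnames(site) <- NULL
  if (!is.null(dims)) {
    if (any(site < 0) || any(site >= rep(dims, each = nrow(site))))
      stop("site outside lattice bounds")
  }
  y <- site[, 2]
  if (field$mode == "uniform") return(rep(field$V, length(y)))
  if (field$y_units == "um") y <- y * field$site_um
  field$V * y
}

#' Snap a continuous position to its lattice site
#'
#' Half-open cube convention: position p belongs to site k iff
#' k * 0.5 <= p < (k + 1) * 0.5 on each axis.
#'
#' @param position numeric 3-vector in micrometres, or a matrix of positions
#'   (one per row).
#' @param site_um lattice site edge length (0.5 um).
#' @param dims optional lattice dimensions; out-of-volume positions error.
#' @return integer site triple (or matrix), 0-based.
#' @examples
#' snap_to_grid(c(0.5, 0.0, 0.0))   # c(1, 0, 0)
#' @export
snap_to_grid <- function(position, site_um = 0.5, dims = NULL) {
  m <- rbind(position)
  dimnames(m) <- NULL
  s <- floor(m / site_um)
  storage.mode(s) <- "integer"
  if (!is.null(dims)) {
    if (any(s < 0) || any(s >= rep(dims, each = nrow(s))))
      stop("position outside simulated volume")
  }
  if (is.null(dim(position))) s[1, ] else s
}

#' Local sensory VEGF input of a memAgent
#'
#' The input driving receptor activation at a site is the mean VEGF level over
#' the site itself and its free (extracellular) Moore neighbours. For a linear
#' gradient with a fully free neighbourhood this equals the site's own level,
#' since neighbours at y - 1 and y + 1 average out.
#'
#' @param field a [vegf_field()].
#' @param site integer site triple (0-based).
#' @param occ optional 3-D occupancy array (0 = free); occupied neighbour
#'   sites are excluded from the average.
#' @param dims lattice dimensions; defaults to `dim(occ)` when available.
#' @return mean VEGF input (scalar).
#' @export
sensing_input <- function(field, site, occ = NULL, dims = NULL) {
  if (is.null(dims) && !is.null(occ)) dims <- dim(occ)
  nb <- moore_neighbourhood(site, dims, include_self = TRUE)
  if (!is.null(occ)) {
    idx <- nb + 1L
    free <- occ[cbind(idx[, 1], idx[, 2], idx[, 3])] == 0L
    free[1] <- TRUE  # own site always counts
    nb <- nb[free, , drop = FALSE]
  }
  mean(vegf_at(field, nb))
}

#' 26-connected Moore neighbourhood of a lattice site
#'
#' @param site integer site triple (0-based).
#' @param dims optional lattice dimensions used to clip out-of-bounds sites.
#' @param include_self prepend the site itself.
#' @return integer matrix of neighbour sites, one per row.
#' @keywords internal
moore_neighbourhood <- function(site, dims = NULL, include_self = FALSE) {
  off <- .moore_offsets
  nb <- sweep(off, 2, as.integer(site), "+")
  if (include_self) nb <- rbind(matrix(as.integer(site), 1), nb)
  if (!is.null(dims)) {
    keep <- nb[, 1] >= 0L & nb[, 2] >= 0L & nb[, 3] >= 0L &
      nb[, 1] < dims[1] & nb[, 2] < dims[2] & nb[, 3] < dims[3]
    nb <- nb[keep, , drop = FALSE]
  }
  nb
}

.moore_offsets <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g
})

#' Dump the VEGF lattice as a data frame
#'
#' One row per site with columns x, y, z (0-based indices) and vegf. Intended
#' for inspection/export of small lattices.
#'
#' @param field a [vegf_field()].
#' @param dims lattice dimensions (sites per axis).
#' @return data.frame with columns x, y, z, vegf.
#' @export
lattice_to_df <- function(field, dims) {
  g <- expand.grid(x = seq_len(dims[1]) - 1L, y = seq_len(dims[2]) - 1L,
                   z = seq_len(dims[3]) - 1L)
  g$vegf <- vegf_at(field, as.matrix(g))
  g
}
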