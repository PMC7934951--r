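#' Build a cylindrical vessel of memAgent cells
#'
#' Constructs the resting geometry of a pre-existing vessel: `n_cells` cells
#' arranged as a ring along the vessel axis (periodic ends), each cell 10 um
#' wide and spanning one full cross-section of a 6 um diameter cylinder. Each
#' cell's surface is a quad ring-lattice of membrane agents (memAgents)
#' connected by Hookean springs; at the default mesh density a cell comprises
#' approximately 1200 memAgents. Agents whose lattice site has a Moore
#' neighbour occupied by another cell are flagged as junction agents.
#'
#' The lattice y axis points away from the vessel wall at y = 0, where the
#' VEGF gradient is anchored at zero; the lattice leaves at least 20 um of
#' headroom above the vessel so filopodia never reach the ceiling under
#' control parameters.
#'
#' @param n_cells number of cells (>= 2; lateral inhibition is undefined for
#'   a single cell).
#' @param mesh_density target agent density in agents per um^2; `NULL` uses
#'   the default mesh (24 axial x 50 circumferential agents per cell,
#'   about 6.4 agents per um^2).
#' @param params an [msm_params()] list (geometry fields are read from it).
#' @return an environment of class `msm_vessel` holding agent positions,
#'   lattice sites, junction flags, apposition lists, springs and the
#'   occupancy lattice.
#' @examples
#' v <- build_vessel(2)
#' table(v$cell)          # about 1200 agents per cell
#' @export
build_vessel <- function(n_cells = 10, mesh_density = NULL,
                         params = msm_params()) {
  if (n_cells < 2) stop("n_cells must be >= 2 (lateral inhibition undefined)")
  su <- params$site_um
  r <- params$radius_um
  w <- params$cell_width_um
  n_ax <- params$mesh_axial
  n_ci <- params$mesh_circ
  if (!is.null(mesh_density)) {
    d0 <- (n_ax * n_ci) / (2 * pi * r * w)
    s <- sqrt(mesh_density / d0)
    n_ax <- max(4L, as.integer(round(n_ax * s)))
    n_ci <- max(8L, as.integer(round(n_ci * s)))
  }
  yc <- r                      # cylinder centre height: wall bottom at y = 0
  z_margin <- 8                # lateral headroom for wandering filopodia (um)
  zc <- r + z_margin
  Lx_um <- n_cells * w
  Ly_um <- 2 * r + params$headroom_um
  Lz_um <- 2 * (r + z_margin)
  dims <- as.integer(ceiling(c(Lx_um, Ly_um, Lz_um) / su))

  # agent grid: one ring of n_ci agents per axial station, n_ax stations/cell
  cell <- rep(seq_len(n_cells), each = n_ax * n_ci)
  ax <- rep(rep(seq_len(n_ax) - 1L, each = n_ci), times = n_cells)
  ci <- rep(seq_len(n_ci) - 1L, times = n_ax * n_cells)
  x <- (cell - 1L) * w + (ax + 0.5) * (w / n_ax)
  th <- 2 * pi * (ci + 0.5) / n_ci          # theta = 0 at the vessel bottom
  y <- yc - r * cos(th)
  z <- zc + r * sin(th)
  pos <- cbind(x, y, z)
  site <- snap_to_grid(pos, su)
  n <- nrow(pos)

  # occupancy lattice (1-based indices internally), cell id per site
  occ <- array(0L, dim = dims)
  occ[site + 1L] <- cell

  # junction detection + apposition lists, with periodic wrap along x.
  # cross-cell Moore adjacency needs |delta x_site| <= 1, so only agents in
  # the first/last two site columns of each cell can qualify.
  near_edge <- logical(n)
  for (k in seq_len(n_cells)) {
    b <- which(cell == k)
    rng <- range(site[b, 1])
    near_edge[b] <- site[b, 1] <= rng[1] + 1L | site[b, 1] >= rng[2] - 1L
  }
  cand <- which(near_edge)
  key <- function(s) s[, 1] + dims[1] * (s[, 2] + dims[2] * s[, 3])
  ckey <- key(site[cand, , drop = FALSE])
  ord <- cand[order(ckey)]
  skey <- sort(ckey)
  nc <- length(ord)
  appose <- vector("list", n)
  is_junction <- logical(n)
  off <- rbind(c(0L, 0L, 0L), .moore_offsets)
  for (d in seq_len(nrow(off))) {
    nb <- cbind((site[cand, 1] + off[d, 1]) %% dims[1],
                site[cand, 2] + off[d, 2], site[cand, 3] + off[d, 3])
    ok <- nb[, 2] >= 0L & nb[, 2] < dims[2] & nb[, 3] >= 0L & nb[, 3] < dims[3]
    nkey <- key(nb)
    first <- match(nkey, skey)
    hit <- which(ok & !is.na(first))
    for (h in hit) {
      i <- cand[h]
      j <- first[h]
      while (j <= nc && skey[j] == nkey[h]) {
        other <- ord[j]
        if (cell[other] != cell[i]) {
          is_junction[i] <- TRUE
          appose[[i]] <- c(appose[[i]], other)
        }
        j <- j + 1L
      }
    }
  }

  # quad-lattice springs: circumferential + axial neighbours (wrapping the
  # ring and the periodic vessel ends)
  idx <- matrix(seq_len(n), nrow = n_ci)        # n_ci x (n_ax * n_cells)
  ncol_tot <- ncol(idx)
  e_circ <- cbind(as.vector(idx), as.vector(idx[c(2:n_ci, 1), ]))
  e_ax <- cbind(as.vector(idx[, seq_len(ncol_tot)]),
                as.vector(idx[, c(2:ncol_tot, 1)]))
  edges <- rbind(e_circ, e_ax)
  dx <- pos[edges[, 1], ] - pos[edges[, 2], ]
  # wrap axial distance across the periodic seam
  dx[, 1] <- ifelse(abs(dx[, 1]) > Lx_um / 2,
                    dx[, 1] - sign(dx[, 1]) * Lx_um, dx[, 1])
  rest <- sqrt(rowSums(dx^2))

  v <- new.env(parent = emptyenv())
  v$params <- params
  v$n_cells <- as.integer(n_cells)
  v$n_ax <- n_ax; v$n_ci <- n_ci
  v$n_body <- n
  v$pos <- pos
  v$site <- site
  v$cell <- cell
  v$ax <- ax; v$ci <- ci
  v$is_junction <- is_junction
  v$appose <- appose
  v$occ <- occ
  v$dims <- dims
  v$Lx_um <- Lx_um
  v$yc <- yc; v$zc <- zc
  v$edges <- edges
  v$rest <- rest
  v$fixed <- rep(TRUE, n)     # cells are pinned in the constrained model
  v$cells <- lapply(seq_len(n_cells), function(k) {
    b <- which(cell == k)
    list(body_idx = b, junction_idx = b[is_junction[b]])
  })
  class(v) <- "msm_vessel"
  v
}

#' @export
print.msm_vessel <- function(x, ...) {
  cat(sprintf("memAgent vessel: %d cells, %d memAgents (%d x %d per cell), %d junction agents\n",
              x$n_cells, x$n_body, x$n_ax, x$n_ci, sum(x$is_junction)))
  invisible(x)
}

#' Equal integer split of a cell pool over its memAgents
#'
#' Each agent receives `floor(total / n)` units; the integer remainder is
#' assigned one unit each to `total %% n` agents chosen by a rotating
#' (round-robin) offset, so the allocation is deterministic yet spatially
#' unbiased over time. Conservation is exact: the allocations always sum to
#' `floor(total)`.
#'
#' @param total pool size (non-negative; fractional totals are floored).
#' @param n number of agents.
#' @param offset rotation offset (e.g. the time step) for remainder placement.
#' @return integer vector of length `n` summing to `floor(total)`.
#' @export
distribute_pool <- function(total, n, offset = 0L) {
  total <- max(0, floor(total))
  base <- total %/% n
  rem <- total %% n
  out <- rep.int(as.integer(base), n)
  if (rem > 0) {
    pick <- ((as.integer(offset) + seq_len(rem) - 1L) %% n) + 1L
    out[pick] <- out[pick] + 1L
  }
  out
}

#' Distribute a cell's receptor and ligand pools over its current surface
#'
#' VEGFR is split equally over all of the cell's current memAgents (body plus
#' any filopodia agents); Dll4 is split equally over the cell's junction
#' agents only, since ligand presentation requires apposition to another
#' cell's membrane. Fractional Dll4 is allowed (ligand amounts are treated as
#' continuous); receptors are integer counts.
#'
#' @param vegfr_total,dll4_total current cell pools.
#' @param n_agents number of memAgents currently composing the cell.
#' @param junction_idx indices (within the cell's agents) of junction agents.
#' @param offset round-robin offset for the receptor remainder.
#' @return list with integer vector `vegfr` (length `n_agents`) and numeric
#'   vector `dll4` (length `n_agents`, zero off-junction).
#' @export
distribute_receptors <- function(vegfr_total, dll4_total, n_agents,
                                 junction_idx, offset = 0L) {
  stopifnot(n_agents >= 1)
  vegfr <- distribute_pool(vegfr_total, n_agents, offset)
  dll4 <- numeric(n_agents)
  if (length(junction_idx) > 0)
    dll4[junction_idx] <- dll4_total / length(junction_idx)
  list(vegfr = vegfr, dll4 = dll4)
}

#' Relax a spring mesh by damped iteration
#'
#' Damped Jacobi relaxation of Hookean springs: each free vertex moves along
#' the net spring force scaled by the damping factor. Fixed vertices (vessel
#' body agents pinned to their initial positions, and filopodium adhesion
#' anchors) never move. Total spring energy is checked to be non-increasing
#' over each full pass; an energy increase raises an error suggesting a
#' smaller damping factor.
#'
#' @param pos n x 3 matrix of vertex positions.
#' @param edges m x 2 integer matrix of spring endpoints.
#' @param rest length-m rest lengths (> 0).
#' @param fixed logical length-n; `TRUE` vertices do not move.
#' @param stiffness spring constant (force per um).
#' @param damping step factor in (0, 1].
#' @param n_iterations relaxation passes.
#' @return list with updated `pos` and the per-pass `energy` trace (the first
#'   entry is the initial energy).
#' @export
relax_springs <- function(pos, edges, rest, fixed,
                          stiffness = 1.0, damping = 0.5, n_iterations = 5) {
  stopifnot(all(rest > 0), stiffness > 0, damping > 0)
  energy <- function(p) {
    d <- p[edges[, 1], , drop = FALSE] - p[edges[, 2], , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    0.5 * stiffness * sum((len - rest)^2)
  }
  e <- energy(pos)
  trace <- e
  free <- which(!fixed)
  if (length(free) == 0) return(list(pos = pos, energy = trace))
  for (it in seq_len(n_iterations)) {
    d <- pos[edges[, 1], , drop = FALSE] - pos[edges[, 2], , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    len[len == 0] <- 1e-12
    fmag <- stiffness * (len - rest) / len    # tension per unit displacement
    fvec <- d * fmag
    force <- matrix(0, nrow(pos), 3)
    for (ax in 1:3) {
      force[, ax] <- force[, ax] -
        unname(tapply(fvec[, ax], factor(edges[, 1], levels = seq_len(nrow(pos))), sum, default = 0))
      force[, ax] <- force[, ax] +
        unname(tapply(fvec[, ax], factor(edges[, 2], levels = seq_len(nrow(pos))), sum, default = 0))
    }
    force[is.na(force)] <- 0
    pos[free, ] <- pos[free, , drop = FALSE] + damping * force[free, , drop = FALSE]
    e_new <- energy(pos)
    if (e_new > e + 1e-9 * max(1, e))
      stop("spring relaxation diverged (energy increased); reduce damping")
    e <- e_new
    trace <- c(trace, e)
  }
  list(pos = pos, energy = trace)
}

#' Export the per-agent state of a vessel as a data frame
#'
#' @param vessel an `msm_vessel`.
#' @return data frame with one row per body memAgent: position, lattice site,
#'   cell id and junction flag.
#' @export
vessel_to_df <- function(vessel) {
  data.frame(agent = seq_len(vessel$n_body),
             cell = vessel$cell,
             x = vessel$pos[, 1], y = vessel$pos[, 2], z = vessel$pos[, 3],
             sx = vessel$site[, 1], sy = vessel$site[, 2], sz = vessel$site[, 3],
             junction = vessel$is_junction)
}
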