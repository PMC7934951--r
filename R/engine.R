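#' Initialise a memAgent-spring model simulation
#'
#' Builds the vessel, seeds the random stream, primes the gene-regulation
#' delay buffers with zeros and prepares the per-step trace. Two testbed
#' modes exist: `"vessel"` (all cells are responsive endothelial cells,
#' lateral inhibition on the full ring) and `"hysteresis"` (three cells where
#' the outer two are non-responsive pseudo-cells presenting a fixed external
#' Dll4 total `d_ext`, split equally between them, and consuming the centre
#' cell's junction Dll4 without ever responding).
#'
#' @param params an [msm_params()] list.
#' @param n_cells number of cells (forced to 3 in hysteresis mode).
#' @param seed integer seed for the single global random stream.
#' @param mode "vessel" or "hysteresis".
#' @param max_steps trace capacity (defaults from `params` by VEGF mode).
#' @param record_ap accumulate the sensory map each step and record the
#'   active-perception measures I and H.
#' @param mesh_density optional agents per um^2 override (see
#'   [build_vessel()]).
#' @param vessel optionally a prebuilt `msm_vessel` to reuse (geometry is
#'   copied where mutated).
#' @return an environment of class `msm_state`; advance it with [msm_step()].
#' @export
msm_init <- function(params = msm_params(), n_cells = params$n_cells,
                     seed = 1, mode = c("vessel", "hysteresis"),
                     max_steps = NULL, record_ap = FALSE,
                     mesh_density = NULL, vessel = NULL) {
  mode <- match.arg(mode)
  if (mode == "hysteresis") n_cells <- 3L
  set.seed(as.integer(seed))
  if (is.null(max_steps))
    max_steps <- if (params$vegf_mode == "uniform") params$max_steps_uniform else params$max_steps
  v <- if (is.null(vessel)) build_vessel(n_cells, mesh_density, params) else vessel
  field <- vegf_field(params$vegf_mode, params$V, params$vegf_y_units,
                      params$site_um)

  st <- new.env(parent = emptyenv())
  st$p <- params
  st$v <- v
  st$field <- field
  st$mode <- mode
  st$seed <- as.integer(seed)
  st$n_cells <- v$n_cells
  st$ec <- if (mode == "hysteresis") c(FALSE, TRUE, FALSE) else rep(TRUE, v$n_cells)
  st$t <- 0L
  st$max_steps <- as.integer(max_steps)
  st$d_ext <- 0

  nc <- v$n_cells
  st$vegfr_cell <- ifelse(st$ec, params$vegfr_max, 0)
  st$d_cell <- numeric(nc)
  st$actin <- ifelse(st$ec, params$actin_max, 0)
  st$nstar_buf <- delay_buffer(params$delay_steps, nc)
  st$astar_buf <- delay_buffer(params$delay_steps, nc)
  st$rr_off <- integer(nc)                 # round-robin remainder offsets

  # per-cell static lookups
  st$body_idx <- lapply(v$cells, `[[`, "body_idx")
  st$jn <- lapply(v$cells, `[[`, "junction_idx")
  st$n_j <- vapply(st$jn, length, 1L)
  st$body_f <- lapply(st$body_idx, function(b)
    vegf_at(field, v$site[b, , drop = FALSE]))
  geom <- list(yc = v$yc, zc = v$zc, radius = params$radius_um,
               Lx_um = v$Lx_um, site_um = params$site_um,
               nbin_ax = as.integer(round(v$Lx_um / params$site_um)),
               nbin_ci = as.integer(round(2 * pi * params$radius_um / params$site_um)))
  st$geom <- geom
  st$body_bin <- lapply(st$body_idx, function(b)
    surface_bin(v$pos[b, , drop = FALSE], geom))

  # directed interface table for Notch binding: for each ordered cell pair
  # (a binds b's ligand), the number of a's junction agents apposed to b
  # (binders) and of b's junction agents apposed to a (presenters). Flank
  # pseudo-cells in hysteresis mode interact with the centre cell only.
  st$flank_jn <- vector("list", nc)
  apposed_cells <- lapply(seq_len(v$n_body), function(i)
    unique(v$cell[v$appose[[i]]]))
  for (k in seq_len(nc)) {
    if (!st$ec[k]) {
      j <- st$jn[[k]]
      face_ec <- vapply(apposed_cells[j], function(ac) any(st$ec[ac]), TRUE)
      st$flank_jn[[k]] <- j[face_ec]
    }
  }
  ifc <- list()
  for (a in seq_len(nc)) for (b in seq_len(nc)) {
    if (a == b) next
    if (!st$ec[a] && !st$ec[b]) next     # flank-flank: no signalling
    ja <- st$jn[[a]]
    n_bind <- sum(vapply(apposed_cells[ja], function(ac) b %in% ac, TRUE))
    if (n_bind == 0) next
    jb <- st$jn[[b]]
    n_pres <- sum(vapply(apposed_cells[jb], function(ac) a %in% ac, TRUE))
    ifc[[length(ifc) + 1L]] <- c(a = a, b = b, n_bind = n_bind,
                                 n_pres = n_pres)
  }
  st$interfaces <- do.call(rbind, ifc)

  # extension-probability normaliser: 1.5 x the per-agent receptor count at
  # rest, so the control propensity F = 2 maps fully activated agents to
  # P = 2/1.5 * f capped at 1; scales with mesh density automatically
  st$p_cap <- if (is.null(params$p_cap))
    1.5 * params$vegfr_max / (v$n_body / v$n_cells)
  else params$p_cap

  st$occ <- v$occ                           # mutated by filopodia

  # filopodia live in flat slot-indexed arrays: slot s owns chain rows
  # (s-1)*chain_cap + 1 .. (s-1)*chain_cap + len
  st$chain_cap <- 96L
  st$fil_cap <- 256L
  nslot <- st$fil_cap * st$chain_cap
  st$fch_x <- integer(nslot); st$fch_y <- integer(nslot)
  st$fch_z <- integer(nslot)
  st$fch_f <- numeric(nslot); st$fch_bin <- integer(nslot)
  st$fil_cell <- integer(st$fil_cap)        # 0 = unused slot
  st$fil_len <- integer(st$fil_cap)
  st$fil_idle <- integer(st$fil_cap)
  st$fil_retr <- logical(st$fil_cap)
  st$fil_base <- integer(st$fil_cap)
  st$fil_adh <- vector("list", st$fil_cap)  # anchored chain positions
  st$fil_order <- integer(0)                # active slots in creation order
  st$fil_free <- seq_len(st$fil_cap)
  st$adh_every <- as.integer(round(2 / params$site_um))   # anchors every 2 um

  st$bases <- lapply(seq_len(nc), function(k)
    matrix(integer(0), ncol = 2))           # active base (ax, ci) per cell
  st$base_agent <- lapply(seq_len(nc), function(k) integer(0))

  st$record_ap <- isTRUE(record_ap)
  T <- st$max_steps
  z <- matrix(NA_real_, T, nc)
  st$tr <- list(D = z, VEGFR = z, NSTAR = z, ASTAR = z, NFIL = z,
                FILAG = z, ACTIN = z)
  st$I <- rep(NA_real_, T)
  st$H <- rep(NA_real_, T)
  st$last_map <- NULL
  class(st) <- "msm_state"
  st
}

#' @export
print.msm_state <- function(x, ...) {
  cat(sprintf("msm_state: %d cells (%s mode), t = %d/%d, seed %d\n",
              x$n_cells, x$mode, x$t, x$max_steps, x$seed))
  invisible(x)
}

#' Advance a memAgent-spring model simulation by one time step
#'
#' Per-step update order (fixed and documented): (1) distribute the cell
#' pools over the current surface; (2) activate VEGFR locally; (3) Notch-Dll4
#' binding across junctions with consumptive debiting; (4) filopodia extend,
#' idle or burst-retract, then new filopodia initiate; (5) spring relaxation
#' (a no-op in the constrained testbeds, where all body agents are pinned and
#' chain agents are lattice-anchored between adhesions); (6) delayed gene
#' regulation. Random draws are consumed in a fixed documented order (per
#' cell: tip extension draws, per-winner direction draws, initiation draws,
#' initiation shuffle, per-initiation direction draws), so runs are exactly
#' reproducible from the seed.
#'
#' @param st an `msm_state` from [msm_init()].
#' @return the state, invisibly (it is modified in place).
#' @export
msm_step <- function(st) {
  p <- st$p
  v <- st$v
  t <- st$t + 1L
  if (t > st$max_steps) stop("trace capacity exhausted; raise max_steps")
  nc <- st$n_cells
  cost <- p$token_strength * p$site_um
  ccap <- st$chain_cap

  # take ownership of the hot arrays (release the environment binding so
  # element writes below modify them in place, then rebind at the end)
  own <- function(nm) { x <- st[[nm]]; st[[nm]] <- NULL; x }
  fch_x <- own("fch_x"); fch_y <- own("fch_y"); fch_z <- own("fch_z")
  fch_f <- own("fch_f"); fch_bin <- own("fch_bin")
  fil_cell <- own("fil_cell"); fil_len <- own("fil_len")
  fil_idle <- own("fil_idle"); fil_retr <- own("fil_retr")
  fil_base <- own("fil_base"); fil_adh <- own("fil_adh")
  fil_order <- own("fil_order"); fil_free <- own("fil_free")
  occ <- own("occ")
  tr <- own("tr")
  order_all <- fil_order

  # ---- (1)+(2) distribute pools and activate VEGFR --------------------------
  fil_of_cell <- vector("list", nc)     # active slots per cell, stable order
  if (length(order_all)) {
    fc <- fil_cell[order_all]
    for (k in seq_len(nc)) fil_of_cell[[k]] <- order_all[fc == k]
  }
  body_act <- vector("list", nc)
  chain_idx <- vector("list", nc)       # flat chain-array rows, per cell
  chain_act <- vector("list", nc)       # activation of those rows
  tip_act <- vector("list", nc)         # activation at each fil's tip
  astar <- numeric(nc)
  n_tot <- integer(nc)
  for (k in seq_len(nc)) {
    nb <- length(st$body_idx[[k]])
    if (!st$ec[k]) { n_tot[k] <- nb; body_act[[k]] <- numeric(0); next }
    slots <- fil_of_cell[[k]]
    lens <- fil_len[slots]
    ncha <- sum(lens)
    ntot <- nb + ncha
    n_tot[k] <- ntot
    base <- st$vegfr_cell[k] %/% ntot
    rem <- st$vegfr_cell[k] %% ntot
    ones <- if (rem > 0) ((seq_len(ntot) - 1L - st$rr_off[k]) %% ntot) < rem else FALSE
    st$rr_off[k] <- (st$rr_off[k] + rem) %% ntot
    va <- base + ones
    if (ncha > 0) {
      idx <- sequence(lens, from = (slots - 1L) * ccap + 1L)
      f_all <- c(st$body_f[[k]], fch_f[idx])
      act <- pmin(va, va * f_all)
      ca <- act[-seq_len(nb)]
      chain_idx[[k]] <- idx
      chain_act[[k]] <- ca
      tip_act[[k]] <- ca[cumsum(lens)]
    } else {
      act <- pmin(va, va * st$body_f[[k]])
      chain_idx[[k]] <- integer(0)
      chain_act[[k]] <- numeric(0)
      tip_act[[k]] <- numeric(0)
    }
    body_act[[k]] <- act[seq_len(nb)]
    astar[k] <- sum(act)
  }

  # ---- (3) Notch-Dll4 binding across directed interfaces --------------------
  # Each cell's Dll4 sits spread equally over its junction agents; on each
  # directed interface the binder cell takes min(binder Notch capacity,
  # presented share), the aggregate outcome of per-agent min() binding with
  # consumptive debiting on a dense mesh.
  d_per <- numeric(nc)
  for (k in seq_len(nc)) {
    d_per[k] <- if (st$ec[k]) {
      if (st$n_j[k] > 0) st$d_cell[k] / st$n_j[k] else 0
    } else {
      njf <- length(st$flank_jn[[k]])
      if (njf > 0) (st$d_ext / 2) / njf else 0
    }
  }
  notch_m <- p$notch_pool / n_tot
  ifc <- st$interfaces
  share <- d_per[ifc[, "b"]] * ifc[, "n_pres"]
  cap <- notch_m[ifc[, "a"]] * ifc[, "n_bind"]
  take <- pmin(share, cap)
  nstar <- numeric(nc)
  consumed <- numeric(nc)
  for (r in seq_along(take)) {
    nstar[ifc[r, "a"]] <- nstar[ifc[r, "a"]] + take[r]
    consumed[ifc[r, "b"]] <- consumed[ifc[r, "b"]] + take[r]
  }
  for (k in seq_len(nc))
    if (st$ec[k]) st$d_cell[k] <- st$d_cell[k] - consumed[k]

  # ---- sensory map (before filopodia change): project this step's
  # activations radially onto the fixed cylindrical surface ------------------
  if (st$record_ap) {
    ecs <- which(st$ec)
    bins <- c(unlist(st$body_bin[ecs], use.names = FALSE),
              fch_bin[unlist(chain_idx[ecs], use.names = FALSE)])
    w <- c(unlist(body_act[ecs], use.names = FALSE),
           unlist(chain_act[ecs], use.names = FALSE))
    N <- st$geom$nbin_ax * st$geom$nbin_ci
    counts <- numeric(N)
    if (length(bins)) {
      agg <- rowsum(w, bins)
      counts[as.integer(rownames(agg))] <- agg[, 1]
    }
    st$last_map <- counts
    I_ <- st$I; st$I <- NULL; I_[t] <- sum(counts); st$I <- I_
    H_ <- st$H; st$H <- NULL; H_[t] <- map_entropy(counts, p$laplace_alpha)
    st$H <- H_
  }

  # ---- (4) filopodia --------------------------------------------------------
  dims <- v$dims
  for (k in seq_len(nc)) {
    if (!st$ec[k]) next
    slots <- fil_of_cell[[k]]
    ns <- length(slots)
    if (ns) {
      # tip extension attempts (batched draws, winners processed in order)
      pe <- pmin(1, p$F * tip_act[[k]] / st$p_cap)
      draws <- stats::runif(ns) < pe
      retr <- fil_retr[slots]
      extended <- logical(ns)
      for (j in which(draws & !retr)) {
        if (st$actin[k] < cost) break
        s <- slots[j]
        len <- fil_len[s]
        if (len >= ccap) next                       # storage limit: idle
        row <- (s - 1L) * ccap + len
        nsite <- choose_step_direction(
          c(fch_x[row], fch_y[row], fch_z[row]),
          st$field, p$G, occ)
        if (is.null(nsite)) next
        row2 <- row + 1L
        fch_x[row2] <- nsite[1]; fch_y[row2] <- nsite[2]
        fch_z[row2] <- nsite[3]
        fch_f[row2] <- vegf_at(st$field, nsite)
        fch_bin[row2] <- surface_bin(rbind((nsite + 0.5) * p$site_um),
                                     st$geom)
        occ[1L + nsite[1] + dims[1] * (nsite[2] + dims[2] * nsite[3])] <- k
        fil_len[s] <- len + 1L
        st$actin[k] <- st$actin[k] - cost
        if ((len + 1L) %% st$adh_every == 0L)
          fil_adh[[s]] <- c(fil_adh[[s]], len + 1L)
        extended[j] <- TRUE
      }
      fil_idle[slots[extended]] <- 0L
      idlers <- slots[!extended & !retr]
      fil_idle[idlers] <- fil_idle[idlers] + 1L
      newly <- idlers[fil_idle[idlers] >= p$filtipmax]
      fil_retr[newly] <- TRUE

      # burst retraction: one burst per step per retracting filopodium
      for (s in slots[fil_retr[slots]]) {
        len <- fil_len[s]
        rb <- retract_burst(len, fil_adh[[s]])
        if (rb$removed > 0) {
          rows <- ((s - 1L) * ccap + rb$new_len + 1L):((s - 1L) * ccap + len)
          occ[1L + fch_x[rows] +
                dims[1] * (fch_y[rows] + dims[2] * fch_z[rows])] <- 0L
          st$actin[k] <- st$actin[k] + rb$removed * cost
        }
        fil_len[s] <- rb$new_len
        fil_adh[[s]] <- rb$adhesions
        if (rb$new_len == 0L) {                     # fully retracted
          fil_cell[s] <- 0L
          fil_retr[s] <- FALSE
          fil_idle[s] <- 0L
          fil_free <- c(fil_free, s)
          fil_order <- fil_order[fil_order != s]
          b <- st$base_agent[[k]]
          at <- which(b == fil_base[s])
          if (length(at)) {
            st$base_agent[[k]] <- b[-at]
            st$bases[[k]] <- st$bases[[k]][-at, , drop = FALSE]
          }
        }
      }
    }

    # new initiations (attempted only while actin remains)
    if (st$actin[k] < cost) next
    bidx <- st$body_idx[[k]]
    pe <- pmin(1, p$F * body_act[[k]] / st$p_cap)
    draw <- stats::runif(length(bidx)) < pe
    cand <- which(draw)
    if (!length(cand)) next
    cand <- cand[!(bidx[cand] %in% st$base_agent[[k]])]
    if (!length(cand)) next
    if (length(cand) > 1) cand <- cand[sample.int(length(cand))]
    cand <- cand[seq_len(min(length(cand), ceiling(st$actin[k] / cost)))]
    for (ci in cand) {
      if (st$actin[k] < cost) break
      gi <- bidx[ci]
      axci <- c(v$ax[gi], v$ci[gi])
      B <- st$bases[[k]]
      if (nrow(B)) {
        dax <- abs(B[, 1] - axci[1])
        dci <- abs(B[, 2] - axci[2])
        dci <- pmin(dci, v$n_ci - dci)
        if (any(pmax(dax, dci) < p$filspacing)) next
      }
      nsite <- choose_step_direction(v$site[gi, ], st$field, p$G, occ)
      if (is.null(nsite)) next
      if (!length(fil_free)) {                      # grow the slot arrays
        old_cap <- st$fil_cap
        new_cap <- old_cap * 2L
        extra <- (new_cap - old_cap) * ccap
        fch_x <- c(fch_x, integer(extra)); fch_y <- c(fch_y, integer(extra))
        fch_z <- c(fch_z, integer(extra))
        fch_f <- c(fch_f, numeric(extra)); fch_bin <- c(fch_bin, integer(extra))
        fil_cell <- c(fil_cell, integer(new_cap - old_cap))
        fil_len <- c(fil_len, integer(new_cap - old_cap))
        fil_idle <- c(fil_idle, integer(new_cap - old_cap))
        fil_retr <- c(fil_retr, logical(new_cap - old_cap))
        fil_base <- c(fil_base, integer(new_cap - old_cap))
        fil_adh <- c(fil_adh, vector("list", new_cap - old_cap))
        fil_free <- (old_cap + 1L):new_cap
        st$fil_cap <- new_cap
      }
      s <- fil_free[1L]
      fil_free <- fil_free[-1L]
      row <- (s - 1L) * ccap + 1L
      fch_x[row] <- nsite[1]; fch_y[row] <- nsite[2]
      fch_z[row] <- nsite[3]
      fch_f[row] <- vegf_at(st$field, nsite)
      fch_bin[row] <- surface_bin(rbind((nsite + 0.5) * p$site_um),
                                  st$geom)
      occ[1L + nsite[1] + dims[1] * (nsite[2] + dims[2] * nsite[3])] <- k
      fil_cell[s] <- k
      fil_len[s] <- 1L
      fil_idle[s] <- 0L
      fil_retr[s] <- FALSE
      fil_base[s] <- gi
      fil_adh[s] <- list(integer(0))
      fil_order <- c(fil_order, s)
      st$actin[k] <- st$actin[k] - cost
      st$bases[[k]] <- rbind(st$bases[[k]], axci)
      st$base_agent[[k]] <- c(st$base_agent[[k]], gi)
    }
  }

  # ---- (5) spring relaxation: all body agents are pinned and chain agents
  # are lattice-anchored, so there are no free vertices to move ---------------

  # ---- (6) delayed gene regulation ------------------------------------------
  ndel <- st$nstar_buf$read()
  adel <- st$astar_buf$read()
  st$nstar_buf$push(nstar)
  st$astar_buf$push(astar)
  for (k in seq_len(nc)) {
    if (!st$ec[k]) next
    up <- gene_regulation_update(st$d_cell[k], ndel[k], adel[k], p)
    st$vegfr_cell[k] <- up$vegfr_cell
    st$d_cell[k] <- up$d_cell
  }

  # ---- record ---------------------------------------------------------------
  nfil <- filag <- numeric(nc)
  if (length(fil_order)) {
    fc <- fil_cell[fil_order]
    fl <- fil_len[fil_order]
    for (k in seq_len(nc)) {
      sel <- fc == k
      nfil[k] <- sum(sel)
      filag[k] <- sum(fl[sel])
    }
  }
  tr$D[t, ] <- st$d_cell
  tr$VEGFR[t, ] <- st$vegfr_cell
  tr$NSTAR[t, ] <- nstar
  tr$ASTAR[t, ] <- astar
  tr$NFIL[t, ] <- nfil
  tr$FILAG[t, ] <- filag
  tr$ACTIN[t, ] <- st$actin

  # rebind the owned arrays
  st$fch_x <- fch_x; st$fch_y <- fch_y; st$fch_z <- fch_z
  st$fch_f <- fch_f; st$fch_bin <- fch_bin
  st$fil_cell <- fil_cell; st$fil_len <- fil_len
  st$fil_idle <- fil_idle; st$fil_retr <- fil_retr
  st$fil_base <- fil_base; st$fil_adh <- fil_adh
  st$fil_order <- fil_order; st$fil_free <- fil_free
  st$occ <- occ
  st$tr <- tr
  st$t <- t
  invisible(st)
}

#' Run a memAgent-spring model simulation
#'
#' Convenience driver: initialise with [msm_init()] and advance `steps`
#' steps, returning the per-step trace.
#'
#' @inheritParams msm_init
#' @param steps number of steps to simulate (default: full trace capacity).
#' @return a list of class `msm_trace`: per-step per-cell matrices `D`
#'   (Dll4), `VEGFR`, `NSTAR` (Notch activation), `ASTAR` (VEGFR activation),
#'   `NFIL`/`FILAG` (filopodium and chain-agent counts), `ACTIN`, and, when
#'   `record_ap`, vectors `I` and `H`; plus `params`, `seed`, `n_cells`.
#' @examples
#' \donttest{
#' tr <- msm_run(msm_params(), n_cells = 2, seed = 1, steps = 50)
#' tail(tr$D)
#' }
#' @export
msm_run <- function(params = msm_params(), n_cells = params$n_cells, seed = 1,
                    steps = NULL, record_ap = FALSE, mesh_density = NULL,
                    mode = "vessel") {
  st <- msm_init(params, n_cells, seed, mode = mode,
                 max_steps = steps, record_ap = record_ap,
                 mesh_density = mesh_density)
  for (i in seq_len(st$max_steps)) msm_step(st)
  msm_trace(st)
}

#' Extract the recorded trace from a simulation state
#'
#' @param st an `msm_state`.
#' @return an `msm_trace` list (see [msm_run()]); rows beyond the current
#'   step are dropped.
#' @export
msm_trace <- function(st) {
  t <- st$t
  out <- lapply(st$tr, function(m) m[seq_len(t), , drop = FALSE])
  out$I <- st$I[seq_len(t)]
  out$H <- st$H[seq_len(t)]
  out$params <- st$p
  out$seed <- st$seed
  out$n_cells <- st$n_cells
  out$mode <- st$mode
  class(out) <- "msm_trace"
  out
}

#' @export
print.msm_trace <- function(x, ...) {
  cat(sprintf("msm_trace: %d cells, %d steps (%s mode, seed %d)\n",
              x$n_cells, nrow(x$D), x$mode, x$seed))
  invisible(x)
}
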