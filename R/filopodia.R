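#' Probability that a memAgent extends a filopodium this step
#'
#' Extension is stochastic with probability proportional to the agent's
#' activated receptor count: P = min(1, F * Vegfr* / p_cap). The normaliser
#' `p_cap` defaults to the per-agent receptor count at rest under control
#' parameters, so that at F = 2 a fully activated agent extends with
#' probability scaled into (0, 1].
#'
#' @param F extension propensity parameter, range (0, 3).
#' @param vegfr_active activated receptor count of the agent (vectorised).
#' @param p_cap probability normaliser.
#' @return extension probability in `[0, 1]`.
#' @export
extension_probability <- function(F, vegfr_active, p_cap = 10) {
  pmin(1, F * vegfr_active / p_cap)
}

#' Stochastic filopodium extension decision
#'
#' Draws an extension event with probability [extension_probability()].
#' Filopodia do not extend without actin: if the cell's available actin is
#' below the cost of one grid step the draw is made (consuming the random
#' stream deterministically) but the event is suppressed.
#'
#' @param vegfr_active activated receptor count of the agent.
#' @param params an [msm_params()] list (`F`, `p_cap`, `token_strength`,
#'   `site_um` are used).
#' @param actin_available the cell's current actin pool (um-tokens).
#' @return logical: whether an extension event takes place.
#' @export
maybe_extend <- function(vegfr_active, params, actin_available) {
  p <- extension_probability(params$F, vegfr_active, params$p_cap)
  hit <- stats::runif(1) < p
  cost <- params$token_strength * params$site_um
  hit && actin_available >= cost
}

#' Choose the next lattice site for an extending filopodium tip
#'
#' Candidate sites are the unoccupied 26-neighbours of the tip site (the x
#' axis wraps around the periodic vessel; y and z are clipped at the lattice
#' boundary). With probability G the candidate with the highest VEGF level is
#' chosen (ties broken uniformly at random); otherwise a candidate is chosen
#' uniformly at random -- so the up-gradient site is never excluded, random
#' stepping can still land on it.
#'
#' @param site current tip site (integer triple, 0-based).
#' @param field a [vegf_field()].
#' @param G guidance probability in `[0, 1]`.
#' @param occ 3-D occupancy array (0 = free).
#' @param wrap_x wrap the x axis (periodic vessel ends).
#' @return the chosen site (integer triple), or `NULL` when no candidate site
#'   is free (the tip idles).
#' @export
choose_step_direction <- function(site, field, G, occ, wrap_x = TRUE) {
  dims <- dim(occ)
  x <- .moore_offsets[, 1] + site[1]
  y <- .moore_offsets[, 2] + site[2]
  z <- .moore_offsets[, 3] + site[3]
  if (wrap_x) x <- x %% dims[1]
  keep <- x >= 0L & x < dims[1] & y >= 0L & y < dims[2] & z >= 0L & z < dims[3]
  if (!any(keep)) return(NULL)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  free <- occ[1L + x + dims[1] * (y + dims[2] * z)] == 0L
  if (!any(free)) return(NULL)
  x <- x[free]; y <- y[free]; z <- z[free]
  if (stats::runif(1) < G) {
    vals <- if (field$mode == "uniform") rep(field$V, length(y))
    else field$V * (if (field$y_units == "um") y * field$site_um else y)
    best <- which(vals == max(vals))
    pick <- if (length(best) == 1) best else best[sample.int(length(best), 1)]
  } else {
    pick <- sample.int(length(x), 1)
  }
  c(x[pick], y[pick], z[pick])
}

#' Burst retraction of a filopodium
#'
#' Once a tip has idled for `filtipmax` steps the filopodium retracts in
#' short rapid bursts: each burst snaps the chain back to the most distal
#' remaining adhesion, deleting the traversed memAgents; the reached adhesion
#' is then released so the next burst can proceed. When no adhesion remains
#' the whole chain retracts to its base and the filopodium is removed, with
#' all actin returned to the cell pool.
#'
#' This is the pure bookkeeping core used by the simulation engine: it
#' operates on a chain description and returns the updated one.
#'
#' @param chain_len current chain length (number of chain memAgents).
#' @param adhesions integer vector of anchored chain positions (1-based along
#'   the chain), possibly empty.
#' @return list with `new_len` (chain length after the burst; 0 means the
#'   filopodium is gone), `removed` (number of agents deleted) and the
#'   remaining `adhesions` after releasing the reached one.
#' @export
retract_burst <- function(chain_len, adhesions) {
  if (chain_len == 0)
    return(list(new_len = 0L, removed = 0L, adhesions = integer(0)))
  adhesions <- adhesions[adhesions <= chain_len]
  if (length(adhesions) == 0) {
    list(new_len = 0L, removed = as.integer(chain_len), adhesions = integer(0))
  } else {
    a <- max(adhesions)
    list(new_len = as.integer(a), removed = as.integer(chain_len - a),
         adhesions = adhesions[adhesions < a])
  }
}
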