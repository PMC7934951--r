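#' VEGF receptor activation of a memAgent
#'
#' The number of activated receptor-ligand complexes on an agent is its local
#' receptor count times its local VEGF input, capped at the receptor count
#' itself (no more receptors can be active than are present). Activation is
#' kept continuous (expected counts): quantising it to integers would create
#' dead zones in which weakly activated cells produce exactly zero signal.
#'
#' @param vegfr receptor count(s) held by the agent(s).
#' @param sensing local VEGF input (see [sensing_input()]); vectorised.
#' @return activated receptor count(s), `<= vegfr`.
#' @examples
#' activate_vegfr(10, 0.5)   # 5
#' activate_vegfr(10, 2.0)   # 10 (capped)
#' @export
activate_vegfr <- function(vegfr, sensing) {
  pmin(vegfr, vegfr * sensing)
}

#' Notch activation of a junction memAgent
#'
#' A junction agent binds the Dll4 presented by apposed agents of the
#' neighbouring cell, up to its local Notch availability: Notch* =
#' min(available Dll4, notch_max). Exactly Notch* units of Dll4 are debited
#' from the apposed agents (binding is consumptive), walking the apposed list
#' in order.
#'
#' @param available_dll4 numeric vector of Dll4 currently held by the apposed
#'   agents (in the order they are debited).
#' @param notch_max local Notch availability of the binding agent.
#' @return list with `notch_active` (the bound amount) and `remaining`
#'   (the apposed Dll4 vector after debiting).
#' @examples
#' bind_notch(c(2, 1), 5)$notch_active   # 3 (Dll4-limited)
#' bind_notch(c(6, 3), 5)$notch_active   # 5 (Notch-limited)
#' @export
bind_notch <- function(available_dll4, notch_max) {
  take <- min(sum(available_dll4), notch_max)
  left <- take
  rem <- available_dll4
  i <- 1L
  while (left > 1e-12 && i <= length(rem)) {
    d <- min(rem[i], left)
    rem[i] <- rem[i] - d
    left <- left - d
    i <- i + 1L
  }
  list(notch_active = take, remaining = rem)
}

#' Delayed gene-regulatory update of a cell's receptor and ligand pools
#'
#' Notch lateral inhibition acts through gene expression with a fixed delay:
#' the VEGFR pool is set from the Notch activation recorded `delay` steps ago
#' (Vegfr_cell = max(0, Vegfr_max - sigma * N*')), and Dll4 is produced from
#' the VEGFR activation recorded `delay` steps ago
#' (D_cell = min(d_max, D_cell + delta * Vegfr*')). In "replace" mode the
#' Dll4 pool is set to delta * Vegfr*' instead of accumulating.
#'
#' @param d_cell current Dll4 pool (after any Notch consumption this step).
#' @param nstar_delayed cell Notch activation from `delay` steps ago.
#' @param astar_delayed cell VEGFR activation from `delay` steps ago.
#' @param params an [msm_params()] list (sigma, delta, vegfr_max, d_max,
#'   dll4_mode are used).
#' @return list with updated `vegfr_cell` and `d_cell`.
#' @examples
#' p <- msm_params()
#' gene_regulation_update(0, 0, 0, p)$vegfr_cell   # uninhibited: vegfr_max
#' @export
gene_regulation_update <- function(d_cell, nstar_delayed, astar_delayed,
                                   params) {
  vegfr <- max(0, round(params$vegfr_max - params$sigma * nstar_delayed))
  d_new <- if (identical(params$dll4_mode, "replace"))
    params$delta * astar_delayed
  else
    d_cell + params$delta * astar_delayed
  list(vegfr_cell = vegfr, d_cell = max(0, min(params$d_max, d_new)))
}

#' Ring buffer implementing the gene-regulatory delay
#'
#' Holds per-cell records for `delay_steps` steps; reading returns the record
#' from `delay_steps` ago (zero-primed before that many pushes).
#'
#' @param delay_steps buffer capacity (28 by default in the model).
#' @param n_cells record width.
#' @return environment of class `delay_buffer` with `$read()` and
#'   `$push(values)` methods.
#' @export
delay_buffer <- function(delay_steps, n_cells) {
  b <- new.env(parent = emptyenv())
  b$buf <- matrix(0, nrow = delay_steps, ncol = n_cells)
  b$ptr <- 1L
  b$delay <- as.integer(delay_steps)
  b$read <- function() b$buf[b$ptr, ]
  b$push <- function(values) {
    b$buf[b$ptr, ] <- values
    b$ptr <- if (b$ptr == b$delay) 1L else b$ptr + 1L
    invisible(NULL)
  }
  class(b) <- "delay_buffer"
  b
}
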