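#' Default memAgent-spring model parameters
#'
#' Returns the full parameter set for the constrained (non-migratory)
#' memAgent-spring model of tip cell selection. Control values follow the
#' published calibration of the model family; loss-of-function (LOF) and
#' gain-of-function (GOF) conditions are obtained by overriding `F`, `V` or
#' `G` within their stated ranges.
#'
#' @param ... named overrides of any default parameter.
#'
#' @details
#' Tunable biology parameters:
#' \describe{
#'   \item{F}{filopodia extension propensity, range (0, 3); control 2.
#'     LOF 0.5, GOF 3.}
#'   \item{V}{VEGF concentration parameter: slope of the linear gradient
#'     (control 0.04, LOF 0.02) or the flat level in uniform mode
#'     (control 0.8).}
#'   \item{G}{guidance: probability that an extending filopodium steps into
#'     the neighbouring lattice site with maximal VEGF; control 0.9.}
#'   \item{vegf_mode}{"gradient" or "uniform".}
#'   \item{filtipmax}{idle steps at the tip before burst retraction starts; 15.}
#'   \item{token_strength}{actin cost per micrometre of filopodium; 1.}
#'   \item{filspacing}{minimum Chebyshev spacing (in memAgent mesh units)
#'     between filopodia bases on one cell; 2.}
#' }
#'
#' Notch/gene-regulation parameters (cell scale):
#' \describe{
#'   \item{vegfr_max}{cell VEGFR pool ceiling (receptors); 12000, i.e. 10 per
#'     memAgent at the default 1200-agent mesh.}
#'   \item{notch_pool}{cell Notch pool distributed equally over all current
#'     memAgents; 13200 (11 per agent at rest). An active cell with many
#'     filopodium agents therefore dilutes Notch at its junctions.}
#'   \item{sigma}{Notch -> VEGFR inhibition strength; 13, placing full
#'     inhibition of an undefended cell near an external Dll4 level of 950.}
#'   \item{delta}{VEGFR* -> Dll4 production gain; 0.55.}
#'   \item{d_max}{Dll4 ceiling; 10000 (the 600-ligand pattern criterion is 6
#'     percent of this value).}
#'   \item{delay_steps}{gene-regulatory delay; 28 time steps.}
#'   \item{actin_max}{actin budget per cell in micrometre-tokens; 360.}
#'   \item{p_cap}{probability normaliser for extension,
#'     P = min(1, F * Vegfr*_m / p_cap); `NULL` (default) resolves at
#'     initialisation to 1.5 x the per-agent receptor count of the resting
#'     mesh (15 at the default 1200-agent mesh), so it adapts to the mesh
#'     density in use.}
#' }
#'
#' Pattern criteria: `dll4_advantage` 600 ligands held for `dll4_window` 100
#' steps (two-cell runs); 4-5 non-adjacent tip cells stable for
#' `stability_window` 100 steps (ring runs); `max_steps` 2000 in gradient
#' mode, 5000 in uniform mode.
#'
#' @return a named list of class `msm_params`.
#' @examples
#' p <- msm_params(F = 0.5)          # filopodia LOF
#' p$F
#' @export
msm_params <- function(...) {
  p <- list(
    # biology / experiment dials
    F = 2, V = 0.04, G = 0.9, vegf_mode = "gradient",
    # filopodia
    filtipmax = 15, token_strength = 1, filspacing = 2,
    actin_max = 360, p_cap = NULL,
    # signalling / gene regulation
    vegfr_max = 12000, notch_pool = 13200,
    sigma = 13, delta = 0.55, d_max = 10000, delay_steps = 28,
    dll4_mode = "accumulate",
    # geometry
    n_cells = 10, radius_um = 3, cell_width_um = 10,
    mesh_axial = 24, mesh_circ = 50, site_um = 0.5,
    headroom_um = 25,
    # y-units for the gradient: "site" (lattice index) or "um"
    vegf_y_units = "um",
    # pattern criteria
    min_tips = 4, max_tips = 5, stability_window = 100,
    dll4_advantage = 600, dll4_window = 100,
    max_steps = 2000, max_steps_uniform = 5000,
    # tip classification: not-inhibited threshold as fraction of vegfr_max
    tip_vegfr_frac = 0.5,
    # hysteresis protocol
    d_ext_step = 50, transient_steps = 250, stat_window = 250,
    epsilon = 0.5, max_steps_per_level = 60000,
    # sensory map
    laplace_alpha = 1,
    # spring mechanics (cells pinned in this constrained mode)
    spring_stiffness = 1.0, spring_damping = 0.5, relax_iterations = 5
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(p$F >= 0, p$F <= 3, p$G >= 0, p$G <= 1, p$V > 0)
  if (!p$vegf_mode %in% c("gradient", "uniform"))
    stop("vegf_mode must be 'gradient' or 'uniform'")
  class(p) <- c("msm_params", "list")
  p
}

#' @export
print.msm_params <- function(x, ...) {
  cat("memAgent-spring model parameters\n")
  cat(sprintf("  F = %g, V = %g (%s), G = %g\n", x$F, x$V, x$vegf_mode, x$G))
  cat(sprintf("  vegfr_max = %g, notch_pool = %g, sigma = %g, delta = %g, d_max = %g\n",
              x$vegfr_max, x$notch_pool, x$sigma, x$delta, x$d_max))
  cat(sprintf("  delay = %d steps, filtipmax = %d, actin = %g um-tokens\n",
              x$delay_steps, x$filtipmax, x$actin_max))
  invisible(x)
}
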