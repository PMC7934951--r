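# shared test helpers: small meshes and traces built in code

# reduced-density parameters for fast dynamical tests; the mesh is coarser
# (about 300 agents per cell) but cell-level pools are unchanged
fast_density <- 2.0

fast_params <- function(...) msm_params(...)

# build a fake two-cell trace with prescribed Dll4 columns
fake_trace2 <- function(D1, D2, params = msm_params()) {
  T <- length(D1)
  z <- matrix(0, T, 2)
  out <- list(D = cbind(D1, D2), VEGFR = z, NSTAR = z, ASTAR = z,
              NFIL = z, FILAG = z, ACTIN = z,
              I = rep(NA_real_, T), H = rep(NA_real_, T),
              params = params, seed = 0L, n_cells = 2L, mode = "vessel")
  class(out) <- "msm_trace"
  out
}

# fake ring trace from per-step tip flags: nfil and vegfr matrices
fake_ring_trace <- function(NFIL, VEGFR, params = msm_params()) {
  T <- nrow(NFIL)
  n <- ncol(NFIL)
  z <- matrix(0, T, n)
  out <- list(D = z, VEGFR = VEGFR, NSTAR = z, ASTAR = z, NFIL = NFIL,
              FILAG = z, ACTIN = z, I = rep(NA_real_, T),
              H = rep(NA_real_, T), params = params, seed = 0L,
              n_cells = n, mode = "vessel")
  class(out) <- "msm_trace"
  out
}
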