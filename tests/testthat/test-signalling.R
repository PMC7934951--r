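test_that("receptor activation is proportional and capped", {
  expect_equal(activate_vegfr(10, 0.5), 5)
  expect_equal(activate_vegfr(10, 0), 0)
  expect_equal(activate_vegfr(10, 2.0), 10)   # a receptor is active or not
  expect_equal(activate_vegfr(c(4, 8), c(0.25, 3)), c(1, 8))
})

test_that("Notch binding takes min(Dll4, Notch) and debits the source", {
  r <- bind_notch(c(2, 1), notch_max = 5)
  expect_equal(r$notch_active, 3)
  expect_equal(r$remaining, c(0, 0))
  r2 <- bind_notch(c(6, 3), notch_max = 5)
  expect_equal(r2$notch_active, 5)
  expect_equal(r2$remaining, c(1, 3))    # debited in order
  expect_equal(bind_notch(numeric(0), 5)$notch_active, 0)
  expect_equal(bind_notch(c(0, 0), 5)$notch_active, 0)
  # equality case: Dll4 == Notch binds everything
  expect_equal(bind_notch(5, 5)$notch_active, 5)
})

test_that("gene regulation applies inhibition, production and bounds", {
  p <- msm_params(sigma = 10, delta = 0.5, vegfr_max = 1000, d_max = 2000)
  up <- gene_regulation_update(0, 0, 0, p)
  expect_equal(up$vegfr_cell, 1000)       # uninhibited cell
  expect_equal(gene_regulation_update(0, 200, 0, p)$vegfr_cell, 0)  # floored
  expect_equal(gene_regulation_update(100, 0, 300, p)$d_cell, 250)
  expect_equal(gene_regulation_update(1990, 0, 300, p)$d_cell, 2000) # ceiling
  pr <- msm_params(sigma = 10, delta = 0.5, dll4_mode = "replace")
  expect_equal(gene_regulation_update(999, 0, 300, pr)$d_cell, 150)
})

test_that("delay buffer returns the record from delay steps ago", {
  b <- delay_buffer(28, 2)
  # zero-primed: the first 28 reads are zero
  for (t in 1:28) {
    expect_equal(b$read(), c(0, 0))
    b$push(c(t, -t))
  }
  # from t = 29 on, reads lag pushes by exactly 28 steps
  for (t in 29:100) {
    expect_equal(b$read(), c(t - 28, -(t - 28)))
    b$push(c(t, -t))
  }
})

test_that("two-cell dynamics match a cell-level delay map with filopodia off", {
  # brute-force oracle: with F = 0 (no filopodia) and uniform VEGF, the full
  # agent-based update collapses to a two-variable delayed map that can be
  # iterated directly at cell level
  p <- msm_params(F = 1e-9, vegf_mode = "uniform", V = 0.8)
  steps <- 220
  tr <- msm_run(p, n_cells = 2, seed = 1, steps = steps)

  v <- build_vessel(2, params = p)
  n_bind <- sum(v$is_junction & v$cell == 1)    # binder agents per cell
  cap <- p$notch_pool / 1200 * n_bind           # junction Notch capacity
  V <- c(p$vegfr_max, p$vegfr_max); D <- c(0, 0)
  bufN <- matrix(0, p$delay_steps, 2); bufA <- bufN; ptr <- 1
  oD <- matrix(0, steps, 2); oV <- oD
  for (t in seq_len(steps)) {
    A <- 0.8 * V                                 # all receptors sub-saturated
    Nst <- pmin(rev(D), cap)                     # bind the neighbour's Dll4
    D <- D - rev(Nst)
    ndel <- bufN[ptr, ]; adel <- bufA[ptr, ]
    bufN[ptr, ] <- Nst; bufA[ptr, ] <- A
    ptr <- if (ptr == p$delay_steps) 1 else ptr + 1
    V <- pmax(0, round(p$vegfr_max - p$sigma * ndel))
    D <- pmin(p$d_max, D + p$delta * adel)
    oD[t, ] <- D; oV[t, ] <- V
  }
  expect_equal(tr$D, oD, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(tr$VEGFR, oV, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("symmetric two-cell runs stay symmetric iff extension is disabled", {
  p0 <- msm_params(F = 1e-9)   # extension probability effectively zero
  tr0 <- msm_run(p0, n_cells = 2, seed = 3, steps = 150)
  expect_equal(tr0$D[, 1], tr0$D[, 2])
  expect_equal(tr0$VEGFR[, 1], tr0$VEGFR[, 2])

  p1 <- msm_params()           # stochastic filopodia break the symmetry
  tr1 <- msm_run(p1, n_cells = 2, seed = 3, steps = 400)
  expect_gt(max(abs(tr1$ASTAR[, 1] - tr1$ASTAR[, 2])), 0)
})

test_that("a saturating external Dll4 source silences the cell", {
  # full-inhibition limit: with a large clamped source the centre cell's
  # VEGFR pool collapses to zero shortly after one delay period
  p <- msm_params(F = 1e-9)   # no filopodia: junction capacity undiluted
  st <- msm_init(p, 3, seed = 1, mode = "hysteresis", max_steps = 120,
                 mesh_density = fast_density)
  st$d_ext <- 10 * p$vegfr_max / p$sigma
  for (i in 1:120) msm_step(st)
  tr <- msm_trace(st)
  expect_equal(tr$VEGFR[120, 2], 0)
  expect_true(all(tr$VEGFR[(p$delay_steps + 5):120, 2] == 0))
})

test_that("Dll4 stays within [0, d_max] throughout a run", {
  tr <- msm_run(msm_params(), n_cells = 2, seed = 2, steps = 300)
  expect_true(all(tr$D >= 0))
  expect_true(all(tr$D <= msm_params()$d_max))
  expect_true(all(tr$VEGFR >= 0 & tr$VEGFR <= msm_params()$vegfr_max))
})
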