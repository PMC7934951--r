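test_that("extension probability is proportional to activation and capped", {
  expect_equal(extension_probability(0, 100), 0)       # F lower bound
  expect_equal(extension_probability(2, 0), 0)         # no activation
  expect_equal(extension_probability(2, 6, p_cap = 15), 0.8)
  expect_equal(extension_probability(3, 1e6), 1)       # capped at 1
})

test_that("extension requires actin regardless of the draw", {
  p <- msm_params(F = 3, p_cap = 1)   # P = 1 for any activated agent
  set.seed(1)
  expect_true(maybe_extend(10, p, actin_available = 10))
  expect_false(maybe_extend(10, p, actin_available = 0))
  expect_false(maybe_extend(0, p, actin_available = 10))  # P = 0
})

test_that("guided stepping picks the max-VEGF free neighbour when G = 1", {
  f <- vegf_field("gradient", V = 0.1, y_units = "site")
  occ <- array(0L, dim = c(7, 7, 7))
  set.seed(1)
  s <- choose_step_direction(c(3, 3, 3), f, G = 1, occ, wrap_x = FALSE)
  expect_equal(s[2], 4L)            # always steps up-gradient
  # fully occupied neighbourhood: tip idles
  occ2 <- array(1L, dim = c(7, 7, 7))
  expect_null(choose_step_direction(c(3, 3, 3), f, G = 1, occ2))
  # occupied sites are excluded: block everything except one site
  occ3 <- array(1L, dim = c(7, 7, 7))
  occ3[3, 3, 3] <- 0L               # site (2,2,2), below the tip
  s3 <- choose_step_direction(c(3, 3, 3), f, G = 1, occ3)
  expect_equal(as.integer(s3), c(2L, 2L, 2L))
})

test_that("step choice follows the G-mixture of argmax and uniform", {
  # empirical law: P(up-gradient) = G + (1 - G) * (9 free up-sites / 26)
  f <- vegf_field("gradient", V = 0.1, y_units = "site")
  occ <- array(0L, dim = c(9, 9, 9))
  up_frac <- function(G, n = 4000) {
    hits <- 0
    for (i in seq_len(n)) {
      s <- choose_step_direction(c(4, 4, 4), f, G, occ, wrap_x = FALSE)
      if (s[2] == 5L) hits <- hits + 1
    }
    hits / n
  }
  set.seed(7)
  expect_equal(up_frac(0), 9 / 26, tolerance = 0.06)
  expect_equal(up_frac(0.9), 0.9 + 0.1 * 9 / 26, tolerance = 0.04)
})

test_that("burst retraction snaps to the most distal adhesion and releases it", {
  # 5 um chain (10 agents), adhesions at 2 um and 4 um (agents 4 and 8)
  r <- retract_burst(10, c(4L, 8L))
  expect_equal(r$new_len, 8L)
  expect_equal(r$removed, 2L)
  expect_equal(r$adhesions, 4L)
  r2 <- retract_burst(r$new_len, r$adhesions)
  expect_equal(r2$new_len, 4L)
  r3 <- retract_burst(r2$new_len, r2$adhesions)
  expect_equal(r3$new_len, 0L)      # fully retracted
  expect_equal(retract_burst(0, integer(0))$removed, 0L)
})

test_that("actin ledger balances at every simulation step", {
  p <- msm_params()
  tr <- msm_run(p, n_cells = 2, seed = 5, steps = 200)
  cost_per_agent <- p$token_strength * p$site_um
  for (k in 1:2) {
    expect_equal(tr$ACTIN[, k] + cost_per_agent * tr$FILAG[, k],
                 rep(p$actin_max, nrow(tr$ACTIN)))
  }
  # total filopodia length is bounded by the actin budget
  expect_true(all(tr$FILAG * cost_per_agent <= p$actin_max))
})

test_that("mean filopodia mass responds monotonically to F", {
  mass <- vapply(c(0.5, 2, 3), function(Fv) {
    m <- vapply(1:3, function(s) {
      tr <- msm_run(msm_params(F = Fv), n_cells = 2, seed = s, steps = 150,
                    mesh_density = fast_density)
      mean(tr$FILAG[50:150, ])
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_true(mass[1] < mass[2])
  expect_true(mass[1] < mass[3])
})
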