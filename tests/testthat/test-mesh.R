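test_that("default mesh gives about 1200 memAgents per cell", {
  v <- build_vessel(2)
  counts <- table(v$cell)
  expect_true(all(counts == 1200))
  expect_equal(v$n_body, 2400)
})

test_that("a single cell is rejected (lateral inhibition undefined)", {
  expect_error(build_vessel(1), "n_cells")
})

test_that("mesh construction is deterministic", {
  v1 <- build_vessel(3)
  v2 <- build_vessel(3)
  expect_identical(v1$pos, v2$pos)
  expect_identical(v1$is_junction, v2$is_junction)
})

test_that("junctions sit on cell-cell interfaces and apposition is symmetric", {
  v <- build_vessel(3)
  # junction agents only occur in the first/last axial stations of a cell
  j <- which(v$is_junction)
  expect_true(all(v$ax[j] %in% c(0L, v$n_ax - 1L)))
  # symmetry: a is apposed to b iff b is apposed to a
  for (i in j) {
    for (b in v$appose[[i]]) {
      expect_true(i %in% v$appose[[b]])
    }
  }
  # every junction agent has at least one apposed agent of another cell
  expect_true(all(vapply(v$appose[j], length, 1L) > 0))
  expect_true(all(vapply(j, function(i)
    all(v$cell[v$appose[[i]]] != v$cell[i]), TRUE)))
})

test_that("two-cell vessel has junctions at both wrapped borders", {
  v <- build_vessel(2)
  j1 <- v$cells[[1]]$junction_idx
  # both the first and the last axial station of cell 1 touch cell 2
  expect_setequal(unique(v$ax[j1]), c(0L, v$n_ax - 1L))
})

test_that("mesh density scales the per-cell agent count", {
  v <- build_vessel(2, mesh_density = 2.0)
  expect_lt(abs(sum(v$cell == 1) / (2 * pi * 3 * 10) - 2.0), 0.5)
})

test_that("equal pool distribution conserves and splits fairly", {
  x <- distribute_pool(1200, 1200)
  expect_true(all(x == 1L))
  y <- distribute_pool(1000, 300, offset = 7)
  expect_equal(sum(y), 1000)
  expect_true(all(y %in% c(3L, 4L)))
  expect_equal(sum(y == 4L), 100)
  # rotating offset moves the remainder deterministically
  y2 <- distribute_pool(1000, 300, offset = 7)
  expect_identical(y, y2)
})

test_that("receptors go everywhere but Dll4 only to junction agents", {
  r <- distribute_receptors(vegfr_total = 1200, dll4_total = 600,
                            n_agents = 1200, junction_idx = 1:100)
  expect_true(all(r$vegfr == 1L))
  expect_equal(sum(r$dll4), 600)
  expect_true(all(r$dll4[1:100] == 6))
  expect_true(all(r$dll4[101:1200] == 0))
})

test_that("springs at rest do not move and stretched springs relax", {
  # three collinear vertices, outer two fixed
  pos <- rbind(c(0, 0, 0), c(0.2, 0, 0), c(2, 0, 0))
  edges <- rbind(c(1L, 2L), c(2L, 3L))
  rest <- c(1, 1)
  fixed <- c(TRUE, FALSE, TRUE)
  # at rest: nothing moves
  pos0 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  r0 <- relax_springs(pos0, edges, rest, fixed)
  expect_equal(r0$pos, pos0)
  # stretched asymmetrically: free vertex settles at the midpoint
  r <- relax_springs(pos, edges, rest, fixed, damping = 0.4,
                     n_iterations = 200)
  expect_equal(r$pos[2, 1], 1, tolerance = 1e-6)
})

test_that("spring energy is non-increasing across a relaxation pass", {
  set.seed(42)
  n <- 12
  pos <- matrix(runif(3 * n, 0, 2), n, 3)
  edges <- cbind(seq_len(n - 1), 2:n)
  rest <- rep(0.5, n - 1)
  fixed <- rep(FALSE, n); fixed[c(1, n)] <- TRUE
  # independent oracle: direct energy summation before/after
  energy <- function(p) {
    d <- p[edges[, 1], ] - p[edges[, 2], ]
    0.5 * sum((sqrt(rowSums(d^2)) - rest)^2)
  }
  e_before <- energy(pos)
  r <- relax_springs(pos, edges, rest, fixed, damping = 0.2,
                     n_iterations = 30)
  expect_lte(energy(r$pos), e_before)
  expect_equal(r$energy[1], e_before)
  expect_true(all(diff(r$energy) <= 1e-9))
})

test_that("vessel export lists every body agent once", {
  v <- build_vessel(2, mesh_density = 2.0)
  d <- vessel_to_df(v)
  expect_equal(nrow(d), v$n_body)
  expect_true(all(d$junction == v$is_junction))
})
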