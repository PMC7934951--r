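test_that("tip classification needs filopodia and an uninhibited pool", {
  p <- msm_params()
  expect_equal(classify_tips(c(3, 0, 2), c(12000, 12000, 11000), p), c(1L, 3L))
  # filopodia but inhibited -> not a tip
  expect_equal(classify_tips(c(3, 3), c(12000, 0), p), 1L)
  expect_length(classify_tips(c(0, 0), c(12000, 12000), p), 0)
})

test_that("non-adjacency on the ring honours the periodic wrap", {
  expect_true(tips_non_adjacent(c(1, 3, 5, 7, 9), 10))
  expect_false(tips_non_adjacent(c(1, 2), 10))
  expect_false(tips_non_adjacent(c(1, 10), 10))      # wrap adjacency
  expect_true(tips_non_adjacent(c(2, 5, 8), 10))
  expect_true(tips_non_adjacent(3L, 10))
})

test_that("a fully alternating ring of ten yields exactly five tips", {
  p <- msm_params()
  nfil <- rep(c(2, 0), 5)
  vegfr <- rep(c(p$vegfr_max, 0), 5)
  tips <- classify_tips(nfil, vegfr, p)
  expect_equal(tips, c(1L, 3L, 5L, 7L, 9L))
  expect_length(tips, 5)
  expect_true(tips_non_adjacent(tips, 10))
})

test_that("time to pattern requires a stable 100-step window", {
  p <- msm_params()
  T <- 600
  n <- 10
  # alternating stable pattern from t = 300 onwards
  NFIL <- matrix(0, T, n); VEG <- matrix(0, T, n)
  NFIL[300:T, seq(1, 9, 2)] <- 1
  VEG[300:T, seq(1, 9, 2)] <- p$vegfr_max
  tr <- fake_ring_trace(NFIL, VEG, p)
  pr <- time_to_pattern(tr)
  expect_true(pr$patterned)
  expect_equal(pr$time_to_pattern, 300L)
  expect_equal(pr$tip_ids, seq(1L, 9L, 2L))

  # an episode of only 99 steps does not qualify
  NFIL2 <- matrix(0, T, n); VEG2 <- matrix(0, T, n)
  NFIL2[300:398, seq(1, 9, 2)] <- 1
  VEG2[300:398, seq(1, 9, 2)] <- p$vegfr_max
  pr2 <- time_to_pattern(fake_ring_trace(NFIL2, VEG2, p))
  expect_false(pr2$patterned)
  expect_true(is.na(pr2$time_to_pattern))
})

test_that("Dll4 advantage timing follows the strict 600/100 rule", {
  p <- msm_params()
  T <- 700
  # advantage of 600 held from t = 400: reported time is the window start
  D1 <- rep(0, T); D1[400:T] <- 800
  pr <- dll4_advantage_time(fake_trace2(D1, rep(0, T), p))
  expect_true(pr$patterned)
  expect_equal(pr$time_to_pattern, 400L)
  expect_equal(pr$tip_ids, 1L)

  # 599 is below the strict threshold forever
  pr2 <- dll4_advantage_time(fake_trace2(rep(599, T), rep(0, T), p))
  expect_false(pr2$patterned)

  # a sign flip inside the window restarts it
  D1f <- rep(0, T); D2f <- rep(0, T)
  D1f[100:149] <- 700            # 50 steps cell 1 ahead
  D2f[150:199] <- 700            # then cell 2 ahead
  D1f[200:T] <- 700              # then cell 1 again, now stably
  prf <- dll4_advantage_time(fake_trace2(D1f, D2f, p))
  expect_equal(prf$time_to_pattern, 200L)
})

test_that("advantage scan agrees with a brute-force window search", {
  p <- msm_params()
  set.seed(11)
  for (rep in 1:5) {
    T <- 400
    D1 <- cumsum(rnorm(T, 1, 30)); D2 <- cumsum(rnorm(T, 0, 30))
    tr <- fake_trace2(D1, D2, p)
    got <- dll4_advantage_time(tr)
    # oracle: direct double-loop scan for the first qualifying window
    w <- p$dll4_window; adv <- p$dll4_advantage
    dd <- D1 - D2
    oracle <- NA_integer_
    for (t0 in seq_len(T - w + 1)) {
      win <- dd[t0:(t0 + w - 1)]
      if (all(win >= adv) || all(-win >= adv)) { oracle <- t0; break }
    }
    expect_identical(got$time_to_pattern, oracle)
  }
})

test_that("time-space export samples the logged Dll4 frames", {
  p <- msm_params()
  T <- 2000
  D1 <- seq_len(T); D2 <- rev(D1)
  tr <- fake_trace2(D1, D2, p)
  m <- export_time_space(tr, frame_stride = 100)
  expect_equal(dim(m), c(20L, 2L))
  expect_equal(m[, 1], seq(100, 2000, by = 100), ignore_attr = TRUE)
  f <- tempfile(fileext = ".csv")
  export_time_space(tr, 100, file = f)
  back <- utils::read.csv(f)
  expect_equal(back$step, seq(100, 2000, 100))
  unlink(f)
})
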