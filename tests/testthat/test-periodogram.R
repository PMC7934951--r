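test_that("a noisy sinusoid's frequency is recovered within one grid step", {
  set.seed(21)
  x <- sort(runif(300, 0, 900))      # uneven sampling
  f0 <- 2 * pi / 90
  y <- sin(f0 * x) + rnorm(300, 0, 0.1)
  sp <- lomb_scargle(x, y)
  i <- which.min(abs(sp$frequency - f0))
  step <- abs(sp$frequency[min(i + 1, length(sp$frequency))] - sp$frequency[i])
  expect_lt(abs(sp$peak$frequency - f0), 1.5 * step)
  expect_equal(sp$peak$period, 90, tolerance = 0.05)
})

test_that("power matches a direct least-squares sinusoid fit", {
  # independent oracle: fit y ~ cos(wx) + sin(wx) by lm() at each frequency;
  # Lomb-Scargle power equals the explained sum of squares / (2 * var)
  set.seed(5)
  x <- sort(runif(60, 0, 200))
  y <- sin(0.11 * x) + 0.4 * cos(0.31 * x) + rnorm(60, 0, 0.2)
  freqs <- c(0.05, 0.11, 0.2, 0.31, 0.5)
  sp <- lomb_scargle(x, y, frequencies = freqs)
  yc <- y - mean(y)
  for (j in seq_along(freqs)) {
    w <- freqs[j]
    fit <- stats::lm(yc ~ 0 + cos(w * x) + sin(w * x))
    ess <- sum(yc^2) - sum(stats::residuals(fit)^2)
    expect_equal(sp$power[j], ess / (2 * stats::var(yc)), tolerance = 1e-6)
  }
})

test_that("constant profiles give zero power and offsets do not matter", {
  x <- seq(0, 100, by = 1)
  sp <- lomb_scargle(x, rep(3.3, length(x)))
  expect_true(all(sp$power == 0))
  y <- sin(0.2 * x)
  p1 <- lomb_scargle(x, y, frequencies = c(0.1, 0.2, 0.4))$power
  p2 <- lomb_scargle(x, y + 17, frequencies = c(0.1, 0.2, 0.4))$power
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("evenly spaced data agree with the classical periodogram", {
  # at Fourier frequencies of an even grid, Lomb-Scargle power reduces to
  # |DFT|^2 / (n * var)
  set.seed(31)
  n <- 128
  x <- 0:(n - 1)
  for (rep in 1:20) {
    y <- rnorm(n)
    yc <- y - mean(y)
    ks <- sample(2:40, 4)
    w <- 2 * pi * ks / n
    sp <- lomb_scargle(x, y, frequencies = w)
    dft <- stats::fft(yc)
    classical <- Mod(dft[ks + 1])^2 / (n * stats::var(yc))
    expect_equal(sp$power, classical, tolerance = 1e-8)
  }
})

test_that("dominant period excludes the near-DC band", {
  expect_equal(dominant_period(0.07)$period, 2 * pi / 0.07, tolerance = 1e-12)
  expect_equal(dominant_period(2 * pi)$period, 1)
  # a spectrum whose largest peak is a full-span mode: excluded from dominance
  sp <- list(frequency = c(0.02, 0.07), power = c(10, 4), span = 400)
  class(sp) <- "periodogram"
  dp <- dominant_period(sp)        # period 314 > 0.8 * 400 excluded? no: 314 < 320
  expect_equal(dp$frequency, 0.02)
  sp2 <- list(frequency = c(0.012, 0.07), power = c(10, 4), span = 400)
  class(sp2) <- "periodogram"
  dp2 <- dominant_period(sp2)      # period 524 > 320: excluded
  expect_equal(dp2$frequency, 0.07)
  # all power below the floor: no dominant mode
  sp3 <- list(frequency = c(0.05, 0.07), power = c(0, 0), span = 400)
  class(sp3) <- "periodogram"
  expect_true(is.na(dominant_period(sp3)$period))
})

test_that("synthetic profiles are periodic by construction", {
  pr <- synth_profile(period = 90, n_bumps = 10, seed = 2)
  expect_true(all(diff(pr$position) > 0))
  sp <- lomb_scargle(pr$position, pr$value)
  dp <- dominant_period(sp)
  expect_equal(dp$period, 90, tolerance = 5)
  # control preset: dominant peak well above the spectrum median
  ctrl <- synth_profile(preset = "control", seed = 3)
  spc <- lomb_scargle(ctrl$position, ctrl$value)
  dpc <- dominant_period(spc)
  expect_gt(dpc$power, 2 * stats::median(spc$power))
  expect_equal(dpc$period, 90, tolerance = 8)
})

test_that("profiles round-trip through CSV", {
  pr <- synth_profile(preset = "latb", seed = 4)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(position = pr$position, value = pr$value,
                              label = attr(pr, "label")), f, row.names = FALSE)
  back <- read_profile(f)
  expect_equal(back$value, pr$value)
  expect_equal(attr(back, "label"), "latb")
  unlink(f)
})
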