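#' Lomb-Scargle periodogram of a 1-D spatial profile
#'
#' Least-squares spectral analysis for (possibly unevenly sampled) intensity
#' profiles, used to quantify spatial periodicity of staining patterns along
#' an axis. The classical Scargle formulation is implemented directly: the
#' profile is mean-subtracted, and for each angular spatial frequency omega
#' the power is
#' \deqn{P(\omega) = \frac{1}{2\sigma^2}\left[
#'   \frac{(\sum_j y_j \cos\omega(x_j-\tau))^2}{\sum_j \cos^2\omega(x_j-\tau)} +
#'   \frac{(\sum_j y_j \sin\omega(x_j-\tau))^2}{\sum_j \sin^2\omega(x_j-\tau)}
#'   \right]}
#' with the phase offset tau defined by tan(2 omega tau) = sum sin(2 omega
#' x) / sum cos(2 omega x). Frequencies are *angular* (radians per length
#' unit), so a spatial period P corresponds to f = 2 pi / P.
#'
#' @param positions strictly increasing sample coordinates (length units).
#' @param values intensity values (finite).
#' @param frequencies optional frequency grid; by default 500 log-spaced
#'   angular frequencies spanning `[2 pi / L, pi / min(dx)]` where L is the
#'   profile span.
#' @param n_freq grid size for the default grid.
#' @return list of class `periodogram`: `frequency`, `power` (>= 0),
#'   `span` (profile length), and `peak` (frequency, power, period = 2 pi /
#'   frequency at the global maximum).
#' @examples
#' x <- seq(0, 900, by = 2)
#' y <- sin(2 * pi * x / 90)
#' sp <- lomb_scargle(x, y)
#' sp$peak$period    # ~90
#' @export
lomb_scargle <- function(positions, values, frequencies = NULL, n_freq = 500) {
  stopifnot(length(positions) == length(values), length(positions) >= 4,
            all(is.finite(values)), all(diff(positions) > 0))
  x <- as.numeric(positions)
  y <- as.numeric(values) - mean(values)
  L <- diff(range(x))
  if (is.null(frequencies)) {
    f_lo <- 2 * pi / L
    f_hi <- pi / min(diff(x))
    frequencies <- exp(seq(log(f_lo), log(f_hi), length.out = n_freq))
  }
  stopifnot(all(frequencies > 0))
  s2 <- stats::var(y)
  if (s2 == 0) {
    power <- rep(0, length(frequencies))
  } else {
    power <- vapply(frequencies, function(w) {
      tau <- atan2(sum(sin(2 * w * x)), sum(cos(2 * w * x))) / (2 * w)
      ct <- cos(w * (x - tau))
      st <- sin(w * (x - tau))
      cc <- sum(ct^2)
      ss <- sum(st^2)
      pc <- if (cc > 0) sum(y * ct)^2 / cc else 0
      ps <- if (ss > 0) sum(y * st)^2 / ss else 0
      (pc + ps) / (2 * s2)
    }, numeric(1))
  }
  peak_i <- which.max(power)
  out <- list(frequency = frequencies, power = power, span = L,
              peak = list(frequency = frequencies[peak_i],
                          power = power[peak_i],
                          period = 2 * pi / frequencies[peak_i]))
  class(out) <- "periodogram"
  out
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("Lomb-Scargle periodogram: %d frequencies, peak f = %.4g (period %.4g), power %.3g\n",
              length(x$frequency), x$peak$frequency, x$peak$period,
              x$peak$power))
  invisible(x)
}

#' Dominant spatial period of a periodogram
#'
#' Converts the peak frequency to a period via P = 2 pi / f, after excluding
#' the near-DC band: modes whose period exceeds `dc_exclude_frac` of the
#' profile span describe a constant offset over the axis rather than a
#' repeating pattern, and are not eligible as the dominant mode.
#'
#' @param spectrum a `periodogram` from [lomb_scargle()], or a single
#'   frequency value (then converted directly).
#' @param dc_exclude_frac periods longer than this fraction of the span are
#'   excluded (0.8).
#' @param min_power peaks below this power are reported as no dominant mode
#'   (`NA`).
#' @return list with `period`, `frequency`, `power` (the latter two `NA` when
#'   a bare frequency was supplied).
#' @examples
#' dominant_period(0.07)$period   # ~89.8, i.e. about 90 length units
#' @export
dominant_period <- function(spectrum, dc_exclude_frac = 0.8,
                            min_power = 1e-8) {
  if (is.numeric(spectrum) && length(spectrum) == 1)
    return(list(period = 2 * pi / spectrum, frequency = spectrum,
                power = NA_real_))
  keep <- 2 * pi / spectrum$frequency <= dc_exclude_frac * spectrum$span
  if (!any(keep) || max(spectrum$power[keep]) < min_power)
    return(list(period = NA_real_, frequency = NA_real_, power = NA_real_))
  f <- spectrum$frequency[keep]
  p <- spectrum$power[keep]
  i <- which.max(p)
  list(period = 2 * pi / f[i], frequency = f[i], power = p[i])
}

#' Synthetic periodic staining profile
#'
#' Generates a 1-D intensity profile emulating quantified tip-cell staining
#' along a vessel axis: Gaussian bumps at a regular spacing with
#' multiplicative amplitude noise, additive positional jitter, and optional
#' bump dropout. The "control" preset mimics a crisp periodic pattern; the
#' "latb" (filopodia loss-of-function) preset uses high jitter and 50 percent
#' dropout to mimic diffuse, unreliable patterning.
#'
#' @param period bump spacing (length units); about 90 in the control-like
#'   setting.
#' @param n_bumps number of bumps (>= 2).
#' @param amplitude_noise sd of the multiplicative amplitude factor.
#' @param position_jitter sd of the bump-centre displacement (length units).
#' @param dropout probability that a bump is missing.
#' @param seed integer seed.
#' @param dx sampling interval of the profile.
#' @param bump_sd Gaussian bump width (defaults to period / 8).
#' @param preset optional shorthand: "control" (jitter 0.05 * period, noise
#'   0.2, no dropout) or "latb" (jitter 0.3 * period, noise 0.4, dropout
#'   0.5); explicit arguments override.
#' @return data.frame of class `profile_1d` with columns `position`, `value`
#'   and attribute `label`.
#' @export
synth_profile <- function(period = 90, n_bumps = 10, amplitude_noise = 0,
                          position_jitter = 0, dropout = 0, seed = 1,
                          dx = 1, bump_sd = period / 8, preset = NULL) {
  stopifnot(period > 0, n_bumps >= 2)
  label <- "custom"
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("control", "latb"))
    label <- preset
    if (preset == "control") {
      if (missing(position_jitter)) position_jitter <- 0.05 * period
      if (missing(amplitude_noise)) amplitude_noise <- 0.2
      if (missing(dropout)) dropout <- 0
    } else {
      if (missing(position_jitter)) position_jitter <- 0.3 * period
      if (missing(amplitude_noise)) amplitude_noise <- 0.4
      if (missing(dropout)) dropout <- 0.5
    }
  }
  set.seed(as.integer(seed))
  x <- seq(0, (n_bumps - 1) * period + 2 * period, by = dx)
  centres <- (seq_len(n_bumps) - 1) * period + period +
    stats::rnorm(n_bumps, 0, position_jitter)
  amps <- pmax(0, 1 + stats::rnorm(n_bumps, 0, amplitude_noise))
  amps[stats::runif(n_bumps) < dropout] <- 0
  y <- rep(0, length(x))
  for (k in seq_len(n_bumps))
    y <- y + amps[k] * exp(-(x - centres[k])^2 / (2 * bump_sd^2))
  out <- data.frame(position = x, value = y)
  attr(out, "label") <- label
  class(out) <- c("profile_1d", "data.frame")
  out
}

#' Read a 1-D profile from CSV
#'
#' Expects columns `position` and `value` (an optional `label` column is
#' carried as an attribute).
#'
#' @param file path to a CSV file.
#' @return a `profile_1d` data.frame.
#' @export
read_profile <- function(file) {
  d <- utils::read.csv(file)
  stopifnot(all(c("position", "value") %in% names(d)))
  out <- data.frame(position = d$position, value = d$value)
  attr(out, "label") <- if ("label" %in% names(d)) as.character(d$label[1]) else "unknown"
  class(out) <- c("profile_1d", "data.frame")
  out
}
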