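#' Quasi-static equilibrium test on a trace segment
#'
#' Stationarity criterion used before advancing the external Dll4 ramp: after
#' a transient, the means and standard deviations of the response in two
#' adjacent non-overlapping windows must agree in the normalised sense
#' |mu_c - mu_p| / (mu_c + mu_p) < epsilon and |sd_c - sd_p| / (sd_c + sd_p)
#' < epsilon (both bounds strict; epsilon = 0.5). A zero/zero ratio counts as
#' passing (identical silence).
#'
#' @param segment numeric response trace at the current ramp level (from the
#'   start of the level); the last two windows are tested.
#' @param params an [msm_params()] list (`transient_steps`, `stat_window`,
#'   `epsilon`).
#' @return logical.
#' @export
quasi_static_check <- function(segment, params = msm_params()) {
  w <- params$stat_window
  need <- params$transient_steps + 2 * w
  if (length(segment) < need)
    stop("segment too short for the stationarity test (need ",
         need, " steps)")
  n <- length(segment)
  cur <- segment[(n - w + 1):n]
  prev <- segment[(n - 2 * w + 1):(n - w)]
  ratio <- function(a, b) {
    s <- a + b
    if (s == 0) 0 else abs(a - b) / s
  }
  ratio(mean(cur), mean(prev)) < params$epsilon &&
    ratio(stats::sd(cur), stats::sd(prev)) < params$epsilon
}

#' Run the single-cell hysteresis protocol
#'
#' Three-cell testbed: the centre endothelial cell is flanked by two
#' non-responsive pseudo-cells presenting a fixed external Dll4 total
#' (`d_ext`). The ramp starts at 0 and rises in increments of 50 until the
#' centre cell has been inhibited for two consecutive levels (capped at
#' `d_max`), then reverses back to 0. At each level the simulation runs until
#' the [quasi_static_check()] passes (after the transient) or
#' `max_steps_per_level` elapses (a timeout is recorded, not fatal), and the
#' equilibrium mean and sd of the centre cell's Dll4 over the last window are
#' recorded.
#'
#' @param params an [msm_params()] list.
#' @param seed integer seed.
#' @param d_ext_max optional ramp ceiling override (defaults to `d_max`).
#' @param mesh_density optional mesh density override.
#' @return data.frame of class `hysteresis_curve`: one row per (level,
#'   direction) with columns `d_ext`, `direction`, `mean`, `sd`, `n_steps`,
#'   `nfil`, `vegfr`, `timeout`, `seed`.
#' @export
run_hysteresis <- function(params = msm_params(), seed = 1,
                           d_ext_max = NULL, mesh_density = NULL) {
  if (is.null(d_ext_max)) d_ext_max <- params$d_max
  st <- msm_init(params, 3, seed, mode = "hysteresis",
                 max_steps = params$max_steps_per_level,
                 mesh_density = mesh_density)
  mid <- 2L
  rec <- list()
  inhibited_run <- 0L

  run_level <- function(d, direction) {
    st$d_ext <- d
    st$t <- 0L                 # reuse the trace buffer for this level
    need <- params$transient_steps + 2 * params$stat_window
    passed <- FALSE
    while (st$t < params$max_steps_per_level) {
      msm_step(st)
      if (st$t >= need &&
          quasi_static_check(st$tr$D[seq_len(st$t), mid], params)) {
        passed <- TRUE
        break
      }
    }
    w <- params$stat_window
    idx <- (st$t - w + 1):st$t
    data.frame(d_ext = d, direction = direction,
               mean = mean(st$tr$D[idx, mid]),
               sd = stats::sd(st$tr$D[idx, mid]),
               n_steps = st$t,
               nfil = mean(st$tr$NFIL[idx, mid]),
               vegfr = mean(st$tr$VEGFR[idx, mid]),
               timeout = !passed, seed = seed)
  }
  is_inhibited <- function(row)
    row$vegfr < params$vegfr_max / 6 && row$nfil < 0.5

  d <- 0
  repeat {
    row <- run_level(d, "up")
    rec[[length(rec) + 1L]] <- row
    inhibited_run <- if (is_inhibited(row)) inhibited_run + 1L else 0L
    if (inhibited_run >= 2L || d >= d_ext_max) break
    d <- d + params$d_ext_step
  }
  for (d2 in seq(d - params$d_ext_step, 0, by = -params$d_ext_step)) {
    rec[[length(rec) + 1L]] <- run_level(d2, "down")
  }
  out <- do.call(rbind, rec)
  class(out) <- c("hysteresis_curve", "data.frame")
  out
}

#' Hysteresis gap of a ramp curve
#'
#' Separation between the up-branch and down-branch equilibrium Dll4. A
#' bistable window shows the up branch (arriving from the active state)
#' sitting above the down branch over a band of levels; a memoryless
#' response overlaps everywhere. Because the bistable band spans only part
#' of the ramp, the summary `gap` is the mean of the three largest per-level
#' differences (a whole-ramp mean would dilute a genuine window to near
#' zero).
#'
#' @param curve a `hysteresis_curve` from [run_hysteresis()].
#' @param top number of largest per-level differences averaged (3).
#' @return list with `gap` (mean of the `top` largest up - down
#'   differences), `max_gap` and the per-level difference table.
#' @export
hysteresis_gap <- function(curve, top = 3) {
  up <- curve[curve$direction == "up", ]
  dn <- curve[curve$direction == "down", ]
  lev <- intersect(up$d_ext, dn$d_ext)
  du <- up$mean[match(lev, up$d_ext)]
  dd <- dn$mean[match(lev, dn$d_ext)]
  diff <- du - dd
  k <- min(top, length(diff))
  list(gap = mean(sort(diff, decreasing = TRUE)[seq_len(k)]),
       max_gap = max(diff),
       table = data.frame(d_ext = lev, up = du, down = dd, diff = diff))
}

#' Width of the bistable window of a ramp curve
#'
#' Classifies each recorded level's branch state on the equilibrium VEGFR
#' pool (active when above `vegfr_max/6`) and returns the width, in external
#' Dll4 units, of the band over which the up branch is still active while
#' the down branch is already inhibited — the defining signature of
#' hysteresis (the up-branch inhibition threshold exceeding the down-branch
#' reactivation threshold). A memoryless response yields width 0. Unlike a
#' Dll4-level gap, this statistic is insensitive to how slowly the Dll4 pool
#' relaxes toward its equilibrium at each level.
#'
#' @param curve a `hysteresis_curve` from [run_hysteresis()].
#' @param params the [msm_params()] the curve was run with.
#' @return list with `width` (>= 0), `up_threshold` (lowest level at which
#'   the up branch is inhibited) and `down_threshold` (lowest level at which
#'   the down branch is active again).
#' @export
bistable_window <- function(curve, params = msm_params()) {
  thr <- params$vegfr_max / 6
  up <- curve[curve$direction == "up", ]
  dn <- curve[curve$direction == "down", ]
  up_inh <- up$d_ext[up$vegfr < thr]
  dn_act <- dn$d_ext[dn$vegfr >= thr]
  up_threshold <- if (length(up_inh)) min(up_inh) else max(up$d_ext)
  down_threshold <- if (length(dn_act)) max(dn_act) + params$d_ext_step
  else min(dn$d_ext)
  list(width = max(0, up_threshold - down_threshold),
       up_threshold = up_threshold, down_threshold = down_threshold)
}

#' Metastable step-response of the hysteresis testbed
#'
#' The centre cell is equilibrated with no external Dll4 for `pre_steps`,
#' then `d_ext` is abruptly raised to the target and the run continues for
#' `post_steps`. The smoothed post-step VEGFR trace is classified against
#' the branch threshold `vegfr_max / 6`: `active` if it stays on the high
#' branch, `inhibited` for a one-way transition to the low branch,
#' `flip_flop` for two or more branch crossings.
#'
#' @param params an [msm_params()] list.
#' @param d_ext_target external Dll4 total applied after the pre-phase.
#' @param seed integer seed.
#' @param pre_steps,post_steps phase lengths (10^4 and 3 x 10^4 by default).
#' @param smooth window (steps) of the running mean used to debounce branch
#'   crossings.
#' @param mesh_density optional mesh density override.
#' @return list with `class` ("active", "inhibited" or "flip_flop"),
#'   `crossings`, `threshold`, `active_mean` and the smoothed post trace.
#' @export
step_response <- function(params = msm_params(), d_ext_target, seed = 1,
                          pre_steps = 10000, post_steps = 30000,
                          smooth = 250, mesh_density = NULL) {
  st <- msm_init(params, 3, seed, mode = "hysteresis",
                 max_steps = pre_steps + post_steps,
                 mesh_density = mesh_density)
  st$d_ext <- 0
  for (i in seq_len(pre_steps)) msm_step(st)
  st$d_ext <- d_ext_target
  for (i in seq_len(post_steps)) msm_step(st)
  mid <- 2L
  pre <- st$tr$VEGFR[seq_len(pre_steps), mid]
  post <- st$tr$VEGFR[(pre_steps + 1):(pre_steps + post_steps), mid]
  active_mean <- mean(pre[(pre_steps - 2000 + 1):pre_steps])
  # branch indicator: the VEGFR pool separates the filopodia-sustained
  # (capacity-protected) branch from the silenced branch far more cleanly
  # than Dll4, whose active-branch equilibrium varies strongly with d_ext
  thr <- params$vegfr_max / 6
  rm_mean <- function(x, w) {
    cs <- cumsum(x)
    (cs[w:length(x)] - c(0, cs)[seq_len(length(x) - w + 1)]) / w
  }
  sm <- rm_mean(post, smooth)
  high <- sm > thr
  crossings <- sum(abs(diff(high)))
  cls <- if (crossings == 0) {
    if (high[length(high)]) "active" else "inhibited"
  } else if (crossings == 1 && !high[length(high)]) "inhibited"
  else if (crossings >= 2) "flip_flop"
  else "active"
  list(class = cls, crossings = crossings, threshold = thr,
       active_mean = active_mean, smoothed = sm, d_ext = d_ext_target,
       seed = seed)
}
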