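#' Time-to-pattern sweep over filopodia and VEGF conditions
#'
#' Runs replicate ring simulations over a grid of extension propensities `F`
#' and VEGF parameters `V`, scoring each run with [time_to_pattern()]. Every
#' run's seed is `base_seed + replicate - 1`, making the sweep fully
#' reproducible.
#'
#' @param F_values extension propensities (each within (0, 3]).
#' @param V_values VEGF parameters.
#' @param reps replicates per condition.
#' @param base_seed first seed.
#' @param params base [msm_params()] (condition values are overridden).
#' @param n_cells ring size (10 for the standard testbed).
#' @param steps run length (default `params$max_steps` by mode).
#' @param mesh_density optional mesh density override (smaller meshes run
#'   proportionally faster; results are reported at whatever density is
#'   used).
#' @return data.frame with one row per run: `F`, `V`, `seed`, `patterned`,
#'   `time_to_pattern`.
#' @export
run_timing_sweep <- function(F_values = c(0.5, 2, 3), V_values = 0.04,
                             reps = 10, base_seed = 1,
                             params = msm_params(), n_cells = 10,
                             steps = NULL, mesh_density = NULL) {
  stopifnot(all(F_values > 0 & F_values <= 3))
  rows <- list()
  for (Fv in F_values) for (Vv in V_values) {
    p <- params; p$F <- Fv; p$V <- Vv
    for (r in seq_len(reps)) {
      sd_ <- base_seed + r - 1L
      tr <- msm_run(p, n_cells = n_cells, seed = sd_, steps = steps,
                    mesh_density = mesh_density)
      pr <- time_to_pattern(tr)
      rows[[length(rows) + 1L]] <- data.frame(
        F = Fv, V = Vv, seed = sd_, patterned = pr$patterned,
        time_to_pattern = if (pr$patterned) pr$time_to_pattern else NA_integer_)
    }
  }
  do.call(rbind, rows)
}

#' Summarise a timing sweep per condition
#'
#' @param sweep output of [run_timing_sweep()].
#' @return data.frame per (F, V): median and quartiles of the patterning time
#'   (over patterned runs) and the fraction of runs left unpatterned.
#' @export
summarize_sweep <- function(sweep) {
  sp <- split(sweep, interaction(sweep$F, sweep$V, drop = TRUE))
  do.call(rbind, lapply(sp, function(d) {
    tt <- d$time_to_pattern[d$patterned]
    data.frame(F = d$F[1], V = d$V[1], n = nrow(d),
               n_patterned = sum(d$patterned),
               frac_unpatterned = mean(!d$patterned),
               median = if (length(tt)) stats::median(tt) else NA_real_,
               q25 = if (length(tt)) unname(stats::quantile(tt, 0.25)) else NA_real_,
               q75 = if (length(tt)) unname(stats::quantile(tt, 0.75)) else NA_real_)
  }))
}

#' Replicated two-cell active-perception experiment
#'
#' Runs `reps` two-cell simulations with the sensory map recorded, and
#' aggregates per-step mean and min-max envelope of the intensity and entropy
#' measures across replicates, plus the mean Dll4-advantage patterning time
#' (counting only runs that patterned).
#'
#' @inheritParams run_timing_sweep
#' @param steps run length.
#' @return list with `summary` (data.frame: t, I_mean, I_min, I_max, H_mean,
#'   H_min, H_max), `pattern_times` per replicate (`NA` when unpatterned),
#'   `mean_pattern_time` (NA when no run patterned) and the per-run
#'   entropy/intensity matrices.
#' @export
run_ap_experiment <- function(params = msm_params(), reps = 10, base_seed = 1,
                              steps = NULL, mesh_density = NULL) {
  Imat <- Hmat <- NULL
  pt <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    res <- ap_signature_run(params, seed = base_seed + r - 1L, steps = steps,
                            mesh_density = mesh_density)
    if (is.null(Imat)) {
      Imat <- matrix(NA_real_, length(res$trace$I), reps)
      Hmat <- Imat
    }
    Imat[, r] <- res$trace$I
    Hmat[, r] <- res$trace$H
    if (res$pattern$patterned) pt[r] <- res$pattern$time_to_pattern
  }
  summary <- data.frame(
    t = seq_len(nrow(Imat)),
    I_mean = rowMeans(Imat), I_min = apply(Imat, 1, min),
    I_max = apply(Imat, 1, max),
    H_mean = rowMeans(Hmat), H_min = apply(Hmat, 1, min),
    H_max = apply(Hmat, 1, max))
  list(summary = summary, pattern_times = pt,
       mean_pattern_time = if (any(!is.na(pt))) mean(pt, na.rm = TRUE) else NA_real_,
       I = Imat, H = Hmat)
}

#' Post-patterning entropy drop of the two-cell testbed
#'
#' For each patterned replicate, compares the mean sensory-map entropy in a
#' window after the patterning time against a window before it, and averages
#' the drop across replicates. This is the quantitative active-perception
#' signature: under control parameters entropy falls by about one bit once
#' one cell has won the Dll4 competition.
#'
#' @param params an [msm_params()] list.
#' @param reps number of replicates.
#' @param base_seed first seed.
#' @param window comparison window length (200 steps).
#' @param steps run length per replicate.
#' @param mesh_density optional override.
#' @return list with `mean_drop` (bits), per-replicate `drops`, and the
#'   number of patterned runs used.
#' @export
entropy_drop_experiment <- function(params = msm_params(), reps = 50,
                                    base_seed = 1, window = 200,
                                    steps = NULL, mesh_density = NULL) {
  drops <- rep(NA_real_, reps)
  if (is.null(steps))
    steps <- if (params$vegf_mode == "uniform") params$max_steps_uniform else params$max_steps
  for (r in seq_len(reps)) {
    st <- msm_init(params, 2, seed = base_seed + r - 1L, record_ap = TRUE,
                   max_steps = steps, mesh_density = mesh_density)
    # advance until the run has patterned and the post window is complete
    # (or the step budget runs out)
    t_stop <- steps
    while (st$t < steps) {
      msm_step(st)
      if (st$t %% 100 == 0 && st$t >= params$dll4_window + window) {
        pr0 <- dll4_advantage_time(msm_trace(st))
        if (pr0$patterned &&
            st$t >= pr0$time_to_pattern + params$dll4_window + window + 10) {
          t_stop <- st$t
          break
        }
      }
    }
    tr <- msm_trace(st)
    pr <- dll4_advantage_time(tr)
    H <- tr$H
    T <- length(H)
    if (!pr$patterned) next
    t0 <- pr$time_to_pattern
    pre <- H[max(1, t0 - window):(t0 - 1)]
    post_start <- min(T, t0 + params$dll4_window)
    post <- H[post_start:min(T, post_start + window - 1)]
    if (length(pre) >= window / 2 && length(post) >= window / 2)
      drops[r] <- mean(pre) - mean(post)
  }
  list(mean_drop = mean(drops, na.rm = TRUE), drops = drops,
       n_patterned = sum(!is.na(drops)))
}

#' Replicated hysteresis ramp experiment
#'
#' Aggregates [run_hysteresis()] curves across replicates: per (level,
#' direction) mean and standard deviation of the equilibrium Dll4.
#'
#' @inheritParams run_timing_sweep
#' @param d_ext_max optional ramp ceiling override.
#' @return list with `aggregate` (per level/direction mean, sd, n) and the
#'   per-replicate `curves`.
#' @export
run_hysteresis_experiment <- function(params = msm_params(), reps = 5,
                                      base_seed = 1, d_ext_max = NULL,
                                      mesh_density = NULL) {
  curves <- lapply(seq_len(reps), function(r)
    run_hysteresis(params, seed = base_seed + r - 1L, d_ext_max = d_ext_max,
                   mesh_density = mesh_density))
  all <- do.call(rbind, curves)
  sp <- split(all, interaction(all$d_ext, all$direction, drop = TRUE))
  aggregate <- do.call(rbind, lapply(sp, function(d)
    data.frame(d_ext = d$d_ext[1], direction = d$direction[1],
               mean = mean(d$mean), sd = stats::sd(d$mean), n = nrow(d))))
  aggregate <- aggregate[order(aggregate$direction, aggregate$d_ext), ]
  rownames(aggregate) <- NULL
  list(aggregate = aggregate, curves = curves)
}

#' Write a per-step state log as CSV
#'
#' Long-format per-step log: t, cell, Dll4, VEGFR, Notch activation, VEGFR
#' activation, filopodium count, actin.
#'
#' @param trace an `msm_trace`.
#' @param file output path.
#' @return the data.frame, invisibly.
#' @export
write_state_log <- function(trace, file) {
  T <- nrow(trace$D)
  n <- trace$n_cells
  d <- data.frame(t = rep(seq_len(T), n),
                  cell = rep(seq_len(n), each = T),
                  d_cell = as.vector(trace$D),
                  vegfr_cell = as.vector(trace$VEGFR),
                  nstar = as.vector(trace$NSTAR),
                  vegfr_star = as.vector(trace$ASTAR),
                  n_filopodia = as.vector(trace$NFIL),
                  actin = as.vector(trace$ACTIN))
  utils::write.csv(d, file, row.names = FALSE)
  invisible(d)
}
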