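#' Classify tip cells from instantaneous state
#'
#' A cell is a tip iff it has sprouted at least one filopodium and it has not
#' been inhibited: its VEGFR pool exceeds `tip_vegfr_frac * vegfr_max`
#' (default half the ceiling, separating the bistable branches).
#'
#' @param nfil per-cell filopodium counts.
#' @param vegfr_cell per-cell VEGFR pools.
#' @param params an [msm_params()] list.
#' @return integer vector of tip cell ids.
#' @examples
#' classify_tips(c(3, 0, 2), c(12000, 0, 11000), msm_params())  # cells 1, 3
#' @export
classify_tips <- function(nfil, vegfr_cell, params = msm_params()) {
  which(nfil >= 1 & vegfr_cell > params$tip_vegfr_frac * params$vegfr_max)
}

#' Are tip cells pairwise non-adjacent on the cell ring?
#'
#' Adjacency includes the periodic wrap (cell 1 borders cell n).
#'
#' @param tips integer tip ids.
#' @param n_cells ring size.
#' @return logical.
#' @export
tips_non_adjacent <- function(tips, n_cells) {
  if (length(tips) < 2) return(TRUE)
  s <- sort(tips)
  gaps <- diff(c(s, s[1] + n_cells))
  all(gaps >= 2)
}

#' Time to salt-and-pepper pattern on the cell ring
#'
#' The ring is "patterned" at the earliest step t such that the qualifying
#' condition -- between `min_tips` and `max_tips` pairwise non-adjacent tip
#' cells active -- holds at every step of the window `[t, t + stability_window
#' - 1]`. Runs that never satisfy this within the trace are unpatterned.
#'
#' @param trace an `msm_trace` from [msm_run()].
#' @param params parameter list; defaults to the trace's own.
#' @return list of class `pattern_result`: `patterned`, `time_to_pattern`
#'   (`NA` when unpatterned), `tip_ids` at the qualifying step, `run_seed`.
#' @export
time_to_pattern <- function(trace, params = trace$params) {
  T <- nrow(trace$D)
  n <- trace$n_cells
  qual <- logical(T)
  tipsets <- vector("list", T)
  for (t in seq_len(T)) {
    tp <- classify_tips(trace$NFIL[t, ], trace$VEGFR[t, ], params)
    tipsets[[t]] <- tp
    qual[t] <- length(tp) >= params$min_tips && length(tp) <= params$max_tips &&
      tips_non_adjacent(tp, n)
  }
  w <- params$stability_window
  t0 <- first_full_window(qual, w)
  structure(list(patterned = !is.na(t0), time_to_pattern = t0,
                 tip_ids = if (!is.na(t0)) tipsets[[t0]] else integer(0),
                 run_seed = trace$seed),
            class = "pattern_result")
}

#' Patterning time of the two-cell testbed by Dll4 advantage
#'
#' The two-cell system is "patterned" at the start of the first window of
#' `dll4_window` consecutive steps throughout which one cell holds a Dll4
#' lead of at least `dll4_advantage` ligands with constant sign (the waiting
#' window itself is excluded from the reported time). A sign flip inside a
#' window restarts it.
#'
#' @param trace a two-cell `msm_trace`.
#' @param params parameter list; defaults to the trace's own.
#' @return a `pattern_result` list; `tip_ids` holds the winning cell.
#' @export
dll4_advantage_time <- function(trace, params = trace$params) {
  stopifnot(trace$n_cells == 2)
  dd <- trace$D[, 1] - trace$D[, 2]
  w <- params$dll4_window
  t_pos <- first_full_window(dd >= params$dll4_advantage, w)
  t_neg <- first_full_window(-dd >= params$dll4_advantage, w)
  t0 <- suppressWarnings(min(t_pos, t_neg, na.rm = TRUE))
  if (!is.finite(t0)) t0 <- NA_integer_
  winner <- if (is.na(t0)) integer(0) else if (dd[t0] > 0) 1L else 2L
  structure(list(patterned = !is.na(t0), time_to_pattern = t0,
                 tip_ids = winner, run_seed = trace$seed),
            class = "pattern_result")
}

#' @export
print.pattern_result <- function(x, ...) {
  if (x$patterned)
    cat(sprintf("patterned at t = %d (tips: %s), seed %d\n",
                x$time_to_pattern, paste(x$tip_ids, collapse = ","),
                x$run_seed))
  else
    cat(sprintf("not patterned within the run, seed %d\n", x$run_seed))
  invisible(x)
}

#' First start index of a window of w consecutive TRUEs
#' @keywords internal
first_full_window <- function(cond, w) {
  T <- length(cond)
  if (T < w) return(NA_integer_)
  cs <- cumsum(!cond)
  ok <- which(cs[w:T] - c(0, cs)[seq_len(T - w + 1)] == 0)
  if (length(ok)) ok[1] else NA_integer_
}

#' Export a time-space matrix of Dll4 levels
#'
#' Samples the per-cell Dll4 trace every `frame_stride` steps, yielding the
#' frames of a time-space plot (rows = frames, columns = cells). A patterned
#' run shows alternating high/low columns in the late frames.
#'
#' @param trace an `msm_trace`.
#' @param frame_stride steps between frames (100 by default).
#' @param file optional path to also write the matrix as CSV.
#' @return numeric matrix `n_frames x n_cells`.
#' @export
export_time_space <- function(trace, frame_stride = 100, file = NULL) {
  steps <- seq(frame_stride, nrow(trace$D), by = frame_stride)
  m <- trace$D[steps, , drop = FALSE]
  rownames(m) <- steps
  if (!is.null(file))
    utils::write.csv(data.frame(step = steps, m, check.names = FALSE),
                     file, row.names = FALSE)
  m
}
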