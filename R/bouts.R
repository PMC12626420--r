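#' Detect movement bouts in a delta-pixel trace
#'
#' A bout is a maximal run of samples with `dpix > threshold`.  Runs
#' separated by a gap shorter than `merge_gap_s` are merged, then
#' merged runs shorter than `min_duration_s` are discarded.  Bout
#' duration is counted in whole samples (`end_s = last sample time +
#' sample interval`), so an isolated supra-threshold sample forms a
#' bout of one sample interval.
#'
#' @param trace A `"dpix_trace"` (see [simulate_behavior_cohort()]) or
#'   any list with numeric `t`, `dpix` and optional `x`, `y`.
#' @param threshold Delta-pixel noise floor; samples must exceed it
#'   strictly.  Default 0 (denoised input).
#' @param merge_gap_s Gaps strictly shorter than this are bridged.
#' @param min_duration_s Minimum merged-run duration kept.
#' @param center_boundary Radius of the well-center disk used for
#'   `center_fraction` (the well is the unit circle; default half the
#'   well radius).
#' @return `data.frame` of class `"bout_table"`, one row per bout:
#'   `start_s`, `end_s`, `n_samples`, `cumulative_movement` (summed
#'   dpix), `peak` (max dpix), `mean_velocity`
#'   (`cumulative_movement / duration`), `center_fraction` (fraction of
#'   bout samples with centroid radius <= `center_boundary`; `NA` when
#'   the trace has no centroid track).
#' @export
#' @examples
#' tr <- list(t = 0:9, dpix = c(0, 5, 5, 5, 0, 0, 2, 0, 0, 0))
#' detect_bouts(tr)
detect_bouts <- function(trace, threshold = 0, merge_gap_s = 0.2,
                         min_duration_s = 0, center_boundary = 0.5) {
  stopifnot(threshold >= 0, merge_gap_s >= 0, min_duration_s >= 0)
  t <- trace$t
  dpix <- trace$dpix
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_samples = integer(0),
                      cumulative_movement = numeric(0), peak = numeric(0),
                      mean_velocity = numeric(0),
                      center_fraction = numeric(0))
  class(empty) <- c("bout_table", "data.frame")
  if (!length(t)) return(empty)
  stopifnot(length(dpix) == length(t), all(diff(t) > 0))
  dt <- if (length(t) > 1) stats::median(diff(t)) else 1

  active <- dpix > threshold
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs_s <- starts[r$values]
  runs_e <- ends[r$values]
  if (!length(runs_s)) return(empty)

  ## merge runs separated by short gaps: consecutive runs belong to one
  ## bout when the gap between them is below merge_gap_s
  if (length(runs_s) > 1) {
    gaps <- t[runs_s[-1]] - (t[runs_e[-length(runs_e)]] + dt)
    grp <- cumsum(c(TRUE, gaps >= merge_gap_s))
    ms <- runs_s[!duplicated(grp)]
    me <- runs_e[c(which(diff(grp) > 0), length(grp))]
  } else {
    ms <- runs_s
    me <- runs_e
  }

  dur <- t[me] + dt - t[ms]
  keep <- dur >= min_duration_s & dur > 0
  ms <- ms[keep]; me <- me[keep]; dur <- dur[keep]
  if (!length(ms)) return(empty)

  ## per-bout aggregates via cumulative sums (merged bouts include the
  ## sub-threshold gap samples they bridge)
  cs <- cumsum(dpix)
  cm <- cs[me] - c(0, cs)[ms]
  peak <- vapply(seq_along(ms), function(i) max(dpix[ms[i]:me[i]]), 0)
  has_xy <- !is.null(trace$x) && !is.null(trace$y)
  cf <- if (has_xy) {
    csc <- cumsum(sqrt(trace$x^2 + trace$y^2) <= center_boundary)
    (csc[me] - c(0, csc)[ms]) / (me - ms + 1)
  } else rep(NA_real_, length(ms))
  out <- data.frame(start_s = t[ms], end_s = t[me] + dt,
                    n_samples = me - ms + 1L,
                    cumulative_movement = cm, peak = peak,
                    mean_velocity = cm / dur,
                    center_fraction = cf)
  class(out) <- c("bout_table", "data.frame")
  out
}
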