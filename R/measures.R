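#' Canonical measure names
#'
#' Measure columns are named `epoch_measure` or `epoch_measure_suffix`,
#' e.g. `day0night_boutcenterfraction_3600` (location measure, hourly
#' bins, first night) or `day5dpfhab1pre_responsefrequency_1_a1f1000d5p`
#' (response frequency to the strong 1000 Hz acoustic stimuli preceding
#' habituation block 1).  The epoch and measure components must not
#' contain the underscore separator; the suffix may (stimulus codes
#' do).
#'
#' @param epoch_label Epoch component (e.g. `"day0night"`, `"combo"`).
#' @param measure Measure component (e.g. `"numberofbouts"`).
#' @param suffix Optional bin size in seconds or stimulus code.
#' @return The canonical name string.
#' @export
#' @examples
#' measure_name("day0night", "boutcenterfraction", 3600)
#' parse_measure_name("day5dpfhab1pre_responsefrequency_1_a1f1000d5p")
measure_name <- function(epoch_label, measure, suffix = NULL) {
  for (comp in list(epoch_label, measure)) {
    if (!nzchar(comp)) stop("empty name component", call. = FALSE)
    if (grepl("_", comp, fixed = TRUE))
      stop("reserved separator '_' in name component: ", comp,
           call. = FALSE)
  }
  if (is.null(suffix) || !length(suffix) || is.na(suffix[1]) ||
      !nzchar(as.character(suffix[1])))
    paste(epoch_label, measure, sep = "_")
  else
    paste(epoch_label, measure, as.character(suffix), sep = "_")
}

#' @rdname measure_name
#' @param name A canonical measure name to decompose.
#' @return For `parse_measure_name()`, a list with `epoch`, `measure`,
#'   `suffix` (`NA` when absent); parsing inverts [measure_name()].
#' @export
parse_measure_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) < 2 || !all(nzchar(parts[1:2])))
    stop("not a canonical measure name: ", name, call. = FALSE)
  list(epoch = parts[1], measure = parts[2],
       suffix = if (length(parts) > 2)
         paste(parts[-(1:2)], collapse = "_") else NA_character_)
}

## category of each named measure
measure_category <- function(measure) {
  switch(measure,
         numberofbouts = , activeseconds = , responsefrequency = "frequency",
         boutcumulativemovement = , boutvelocity = ,
         responsemagnitude = "magnitude",
         boutcenterfraction = "location",
         responselatency = "latency",
         stop("unknown measure: ", measure, call. = FALSE))
}

#' Epoch specification
#'
#' @param label Epoch label (underscore-free), e.g. `"combo"`,
#'   `"day0"`, `"day0night"`.
#' @param start_s,end_s Epoch bounds in seconds since experiment start.
#' @param bin_s Bin width in seconds (3600 = hourly); only complete
#'   bins are retained, a trailing partial bin is dropped.
#' @return List of class `"epoch_spec"`.
#' @export
epoch_spec <- function(label, start_s, end_s, bin_s = 3600) {
  stopifnot(end_s > start_s, bin_s > 0)
  if (grepl("_", label, fixed = TRUE))
    stop("epoch label must not contain '_'", call. = FALSE)
  structure(list(label = label, start_s = start_s, end_s = end_s,
                 bin_s = bin_s), class = "epoch_spec")
}

#' Default epochs for a simulated cohort
#'
#' `combo` spans the whole recording; in addition one epoch per
#' contiguous light-cycle segment is emitted (`day0`, `day0night`,
#' `day1`, ...), skipping segments shorter than one bin.
#'
#' @param config A [sim_config()].
#' @param bin_s Bin width (clipped to the recording length).
#' @return List of [epoch_spec()] objects.
#' @export
default_epochs <- function(config, bin_s = 3600) {
  dur <- config$duration_s
  bin_s <- min(bin_s, dur)
  eps <- list(epoch_spec("combo", 0, dur, bin_s))
  ## light segments
  dt <- 1 / config$frame_rate_hz
  t <- seq(0, dur - dt, by = dt)
  night <- is_night(t, config)
  seg_start <- c(1L, which(diff(night) != 0) + 1L)
  seg_end <- c(seg_start[-1] - 1L, length(t))
  day_idx <- 0L
  for (s in seq_along(seg_start)) {
    a <- t[seg_start[s]]
    b <- t[seg_end[s]] + dt
    is_n <- night[seg_start[s]]
    label <- if (is_n) sprintf("day%dnight", day_idx)
             else sprintf("day%d", day_idx)
    if (is_n) day_idx <- day_idx + 1L
    if (b - a >= bin_s)
      eps[[length(eps) + 1L]] <- epoch_spec(label, a, b, bin_s)
  }
  eps
}

#' Baseline behavior measures for one larva
#'
#' For each epoch, bouts are assigned to the complete `bin_s`-wide bins
#' by their start time (a trailing partial bin is dropped) and the
#' epoch is summarized by one column per measure:
#'
#' * `numberofbouts` — mean bouts per bin (frequency);
#' * `activeseconds` — mean summed bout duration per bin (frequency);
#' * `boutcumulativemovement` — mean summed dpix per bout (magnitude);
#' * `boutvelocity` — mean of per-bout `mean_velocity` (magnitude);
#' * `boutcenterfraction` — duration-weighted mean fraction of bout
#'   time spent in the well center (location).
#'
#' Epochs with no bouts yield zero for the frequency measures and
#' missing (`NA`) magnitude/location measures.
#'
#' @param bouts A [detect_bouts()] table.
#' @param trace The trace the bouts came from (span validation).
#' @param epochs List of [epoch_spec()]s, all within the trace span.
#' @return `data.frame` with columns `name`, `value`, `category`,
#'   `epoch`, `suffix`.
#' @export
baseline_measures <- function(bouts, trace, epochs) {
  dt <- if (length(trace$t) > 1) stats::median(diff(trace$t)) else 1
  span <- c(trace$t[1], trace$t[length(trace$t)] + dt)
  rows <- list()
  for (ep in epochs) {
    if (ep$start_s < span[1] - 1e-9 || ep$end_s > span[2] + 1e-9)
      stop("epoch '", ep$label, "' outside trace span", call. = FALSE)
    n_bins <- floor((ep$end_s - ep$start_s) / ep$bin_s)
    if (n_bins < 1)
      stop("epoch '", ep$label, "' shorter than one bin", call. = FALSE)
    lim <- ep$start_s + n_bins * ep$bin_s
    sel <- bouts$start_s >= ep$start_s & bouts$start_s < lim
    b <- bouts[sel, , drop = FALSE]
    bin_of <- floor((b$start_s - ep$start_s) / ep$bin_s) + 1L
    counts <- tabulate(bin_of, nbins = n_bins)
    act <- numeric(n_bins)
    if (nrow(b)) {
      agg <- tapply(b$end_s - b$start_s, bin_of, sum)
      act[as.integer(names(agg))] <- agg
    }
    dur <- b$end_s - b$start_s
    vals <- c(numberofbouts = mean(counts),
              activeseconds = mean(act),
              boutcumulativemovement = if (nrow(b))
                mean(b$cumulative_movement) else NA_real_,
              boutvelocity = if (nrow(b)) mean(b$mean_velocity) else NA_real_,
              boutcenterfraction = if (nrow(b) &&
                                       !anyNA(b$center_fraction))
                sum(b$center_fraction * dur) / sum(dur) else NA_real_)
    for (m in names(vals))
      rows[[length(rows) + 1L]] <-
        data.frame(name = measure_name(ep$label, m, ep$bin_s),
                   value = unname(vals[m]),
                   category = measure_category(m),
                   epoch = ep$label, suffix = as.character(ep$bin_s),
                   stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Per-bin bout counts within an epoch
#'
#' Helper exposing the bin assignment used by [baseline_measures()]
#' (bouts assigned by start time; trailing partial bin dropped).
#'
#' @inheritParams baseline_measures
#' @param epoch One [epoch_spec()].
#' @return Integer vector of bout counts, one per complete bin.
#' @export
bin_bout_counts <- function(bouts, epoch) {
  n_bins <- floor((epoch$end_s - epoch$start_s) / epoch$bin_s)
  lim <- epoch$start_s + n_bins * epoch$bin_s
  sel <- bouts$start_s >= epoch$start_s & bouts$start_s < lim
  tabulate(floor((bouts$start_s[sel] - epoch$start_s) / epoch$bin_s) + 1L,
           nbins = n_bins)
}

#' Stimulus-response measures for one larva
#'
#' For each stimulus subset, the high-speed bursts of the subset's
#' events are scanned for a response onset (first sample with
#' `dpix > response_threshold`) and summarized as:
#'
#' * `responsefrequency` — fraction of events with a response;
#' * `responselatency` — mean onset time in ms over responded events
#'   only (`onset index / burst rate`); missing when no event was
#'   responded to;
#' * `responsemagnitude` — mean cumulative burst dpix over responded
#'   events only; missing when none.
#'
#' @param trace A `"dpix_trace"` carrying per-event `bursts`.
#' @param schedule The [stimulus_schedule()] the bursts belong to.
#' @param subsets List of subsets (`label`, `event_ids`, optional
#'   `suffix`), e.g. from [default_subsets()].
#' @param response_threshold Supra-threshold rule for the onset.
#' @return `data.frame` with columns `name`, `value`, `category`,
#'   `epoch`, `suffix`.
#' @export
stimulus_measures <- function(trace, schedule, subsets,
                              response_threshold = 0) {
  rate <- trace$burst_rate_hz
  rows <- list()
  for (ss in subsets) {
    if (!length(ss$event_ids))
      stop("subset '", ss$label, "' has zero events", call. = FALSE)
    missing_ev <- setdiff(ss$event_ids, names(trace$bursts))
    if (length(missing_ev))
      stop("subset '", ss$label, "' references events without bursts: ",
           paste(missing_ev, collapse = ", "), call. = FALSE)
    onsets <- vapply(trace$bursts[ss$event_ids], function(v) {
      i <- which(v > response_threshold)
      if (length(i)) i[1] else NA_integer_
    }, integer(1))
    responded <- !is.na(onsets)
    mags <- vapply(trace$bursts[ss$event_ids], sum, numeric(1))
    vals <- c(responsefrequency = mean(responded),
              responselatency = if (any(responded))
                mean(onsets[responded] / rate * 1000) else NA_real_,
              responsemagnitude = if (any(responded))
                mean(mags[responded]) else NA_real_)
    for (m in names(vals))
      rows[[length(rows) + 1L]] <-
        data.frame(name = measure_name(ss$label, m, ss$suffix),
                   value = unname(vals[m]),
                   category = measure_category(m),
                   epoch = ss$label,
                   suffix = if (is.null(ss$suffix)) NA_character_
                            else ss$suffix,
                   stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Assemble the larva-by-measure matrix for a cohort
#'
#' Runs bout detection, [baseline_measures()] and
#' [stimulus_measures()] for every larva and binds the results into a
#' numeric matrix with per-column metadata.
#'
#' @param cohort A `"behavior_cohort"` (or list of traces plus
#'   `schedule`).
#' @param epochs List of [epoch_spec()]s; default [default_epochs()]
#'   of the cohort config.
#' @param subsets Stimulus subsets; default [default_subsets()] of the
#'   cohort schedule (skipped if the schedule has no events).
#' @param threshold,merge_gap_s,min_duration_s,center_boundary Passed
#'   to [detect_bouts()].
#' @param response_threshold Passed to [stimulus_measures()].
#' @return Numeric matrix of class `"measure_matrix"` (rows = larvae,
#'   columns = canonical measure names) with attribute `measure_meta`,
#'   a data.frame of per-column `name`, `category`, `epoch`, `suffix`.
#' @export
build_measure_matrix <- function(cohort, epochs = NULL, subsets = NULL,
                                 threshold = 0, merge_gap_s = 0.2,
                                 min_duration_s = 0, center_boundary = 0.5,
                                 response_threshold = 0) {
  if (is.null(epochs)) epochs <- default_epochs(cohort$config)
  if (is.null(subsets) && nrow(cohort$schedule$events))
    subsets <- default_subsets(cohort$schedule)
  per_larva <- lapply(cohort$traces, function(tr) {
    bouts <- detect_bouts(tr, threshold = threshold,
                          merge_gap_s = merge_gap_s,
                          min_duration_s = min_duration_s,
                          center_boundary = center_boundary)
    rows <- baseline_measures(bouts, tr, epochs)
    if (length(subsets))
      rows <- rbind(rows, stimulus_measures(tr, cohort$schedule, subsets,
                                            response_threshold))
    rows
  })
  meta <- per_larva[[1]][c("name", "category", "epoch", "suffix")]
  mat <- t(vapply(per_larva, function(d) d$value,
                  numeric(nrow(meta))))
  colnames(mat) <- meta$name
  rownames(mat) <- names(cohort$traces)
  structure(mat, measure_meta = meta,
            class = c("measure_matrix", class(mat)))
}

#' @export
print.measure_matrix <- function(x, ...) {
  meta <- attr(x, "measure_meta")
  cat("Measure matrix:", nrow(x), "larvae x", ncol(x), "measures (",
      paste(sprintf("%s: %d", names(table(meta$category)),
                    as.integer(table(meta$category))), collapse = ", "),
      ")\n")
  cat(" ", sum(is.na(x)), "missing cells\n")
  invisible(x)
}
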