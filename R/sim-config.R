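#' Simulation configuration for a synthetic screening cohort
#'
#' Bundles the cohort design (group sizes, genotype labels), acquisition
#' parameters (baseline frame rate, high-speed burst rate), the light
#' cycle, planted-effect descriptors and dispersion parameters into one
#' validated object consumed by [simulate_behavior_cohort()] and
#' [simulate_brain_cohort()].
#'
#' Planted effects act on homozygous mutant (`-/-`) larvae only;
#' wild-type (`+/+`) and heterozygous (`+/-`) larvae are drawn from the
#' baseline process.  All effects default to neutral (multipliers 1,
#' deltas 0), so an unmodified config describes a null cohort.
#'
#' @param n_per_genotype Larvae (or fish stacks) per genotype class;
#'   at least 2.
#' @param genotypes Genotype labels, a subset of
#'   `c("+/+", "+/-", "-/-")`.
#' @param frame_rate_hz Baseline tracking rate in frames/s (the screen
#'   tracks one aggregate delta-pixel value per second).
#' @param duration_s Experiment length in seconds.
#' @param light_cycle List with elements `day_h` (lights-on hours, 14),
#'   `night_h` (lights-off hours, 10) and `start_in_cycle_h` (circadian
#'   hour at which the recording starts; night begins at hour `day_h`).
#' @param effect_spec Named list of planted-effect descriptors.  Known
#'   names: `bout_rate` (multiplier on baseline bout initiation rate),
#'   `bout_magnitude` (multiplier on per-frame movement during bouts),
#'   `center_shift` (additive shift on the probability of being in the
#'   well center), `response_prob` (additive delta on stimulus response
#'   probability), `latency_shift_ms` (additive shift on response onset
#'   latency), `response_magnitude` (multiplier on response movement),
#'   `region_delta` (additive activity change inside the target atlas
#'   region), `region_scale` (multiplier on structure/deformation values
#'   inside the target region), `region_label` (name of the target
#'   region).  Unknown names are a configuration error.
#' @param noise_spec Named list of dispersion parameters; see Details.
#' @param replicate Replicate identifier attached to every larva
#'   (biological replicates are labeled `"1"` and `"2"` in screen
#'   output).
#' @param seed Integer seed; a fixed seed makes every simulated artifact
#'   byte-identical across runs.
#'
#' @details
#' `noise_spec` entries and their defaults: `mean_on_s = 2` and
#' `mean_off_day_s = 9` / `mean_off_night_s = 29` (exponential means of
#' the alternating bout on/off process; night is less active),
#' `dpix_shape = 3` and `dpix_scale = 10` (gamma per-frame movement
#' during a bout), `p_center = 0.25` (baseline probability of a sample
#' lying in the well center, the area fraction of a half-radius disk),
#' `stack_baseline = 1` and `stack_sd = 1` (brain-stack voxel mean and
#' i.i.d. Gaussian noise sd).
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [default_schedule()], [simulate_behavior_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_per_genotype = 5, duration_s = 600,
#'                   effect_spec = list(bout_rate = 2))
#' cfg
sim_config <- function(n_per_genotype = 20,
                       genotypes = c("+/+", "-/-"),
                       frame_rate_hz = 1,
                       duration_s = 7200,
                       light_cycle = list(day_h = 14, night_h = 10,
                                          start_in_cycle_h = 0),
                       effect_spec = list(),
                       noise_spec = list(),
                       replicate = "1",
                       seed = 1L) {
  stopifnot(is.numeric(n_per_genotype), length(n_per_genotype) == 1)
  if (n_per_genotype < 2)
    stop("n_per_genotype must be at least 2", call. = FALSE)
  if (!all(genotypes %in% c("+/+", "+/-", "-/-")))
    stop("genotypes must be drawn from {+/+, +/-, -/-}", call. = FALSE)
  if (anyDuplicated(genotypes))
    stop("duplicated genotype labels", call. = FALSE)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive", call. = FALSE)
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be positive", call. = FALSE)

  eff_defaults <- list(bout_rate = 1, bout_magnitude = 1, center_shift = 0,
                       response_prob = 0, latency_shift_ms = 0,
                       response_magnitude = 1,
                       region_delta = 0, region_scale = 1,
                       region_label = NA_character_)
  unknown <- setdiff(names(effect_spec), names(eff_defaults))
  if (length(unknown))
    stop("configuration error: unknown effect_spec entries: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  effect <- utils::modifyList(eff_defaults, effect_spec)
  mult <- c(effect$bout_rate, effect$bout_magnitude,
            effect$response_magnitude, effect$region_scale)
  if (any(!is.finite(mult)) || any(mult <= 0))
    stop("configuration error: all multipliers must be positive",
         call. = FALSE)

  noise_defaults <- list(mean_on_s = 2, mean_off_day_s = 9,
                         mean_off_night_s = 29,
                         dpix_shape = 3, dpix_scale = 10,
                         p_center = 0.25,
                         stack_baseline = 1, stack_sd = 1)
  unknown <- setdiff(names(noise_spec), names(noise_defaults))
  if (length(unknown))
    stop("configuration error: unknown noise_spec entries: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  noise <- utils::modifyList(noise_defaults, noise_spec)

  lc_defaults <- list(day_h = 14, night_h = 10, start_in_cycle_h = 0)
  light <- utils::modifyList(lc_defaults, light_cycle)

  structure(list(n_per_genotype = as.integer(n_per_genotype),
                 genotypes = genotypes,
                 frame_rate_hz = frame_rate_hz,
                 duration_s = duration_s,
                 light_cycle = light,
                 effect_spec = effect,
                 noise_spec = noise,
                 replicate = as.character(replicate),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_per_genotype, "larvae per genotype {",
      paste(x$genotypes, collapse = ", "), "},",
      x$duration_s, "s at", x$frame_rate_hz, "Hz, seed", x$seed, "\n")
  planted <- character(0)
  e <- x$effect_spec
  if (e$bout_rate != 1) planted <- c(planted, sprintf("bout_rate x%g", e$bout_rate))
  if (e$bout_magnitude != 1) planted <- c(planted, sprintf("bout_magnitude x%g", e$bout_magnitude))
  if (e$response_magnitude != 1) planted <- c(planted, sprintf("response_magnitude x%g", e$response_magnitude))
  if (e$region_scale != 1) planted <- c(planted, sprintf("region_scale x%g", e$region_scale))
  if (e$center_shift != 0) planted <- c(planted, sprintf("center_shift %+g", e$center_shift))
  if (e$response_prob != 0) planted <- c(planted, sprintf("response_prob %+g", e$response_prob))
  if (e$latency_shift_ms != 0) planted <- c(planted, sprintf("latency %+g ms", e$latency_shift_ms))
  if (e$region_delta != 0) planted <- c(planted, sprintf("region_delta %+g in %s", e$region_delta, e$region_label))
  cat("  planted effects (on -/-):",
      if (length(planted)) paste(planted, collapse = "; ") else "none", "\n")
  invisible(x)
}

#' Is a time point in the dark phase of the light cycle?
#'
#' @param t_s Time in seconds since experiment start.
#' @param config A [sim_config()].
#' @return Logical vector; `TRUE` during the night (lights-off) phase of
#'   the 14 h / 10 h cycle.
#' @export
is_night <- function(t_s, config) {
  lc <- config$light_cycle
  period <- lc$day_h + lc$night_h
  h <- (t_s / 3600 + lc$start_in_cycle_h) %% period
  h >= lc$day_h
}

#' Stimulus schedule
#'
#' An ordered set of stimulus events, each captured as a separate
#' high-speed burst movie (1 s at 285 frames/s in the screen design).
#'
#' @param events `data.frame` with columns `time_s` (strictly
#'   increasing), `kind` (one of `dark_flash`, `light_flash`,
#'   `acoustic_weak`, `acoustic_strong`, `acoustic_prepulse`),
#'   `block_id` (character block tag, e.g. `"df1"`), and optionally
#'   `freq_hz` (sound frequency for acoustic events).
#' @param burst_window_s High-speed capture length per event (seconds).
#' @param burst_rate_hz High-speed frame rate (285 fps).
#' @return Object of class `"stimulus_schedule"`.
#' @export
stimulus_schedule <- function(events, burst_window_s = 1, burst_rate_hz = 285) {
  stopifnot(is.data.frame(events),
            all(c("time_s", "kind", "block_id") %in% names(events)))
  kinds <- c("dark_flash", "light_flash", "acoustic_weak",
             "acoustic_strong", "acoustic_prepulse")
  if (!all(events$kind %in% kinds))
    stop("unknown stimulus kind(s): ",
         paste(setdiff(events$kind, kinds), collapse = ", "), call. = FALSE)
  if (nrow(events) && any(diff(events$time_s) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  if (nrow(events) > 1 && any(diff(events$time_s) < burst_window_s))
    stop("burst windows overlap: events closer than burst_window_s",
         call. = FALSE)
  if (is.null(events$freq_hz)) events$freq_hz <- rep(NA_real_, nrow(events))
  events$event_id <- sprintf("ev%03d", seq_len(nrow(events)))
  structure(list(events = events,
                 burst_window_s = burst_window_s,
                 burst_rate_hz = burst_rate_hz),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat("Stimulus schedule:", nrow(x$events), "events,",
      x$burst_window_s, "s bursts at", x$burst_rate_hz, "fps\n")
  if (nrow(x$events))
    print(table(kind = x$events$kind, block = x$events$block_id))
  invisible(x)
}

#' Default stimulus schedule for a synthetic screening day
#'
#' A compact stand-in for one assay day: a block of dark flashes, mixed
#' strong/weak acoustic stimuli (1000 Hz), and an acoustic habituation
#' block with pre / during / post phases.
#'
#' @param duration_s Experiment length the schedule must fit into.
#' @return A [stimulus_schedule()].
#' @export
default_schedule <- function(duration_s = 7200) {
  ev <- rbind(
    data.frame(time_s = 60 + 30 * (0:9), kind = "dark_flash",
               block_id = "df1", freq_hz = NA_real_),
    data.frame(time_s = 400 + 20 * (0:9), kind = "acoustic_strong",
               block_id = "a1", freq_hz = 1000),
    data.frame(time_s = 610 + 20 * (0:9), kind = "acoustic_weak",
               block_id = "a1", freq_hz = 1000),
    data.frame(time_s = 850 + 15 * (0:9), kind = "acoustic_strong",
               block_id = "hab1pre", freq_hz = 1000),
    data.frame(time_s = 1020 + 3 * (0:29), kind = "acoustic_strong",
               block_id = "hab1during", freq_hz = 1000),
    data.frame(time_s = 1130 + 15 * (0:9), kind = "acoustic_strong",
               block_id = "hab1post", freq_hz = 1000)
  )
  ev <- ev[ev$time_s + 1 <= duration_s, ]
  if (!nrow(ev))
    stop("duration_s too short for the default schedule", call. = FALSE)
  stimulus_schedule(ev)
}

#' Default stimulus subsets for measure extraction
#'
#' Builds the per-block stimulus subsets that [stimulus_measures()]
#' summarizes, with epoch labels in the screen's naming style
#' (`day5dpfdf1a`, `day5dpfhab1pre`, ...) and acoustic suffixes encoding
#' the stimulus parameters (`1_a1f1000d5p`).
#'
#' @param schedule A [stimulus_schedule()].
#' @param day_label Day prefix for epoch labels (default `"day5dpf"`).
#' @return List of subsets, each a list with `label`, `event_ids`, and
#'   optional `suffix`.
#' @export
default_subsets <- function(schedule, day_label = "day5dpf") {
  ev <- schedule$events
  out <- list()
  for (blk in unique(ev$block_id)) {
    for (kind in unique(ev$kind[ev$block_id == blk])) {
      sel <- ev[ev$block_id == blk & ev$kind == kind, ]
      tag <- switch(kind,
                    dark_flash = "a", light_flash = "l",
                    acoustic_strong = "1_a1f%dd5p",
                    acoustic_weak = "3_a1f%dd5p",
                    acoustic_prepulse = "2_a1f%dd5p")
      if (kind %in% c("dark_flash", "light_flash")) {
        label <- paste0(day_label, blk, tag)
        suffix <- NULL
      } else {
        label <- paste0(day_label, blk)
        suffix <- sprintf(tag, ifelse(is.na(sel$freq_hz[1]), 0,
                                      sel$freq_hz[1]))
      }
      out[[length(out) + 1L]] <- list(label = label,
                                      event_ids = sel$event_id,
                                      suffix = suffix)
    }
  }
  out
}

## run an expression under a fixed seed without disturbing the caller's
## RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
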