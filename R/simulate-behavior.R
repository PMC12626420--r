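#' Simulate a behavioral cohort with planted genotype effects
#'
#' Draws one delta-pixel trace per larva from an alternating-renewal
#' bout process (exponential on/off durations, gamma per-frame movement
#' while active, day/night rate modulation on the light cycle), plus one
#' high-speed 285 fps burst per scheduled stimulus event with
#' genotype-dependent response probability, onset latency and
#' magnitude.  Homozygous mutants realize the planted effects declared
#' in `config$effect_spec`; all other genotypes follow the baseline
#' process.
#'
#' Centroid positions are drawn in the unit-circle well: with
#' probability `p_center` (plus the planted `center_shift` for mutants)
#' a sample lies uniformly in the half-radius center disk, otherwise
#' uniformly in the outer annulus.
#'
#' @param config A [sim_config()].
#' @param schedule A [stimulus_schedule()]; must fit within
#'   `config$duration_s`.
#' @return A list of class `"behavior_cohort"` with elements `traces`
#'   (named list of `"dpix_trace"` objects), `genotypes` (data.frame
#'   `larva_id`, `genotype`, `replicate`), `schedule`, and `config`.
#' @export
#' @examples
#' cfg <- sim_config(n_per_genotype = 3, duration_s = 900, seed = 7)
#' coh <- simulate_behavior_cohort(cfg, default_schedule(900))
#' coh
simulate_behavior_cohort <- function(config, schedule = default_schedule(config$duration_s)) {
  stopifnot(inherits(config, "sim_config"),
            inherits(schedule, "stimulus_schedule"))
  ev <- schedule$events
  if (nrow(ev) && max(ev$time_s) + schedule$burst_window_s > config$duration_s)
    stop("schedule does not fit within duration_s", call. = FALSE)

  with_seed(config$seed, {
    traces <- list()
    gmap <- list()
    for (g in config$genotypes) {
      mutant <- identical(g, "-/-")
      for (i in seq_len(config$n_per_genotype)) {
        id <- sprintf("larva_%s_r%s_%02d",
                      c("+/+" = "wt", "+/-" = "het", "-/-" = "hom")[[g]],
                      config$replicate, i)
        traces[[id]] <- simulate_trace(id, mutant, config, schedule)
        gmap[[id]] <- g
      }
    }
    genotypes <- data.frame(larva_id = names(gmap),
                            genotype = unlist(gmap, use.names = FALSE),
                            replicate = config$replicate,
                            stringsAsFactors = FALSE)
    rownames(genotypes) <- NULL
    structure(list(traces = traces, genotypes = genotypes,
                   schedule = schedule, config = config),
              class = "behavior_cohort")
  })
}

## one larva: baseline trace + per-event bursts
simulate_trace <- function(id, mutant, config, schedule) {
  eff <- config$effect_spec
  ns <- config$noise_spec
  dt <- 1 / config$frame_rate_hz
  t <- seq(0, config$duration_s - dt, by = dt)
  n <- length(t)

  rate_mult <- if (mutant) eff$bout_rate else 1
  mag_mult <- if (mutant) eff$bout_magnitude else 1
  p_center <- ns$p_center + if (mutant) eff$center_shift else 0
  p_center <- min(max(p_center, 0), 1)

  ## alternating on/off process, generated per light-phase segment so
  ## the off rate can switch at lights-on/off boundaries
  night <- is_night(t, config)
  seg_start <- c(1L, which(diff(night) != 0) + 1L)
  seg_end <- c(seg_start[-1] - 1L, n)
  active <- logical(n)
  for (s in seq_along(seg_start)) {
    idx <- seg_start[s]:seg_end[s]
    mean_off <- if (night[seg_start[s]]) ns$mean_off_night_s else ns$mean_off_day_s
    mean_off <- mean_off / rate_mult
    span <- length(idx) * dt
    k <- ceiling(span / (mean_off + ns$mean_on_s)) * 3 + 10
    offs <- stats::rexp(k, 1 / mean_off)
    ons <- pmax(stats::rexp(k, 1 / ns$mean_on_s), dt)
    bounds <- cumsum(as.vector(rbind(offs, ons)))
    while (bounds[length(bounds)] < span) {   # rare: extend
      offs2 <- stats::rexp(k, 1 / mean_off)
      ons2 <- pmax(stats::rexp(k, 1 / ns$mean_on_s), dt)
      bounds <- c(bounds, bounds[length(bounds)] +
                    cumsum(as.vector(rbind(offs2, ons2))))
    }
    local_t <- (seq_along(idx) - 1) * dt
    active[idx] <- findInterval(local_t, bounds) %% 2 == 1
  }

  dpix <- numeric(n)
  n_act <- sum(active)
  if (n_act)
    dpix[active] <- stats::rgamma(n_act, shape = ns$dpix_shape,
                                  scale = ns$dpix_scale * mag_mult)

  in_center <- stats::runif(n) < p_center
  u <- stats::runif(n)
  r <- ifelse(in_center, 0.5 * sqrt(u), sqrt(0.25 + 0.75 * u))
  theta <- stats::runif(n, 0, 2 * pi)
  x <- r * cos(theta)
  y <- r * sin(theta)

  bursts <- simulate_bursts(mutant, config, schedule)

  structure(list(larva_id = id, t = t, dpix = dpix, x = x, y = y,
                 bursts = bursts,
                 burst_rate_hz = schedule$burst_rate_hz,
                 burst_window_s = schedule$burst_window_s),
            class = "dpix_trace")
}

## response parameters per stimulus kind: probability of responding,
## mean onset latency (ms) and its sd, response strength scale
burst_kind_params <- function(kind) {
  switch(kind,
         dark_flash       = list(p = 0.7, lat = 250, lat_sd = 80, mag = 25),
         light_flash      = list(p = 0.5, lat = 150, lat_sd = 50, mag = 15),
         acoustic_strong  = list(p = 0.8, lat = 20, lat_sd = 8, mag = 30),
         acoustic_weak    = list(p = 0.3, lat = 25, lat_sd = 10, mag = 15),
         acoustic_prepulse = list(p = 0.5, lat = 30, lat_sd = 10, mag = 20))
}

simulate_bursts <- function(mutant, config, schedule) {
  eff <- config$effect_spec
  ev <- schedule$events
  rate <- schedule$burst_rate_hz
  len <- round(schedule$burst_window_s * rate)
  bursts <- vector("list", nrow(ev))
  names(bursts) <- ev$event_id
  for (j in seq_len(nrow(ev))) {
    v <- numeric(len)
    p <- burst_kind_params(ev$kind[j])
    prob <- p$p + if (mutant) eff$response_prob else 0
    prob <- min(max(prob, 0), 1)
    if (stats::runif(1) < prob) {
      lat <- stats::rnorm(1, p$lat, p$lat_sd) +
        if (mutant) eff$latency_shift_ms else 0
      lat <- min(max(lat, 1000 / rate), 900)
      onset <- max(1L, round(lat / 1000 * rate))
      dur <- min(len - onset + 1L, round(0.1 * rate))
      mag <- p$mag * (if (mutant) eff$response_magnitude else 1)
      v[onset:(onset + dur - 1L)] <-
        stats::rgamma(dur, shape = 4, scale = mag / 4)
    }
    bursts[[j]] <- v
  }
  bursts
}

#' @export
print.behavior_cohort <- function(x, ...) {
  cat("Behavior cohort: ", length(x$traces), " larvae (",
      paste(sprintf("%s: %d", names(table(x$genotypes$genotype)),
                    as.integer(table(x$genotypes$genotype))),
            collapse = ", "), "), ",
      x$config$duration_s, " s baseline, ",
      nrow(x$schedule$events), " stimulus events\n", sep = "")
  invisible(x)
}

#' @export
print.dpix_trace <- function(x, ...) {
  cat("dpix trace", x$larva_id, ":", length(x$t), "samples,",
      length(x$bursts), "bursts,",
      sprintf("%.1f%% active frames", 100 * mean(x$dpix > 0)), "\n")
  invisible(x)
}
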