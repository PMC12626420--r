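test_that("bout detection matches closed-form pulse examples", {
  expect_identical(nrow(detect_bouts(toy_trace(rep(0, 20)))), 0L)
  expect_identical(nrow(detect_bouts(list(t = numeric(0),
                                          dpix = numeric(0)))), 0L)
  ## single rectangular pulse: height 5 over 3 samples
  b <- detect_bouts(toy_trace(c(0, 5, 5, 5, 0, 0)))
  expect_identical(nrow(b), 1L)
  expect_equal(b$cumulative_movement, 15)
  expect_equal(b$peak, 5)
  expect_equal(b$n_samples, 3L)
  expect_equal(b$mean_velocity, 15 / 3)
})

test_that("gap merging follows the run/merge rules", {
  ## two pulses, 2-sample gap (2 s at 1 Hz): separate at default gap
  tr <- toy_trace(c(5, 5, 0, 0, 5, 5))
  expect_identical(nrow(detect_bouts(tr)), 2L)
  ## same pulses with merge_gap larger than the gap: one bout
  m <- detect_bouts(tr, merge_gap_s = 2.5)
  expect_identical(nrow(m), 1L)
  expect_equal(m$cumulative_movement, 20)
  ## min duration discards short merged runs
  expect_identical(nrow(detect_bouts(toy_trace(c(0, 5, 0)),
                                     min_duration_s = 2)), 0L)
})

test_that("bout detection agrees with run-length enumeration on random traces", {
  set.seed(1)
  for (rep_ in 1:40) {
    n <- sample(5:50, 1)
    dpix <- round(rexp(n, 0.5) * rbinom(n, 1, 0.4), 2)
    thr <- sample(c(0, 0.5), 1)
    gap <- sample(c(0, 1.5, 2.5), 1)
    mind <- sample(c(0, 2), 1)
    got <- detect_bouts(toy_trace(dpix), threshold = thr,
                        merge_gap_s = gap, min_duration_s = mind)
    want <- oracle_bouts(seq_len(n) - 1, dpix, thr, gap, mind)
    expect_identical(nrow(got), nrow(want))
    expect_equal(got$start_s, want$start)
    expect_equal(got$cumulative_movement, want$cum)
    expect_equal(got$peak, want$peak)
  }
})

test_that("bout movement is conserved relative to the raw trace", {
  set.seed(2)
  dpix <- round(rexp(60, 0.5) * rbinom(60, 1, 0.5), 2)
  tr <- toy_trace(dpix)
  ## equality at fully permissive parameters
  b0 <- detect_bouts(tr, threshold = 0, merge_gap_s = 0, min_duration_s = 0)
  expect_equal(sum(b0$cumulative_movement), sum(dpix))
  ## inequality once a threshold filters samples
  b1 <- detect_bouts(tr, threshold = 1)
  expect_lte(sum(b1$cumulative_movement), sum(dpix))
})

test_that("baseline measures summarize epochs per the measure taxonomy", {
  ## 4 bouts in one 1-h bin; two with known cumulative movements
  dpix <- rep(0, 3600)
  dpix[c(10, 100, 101, 500, 2000)] <- c(10, 15, 15, 4, 6)
  x <- rep(1, 3600); y <- rep(0, 3600)   # all samples at the edge
  x[c(10, 100, 101)] <- 0                # first two bouts in center
  tr <- toy_trace(dpix, x = x, y = y)
  b <- detect_bouts(tr)
  expect_identical(nrow(b), 4L)
  m <- baseline_measures(b, tr, list(epoch_spec("combo", 0, 3600, 3600)))
  v <- setNames(m$value, m$name)
  expect_equal(v[["combo_numberofbouts_3600"]], 4)
  expect_equal(v[["combo_boutcumulativemovement_3600"]], (10 + 30 + 4 + 6) / 4)
  ## bout-time-weighted center fraction: bouts 1,2 fully centered
  ## (durations 1 and 2 s of 5 s bout time)
  expect_equal(v[["combo_boutcenterfraction_3600"]], 3 / 5)
  expect_equal(v[["combo_activeseconds_3600"]], 5)
  ## all-center trace gives fraction 1
  tr2 <- toy_trace(dpix, x = rep(0, 3600), y = rep(0, 3600))
  m2 <- baseline_measures(detect_bouts(tr2), tr2,
                          list(epoch_spec("combo", 0, 3600, 3600)))
  expect_equal(m2$value[m2$name == "combo_boutcenterfraction_3600"], 1)
})

test_that("epochs with no bouts give zero frequency and missing magnitude", {
  tr <- toy_trace(rep(0, 7200))
  m <- baseline_measures(detect_bouts(tr), tr,
                         list(epoch_spec("combo", 0, 7200, 3600)))
  v <- setNames(m$value, vapply(m$name, function(n)
    parse_measure_name(n)$measure, ""))
  expect_equal(v[["numberofbouts"]], 0)
  expect_equal(v[["activeseconds"]], 0)
  expect_true(is.na(v[["boutcumulativemovement"]]))
  expect_true(is.na(v[["boutcenterfraction"]]))
  expect_error(baseline_measures(detect_bouts(tr), tr,
                                 list(epoch_spec("late", 0, 9000, 3600))),
               "late")
})

test_that("bout counts are additive over bins within an epoch", {
  set.seed(3)
  dpix <- round(rexp(7200, 1) * rbinom(7200, 1, 0.1), 2)
  tr <- toy_trace(dpix)
  b <- detect_bouts(tr)
  ep <- epoch_spec("combo", 0, 7200, 3600)
  counts <- bin_bout_counts(b, ep)
  expect_identical(length(counts), 2L)
  expect_identical(sum(counts), sum(b$start_s < 7200))
  ## and the epoch mean matches the per-bin mean
  m <- baseline_measures(b, tr, list(ep))
  expect_equal(m$value[m$name == "combo_numberofbouts_3600"], mean(counts))
})

test_that("stimulus measures quantify response frequency, latency, magnitude", {
  mk_burst <- function(onset, height = 10, dur = 20) {
    v <- rep(0, 285)
    if (!is.na(onset)) v[onset:(onset + dur - 1)] <- height
    v
  }
  bursts <- c(lapply(1:7, function(i) mk_burst(30 + i)),
              lapply(1:3, function(i) mk_burst(NA)))
  names(bursts) <- sprintf("ev%03d", 1:10)
  tr <- toy_burst_trace(bursts)
  sch <- stimulus_schedule(data.frame(time_s = 1:10 * 20,
                                      kind = "dark_flash",
                                      block_id = "df1"))
  subsets <- list(list(label = "day6dpfdf1a", event_ids = names(bursts)))
  m <- stimulus_measures(tr, sch, subsets)
  v <- setNames(m$value, m$name)
  ## 7 of 10 responded
  expect_equal(v[["day6dpfdf1a_responsefrequency"]], 0.7)
  ## onset at index 57 of a 285 Hz window = 200 ms
  tr2 <- toy_burst_trace(list(ev001 = mk_burst(57)))
  m2 <- stimulus_measures(tr2, sch,
                          list(list(label = "df", event_ids = "ev001")))
  expect_equal(m2$value[m2$name == "df_responselatency"], 200)
  ## magnitude = mean cumulative dpix over responders
  expect_equal(v[["day6dpfdf1a_responsemagnitude"]], 10 * 20)
  ## no responders: frequency 0, latency missing
  tr3 <- toy_burst_trace(list(ev001 = rep(0, 285), ev002 = rep(0, 285)))
  m3 <- stimulus_measures(tr3, sch,
                          list(list(label = "df",
                                    event_ids = c("ev001", "ev002"))))
  v3 <- setNames(m3$value, m3$name)
  expect_equal(v3[["df_responsefrequency"]], 0)
  expect_true(is.na(v3[["df_responselatency"]]))
  ## zero-event subsets and missing bursts are errors
  expect_error(stimulus_measures(tr3, sch,
                                 list(list(label = "x",
                                           event_ids = character(0)))),
               "zero events")
  expect_error(stimulus_measures(tr3, sch,
                                 list(list(label = "x",
                                           event_ids = "ev099"))),
               "without bursts")
})

test_that("measure naming grammar round-trips the screen's names", {
  expect_identical(measure_name("day0night", "boutcenterfraction", 3600),
                   "day0night_boutcenterfraction_3600")
  expect_identical(measure_name("day6dpfdf1a", "responselatency"),
                   "day6dpfdf1a_responselatency")
  p <- parse_measure_name("day5dpfhab1pre_responsefrequency_1_a1f1000d5p")
  expect_identical(p$epoch, "day5dpfhab1pre")
  expect_identical(p$measure, "responsefrequency")
  expect_identical(p$suffix, "1_a1f1000d5p")
  ## inversion property on random well-formed names
  for (ep in c("combo", "dpix", "day1night"))
    for (sfx in list(NULL, "3600", "1_a1f1000d5p")) {
      nm <- measure_name(ep, "numberofbouts", sfx)
      q <- parse_measure_name(nm)
      expect_identical(q$epoch, ep)
      expect_identical(q$measure, "numberofbouts")
      if (!is.null(sfx)) expect_identical(q$suffix, sfx)
    }
  expect_error(measure_name("day_0", "bouts"), "reserved separator")
  expect_error(measure_name("", "bouts"), "empty")
})

test_that("the measure matrix is invariant to larva ordering", {
  cfg <- sim_config(n_per_genotype = 3, duration_s = 1200, seed = 13)
  coh <- simulate_behavior_cohort(cfg, default_schedule(1200))
  mm <- build_measure_matrix(coh)
  coh2 <- coh
  perm <- rev(seq_along(coh$traces))
  coh2$traces <- coh$traces[perm]
  mm2 <- build_measure_matrix(coh2)
  expect_equal(mm[rownames(mm2), ], unclass(mm2)[, colnames(mm)],
               ignore_attr = TRUE)
  ## response frequencies live in [0, 1]; latencies in (0, 1000] ms
  meta <- attr(mm, "measure_meta")
  rf <- mm[, meta$name[grepl("responsefrequency", meta$name)]]
  expect_true(all(rf >= 0 & rf <= 1))
  rl <- mm[, meta$name[grepl("responselatency", meta$name)]]
  expect_true(all(is.na(rl) | (rl > 0 & rl <= 1000)))
})
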