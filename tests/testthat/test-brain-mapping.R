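test_that("voxel Z maps are antisymmetric and hit the rank-sum extreme", {
  a <- small_null_stacks(5, c(3, 3, 3), seed = 1)
  b <- small_null_stacks(5, c(3, 3, 3), seed = 2)
  z <- voxel_zmap(a, b)
  expect_identical(dim(z), c(3L, 3L, 3L))
  expect_equal(voxel_zmap(b, a), -z)
  ## separated groups reach the 5+5 closed-form extreme
  ## Z = (40 - 27.5) / sqrt(25 * 11 / 12)
  hi <- lapply(a, function(s) s + 100)
  zext <- voxel_zmap(hi, b)
  expect_equal(max(abs(zext - 12.5 / sqrt(25 * 11 / 12))), 0,
               tolerance = 1e-12)
  expect_true(all(zext > 0))
  expect_error(voxel_zmap(a, small_null_stacks(4, c(2, 2, 2))),
               "congruent|shape")
  expect_error(voxel_zmap(a[1], b), "at least 2")
})

test_that("voxel Z agrees with a per-voxel rank-sum oracle, ties included", {
  set.seed(6)
  shape <- c(5, 5, 4)   # 100 voxels
  a <- replicate(4, array(round(rnorm(100), 1), shape), simplify = FALSE)
  b <- replicate(4, array(round(rnorm(100), 1), shape), simplify = FALSE)
  z <- voxel_zmap(a, b)
  for (v in seq_len(100)) {
    av <- vapply(a, function(s) s[[v]], 0)
    bv <- vapply(b, function(s) s[[v]], 0)
    expect_equal(z[[v]], oracle_ranksum_z(av, bv), tolerance = 1e-12)
  }
})

test_that("effect maps are median differences, sign-consistent with Z", {
  a <- small_null_stacks(5, c(3, 3, 2), seed = 3)
  b <- small_null_stacks(5, c(3, 3, 2), seed = 4)
  eff <- voxel_effect(a, b)
  v <- 7
  expect_equal(eff[[v]],
               median(vapply(a, function(s) s[[v]], 0)) -
                 median(vapply(b, function(s) s[[v]], 0)))
  expect_equal(voxel_effect(b, a), -eff)
})

test_that("threshold calibration realizes the target control fraction", {
  ctrl <- small_null_stacks(8, c(8, 8, 4), seed = 5)
  cal <- calibrate_threshold(ctrl, target_fraction = 0.05, n_splits = 20,
                             seed = 1)
  expect_s3_class(cal, "brain_calibration")
  ## fresh null cohorts flag about the target fraction
  fracs <- vapply(1:30, function(i) {
    nul <- small_null_stacks(8, c(8, 8, 4), seed = 100 + i)
    z <- voxel_zmap(nul[1:4], nul[5:8])
    mean(abs(z) >= cal$z_threshold)
  }, 0)
  ## attainable 4v4 atoms: the largest exact tail at or below 5% is
  ## 2/70 = 2.86%; the Monte-Carlo mean must sit near an attainable
  ## atom and never exceed the target
  expect_lte(mean(fracs), 0.05 + 3 * sd(fracs) / sqrt(30))
  expect_gt(mean(fracs), 0.005)
  ## quantile identity: target 0.5 lands at the pooled median
  cal50 <- calibrate_threshold(ctrl, target_fraction = 0.5, n_splits = 20,
                               seed = 1)
  expect_lt(cal50$realized_fraction, 0.6)
  expect_gt(cal50$realized_fraction, 0.4)
  ## boundary targets rejected; too few controls rejected
  expect_error(calibrate_threshold(ctrl, target_fraction = 1), "0, 1")
  expect_error(calibrate_threshold(ctrl[1:3], 0.05), "at least 4")
})

test_that("calibration is stable under more splits", {
  ctrl <- small_null_stacks(10, c(8, 8, 4), seed = 7)
  c1 <- calibrate_threshold(ctrl, target_fraction = 0.02, n_splits = 20,
                            seed = 3)
  c2 <- calibrate_threshold(ctrl, target_fraction = 0.02, n_splits = 40,
                            seed = 3)
  ## thresholds sit on neighboring discrete |Z| atoms at worst
  expect_lt(abs(c1$z_threshold - c2$z_threshold), 0.5)
})

test_that("significance maps are thresholded, signed, and antisymmetric", {
  a <- small_null_stacks(5, c(4, 4, 2), seed = 8)
  b <- small_null_stacks(5, c(4, 4, 2), seed = 9)
  z <- voxel_zmap(a, b)
  eff <- voxel_effect(a, b)
  sig <- significance_map(z, eff, 1.5)
  expect_true(all(sig[abs(z) < 1.5] == 0))
  expect_equal(unclass(sig)[abs(z) >= 1.5], eff[abs(z) >= 1.5],
               ignore_attr = TRUE)
  ## infinite threshold blanks the map
  expect_true(all(significance_map(z, eff, Inf) == 0))
  ## group swap negates the map exactly
  sig_sw <- significance_map(voxel_zmap(b, a), voxel_effect(b, a), 1.5)
  expect_equal(unclass(sig_sw), -unclass(sig), ignore_attr = TRUE)
  expect_error(significance_map(z, eff[1:2, , ], 1), "congruent")
})

test_that("a planted region dominates the significance map and its ranking", {
  atlas <- make_atlas(c(16, 16, 8), n_regions = 4, seed = 11)
  cfg <- sim_config(n_per_genotype = 10, duration_s = 60, seed = 81,
                    effect_spec = list(region_delta = 5,
                                       region_label = "region2"))
  coh <- simulate_brain_cohort(cfg, atlas)
  geno <- coh$genotypes$genotype
  ga <- coh$stacks[geno == "-/-"]
  gb <- coh$stacks[geno == "+/+"]
  z <- voxel_zmap(ga, gb)
  ## calibrate on a larger control-only pool so half-splits share the
  ## 10 vs 10 geometry of the contrast
  ctrl_cfg <- sim_config(n_per_genotype = 20, genotypes = "+/+",
                         duration_s = 60, seed = 82)
  ctrl <- simulate_brain_cohort(ctrl_cfg, atlas)$stacks
  cal <- calibrate_threshold(ctrl, target_fraction = 5e-4, n_splits = 60,
                             seed = 2)
  sig <- significance_map(z, voxel_effect(ga, gb), cal)
  nz <- which(unclass(sig) != 0)
  expect_gt(length(nz), 0)
  ## >= 80% of nonzero voxels inside the planted region, all positive
  expect_gte(mean(atlas[nz] == 2), 0.8)
  expect_true(all(sig[atlas == 2 & unclass(sig) != 0] > 0))
  reg <- region_quantify(sig, atlas)
  expect_identical(reg$region[which.max(reg$increased + reg$decreased)],
                   "region2")
})

test_that("region quantification divides summed signal by region size", {
  atlas <- structure(array(c(rep(1L, 10), rep(2L, 20), rep(0L, 34)),
                           c(4, 4, 4)),
                     region_names = c("A", "B"), class = "region_atlas")
  m <- array(0, c(4, 4, 4))
  ## uniform value across all of region A: summary equals the value
  m[1:10] <- 7
  r <- region_quantify(m, atlas)
  expect_equal(r$increased[r$region == "A"], 7)
  ## value 4 in half of region B's voxels: summary = 2
  m2 <- array(0, c(4, 4, 4))
  m2[11:20] <- 4
  r2 <- region_quantify(m2, atlas)
  expect_equal(r2$increased[r2$region == "B"], 2)
  expect_equal(r2$decreased[r2$region == "B"], 0)
  ## negative signal lands in the decreased channel
  m3 <- array(0, c(4, 4, 4))
  m3[11:30] <- -3
  r3 <- region_quantify(m3, atlas)
  expect_equal(r3$decreased[r3$region == "B"], 3)
  expect_equal(r3$increased[r3$region == "B"], 0)
  ## all-zero map: all summaries zero
  r0 <- region_quantify(array(0, c(4, 4, 4)), atlas)
  expect_true(all(r0$increased == 0) && all(r0$decreased == 0))
  expect_error(region_quantify(array(0, c(2, 2, 2)), atlas), "congruent")
})

test_that("total signal sums absolute significant signal", {
  m <- array(0, c(3, 3, 3))
  expect_equal(total_signal(m), 0)
  m[1:3] <- 2; m[4:7] <- -1
  expect_equal(total_signal(m), 10)
  expect_equal(total_signal(-m), total_signal(m))
})

test_that("sum-of-slices projections are linear and conserve totals", {
  m <- array(0, c(3, 4, 5))
  m[2, 3, 4] <- 7
  pz <- sum_of_slices(m, "z")
  expect_identical(dim(pz), c(4L, 5L))
  expect_equal(sum(pz != 0), 1)
  expect_equal(pz[3, 4], 7)
  px <- sum_of_slices(m, "x")
  expect_identical(dim(px), c(3L, 4L))
  expect_equal(px[2, 3], 7)
  set.seed(12)
  m1 <- array(rnorm(60), c(3, 4, 5))
  m2 <- array(rnorm(60), c(3, 4, 5))
  expect_equal(sum_of_slices(m1 + m2, "z"),
               sum_of_slices(m1, "z") + sum_of_slices(m2, "z"))
  expect_equal(sum(sum_of_slices(m1, "z")), sum(m1))
  expect_error(sum_of_slices(m1, "y"), "arg")
})

test_that("structure channel maps planted shrinkage as decreased signal", {
  atlas <- make_atlas(c(12, 12, 6), n_regions = 3, seed = 13)
  cfg <- sim_config(n_per_genotype = 10, duration_s = 60, seed = 91,
                    noise_spec = list(stack_baseline = 10, stack_sd = 1),
                    effect_spec = list(region_scale = 0.5,
                                       region_label = "region1"))
  coh <- simulate_brain_cohort(cfg, atlas, channel = "structure")
  geno <- coh$genotypes$genotype
  ga <- coh$stacks[geno == "-/-"]
  gb <- coh$stacks[geno == "+/+"]
  sig <- significance_map(voxel_zmap(ga, gb), voxel_effect(ga, gb),
                          calibrate_threshold(gb, 0.01, 20, seed = 4))
  reg <- region_quantify(sig, atlas)
  r1 <- reg[reg$region == "region1", ]
  expect_gt(r1$decreased, 0)
  expect_gt(r1$decreased, max(reg$decreased[reg$region != "region1"]))
  expect_equal(r1$increased, 0)
})

test_that("NRRD round-trips stacks and atlases", {
  tmp <- withr::local_tempdir()
  x <- array(rnorm(24), c(2, 3, 4))
  p <- file.path(tmp, "stack.nrrd")
  write_nrrd(x, p)
  expect_equal(read_nrrd(p), x)
  atlas <- make_atlas(c(8, 8, 4), 2, seed = 1)
  pa <- file.path(tmp, "atlas.nrrd")
  write_nrrd(atlas, pa)
  back <- read_atlas(pa)
  expect_equal(unclass(back), unclass(atlas), ignore_attr = TRUE)
  expect_identical(attr(back, "region_names"), c("region1", "region2"))
})
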