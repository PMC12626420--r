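## stacks (list of congruent 3D arrays) -> n x V matrix
stacks_to_matrix <- function(stacks) {
  dims <- lapply(stacks, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("stacks are not congruent (shape mismatch)", call. = FALSE)
  do.call(rbind, lapply(stacks, as.vector))
}

## midranks per column of an n x V matrix, plus the per-column tie
## term sum(t^3 - t).  Pairwise-comparison formulation: vectorized over
## voxels, O(n^2) passes over rows.
column_midranks <- function(X) {
  n <- nrow(X)
  R <- matrix(1, n, ncol(X))
  eq_pairs <- numeric(ncol(X))   # ordered unequal-index equal pairs
  for (i in seq_len(n)) {
    xi <- X[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      lt <- X[j, ] < xi
      eq <- X[j, ] == xi
      R[i, ] <- R[i, ] + lt + 0.5 * eq
      eq_pairs <- eq_pairs + eq
    }
  }
  tie_term <- numeric(ncol(X))
  tied <- which(eq_pairs > 0)
  for (v in tied) {
    tt <- table(X[, v])
    tie_term[v] <- sum(tt^3 - tt)
  }
  list(ranks = R, tie_term = tie_term)
}

## rank-sum Z per column given precomputed midranks; positive when the
## rows in a_rows are stochastically larger
ranksum_z <- function(ranks, tie_term, a_rows) {
  n <- nrow(ranks)
  na <- length(a_rows)
  nb <- n - na
  W <- colSums(ranks[a_rows, , drop = FALSE])
  mu <- na * (n + 1) / 2
  v <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- numeric(ncol(ranks))
  ok <- v > 0
  z[ok] <- (W[ok] - mu) / sqrt(v[ok])
  z
}

#' Voxel-wise rank-sum Z map between two groups of stacks
#'
#' Per voxel, the two-sided Mann-Whitney rank-sum statistic as a
#' tie-corrected normal deviate, signed so positive means `group_a`
#' stochastically larger.  Voxels where all values are tied (zero rank
#' variance) get Z = 0.
#'
#' @param group_a,group_b Lists of congruent 3D arrays (>= 2 each).
#' @return 3D numeric array of signed Z values, same shape as the
#'   stacks.
#' @export
voxel_zmap <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need at least 2 stacks per group", call. = FALSE)
  X <- stacks_to_matrix(c(group_a, group_b))
  mr <- column_midranks(X)
  z <- ranksum_z(mr$ranks, mr$tie_term, seq_along(group_a))
  array(z, dim(group_a[[1]]))
}

#' Voxel-wise effect map: difference of group medians
#'
#' The displayed effect magnitude of the mapping pipeline: per voxel,
#' `median(group_a) - median(group_b)`; robust and sign-consistent with
#' the rank statistic.
#'
#' @inheritParams voxel_zmap
#' @return 3D numeric array.
#' @export
voxel_effect <- function(group_a, group_b) {
  med <- function(stacks) {
    X <- stacks_to_matrix(stacks)
    n <- nrow(X)
    ## sort within columns with one order() call (column-major layout:
    ## consecutive n entries of as.vector(X) belong to one voxel)
    vv <- as.vector(X)
    o <- order(rep(seq_len(ncol(X)), each = n), vv)
    s <- matrix(vv[o], n, ncol(X))
    (s[floor((n + 1) / 2), ] + s[ceiling((n + 1) / 2), ]) / 2
  }
  a <- c(group_a); b <- c(group_b)
  if (!identical(dim(a[[1]]), dim(b[[1]])))
    stop("stacks are not congruent (shape mismatch)", call. = FALSE)
  array(med(a) - med(b), dim(a[[1]]))
}

#' Calibrate the voxel significance threshold on control stacks
#'
#' Operationalizes the screen's empirical false-discovery rule: the
#' |Z| threshold is chosen so that a stated fraction of control voxels
#' (0.05% in the screen design) would be called significant.  Control
#' stacks are repeatedly split at random into two pseudo-groups, a
#' rank-sum Z map is computed per split, all control |Z| values are
#' pooled, and the threshold is the smallest pooled value whose
#' at-or-above fraction does not exceed `target_fraction` (a
#' left-continuous empirical `1 - target_fraction` quantile, so the
#' flagged fraction never overshoots the target).  The realized
#' fraction is reported on one additional held-out split.
#'
#' @param control_stacks List of >= 4 congruent control 3D arrays.
#' @param target_fraction Fraction of control voxels to be called
#'   significant; 0 < f < 1 (0.0005 = 0.05%).
#' @param n_splits Number of random half-splits pooled.
#' @param seed Integer seed for the split draws.
#' @return Object of class `"brain_calibration"`: `z_threshold`,
#'   `target_fraction`, `realized_fraction` (held-out split),
#'   `n_splits`, `n_controls`, `seed`.
#' @export
#' @examples
#' set.seed(1)
#' ctrl <- replicate(8, array(rnorm(4 * 4 * 2), c(4, 4, 2)),
#'                   simplify = FALSE)
#' calibrate_threshold(ctrl, target_fraction = 0.05, n_splits = 5)
calibrate_threshold <- function(control_stacks, target_fraction = 5e-4,
                                n_splits = 20, seed = 1L) {
  n <- length(control_stacks)
  if (n < 4)
    stop("need at least 4 control stacks to split", call. = FALSE)
  if (!(target_fraction > 0 && target_fraction < 1))
    stop("target_fraction must be in (0, 1)", call. = FALSE)
  X <- stacks_to_matrix(control_stacks)
  mr <- column_midranks(X)
  na <- n %/% 2
  V <- ncol(mr$ranks)
  with_seed(seed, {
    ## pool |Z| across splits.  The threshold lives in the extreme
    ## upper tail, so only values above a generous cutoff (50x the
    ## target tail, estimated from the first split) need to be kept;
    ## everything below cannot become the quantile.  Midrank sums are
    ## exact multiples of 0.5, so the discrete |Z| values are bitwise
    ## reproducible across splits and the truncation is exact.
    z1 <- abs(ranksum_z(mr$ranks, mr$tie_term, sample.int(n, na)))
    keep_frac <- min(1, 50 * target_fraction)
    c0 <- if (keep_frac >= 1) -Inf
          else stats::quantile(z1, 1 - keep_frac, type = 1, names = FALSE)
    stored <- vector("list", n_splits)
    stored[[1]] <- z1[z1 >= c0]
    for (s in seq_len(n_splits - 1L)) {
      zs <- abs(ranksum_z(mr$ranks, mr$tie_term, sample.int(n, na)))
      stored[[s + 1L]] <- zs[zs >= c0]
    }
    pool_hi <- unlist(stored)
    allowed <- floor(target_fraction * n_splits * V)
    thr <- empirical_tail_threshold(pool_hi, allowed)
    heldout <- abs(ranksum_z(mr$ranks, mr$tie_term, sample.int(n, na)))
    structure(list(z_threshold = thr,
                   target_fraction = target_fraction,
                   realized_fraction = mean(heldout >= thr),
                   n_splits = n_splits, n_controls = n,
                   seed = as.integer(seed)),
              class = "brain_calibration")
  })
}

## smallest pooled value v with #(pool >= v) <= allowed; pool may be
## pre-truncated from below (values that can never be the quantile
## dropped).  Inf when even the maximum occurs too often.
empirical_tail_threshold <- function(pool, allowed) {
  if (allowed < 1 || !length(pool)) return(Inf)
  if (length(pool) <= allowed) return(min(pool))
  s <- sort(pool, decreasing = TRUE)
  cand <- s[allowed]
  if (sum(pool >= cand) <= allowed) return(cand)
  above <- s[s > cand]
  if (!length(above)) return(Inf)
  min(above)
}

#' @export
print.brain_calibration <- function(x, ...) {
  cat(sprintf(paste0("Calibrated |Z| threshold: %.4f (target %.4g%% of",
                     " control voxels; realized %.4g%% on held-out",
                     " split; %d splits of %d controls)\n"),
              x$z_threshold, 100 * x$target_fraction,
              100 * x$realized_fraction, x$n_splits, x$n_controls))
  invisible(x)
}

#' Signed significance map
#'
#' Zero where `|Z|` is below the calibrated threshold; elsewhere the
#' signed effect magnitude (positive = increased in group A, negative =
#' decreased — the green/magenta channels of a mapping figure).
#'
#' @param zmap [voxel_zmap()] output.
#' @param effect_map Congruent per-voxel group difference, e.g.
#'   [voxel_effect()].
#' @param calibration A [calibrate_threshold()] result (or a single
#'   numeric threshold).
#' @return 3D array of class `"significance_map"` with attributes
#'   `z_threshold` and `target_fraction`.
#' @export
significance_map <- function(zmap, effect_map, calibration) {
  if (!identical(dim(zmap), dim(effect_map)))
    stop("zmap and effect_map are not congruent", call. = FALSE)
  thr <- if (inherits(calibration, "brain_calibration"))
    calibration$z_threshold else as.numeric(calibration)
  sig <- effect_map * (abs(zmap) >= thr)
  structure(sig, z_threshold = thr,
            target_fraction = if (inherits(calibration, "brain_calibration"))
              calibration$target_fraction else NA_real_,
            class = "significance_map")
}

#' @export
print.significance_map <- function(x, ...) {
  nz <- sum(x != 0)
  cat(sprintf(paste0("Significance map %s (z y x): %d voxels nonzero",
                     " (%.4g%%), %d increased / %d decreased, |Z| >= %.3f\n"),
              paste(dim(x), collapse = " x "), nz, 100 * nz / length(x),
              sum(x > 0), sum(x < 0), attr(x, "z_threshold")))
  invisible(x)
}

#' Quantify a significance map by atlas region
#'
#' Per region, the significant signal is summed and divided by the
#' region size (voxel count); increased (positive) and decreased
#' (negative, reported as its absolute sum) signal are summarized
#' separately.
#'
#' @param sigmap A [significance_map()] (or any congruent 3D array).
#' @param atlas A [make_atlas()] volume congruent with the map.
#' @return `data.frame`: `label`, `region`, `n_voxels`, `increased`,
#'   `decreased`.
#' @export
region_quantify <- function(sigmap, atlas) {
  if (!identical(dim(sigmap), dim(atlas)))
    stop("atlas is not congruent with the map", call. = FALSE)
  labels <- as.integer(atlas)
  rn <- attr(atlas, "region_names")
  n_regions <- length(rn)
  sizes <- tabulate(labels, nbins = n_regions)
  if (any(sizes == 0))
    stop("atlas contains empty region(s): ",
         paste(rn[sizes == 0], collapse = ", "), call. = FALSE)
  v <- as.vector(unclass(sigmap))
  pos <- rowsum(pmax(v, 0), labels)
  neg <- rowsum(-pmin(v, 0), labels)
  keep <- as.integer(rownames(pos)) > 0
  lab <- as.integer(rownames(pos))[keep]
  data.frame(label = lab, region = rn[lab], n_voxels = sizes[lab],
             increased = pos[keep] / sizes[lab],
             decreased = neg[keep] / sizes[lab],
             stringsAsFactors = FALSE)
}

#' Total significant signal of a map
#'
#' Sum of absolute significant signal over all voxels; increased and
#' decreased signal count as one comparison.
#'
#' @param sigmap A [significance_map()] or congruent array.
#' @return Scalar.
#' @export
total_signal <- function(sigmap) sum(abs(sigmap))

#' Sum-of-slices projection of a signed map
#'
#' Collapses the `(z, y, x)` volume along one axis by summation
#' (positive and negative signal sum independently and recombine
#' signed, which for a linear sum is the plain per-pixel sum).
#'
#' @param sigmap 3D array in `(z, y, x)` axis order.
#' @param axis `"z"` (returns a `y` by `x` image) or `"x"` (returns
#'   `z` by `y`).
#' @return 2D signed matrix.
#' @export
sum_of_slices <- function(sigmap, axis = c("z", "x")) {
  axis <- match.arg(axis)
  x <- unclass(sigmap)
  attributes(x) <- list(dim = dim(sigmap))
  if (axis == "z") colSums(x) else rowSums(x, dims = 2)
}

#' Display a significance-map projection
#'
#' Renders a [sum_of_slices()] projection with a diverging palette
#' (green = increased, magenta = decreased).
#'
#' @param x A `"significance_map"`.
#' @param axis Projection axis, `"z"` or `"x"`.
#' @param ... Passed to [graphics::image()].
#' @return The projection matrix, invisibly.
#' @export
plot.significance_map <- function(x, axis = "z", ...) {
  proj <- sum_of_slices(x, axis)
  lim <- max(abs(proj), 1e-12)
  pal <- grDevices::colorRampPalette(c("magenta", "black", "green"))(255)
  graphics::image(t(proj), col = pal, zlim = c(-lim, lim), axes = FALSE,
                  asp = nrow(proj) / ncol(proj), ...)
  invisible(proj)
}
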