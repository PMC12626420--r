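#' Build a synthetic labeled region atlas
#'
#' Stand-in for an anatomical atlas mask volume: `n_regions` compact,
#' non-overlapping labeled blobs placed in a background-0 volume.
#' Each region is the set of voxels within `radius` of a randomly
#' placed seed voxel, with overlaps resolved to the nearest seed
#' (lowest label on exact ties), so regions are compact and every
#' region contains at least its own seed.
#'
#' @param shape Integer vector of length 3: volume extent in `(z, y, x)`
#'   order.
#' @param n_regions Number of labeled regions (>= 1).
#' @param seed Integer seed for seed-voxel placement.
#' @param radius Region radius in voxels; default `max(2, min(shape) %/% 4)`.
#' @return Integer 3D array of class `"region_atlas"` with attribute
#'   `region_names` naming labels `1..n_regions` (`"region1"`, ...).
#' @export
#' @examples
#' atlas <- make_atlas(c(16, 16, 8), n_regions = 3, seed = 1)
#' table(atlas)
make_atlas <- function(shape, n_regions = 5, seed = 1L, radius = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3)
  if (n_regions < 1) stop("n_regions must be >= 1", call. = FALSE)
  if (any(shape < 2) || prod(shape) < 8 * n_regions)
    stop("shape too small for ", n_regions, " regions", call. = FALSE)
  if (is.null(radius)) radius <- max(2L, min(shape) %/% 4L)

  with_seed(seed, {
    centers <- cbind(z = sample.int(shape[1], n_regions, replace = TRUE),
                     y = sample.int(shape[2], n_regions, replace = TRUE),
                     x = sample.int(shape[3], n_regions, replace = TRUE))
    ## reject duplicate centers (regions must be non-empty and distinct)
    while (anyDuplicated(centers)) {
      dup <- which(duplicated(centers))
      centers[dup, ] <- cbind(sample.int(shape[1], length(dup), TRUE),
                              sample.int(shape[2], length(dup), TRUE),
                              sample.int(shape[3], length(dup), TRUE))
    }
    zz <- slice.index(array(0, shape), 1)
    yy <- slice.index(array(0, shape), 2)
    xx <- slice.index(array(0, shape), 3)
    best_d2 <- array(Inf, shape)
    labels <- array(0L, shape)
    for (k in seq_len(n_regions)) {
      d2 <- (zz - centers[k, 1])^2 + (yy - centers[k, 2])^2 +
        (xx - centers[k, 3])^2
      take <- d2 <= radius^2 & d2 < best_d2
      labels[take] <- k
      best_d2[take] <- d2[take]
    }
    structure(labels, class = "region_atlas",
              region_names = paste0("region", seq_len(n_regions)))
  })
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("Region atlas", paste(dim(x), collapse = " x "), "(z y x):",
      length(attr(x, "region_names")), "regions,",
      sum(x == 0), "background voxels\n")
  sizes <- tabulate(x, nbins = length(attr(x, "region_names")))
  cat(" ", paste(sprintf("%s: %d", attr(x, "region_names"), sizes),
                 collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a cohort of registered brain stacks
#'
#' Generates one 3D scalar stack per fish on the atlas geometry:
#' baseline intensity plus i.i.d. Gaussian noise.  For homozygous
#' mutants, the activity channel receives the additive
#' `effect_spec$region_delta` inside the target region
#' (`effect_spec$region_label`) only; the structure channel
#' (deformation determinant) is instead multiplied by
#' `effect_spec$region_scale` inside that region.
#'
#' @param config A [sim_config()]; `n_per_genotype`, `genotypes`,
#'   `noise_spec$stack_baseline`, `noise_spec$stack_sd`, and the region
#'   effect entries are used.
#' @param atlas A [make_atlas()] volume (or any `"region_atlas"`).
#' @param channel `"activity"` (pErk-like ratio) or `"structure"`
#'   (deformation-determinant-like).
#' @return List of class `"brain_cohort"`: `stacks` (named list of 3D
#'   arrays congruent with `atlas`), `genotypes` data.frame, `channel`,
#'   `atlas`.
#' @export
simulate_brain_cohort <- function(config, atlas, channel = c("activity", "structure")) {
  stopifnot(inherits(config, "sim_config"), inherits(atlas, "region_atlas"))
  channel <- match.arg(channel)
  eff <- config$effect_spec
  ns <- config$noise_spec
  has_effect <- (channel == "activity" && eff$region_delta != 0) ||
    (channel == "structure" && eff$region_scale != 1)
  region_voxels <- NULL
  if (has_effect) {
    rn <- attr(atlas, "region_names")
    if (is.na(eff$region_label) || !(eff$region_label %in% rn))
      stop("effect region label '", eff$region_label,
           "' absent from atlas", call. = FALSE)
    region_voxels <- which(as.integer(atlas) == match(eff$region_label, rn))
  }

  with_seed(config$seed + 1L, {
    stacks <- list()
    gmap <- list()
    shp <- dim(atlas)
    for (g in config$genotypes) {
      mutant <- identical(g, "-/-")
      for (i in seq_len(config$n_per_genotype)) {
        id <- sprintf("fish_%s_r%s_%02d",
                      c("+/+" = "wt", "+/-" = "het", "-/-" = "hom")[[g]],
                      config$replicate, i)
        v <- array(stats::rnorm(prod(shp), mean = ns$stack_baseline,
                                sd = ns$stack_sd), shp)
        if (mutant && has_effect) {
          if (channel == "activity")
            v[region_voxels] <- v[region_voxels] + eff$region_delta
          else
            v[region_voxels] <- v[region_voxels] * eff$region_scale
        }
        stacks[[id]] <- v
        gmap[[id]] <- g
      }
    }
    genotypes <- data.frame(larva_id = names(gmap),
                            genotype = unlist(gmap, use.names = FALSE),
                            replicate = config$replicate,
                            stringsAsFactors = FALSE)
    structure(list(stacks = stacks, genotypes = genotypes,
                   channel = channel, atlas = atlas),
              class = "brain_cohort")
  })
}

#' @export
print.brain_cohort <- function(x, ...) {
  cat("Brain cohort (", x$channel, "): ", length(x$stacks), " stacks of ",
      paste(dim(x$stacks[[1]]), collapse = " x "), " (z y x)\n", sep = "")
  print(table(x$genotypes$genotype))
  invisible(x)
}
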