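#' Run the screening pipeline end to end
#'
#' Orchestrates the stages on a single configuration: simulate a
#' behavioral cohort, extract the measure matrix, compare genotype
#' groups and summarize categories, and/or simulate + map a brain
#' cohort with calibrated thresholds and region quantification.  All
#' artifacts are written to `out_dir` as TSV/JSON/YAML/NRRD, together
#' with the resolved configuration and a provenance record, so a rerun
#' with the same resolved configuration reproduces every output
#' byte-identically (timestamps live only in the log).
#'
#' @param config A named list, or path to a YAML file, with (all
#'   optional except `out_dir`):
#'   `out_dir`; `seed` (default 1); `stages` (subset of
#'   `c("behavior", "stats", "brain")`, default all);
#'   `behavior` (arguments for [sim_config()]); `brain` (list with
#'   `shape`, `n_regions`, `target_fraction`, `n_splits`, `channel`,
#'   plus [sim_config()] arguments); `alpha`; `group_pair`.
#'   Unknown keys are rejected.
#' @return The output directory, invisibly, with the written file
#'   names as an attribute.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("out_dir", "seed", "stages", "behavior", "brain", "alpha",
             "group_pair")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("config error: unknown config keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(config$out_dir))
    stop("config error: out_dir is required", call. = FALSE)
  defaults <- list(seed = 1L, stages = c("behavior", "stats", "brain"),
                   alpha = 0.05, group_pair = c("-/-", "+/+"),
                   behavior = list(), brain = list())
  cfg <- utils::modifyList(defaults, config)
  bad_stage <- setdiff(cfg$stages, c("behavior", "stats", "brain"))
  if (length(bad_stage))
    stop("config error: unknown stage(s): ",
         paste(bad_stage, collapse = ", "), call. = FALSE)
  if ("stats" %in% cfg$stages && !("behavior" %in% cfg$stages))
    stop("config error: 'stats' requires the 'behavior' stage",
         call. = FALSE)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  logf <- file.path(cfg$out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                ..., "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  emit <- function(path) { files <<- c(files, path); path }

  resolved <- file.path(cfg$out_dir, "resolved_config.yaml")
  yaml::write_yaml(cfg, resolved)
  emit(resolved)
  log_line("pipeline start; stages: ", paste(cfg$stages, collapse = ", "),
           "; seed ", cfg$seed)

  mm <- NULL
  if ("behavior" %in% cfg$stages) {
    bcfg_args <- utils::modifyList(list(seed = cfg$seed), cfg$behavior)
    bcfg <- do.call(sim_config, bcfg_args)
    schedule <- default_schedule(bcfg$duration_s)
    coh <- simulate_behavior_cohort(bcfg, schedule)
    write_traces(coh, emit(file.path(cfg$out_dir, "traces.tsv")),
                 emit(file.path(cfg$out_dir, "bursts.tsv")))
    write_genotypes(coh$genotypes,
                    emit(file.path(cfg$out_dir, "genotypes.tsv")))
    write_schedule(schedule, emit(file.path(cfg$out_dir, "schedule.yaml")))
    mm <- build_measure_matrix(coh)
    write_measure_matrix(mm, emit(file.path(cfg$out_dir, "measures.tsv")),
                         emit(file.path(cfg$out_dir, "measures.meta.json")))
    log_line("behavior: ", nrow(mm), " larvae x ", ncol(mm), " measures")

    if ("stats" %in% cfg$stages) {
      res <- compare_all_measures(mm, coh$genotypes,
                                  group_pair = cfg$group_pair,
                                  alpha = cfg$alpha)
      utils::write.table(res, emit(file.path(cfg$out_dir,
                                             "comparisons.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      bub <- summarize_categories(res)
      utils::write.table(as.data.frame(bub),
                         emit(file.path(cfg$out_dir, "bubble_summary.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_line("stats: ", sum(res$significant), " of ", nrow(res),
               " measures significant at alpha ", cfg$alpha)
    }
  }

  if ("brain" %in% cfg$stages) {
    br_defaults <- list(shape = c(32, 32, 8), n_regions = 5,
                        target_fraction = 5e-4, n_splits = 20,
                        channel = "activity")
    br <- utils::modifyList(br_defaults, cfg$brain)
    sim_args <- br[setdiff(names(br), names(br_defaults))]
    bcfg <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                                  sim_args))
    atlas <- make_atlas(br$shape, n_regions = br$n_regions,
                        seed = cfg$seed)
    write_nrrd(atlas, emit(file.path(cfg$out_dir, "atlas.nrrd")))
    bc <- simulate_brain_cohort(bcfg, atlas, channel = br$channel)
    geno <- bc$genotypes$genotype
    controls <- bc$stacks[geno == "+/+"]
    cal <- calibrate_threshold(controls,
                               target_fraction = br$target_fraction,
                               n_splits = br$n_splits,
                               seed = cfg$seed)
    write_calibration(cal, emit(file.path(cfg$out_dir, "calibration.json")))
    ga <- bc$stacks[geno == cfg$group_pair[1]]
    gb <- bc$stacks[geno == cfg$group_pair[2]]
    zm <- voxel_zmap(ga, gb)
    sig <- significance_map(zm, voxel_effect(ga, gb), cal)
    write_nrrd(unclass(sig), emit(file.path(cfg$out_dir,
                                            "significance_map.nrrd")))
    reg <- region_quantify(sig, atlas)
    utils::write.table(reg, emit(file.path(cfg$out_dir,
                                           "region_summary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tot <- data.frame(total_signal = total_signal(sig),
                      n_voxels_significant = sum(sig != 0))
    utils::write.table(tot, emit(file.path(cfg$out_dir,
                                           "total_signal.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("brain: |Z| threshold ", signif(cal$z_threshold, 5), "; ",
             sum(sig != 0), " significant voxels")
  }

  ## config hash excludes out_dir so identical analyses written to
  ## different directories carry the same provenance
  hash_tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[setdiff(names(cfg), "out_dir")], hash_tmp)
  prov <- list(package = "mexscreen",
               version = as.character(utils::packageVersion("mexscreen")),
               seed = cfg$seed,
               config_md5 = unname(tools::md5sum(hash_tmp)))
  unlink(hash_tmp)
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  files <- c(files, file.path(cfg$out_dir, "provenance.json"))
  log_line("pipeline done; ", length(files), " artifacts")
  invisible(structure(cfg$out_dir, files = basename(files)))
}

#' Clustered mutant-by-region heatmap tables
#'
#' Assembles per-mutant region summaries into mutant x region matrices
#' (increased and decreased channels separately) and orders rows and
#' columns by average-linkage clustering of the combined absolute
#' signal, the layout of a screen summary heatmap.
#'
#' @param summaries Named list (one element per mutant comparison) of
#'   [region_quantify()] tables over a common region set.
#' @param out_dir Optional directory; when given, the two matrices are
#'   written as `heatmap_increased.tsv` / `heatmap_decreased.tsv`.
#' @return List: `increased`, `decreased` (matrices in clustered
#'   order), `row_order`, `col_order`.
#' @export
export_heatmap_tables <- function(summaries, out_dir = NULL) {
  if (length(summaries) < 2)
    stop("need at least 2 comparisons", call. = FALSE)
  regions <- summaries[[1]]$region
  for (s in summaries)
    if (!identical(s$region, regions))
      stop("inconsistent region sets across summaries", call. = FALSE)
  inc <- do.call(rbind, lapply(summaries, function(s) s$increased))
  dec <- do.call(rbind, lapply(summaries, function(s) s$decreased))
  rownames(inc) <- rownames(dec) <- names(summaries)
  colnames(inc) <- colnames(dec) <- regions
  comb <- inc + dec
  row_order <- if (nrow(comb) > 2)
    stats::hclust(stats::dist(comb), method = "average")$order
  else seq_len(nrow(comb))
  col_order <- if (ncol(comb) > 2)
    stats::hclust(stats::dist(t(comb)), method = "average")$order
  else seq_len(ncol(comb))
  inc <- inc[row_order, col_order, drop = FALSE]
  dec <- dec[row_order, col_order, drop = FALSE]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("increased", "decreased")) {
      m <- if (nm == "increased") inc else dec
      utils::write.table(data.frame(mutant = rownames(m), m,
                                    check.names = FALSE),
                         file.path(out_dir, paste0("heatmap_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(increased = inc, decreased = dec,
       row_order = row_order, col_order = col_order)
}
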