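#' Strictly standardized mean difference
#'
#' `ssmd(a, b) = (mean(a) - mean(b)) / sqrt(var(a) + var(b))` with
#' sample variances; positive when group `a` exceeds group `b`.  The
#' variance-penalized effect size used to color screen summaries.
#'
#' @param values_a,values_b Numeric samples, each of length >= 2
#'   (missing values dropped).
#' @return Signed effect size; `NA` with a warning when both variances
#'   are zero.
#' @export
#' @examples
#' ssmd(c(3, 4, 5), c(1, 2, 3))
ssmd <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample must have at least 2 values", call. = FALSE)
  v <- stats::var(a) + stats::var(b)
  if (v == 0) {
    warning("both groups have zero variance; SSMD undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(v)
}

## tie-corrected Kruskal-Wallis H statistic
kw_statistic <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  sums <- tapply(r, groups, sum)
  sizes <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(sums^2 / sizes) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h / corr else 0
}

## exact permutation p-value of H for a two-group comparison: H only
## depends on the group-a rank sum, so enumerate all assignments of
## group-a positions over precomputed midranks
kw_exact_p <- function(values, groups) {
  g <- unique(groups)
  stopifnot(length(g) == 2)
  n <- length(values)
  na <- sum(groups == g[1])
  nb <- n - na
  r <- rank(values)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h_of <- function(Wa) {
    h <- 12 / (n * (n + 1)) * (Wa^2 / na + (sum(r) - Wa)^2 / nb) -
      3 * (n + 1)
    if (corr > 0) h / corr else 0 * h
  }
  h_obs <- h_of(sum(r[groups == g[1]]))
  combos <- utils::combn(n, na)
  was <- colSums(matrix(r[combos], nrow = na))
  mean(h_of(was) >= h_obs - 1e-12)
}

#' Compare genotype groups for one measure
#'
#' Two-group Kruskal-Wallis test (tie-corrected H) between the
#' genotypes in `group_pair`, with the SSMD effect size attached.
#' The p-value is computed by exhaustive permutation of group labels
#' when the pooled sample is small (`n <= exact_max_n`), otherwise by
#' the chi-square approximation.  Missing measure values are dropped;
#' a group left with fewer than 2 values marks the result untestable
#' (never significant).
#'
#' @param mm A [build_measure_matrix()] matrix (or any numeric matrix
#'   with larva rownames).
#' @param genotypes Genotype map data.frame (`larva_id`, `genotype`).
#' @param measure Column name to test.
#' @param group_pair Length-2 genotype labels, effect direction is
#'   `group_pair[1] - group_pair[2]` (mutant vs wild-type sibling by
#'   default).
#' @param alpha Per-measure significance level (no multiple-testing
#'   correction; replication across biological replicates is the
#'   screen's guard against false positives).
#' @param exact_max_n Pooled-n cutoff for the exact permutation
#'   p-value.
#' @return One-row `data.frame`: `measure`, `group_a`, `group_b`,
#'   `n_a`, `n_b`, `statistic`, `p_value`, `ssmd`, `significant`,
#'   `testable`, `method`.
#' @export
compare_measure <- function(mm, genotypes, measure,
                            group_pair = c("-/-", "+/+"),
                            alpha = 0.05, exact_max_n = 10) {
  stopifnot(length(group_pair) == 2, measure %in% colnames(mm))
  geno <- genotypes$genotype[match(rownames(mm), genotypes$larva_id)]
  vals <- mm[, measure]
  out <- data.frame(measure = measure, group_a = group_pair[1],
                    group_b = group_pair[2], n_a = NA_integer_,
                    n_b = NA_integer_, statistic = NA_real_,
                    p_value = NA_real_, ssmd = NA_real_,
                    significant = FALSE, testable = FALSE,
                    method = NA_character_, stringsAsFactors = FALSE)
  a <- vals[geno %in% group_pair[1] & !is.na(vals)]
  b <- vals[geno %in% group_pair[2] & !is.na(vals)]
  out$n_a <- length(a)
  out$n_b <- length(b)
  if (length(a) < 2 || length(b) < 2) return(out)
  values <- c(a, b)
  groups <- rep(group_pair, c(length(a), length(b)))
  out$statistic <- kw_statistic(values, groups)
  if (stats::var(values) == 0) {       # degenerate all-tied case
    out$p_value <- 1
    out$method <- "degenerate"
  } else if (length(values) <= exact_max_n) {
    out$p_value <- kw_exact_p(values, groups)
    out$method <- "exact permutation"
  } else {
    out$p_value <- stats::pchisq(out$statistic, df = 1, lower.tail = FALSE)
    out$method <- "chi-square"
  }
  out$ssmd <- tryCatch(suppressWarnings(ssmd(a, b)), error = function(e) NA_real_)
  out$testable <- TRUE
  out$significant <- is.finite(out$p_value) && out$p_value < alpha
  out
}

#' Compare all measures of a matrix between two genotype groups
#'
#' @inheritParams compare_measure
#' @param measures Columns to test (default: all).
#' @return `data.frame`, one [compare_measure()] row per measure, with
#'   the matrix's per-column `category` metadata joined when present.
#' @export
compare_all_measures <- function(mm, genotypes,
                                 group_pair = c("-/-", "+/+"),
                                 alpha = 0.05, exact_max_n = 10,
                                 measures = colnames(mm)) {
  res <- do.call(rbind, lapply(measures, function(m)
    compare_measure(mm, genotypes, m, group_pair, alpha, exact_max_n)))
  meta <- attr(mm, "measure_meta")
  if (!is.null(meta))
    res$category <- meta$category[match(res$measure, meta$name)]
  res
}

#' Category-level bubble summary of comparison results
#'
#' Merges related measures into summarized categories and reports, per
#' category and effect direction, the percent of significant measures
#' and the mean SSMD of the significant measures — the quantities a
#' screen bubble plot encodes as bubble size and color.  Significant
#' measures are split by SSMD sign (`increased` / `decreased`); both
#' directions can be present in one category (two offset bubbles).
#' The denominator of `percent_significant` is the category's full
#' measure count.  Categories with no significant measures emit no
#' rows.
#'
#' @param results A [compare_all_measures()] table.
#' @param category_map Optional named character vector
#'   (measure -> category) overriding the `category` column.
#' @return `data.frame` of class `"bubble_summary"`: `category`,
#'   `direction`, `percent_significant`, `mean_ssmd`, `n_measures`,
#'   `n_significant`.
#' @export
summarize_categories <- function(results, category_map = NULL) {
  if (!is.null(category_map)) {
    results$category <- unname(category_map[results$measure])
  }
  if (is.null(results$category))
    stop("results carry no category column; supply category_map",
         call. = FALSE)
  if (anyNA(results$category))
    stop("measures without a category mapping: ",
         paste(results$measure[is.na(results$category)], collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (cat_ in unique(results$category)) {
    sub <- results[results$category == cat_, , drop = FALSE]
    n_measures <- nrow(sub)
    sig <- sub[sub$significant & !is.na(sub$ssmd), , drop = FALSE]
    for (dir in c("increased", "decreased")) {
      s <- if (dir == "increased") sig[sig$ssmd > 0, , drop = FALSE]
           else sig[sig$ssmd < 0, , drop = FALSE]
      if (!nrow(s)) next
      rows[[length(rows) + 1L]] <-
        data.frame(category = cat_, direction = dir,
                   percent_significant = 100 * nrow(s) / n_measures,
                   mean_ssmd = mean(s$ssmd),
                   n_measures = n_measures, n_significant = nrow(s),
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(category = character(0), direction = character(0),
                         percent_significant = numeric(0),
                         mean_ssmd = numeric(0), n_measures = integer(0),
                         n_significant = integer(0))
  class(out) <- c("bubble_summary", "data.frame")
  out
}

#' Per-measure mean +/- SEM traces by genotype
#'
#' Exports the data behind group trace plots: per measure and genotype,
#' the group mean and standard error.
#'
#' @inheritParams compare_all_measures
#' @return Long `data.frame`: `measure`, `genotype`, `n`, `mean`,
#'   `sem`.
#' @export
group_measure_table <- function(mm, genotypes) {
  geno <- genotypes$genotype[match(rownames(mm), genotypes$larva_id)]
  do.call(rbind, lapply(colnames(mm), function(m) {
    do.call(rbind, lapply(unique(geno), function(g) {
      v <- mm[geno == g, m]
      v <- v[!is.na(v)]
      data.frame(measure = m, genotype = g, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1)
                   stats::sd(v) / sqrt(length(v)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
}
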