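#' Simulate a set of microexon records with known properties
#'
#' Builds fixture microexon records for the sequence utilities: peptide
#' / ortholog-peptide pairs whose realized identity matches the
#' requested targets, upstream intron sequences constructed to satisfy
#' (or fail) the splice-regulatory layout classifier, and exon lengths
#' both inside and outside the 3-30 nt microexon definition so the
#' length filter is exercised.
#'
#' Upstream introns are 150 nt of DNA whose distal 50 nt are
#' unconstrained random sequence; the proximal 100 nt (the classifier
#' scan window) are purine-biased background into which the requested
#' features are planted: `canonical` gets both a TGC (UGC on the
#' transcript) triplet repeat in the proximal 30 nt and a >= 12 nt
#' pyrimidine tract; `partial` gets exactly one of the two; and
#' `noncanonical` gets neither (purines only).
#'
#' @param n Number of records.
#' @param identity_targets Target peptide identities in `[0, 1]`,
#'   recycled over records.
#' @param layout_mix Named proportions over
#'   `c("canonical", "partial", "noncanonical")`.
#' @param frac_outside Fraction of records drawn with exon length
#'   outside the 3-30 nt range (default 0.2).
#' @param seed Integer seed.
#' @return `data.frame` of class `"microexon_set"` with columns `gene`,
#'   `nt_seq`, `peptide`, `ortholog_peptide`, `upstream_intron`,
#'   `layout_class`, `identity_target`, `frame_preserving`,
#'   `nt_length`, `aa_length`.
#' @export
#' @examples
#' mx <- simulate_microexon_set(6, identity_targets = c(1, 0.8), seed = 2)
#' mx$layout_class
simulate_microexon_set <- function(n,
                                   identity_targets = 0.9,
                                   layout_mix = c(canonical = 1/3,
                                                  partial = 1/3,
                                                  noncanonical = 1/3),
                                   frac_outside = 0.2,
                                   seed = 1L) {
  stopifnot(n >= 1)
  if (any(identity_targets < 0 | identity_targets > 1))
    stop("identity targets must be in [0, 1]", call. = FALSE)
  classes <- c("canonical", "partial", "noncanonical")
  if (!all(names(layout_mix) %in% classes))
    stop("layout_mix names must be canonical/partial/noncanonical",
         call. = FALSE)
  mix <- layout_mix[classes]
  mix[is.na(mix)] <- 0
  mix <- mix / sum(mix)
  targets <- rep_len(identity_targets, n)

  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    layout <- sample(classes, n, replace = TRUE, prob = mix)
    outside <- stats::runif(n) < frac_outside
    recs <- lapply(seq_len(n), function(i) {
      aa_len <- if (outside[i]) sample(11:14, 1) else sample(1:10, 1)
      ## a few non-frame-preserving exons (nt length not divisible by 3)
      frame <- stats::runif(1) > 0.15
      nt_len <- 3L * aa_len + if (frame) 0L else sample(1:2, 1)
      pep <- paste(sample(aa, aa_len, replace = TRUE), collapse = "")
      k <- round((1 - targets[i]) * aa_len)
      orth <- mutate_peptide(pep, k, aa)
      data.frame(gene = sprintf("gene%03d", i),
                 nt_seq = rand_dna(nt_len),
                 peptide = pep,
                 ortholog_peptide = orth,
                 upstream_intron = build_upstream(layout[i]),
                 layout_class = layout[i],
                 identity_target = targets[i],
                 frame_preserving = frame,
                 nt_length = nt_len,
                 aa_length = aa_len,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    class(out) <- c("microexon_set", "data.frame")
    out
  })
}

mutate_peptide <- function(pep, k, alphabet) {
  s <- strsplit(pep, "")[[1]]
  if (k > 0) {
    pos <- sample(seq_along(s), min(k, length(s)))
    for (p in pos) s[p] <- sample(setdiff(alphabet, s[p]), 1)
  }
  paste(s, collapse = "")
}

rand_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## proximal 100 nt engineered per layout class; sequence is given
## 5'->3' ending at the exon boundary
build_upstream <- function(layout) {
  purine <- function(len) rand_dna(len, c("A", "G"))
  tract <- paste(rep(c("T", "C"), 7), collapse = "")   # 14 nt, all pyrimidine
  ugc <- "TGCTGCTGC"
  proximal <- switch(layout,
    canonical = paste0(purine(100 - 14 - 9 - 10), tract, purine(4),
                       ugc, purine(6)),
    partial = if (stats::runif(1) < 0.5)
        paste0(purine(100 - 9 - 10), ugc, purine(10))   # UGC only
      else
        paste0(purine(100 - 14 - 20), tract, purine(20)),  # tract only
    noncanonical = purine(100))
  paste0(rand_dna(50), proximal)
}
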