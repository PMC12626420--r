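#' Microexon length filter
#'
#' A microexon is an exon of 3-30 nucleotides (equivalently 1-10 amino
#' acids for frame-preserving exons).
#'
#' @param nt_seq Exon nucleotide sequence(s), or a `"microexon_set"`
#'   data.frame (its `nt_seq` column is used).
#' @return Logical vector: `TRUE` iff the nucleotide length is in
#'   `[3, 30]`.  Empty sequences are an error.
#' @export
#' @examples
#' microexon_length_filter(c("ATG", strrep("A", 30), strrep("A", 31)))
microexon_length_filter <- function(nt_seq) {
  if (is.data.frame(nt_seq)) nt_seq <- nt_seq$nt_seq
  if (!length(nt_seq) || any(!nzchar(nt_seq)) || anyNA(nt_seq))
    stop("empty nucleotide sequence", call. = FALSE)
  n <- nchar(nt_seq)
  n >= 3 & n <= 30
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Percent identity of two peptides under global alignment
#'
#' Needleman-Wunsch global alignment with identity scoring (match 1,
#' mismatch 0, linear gap penalty -1); identity is the number of
#' matched columns divided by the total alignment length, in percent.
#' Symmetric in its arguments.
#'
#' @param pep_a,pep_b Peptide strings over the 20 standard residues.
#' @param match,mismatch,gap Scoring parameters (linear gap model).
#' @return Identity percentage in `[0, 100]`.
#' @export
#' @examples
#' percent_identity("PKTLV", "PKALV")   # 80
percent_identity <- function(pep_a, pep_b, match = 1, mismatch = 0,
                             gap = -1) {
  for (p in c(pep_a, pep_b)) {
    if (!nzchar(p)) stop("empty peptide", call. = FALSE)
    bad <- setdiff(strsplit(toupper(p), "")[[1]], AA_ALPHABET20)
    if (length(bad))
      stop("invalid residue character(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  sub_mat <- matrix(mismatch, 20, 20,
                    dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  diag(sub_mat) <- match
  al <- Biostrings::pairwiseAlignment(toupper(pep_a), toupper(pep_b),
                                      substitutionMatrix = sub_mat,
                                      gapOpening = 0, gapExtension = -gap,
                                      type = "global")
  cols <- nchar(as.character(Biostrings::alignedPattern(al)))
  100 * Biostrings::nmatch(al) / cols
}

#' Relative conservation of a microexon within its protein
#'
#' Microexon identity divided by the identity of the entire protein;
#' values above 1 mean the microexon is more conserved than its host
#' protein.
#'
#' @param microexon_identity,full_protein_identity Percent identities
#'   (same units); the denominator must be positive.
#' @return Ratio; `NA` with a warning on a zero denominator.
#' @export
identity_ratio <- function(microexon_identity, full_protein_identity) {
  out <- microexon_identity / full_protein_identity
  zero <- !is.na(full_protein_identity) & full_protein_identity == 0
  if (any(zero)) {
    warning("zero full-protein identity; ratio undefined")
    out[zero] <- NA_real_
  }
  out
}

#' Classify the upstream splice-regulatory layout of a microexon
#'
#' Canonically regulated microexons sit downstream of both a UGC
#' repeat and a UC repeat / polypyrimidine tract.  The classifier
#' scans a window upstream of the exon boundary for two features:
#'
#' * UGC feature — at least `min_ugc` occurrences of `UGC` within the
#'   proximal `proximal_nt` of the window;
#' * tract feature — any run of `tract_min_len` nt within the window
#'   with pyrimidine (C/U) fraction at least `tract_min_frac`.
#'
#' Both features present is `canonical`, exactly one `partial`,
#' neither `noncanonical`.  DNA input is accepted and transcribed
#' (T to U) before scanning.
#'
#' @param intron_seq Upstream intron sequence(s), 5' to 3', ending at
#'   the exon boundary.
#' @param window_nt Scan window length (nt) measured back from the
#'   exon boundary; shrunk with a warning when the sequence is
#'   shorter.
#' @param proximal_nt Proximal sub-window for the UGC feature.
#' @param min_ugc Minimum UGC occurrences in the proximal window.
#' @param tract_min_len,tract_min_frac Pyrimidine-tract rule.
#' @return Character vector over
#'   `{"canonical", "partial", "noncanonical"}`.
#' @export
#' @examples
#' classify_upstream_layout("AAGAAGTGCTGCTGCTCTCTCTCTCTC")
classify_upstream_layout <- function(intron_seq, window_nt = 100,
                                     proximal_nt = 30, min_ugc = 2,
                                     tract_min_len = 10,
                                     tract_min_frac = 0.75) {
  vapply(intron_seq, function(s) {
    s <- gsub("T", "U", toupper(s), fixed = TRUE)
    n <- nchar(s)
    if (n < window_nt) {
      warning("scan window longer than sequence; shrinking to ", n, " nt")
      window_nt <- n
    }
    win <- substr(s, n - window_nt + 1, n)
    prox <- substr(win, max(1, nchar(win) - proximal_nt + 1), nchar(win))
    ## overlap-tolerant UGC count
    hits <- gregexpr("(?=UGC)", prox, perl = TRUE)[[1]]
    ugc_n <- if (hits[1] == -1) 0L else length(hits)
    has_ugc <- ugc_n >= min_ugc
    has_tract <- has_pyrimidine_tract(win, tract_min_len, tract_min_frac)
    if (has_ugc && has_tract) "canonical"
    else if (has_ugc || has_tract) "partial"
    else "noncanonical"
  }, character(1), USE.NAMES = FALSE)
}

## sliding-window pyrimidine content via cumulative sums
has_pyrimidine_tract <- function(seq_rna, min_len, min_frac) {
  v <- strsplit(seq_rna, "")[[1]] %in% c("C", "U")
  n <- length(v)
  if (n < min_len) return(FALSE)
  cs <- cumsum(v)
  counts <- cs[min_len:n] - c(0, cs)[1:(n - min_len + 1)]
  any(counts / min_len >= min_frac)
}

#' Exon inclusion fraction from RT-PCR band intensities
#'
#' `included / (included + skipped)`, the gel-based percent-spliced-in
#' estimate.
#'
#' @param included_intensity,skipped_intensity Nonnegative band
#'   intensities (vectorized).
#' @return Inclusion fraction in `[0, 1]`; `NA` with a warning where
#'   both bands are zero.
#' @export
rtpcr_inclusion <- function(included_intensity, skipped_intensity) {
  if (any(included_intensity < 0, na.rm = TRUE) ||
      any(skipped_intensity < 0, na.rm = TRUE))
    stop("negative band intensity", call. = FALSE)
  tot <- included_intensity + skipped_intensity
  out <- included_intensity / tot
  if (any(tot == 0, na.rm = TRUE)) {
    warning("included and skipped intensity both zero; inclusion undefined")
    out[tot == 0] <- NA_real_
  }
  out
}

#' Cluster developmental inclusion profiles
#'
#' Agglomerative hierarchical clustering of microexon inclusion
#' profiles (average linkage on Euclidean distances — the defaults of
#' the common clustered-heatmap tools), giving a deterministic row
#' ordering and a dendrogram.
#'
#' @param profiles Numeric matrix, rows = microexons, columns =
#'   developmental stages; no missing values.
#' @return List of class `"inclusion_clustering"`: `hclust` (the
#'   [stats::hclust()] tree), `order` (row ordering), `heights`
#'   (merge heights), `newick` (dendrogram serialized as a Newick
#'   string).
#' @export
cluster_inclusion_profiles <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2)
    stop("need at least 2 profiles", call. = FALSE)
  if (anyNA(profiles))
    stop("profiles contain missing values; impute before clustering",
         call. = FALSE)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("mx", seq_len(nrow(profiles)))
  hc <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                      method = "average")
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, order = hc$order, heights = hc$height,
                 labels = rownames(profiles),
                 newick = ape::write.tree(phy)),
            class = "inclusion_clustering")
}

#' @export
print.inclusion_clustering <- function(x, ...) {
  cat("Average-linkage clustering of", length(x$labels),
      "inclusion profiles; merge heights:",
      paste(signif(x$heights, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `2^-(dCt - mean(control dCt))` where `dCt = Ct_target -
#' Ct_reference`; the control group's mean relative expression is 1 by
#' construction.
#'
#' @param ct_target,ct_reference Sample Ct values for the target and
#'   reference (housekeeping) gene; finite, equal length.
#' @param control_dct Delta-Ct values (`Ct_target - Ct_reference`) of
#'   the control group; nonempty.
#' @return Relative expression values.
#' @export
#' @examples
#' ddct(c(20, 21), c(15, 15), control_dct = c(5, 5))  # 1, 0.5
ddct <- function(ct_target, ct_reference, control_dct) {
  if (!length(control_dct))
    stop("empty control group", call. = FALSE)
  if (any(!is.finite(c(ct_target, ct_reference, control_dct))))
    stop("Ct values must be finite", call. = FALSE)
  dct <- ct_target - ct_reference
  2^-(dct - mean(control_dct))
}
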