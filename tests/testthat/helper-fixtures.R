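## shared fixture builders (code-generated; no data files)

## a hand-buildable trace: 1 Hz, dpix/x/y supplied
toy_trace <- function(dpix, x = NULL, y = NULL, t = seq_along(dpix) - 1) {
  structure(list(larva_id = "toy", t = t, dpix = dpix,
                 x = if (is.null(x)) rep(0, length(dpix)) else x,
                 y = if (is.null(y)) rep(0, length(dpix)) else y,
                 bursts = list(), burst_rate_hz = 285, burst_window_s = 1),
            class = "dpix_trace")
}

## trace with explicit bursts attached
toy_burst_trace <- function(bursts) {
  structure(list(larva_id = "toy", t = 0:9, dpix = rep(0, 10),
                 x = rep(0, 10), y = rep(0, 10), bursts = bursts,
                 burst_rate_hz = 285, burst_window_s = 1),
            class = "dpix_trace")
}

## independent brute-force bout oracle: run-length enumeration by
## walking the samples one by one
oracle_bouts <- function(t, dpix, threshold = 0, merge_gap_s = 0.2,
                         min_duration_s = 0) {
  dt <- if (length(t) > 1) median(diff(t)) else 1
  runs <- list()
  cur <- NULL
  for (i in seq_along(dpix)) {
    if (dpix[i] > threshold) {
      if (is.null(cur)) cur <- c(i, i) else cur[2] <- i
    } else if (!is.null(cur)) {
      runs[[length(runs) + 1]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  ## merge pass
  merged <- list()
  for (r in runs) {
    if (length(merged) &&
        (t[r[1]] - (t[merged[[length(merged)]][2]] + dt)) < merge_gap_s)
      merged[[length(merged)]][2] <- r[2]
    else merged[[length(merged) + 1]] <- r
  }
  keep <- Filter(function(r) (t[r[2]] + dt - t[r[1]]) >= min_duration_s,
                 merged)
  data.frame(start = vapply(keep, function(r) t[r[1]], 0),
             cum = vapply(keep, function(r) sum(dpix[r[1]:r[2]]), 0),
             peak = vapply(keep, function(r) max(dpix[r[1]:r[2]]), 0))
}

## independent per-voxel rank-sum Z oracle (textbook formula on rank())
oracle_ranksum_z <- function(a_vals, b_vals) {
  x <- c(a_vals, b_vals)
  na <- length(a_vals); nb <- length(b_vals); n <- na + nb
  r <- rank(x)
  W <- sum(r[seq_len(na)])
  ties <- table(x)
  v <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) return(0)
  (W - na * (n + 1) / 2) / sqrt(v)
}

## independent average-linkage agglomeration oracle (naive O(n^3))
oracle_average_linkage_heights <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

## brute-force global alignment: enumerate all gapped alignments and
## return the maximum score (match 1, mismatch 0, gap -1)
oracle_align_score <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b))
      best <- max(best, (a[i] == b[j]) * 1 + rec(i + 1, j + 1))
    if (i <= length(a)) best <- max(best, -1 + rec(i + 1, j))
    if (j <= length(b)) best <- max(best, -1 + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

small_null_stacks <- function(n, shape = c(4, 4, 4), seed = 1) {
  set.seed(seed)
  replicate(n, array(rnorm(prod(shape)), shape), simplify = FALSE)
}
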