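# Independent oracles used by the property and acceptance tests.
#
# oracle_scan_exhaustive enumerates EVERY valid (t1,l1,t2,l2,t3,l3,t4)
# tiling at every start position by brute force (no shared code with the
# scanner), orders parses lexicographically on
# (start, t1, t2, t3, t4, l1, l2, l3), takes the first, and restarts after
# its end (non-overlap). oracle_cgcc recomputes the cG/cC sums by
# per-residue summation instead of per-run aggregation.

oracle_all_parses <- function(ch, p, tmin, lb) {
  n <- length(ch)
  out <- list()
  is_g_run <- function(a, len) {
    if (a + len - 1L > n) return(FALSE)
    all(ch[a:(a + len - 1L)] == "G")
  }
  t1 <- tmin
  while (is_g_run(p, t1)) {
    for (l1 in lb[1, 1]:lb[1, 2]) {
      q1 <- p + t1 + l1
      t2 <- tmin
      while (is_g_run(q1, t2)) {
        for (l2 in lb[2, 1]:lb[2, 2]) {
          q2 <- q1 + t2 + l2
          t3 <- tmin
          while (is_g_run(q2, t3)) {
            for (l3 in lb[3, 1]:lb[3, 2]) {
              q3 <- q2 + t3 + l3
              t4 <- tmin
              while (is_g_run(q3, t4)) {
                out[[length(out) + 1L]] <- c(t1, l1, t2, l2, t3, l3, t4)
                t4 <- t4 + 1L
              }
            }
            t3 <- t3 + 1L
          }
        }
        t2 <- t2 + 1L
      }
    }
    t1 <- t1 + 1L
  }
  out
}

oracle_scan_exhaustive <- function(seq, pattern) {
  pattern <- quadloop::g4_pattern_builtin(pattern)
  tmin <- pattern$min_track_len
  lb <- pattern$loop_bounds
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  hits <- list()
  p <- 1L
  while (p <= n) {
    parses <- oracle_all_parses(ch, p, tmin, lb)
    if (!length(parses)) {
      p <- p + 1L
      next
    }
    key_order <- order(vapply(parses, function(x) {
      # track lengths before loop lengths, each field three digits
      sprintf("%03d%03d%03d%03d%03d%03d%03d",
              x[1], x[3], x[5], x[7], x[2], x[4], x[6])
    }, ""))
    best <- parses[[key_order[1]]]
    hits[[length(hits) + 1L]] <- c(start = p - 1L, best)
    p <- p + sum(best)
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), t1 = integer(0), l1 = integer(0),
                      t2 = integer(0), l2 = integer(0), t3 = integer(0),
                      l3 = integer(0), t4 = integer(0)))
  }
  m <- do.call(rbind, hits)
  colnames(m) <- c("start", "t1", "l1", "t2", "l2", "t3", "l3", "t4")
  as.data.frame(m)
}

# hits data frame -> the oracle's column layout, for comparison
hits_to_lengths <- function(hits) {
  data.frame(start = hits$start,
             t1 = nchar(hits$track1), l1 = nchar(hits$loop1),
             t2 = nchar(hits$track2), l2 = nchar(hits$loop2),
             t3 = nchar(hits$track3), l3 = nchar(hits$loop3),
             t4 = nchar(hits$track4))
}

# per-residue cG/cC oracle: each residue weighted by the maximal run it
# sits in, w(L) = 10 * min(L, 3)
oracle_cgcc <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  sums <- c(G = 0, C = 0)
  for (base in c("G", "C")) {
    r <- rle(ch == base)
    run_len_here <- rep(r$lengths, r$lengths)  # run length at each residue
    sums[base] <- sum(ifelse(ch == base, 10 * pmin(run_len_here, 3), 0))
  }
  list(cG = unname(sums["G"]), cC = unname(sums["C"]),
       score = if (sums["C"] > 0) unname(sums["G"] / sums["C"]) else Inf)
}

random_rna <- function(len, probs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

complement_rna <- function(seq) chartr("ACGU", "UGCA", seq)
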