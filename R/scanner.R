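# Core motif scanner: locates PG4 matches and their full track/loop
# decomposition under lazy (minimal) quantifier semantics, with track
# minimality taking precedence over loop minimality.
#
# Parse order is lexicographic ascending on
# (start, |T1|, |T2|, |T3|, |T4|, |L1|, |L2|, |L3|); |T4| is always minimal.
# Both halves of this ordering are load-bearing for reproducing published
# candidate decompositions: greedy parsing contradicts them (a 4-nt loop 1
# is carved out of a 6-G run, 5-G runs are split 3 + 2 between a track and
# the adjacent loop), and loop-before-track minimality contradicts them too
# (a loop-terminal G must stay in its loop rather than seed the next track,
# keeping all tracks at 3 guanines). After a hit is emitted, scanning
# resumes at its end, so hits never overlap.

HIT_COLUMNS <- c("start", "end", "length",
                 "track1", "loop1", "track2", "loop2", "track3", "loop3",
                 "track4", "sequence", "pattern")

empty_hits <- function() {
  out <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                    track1 = character(0), loop1 = character(0),
                    track2 = character(0), loop2 = character(0),
                    track3 = character(0), loop3 = character(0),
                    track4 = character(0), sequence = character(0),
                    pattern = character(0), stringsAsFactors = FALSE)
  out
}

# length of the G-run starting at each position (0 where the base is not G)
g_run_ahead <- function(is_g) {
  n <- length(is_g)
  out <- integer(n)
  r <- rle(is_g)
  pos <- 1L
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]
    if (r$values[k]) out[pos:(pos + len - 1L)] <- len:1L
    pos <- pos + len
  }
  out
}

#' Scan a sequence for PG4 motifs with full decomposition
#'
#' Performs a left-to-right scan for matches of a four-track/three-loop
#' pattern. At each candidate start the match is the lazy (minimal) parse
#' with track minimality taking precedence: the parse chosen is the
#' lexicographically smallest on `(|T1|, |T2|, |T3|, |T4|, |L1|, |L2|,
#' |L3|)` among all valid tilings — every G-track takes the fewest guanines
#' (at least `min_track_len`, so tracks of a typical match are 3 nt even
#' inside longer G-runs) and, given the tracks, each loop takes the fewest
#' nucleotides within its bounds such that a complete match exists. Among
#' complete matches the leftmost start wins. After emitting a hit, scanning
#' resumes at the hit's end, so reported hits never overlap. G-tracks are
#' not required to be maximal G-runs: guanines beyond the lazy parse belong
#' to loops or to the flanking sequence.
#'
#' @param seq A normalized RNA string (see [normalize_alphabet()]).
#' @param pattern A [g4_pattern()] or built-in pattern name.
#' @return A data frame with one row per hit: 0-based half-open `start`/`end`,
#'   `length`, the four `track*` and three `loop*` substrings (which tile the
#'   match contiguously), the matched `sequence` and the `pattern` name.
#'   Zero rows when there is no match.
#' @export
scan_sequence <- function(seq, pattern) {
  pattern <- g4_pattern_builtin(pattern)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  n <- nchar(seq)
  tmin <- pattern$min_track_len
  lb <- pattern$loop_bounds
  mins <- c(tmin, lb[1, 1], tmin, lb[2, 1], tmin, lb[3, 1], tmin)
  minrem <- rev(cumsum(rev(mins)))  # minimal length of parts idx..7
  if (n < minrem[1]) return(empty_hits())

  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c(RNA_ALPHABET, "N"))) {
    stop("sequence is not normalized; call normalize_alphabet() first")
  }
  grl <- g_run_ahead(ch == "G")
  maxg <- max(grl)

  # Given pinned track lengths, find the lexicographically minimal loop
  # lengths (l1, l2, l3); track k + 1 must start on a G-run of >= t[k + 1].
  find_loops <- function(p, tr) {
    need <- c(tr[2] + lb[2, 1] + tr[3] + lb[3, 1] + tr[4],
              tr[3] + lb[3, 1] + tr[4],
              tr[4])
    q1 <- p + tr[1]
    hi1 <- min(lb[1, 2], n - need[1] - q1 + 1L)
    if (hi1 < lb[1, 1]) return(NULL)
    for (l1 in lb[1, 1]:hi1) {
      if (grl[q1 + l1] < tr[2]) next
      q2 <- q1 + l1 + tr[2]
      hi2 <- min(lb[2, 2], n - need[2] - q2 + 1L)
      if (hi2 < lb[2, 1]) next
      for (l2 in lb[2, 1]:hi2) {
        if (grl[q2 + l2] < tr[3]) next
        q3 <- q2 + l2 + tr[3]
        hi3 <- min(lb[3, 2], n - need[3] - q3 + 1L)
        if (hi3 < lb[3, 1]) next
        for (l3 in lb[3, 1]:hi3) {
          if (grl[q3 + l3] >= tr[4]) return(c(l1, l2, l3))
        }
      }
    }
    NULL
  }

  # Minimal parse at start p under the (t1, t2, t3, t4, l1, l2, l3) key;
  # t4 is minimal by construction.
  try_match <- function(p) {
    avail <- n - p + 1L
    t1_hi <- min(grl[p], avail - minrem[2L] + mins[1L])
    if (t1_hi < tmin) return(NULL)
    for (t1 in tmin:t1_hi) {
      t2_hi <- min(maxg, avail - t1 - lb[1, 1] - minrem[4L] + mins[3L])
      if (t2_hi < tmin) next
      for (t2 in tmin:t2_hi) {
        t3_hi <- min(maxg, avail - t1 - lb[1, 1] - t2 - lb[2, 1] -
                       minrem[6L] + mins[5L])
        if (t3_hi < tmin) next
        for (t3 in tmin:t3_hi) {
          loops <- find_loops(p, c(t1, t2, t3, tmin))
          if (!is.null(loops)) {
            return(c(t1, loops[1], t2, loops[2], t3, loops[3], tmin))
          }
        }
      }
    }
    NULL
  }

  starts <- which(grl >= tmin)
  hits <- list()
  p_min <- 1L
  for (p in starts) {
    if (p < p_min) next
    if (p + minrem[1] - 1L > n) break
    lens <- try_match(p)
    if (is.null(lens)) next
    ends <- p - 1L + cumsum(lens)
    begs <- c(p, ends[-7L] + 1L)
    parts <- substring(seq, begs, ends)
    hits[[length(hits) + 1L]] <- data.frame(
      start = p - 1L, end = ends[7L], length = ends[7L] - p + 1L,
      track1 = parts[1], loop1 = parts[2], track2 = parts[3],
      loop2 = parts[4], track3 = parts[5], loop3 = parts[6],
      track4 = parts[7],
      sequence = substr(seq, p, ends[7L]),
      pattern = pattern$name, stringsAsFactors = FALSE)
    p_min <- ends[7L] + 1L
  }
  if (!length(hits)) return(empty_hits())
  do.call(rbind, hits)
}

#' Classify hits by loop geometry
#'
#' Adds (or recomputes) a `loop_class` column: `long_loop1` if loop 1 is
#' 8-40 nt, `long_loop3` if loop 3 is 8-40 nt, `canonical` if all loops are
#' at most 7 nt. A hit with both oversized loops (not producible by the
#' built-in patterns) is labelled `long_both` with a warning. Loop lengths
#' above 40 violate the motif construction and raise an error.
#'
#' @param hits A hits data frame from [scan_sequence()] or [scan_transcript()].
#' @param long_range Inclusive loop-length range regarded as "long".
#' @return `hits` with a `loop_class` character column.
#' @export
classify_hits <- function(hits, long_range = c(8L, 40L)) {
  if (nrow(hits) == 0L) {
    hits$loop_class <- character(0)
    return(hits)
  }
  l1 <- nchar(hits$loop1)
  l2 <- nchar(hits$loop2)
  l3 <- nchar(hits$loop3)
  if (any(pmax(l1, l2, l3) > long_range[2])) {
    stop(sprintf("loop length above %d violates the motif construction",
                 long_range[2]))
  }
  long1 <- l1 >= long_range[1]
  long3 <- l3 >= long_range[1]
  cls <- ifelse(long1 & long3, "long_both",
         ifelse(long1, "long_loop1",
         ifelse(long3, "long_loop3", "canonical")))
  if (any(cls == "long_both")) {
    warning("hit(s) with both loop 1 and loop 3 oversized: labelled 'long_both'")
  }
  hits$loop_class <- cls
  hits
}

#' Scan a transcript and keep UTR hits
#'
#' Scans the full transcript sequence with [scan_sequence()], then keeps a
#' hit if and only if the majority (> 50\%) of its nucleotides lie within one
#' UTR. Kept hits are annotated with the accession, gene, `region_kind`
#' (`utr5` or `utr3`), the signed 1-based `utr_position` of the hit start
#' (negative when the hit begins upstream of the UTR, see [utr_position()]),
#' and `loop_class`.
#'
#' @param record A [transcript_record()].
#' @param pattern A [g4_pattern()] or built-in name.
#' @return A hits data frame (possibly zero rows).
#' @export
scan_transcript <- function(record, pattern) {
  stopifnot(inherits(record, "transcript_record"))
  hits <- scan_sequence(record$sequence, pattern)
  n <- nchar(record$sequence)
  ann_empty <- function(h) {
    h$accession <- character(nrow(h))
    h$gene <- character(nrow(h))
    h$region_kind <- character(nrow(h))
    h$utr_position <- integer(nrow(h))
    h
  }
  if (nrow(hits) == 0L) return(classify_hits(ann_empty(hits)))
  ov5 <- pmax(0L, pmin(hits$end, record$cds_start) - hits$start)
  ov3 <- pmax(0L, hits$end - pmax(hits$start, record$cds_end))
  frac5 <- ov5 / hits$length
  frac3 <- ov3 / hits$length
  keep <- pmax(frac5, frac3) > 0.5
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(classify_hits(ann_empty(hits)))
  in5 <- frac5[keep] >= frac3[keep]
  hits$accession <- record$accession
  hits$gene <- record$gene
  hits$region_kind <- ifelse(in5, "utr5", "utr3")
  hits$utr_position <- ifelse(
    in5, utr_position(hits$start, 0L),
    utr_position(hits$start, record$cds_end))
  rownames(hits) <- NULL
  classify_hits(hits)
}

#' Scan a set of transcripts with one or more patterns
#'
#' Convenience wrapper running [scan_transcript()] for every transcript and
#' pattern. Each pattern is an independent scan (the non-overlap rule applies
#' within one pattern, per transcript, not across patterns).
#'
#' @param records Named list of [transcript_record()] objects.
#' @param patterns Vector of built-in names and/or list of [g4_pattern()]s.
#' @return Combined hits data frame.
#' @export
scan_transcriptome <- function(records, patterns = c("PLL1", "PLL3")) {
  if (!is.list(patterns)) patterns <- as.list(patterns)
  res <- lapply(patterns, function(p) {
    do.call(rbind, lapply(records, scan_transcript, pattern = p))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- classify_hits(scan_transcript_empty())
  rownames(out) <- NULL
  out
}

scan_transcript_empty <- function() {
  h <- empty_hits()
  h$accession <- character(0)
  h$gene <- character(0)
  h$region_kind <- character(0)
  h$utr_position <- integer(0)
  h
}

#' Collapse isoform-redundant hits
#'
#' Transcript isoforms of one gene produce multiple identical hits. This
#' filter keeps, per uniqueness key `(gene, matched sequence, region_kind)`,
#' the first hit in input order, annotated with the number of hits collapsed
#' into it (`multiplicity`). Identical sequences in different genes remain
#' distinct. The operation is idempotent.
#'
#' @param hits Annotated hits data frame (from [scan_transcript()] or
#'   [scan_transcriptome()]).
#' @return Deduplicated hits with a `multiplicity` integer column.
#' @export
deduplicate_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    hits$multiplicity <- integer(0)
    return(hits)
  }
  key <- paste(hits$gene, hits$sequence, hits$region_kind, sep = "\r")
  first <- !duplicated(key)
  mult <- as.integer(table(factor(key, levels = key[first]))[key[first]])
  if (!is.null(hits$multiplicity)) {
    # idempotence: re-deduplicating keeps existing counts
    mult <- as.integer(tapply(hits$multiplicity,
                              factor(key, levels = key[first]), sum)[key[first]])
  }
  out <- hits[first, , drop = FALSE]
  out$multiplicity <- mult
  rownames(out) <- NULL
  out
}

#' Write hits to TSV or BED
#'
#' TSV output carries the columns `accession`, `gene`, `region_kind`,
#' `utr_position`, `length`, `loop_class`, `track1..track4`, `loop1..loop3`,
#' `sequence`, optionally the cG/cC columns when present, and `multiplicity`;
#' empty fields are written as `"."`. BED6 output uses transcript-space
#' 0-based half-open coordinates, `name = gene|loop_class`,
#' `score = round(100 * cG/cC)` (0 when unscored, capped at 1000) and
#' strand `"+"`.
#'
#' @param hits Annotated hits data frame.
#' @param path Output file path.
#' @param format `"tsv"` or `"bed"`.
#' @param header_lines Optional character vector of `#`-prefixed provenance
#'   lines written before the data.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path, format = c("tsv", "bed"),
                       header_lines = NULL) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  if (format == "bed") {
    score <- if (!is.null(hits$cgcc_score)) {
      pmin(1000, round(100 * ifelse(is.finite(hits$cgcc_score),
                                    hits$cgcc_score, 10)))
    } else rep(0L, nrow(hits))
    bed <- data.frame(
      chrom = hits$accession, start = hits$start, end = hits$end,
      name = paste(hits$gene, hits$loop_class, sep = "|"),
      score = score, strand = rep("+", nrow(hits)),
      stringsAsFactors = FALSE)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  cols <- c("accession", "gene", "region_kind", "utr_position", "length",
            "loop_class", "track1", "track2", "track3", "track4",
            "loop1", "loop2", "loop3", "sequence")
  if (!is.null(hits$cgcc_score)) cols <- c(cols, "cG", "cC", "cgcc_score",
                                           "cgcc_class")
  cols <- c(cols, "multiplicity")
  out <- hits
  if (is.null(out$multiplicity)) out$multiplicity <- rep(1L, nrow(out))
  out <- out[, intersect(cols, names(out)), drop = FALSE]
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.numeric(v)) v <- ifelse(is.infinite(v), "Inf", as.character(v))
    v[is.na(v) | v == ""] <- "."
    out[[j]] <- v
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
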