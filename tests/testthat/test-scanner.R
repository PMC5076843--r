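test_that("patterns validate their construction", {
  expect_error(g4_pattern("x", list(c(1, 7), c(1, 7), c(1, 7)), 2), ">= 3")
  expect_error(g4_pattern("x", list(c(0, 7), c(1, 7), c(1, 7))), "min <= max")
  expect_error(g4_pattern_builtin("PLL2"), "unknown")
  p <- g4_pattern_builtin("pll1")
  expect_identical(unname(p$loop_bounds[1, ]), c(1L, 40L))
  expect_identical(unname(p$loop_bounds[3, ]), c(1L, 7L))
})

test_that("scan_sequence reproduces the published TEF parse", {
  tef <- candidate_sequence("TEF")
  expect_identical(nchar(tef), 43L)
  h <- scan_sequence(tef, "PLL3")
  expect_identical(nrow(h), 1L)
  # loop 1 of 4 nt carved out of the leading 6-G run, loop 2 of 1 nt, long
  # loop 3 of 26 nt
  expect_identical(nchar(h$loop1), 4L)
  expect_identical(h$loop1, "GGGC")
  expect_identical(nchar(h$loop2), 1L)
  expect_identical(nchar(h$loop3), 26L)
  expect_identical(h$length, 43L)
  expect_identical(nchar(h$track3), 3L)  # the 5-G run is split 3 + 2
})

test_that("scan_sequence basics: no match, unique tiling, derived example", {
  expect_identical(nrow(scan_sequence("AUAUAUAU", "PLL1")), 0L)
  h <- scan_sequence("GGGAGGGAGGGAGGG", "CANONICAL")
  expect_identical(nrow(h), 1L)
  expect_identical(nchar(c(h$loop1, h$loop2, h$loop3)), c(1L, 1L, 1L))
  expect_identical(nchar(c(h$track1, h$track2, h$track3, h$track4)),
                   c(3L, 3L, 3L, 3L))
  # expected values frozen from the exhaustive-tiling oracle
  h2 <- scan_sequence("GGGGAGGGAGGGAGGGG", "CANONICAL")
  expect_identical(hits_to_lengths(h2),
                   data.frame(start = 0L, t1 = 3L, l1 = 2L, t2 = 3L, l2 = 1L,
                              t3 = 3L, l3 = 1L, t4 = 3L))
  expect_identical(hits_to_lengths(h2),
                   oracle_scan_exhaustive("GGGGAGGGAGGGAGGGG", "CANONICAL"))
})

test_that("hit parts tile the match and satisfy the pattern", {
  set.seed(202)
  for (i in 1:60) {
    s <- random_rna(sample(20:60, 1), c(A = 0.2, C = 0.15, G = 0.45, U = 0.2))
    for (pat in c("PLL1", "PLL3", "CANONICAL")) {
      h <- scan_sequence(s, pat)
      if (nrow(h) == 0) next
      p <- g4_pattern_builtin(pat)
      reassembled <- paste0(h$track1, h$loop1, h$track2, h$loop2,
                            h$track3, h$loop3, h$track4)
      expect_identical(reassembled, h$sequence)
      expect_identical(h$sequence, substring(s, h$start + 1, h$end))
      expect_true(all(grepl("^G+$", c(h$track1, h$track2, h$track3, h$track4))))
      for (li in 1:3) {
        len <- nchar(h[[paste0("loop", li)]])
        expect_true(all(len >= p$loop_bounds[li, 1] &
                          len <= p$loop_bounds[li, 2]))
      }
      # non-overlap, left to right
      if (nrow(h) > 1) expect_true(all(h$end[-nrow(h)] <= h$start[-1]))
    }
  }
})

test_that("scanner equals the exhaustive-tiling oracle on random sequences", {
  set.seed(303)
  n_checked <- 0L
  for (i in 1:400) {
    gc <- sample(c(0.4, 0.6, 0.8), 1)
    s <- random_rna(sample(15:60, 1),
                    c(A = (1 - gc) / 2, C = gc / 4, G = 3 * gc / 4,
                      U = (1 - gc) / 2))
    pat <- sample(c("PLL1", "PLL3", "CANONICAL"), 1)
    got <- hits_to_lengths(scan_sequence(s, pat))
    want <- oracle_scan_exhaustive(s, pat)
    expect_identical(got, want, info = paste(pat, s))
    n_checked <- n_checked + nrow(want)
  }
  expect_gt(n_checked, 50)  # the case mix actually exercises matches
})

test_that("classify_hits labels loop geometry and rejects impossible loops", {
  h <- scan_sequence(candidate_sequence("B3GNT8"), "PLL1")
  expect_identical(classify_hits(h)$loop_class, "long_loop1")
  expect_identical(nchar(h$loop1), 38L)
  h3 <- classify_hits(scan_sequence(candidate_sequence("TEF"), "PLL3"))
  expect_identical(h3$loop_class, "long_loop3")
  hc <- classify_hits(scan_sequence("GGGAGGGAGGGAGGG", "CANONICAL"))
  expect_identical(hc$loop_class, "canonical")
  fake <- hc
  fake$loop1 <- strrep("A", 41)
  expect_error(classify_hits(fake), "violates")
  both <- hc
  both$loop1 <- strrep("A", 10)
  both$loop3 <- strrep("U", 10)
  expect_warning(cls <- classify_hits(both), "long_both")
  expect_identical(cls$loop_class, "long_both")
})

test_that("scan_transcript keeps majority-UTR hits with signed positions", {
  pg4 <- candidate_sequence("DOK1")  # 33 nt, PLL3
  # fully inside the 3' UTR
  tr <- fixture_transcript(pg4, at = 120L, total = 200L,
                           cds_start = 30L, cds_end = 100L)
  h <- scan_transcript(tr, "PLL3")
  expect_identical(nrow(h), 1L)
  expect_identical(h$region_kind, "utr3")
  expect_identical(h$utr_position, utr_position(120L, 100L))
  # starting 6 nt before the 3' UTR: 6/55 nt in CDS, still a UTR hit at -6
  tada <- candidate_sequence("TADA3")  # 55 nt
  tr2 <- fixture_transcript(tada, at = 94L, total = 220L,
                            cds_start = 30L, cds_end = 100L)
  h2 <- scan_transcript(tr2, "PLL1")
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$region_kind, "utr3")
  expect_identical(h2$utr_position, -6L)
  # fully inside the CDS: dropped
  tr3 <- fixture_transcript(pg4, at = 60L, total = 220L,
                            cds_start = 30L, cds_end = 180L)
  expect_identical(nrow(scan_transcript(tr3, "PLL3")), 0L)
  # 5' UTR hit
  tr4 <- fixture_transcript(pg4, at = 2L, total = 200L,
                            cds_start = 60L, cds_end = 140L)
  h4 <- scan_transcript(tr4, "PLL3")
  expect_identical(h4$region_kind, "utr5")
  expect_identical(h4$utr_position, 3L)
})

test_that("deduplicate_hits collapses per (gene, sequence, region) and is idempotent", {
  pg4 <- candidate_sequence("PTPRU")
  iso1 <- fixture_transcript(pg4, at = 120L, total = 200L, cds_start = 30L,
                             cds_end = 100L, accession = "NM_1", gene = "G1")
  iso2 <- fixture_transcript(pg4, at = 130L, total = 210L, cds_start = 30L,
                             cds_end = 100L, accession = "NM_2", gene = "G1")
  other <- fixture_transcript(pg4, at = 120L, total = 200L, cds_start = 30L,
                              cds_end = 100L, accession = "NM_3", gene = "G2")
  hits <- scan_transcriptome(list(iso1, iso2, other), "PLL3")
  expect_identical(nrow(hits), 3L)
  ded <- deduplicate_hits(hits)
  expect_identical(nrow(ded), 2L)
  expect_identical(ded$multiplicity, c(2L, 1L))
  expect_identical(ded$accession[1], "NM_1")  # first occurrence kept
  expect_identical(deduplicate_hits(ded), ded)
})

test_that("write_hits emits well-formed TSV and BED", {
  dir <- make_tempdir()
  tr <- fixture_transcript(candidate_sequence("TEF"), at = 120L, total = 200L,
                           cds_start = 30L, cds_end = 100L)
  hits <- deduplicate_hits(scan_transcript(tr, "PLL3"))
  tsv <- file.path(dir, "hits.tsv")
  write_hits(hits, tsv, "tsv", header_lines = "#key=value")
  lines <- readLines(tsv)
  expect_identical(lines[1], "#key=value")
  tab <- utils::read.delim(tsv, comment.char = "#")
  expect_identical(nrow(tab), 1L)
  expect_identical(
    nchar(paste0(tab$track1, tab$track2, tab$track3, tab$track4,
                 tab$loop1, tab$loop2, tab$loop3)), tab$length)
  bed <- file.path(dir, "hits.bed")
  write_hits(hits, bed, "bed")
  b <- utils::read.delim(bed, header = FALSE)
  expect_identical(b$V2, hits$start)
  expect_identical(b$V3, hits$end)
  expect_identical(b$V4, paste(hits$gene, hits$loop_class, sep = "|"))
  expect_identical(b$V6, "+")
  # zero hits: header-only TSV
  empty <- file.path(dir, "empty.tsv")
  write_hits(hits[0, ], empty, "tsv")
  expect_identical(length(readLines(empty)), 1L)
})
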