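test_that("run_decomposition finds maximal runs", {
  expect_identical(run_decomposition("GGGAGGG", "G"),
                   data.frame(offset = c(0L, 4L), length = c(3L, 3L)))
  expect_identical(nrow(run_decomposition("AAAA", "C")), 0L)
  expect_identical(run_decomposition("GGCGG", "G"),
                   data.frame(offset = c(0L, 3L), length = c(2L, 2L)))
  set.seed(5)
  for (i in 1:20) {
    s <- random_rna(sample(1:80, 1))
    d <- run_decomposition(s, "G")
    expect_identical(sum(d$length),
                     nchar(gsub("[^G]", "", s)))
  }
})

test_that("cgcc_score matches hand-enumerated and oracle values", {
  r1 <- cgcc_score("GGGACCC")
  expect_identical(r1$cG, 90)
  expect_identical(r1$cC, 90)
  expect_identical(r1$score, 1.0)
  # derived: two 3-G runs (2 * 90) over one CC pair (2 * 20)
  r2 <- cgcc_score("GGGAGGGACC")
  expect_identical(r2$cG, 180)
  expect_identical(r2$cC, 40)
  expect_identical(r2$score, 4.5)
  # per-residue summation oracle on random sequences
  set.seed(21)
  for (i in 1:50) {
    s <- random_rna(sample(10:120, 1),
                    c(A = 0.2, C = 0.3, G = 0.3, U = 0.2))
    got <- cgcc_score(s)
    want <- oracle_cgcc(s)
    expect_identical(got$cG, want$cG)
    expect_identical(got$cC, want$cC)
    expect_identical(got$score, want$score)
  }
  expect_error(cgcc_score(""), "empty")
})

test_that("no-C windows yield the sentinel, classified likely_folded", {
  r <- cgcc_score("GGGAGGGAGGGAGGG")
  expect_identical(r$score, Inf)
  expect_identical(r$classification, "likely_folded")
})

test_that("classification thresholds are inclusive toward their class", {
  expect_identical(classify_score(4.23), "likely_folded")
  expect_identical(classify_score(1.97), "unlikely")
  expect_identical(classify_score(2.53), "ambiguous")
  expect_identical(classify_score(3.05), "likely_folded")
  expect_identical(classify_score(2.05), "unlikely")
  expect_identical(classify_score(c(2.06, 2.39, 2.53, 3.049)),
                   rep("ambiguous", 4))
})

test_that("complement inversion and U/T invariance hold", {
  set.seed(31)
  n_informative <- 0L
  for (i in 1:60) {
    s <- random_rna(sample(15:90, 1), c(A = 0.2, C = 0.3, G = 0.3, U = 0.2))
    r <- cgcc_score(s)
    if (!is.finite(r$score) || r$score == 0) next
    rc <- cgcc_score(complement_rna(s))
    expect_equal(rc$score, 1 / r$score)
    rt <- cgcc_score(normalize_alphabet(chartr("U", "T", s)))
    expect_identical(rt$score, r$score)
    n_informative <- n_informative + 1L
  }
  expect_gt(n_informative, 30)
})

test_that("appending a disjoint G-run strictly increases cG and the score", {
  set.seed(41)
  for (i in 1:20) {
    s <- random_rna(sample(15:60, 1), c(A = 0.2, C = 0.3, G = 0.3, U = 0.2))
    r <- cgcc_score(s)
    if (!is.finite(r$score)) next
    r2 <- cgcc_score(paste0(s, "A", strrep("G", sample(1:5, 1)), "A"))
    expect_gt(r2$cG, r$cG)
    expect_identical(r2$cC, r$cC)
    expect_gt(r2$score, r$score)
  }
})

test_that("score_window truncates flanks at transcript ends", {
  tr <- transcript_record("NM_1", "X", strrep("A", 10) %+%
                            "GGGAGGGAGGGAGGG" %+% strrep("U", 50), 0, 5)
  w <- score_window(tr, 10, 25, flank = 25)
  expect_identical(w$flank_up_len, 10L)
  expect_identical(w$flank_down_len, 25L)
  expect_identical(nchar(w$sequence), 10L + 15L + 25L)
  expect_true(grepl("GGGAGGGAGGGAGGG", w$sequence, fixed = TRUE))
  expect_error(score_window(tr, 20, 10), "span")
})

test_that("add_cgcc appends score columns keyed by accession", {
  tr <- fixture_transcript(candidate_sequence("TEF"), at = 120L, total = 220L,
                           cds_start = 30L, cds_end = 100L)
  hits <- scan_transcript(tr, "PLL3")
  scored <- add_cgcc(hits, list(tr))
  expect_true(all(c("cG", "cC", "cgcc_score", "cgcc_class") %in% names(scored)))
  # A/U background contributes nothing: window score equals hit-window score
  w <- score_window(tr, hits$start, hits$end)
  expect_identical(scored$cgcc_score, cgcc_score(w)$score)
  expect_error(add_cgcc(hits, list()), "missing")
})
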