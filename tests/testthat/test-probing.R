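test_that("normalize_lane modes behave as documented", {
  expect_identical(normalize_lane(c(2, 2, 4)), c(0.25, 0.25, 0.5))
  expect_identical(normalize_lane(c(2, 2, 4), "none"), c(2, 2, 4))
  expect_identical(normalize_lane(7 * c(2, 2, 4)), normalize_lane(c(2, 2, 4)))
  expect_error(normalize_lane(c(0, 0, 0)), "degenerate")
  expect_error(normalize_lane(c(-1, 2)), "negative")
})

test_that("ratio_profile computes per-replicate ratios, mean and SD", {
  p1 <- suppressWarnings(ratio_profile(c(2, 6), c(2, 2)))
  expect_identical(p1$mean_ratio, c(1, 3))
  k <- cbind(c(2, 6), c(2, 6))
  li <- cbind(c(2, 2), c(2, 2))
  p2 <- ratio_profile(k, li)
  expect_identical(p2$sd_ratio, c(0, 0))
  expect_identical(attr(p2, "n_replicates"), 2L)
  # undefined where Li = 0
  p3 <- suppressWarnings(ratio_profile(cbind(c(1, 1)), cbind(c(0, 2))))
  expect_true(is.na(p3$mean_ratio[1]))
  expect_identical(p3$n_defined, c(0, 1))
  expect_error(ratio_profile(cbind(1:3), cbind(1:2)), "mismatched")
  expect_error(ratio_profile(c(1, 2), c(1, 2), loop_positions = 1,
                             track_positions = 1), "disjoint")
  expect_warning(ratio_profile(c(1, 2), c(1, 2)), "single replicate")
})

test_that("total-normalized ratios are invariant under per-lane rescaling", {
  set.seed(7)
  k <- matrix(rlnorm(40), 20, 2)
  li <- matrix(rlnorm(40), 20, 2)
  base <- ratio_profile(k, li, normalize = "total")
  scaled <- ratio_profile(k %*% diag(c(3.7, 0.2)), li %*% diag(c(11, 5.5)),
                          normalize = "total")
  expect_equal(scaled$mean_ratio, base$mean_ratio)
  expect_equal(scaled$sd_ratio, base$sd_ratio)
})

test_that("call_folding implements the threshold rule with mutant control", {
  mk <- function(loop_ratios, other = 1.0) {
    n <- length(loop_ratios) + 4L
    loops <- seq_len(length(loop_ratios)) + 2L
    vals <- rep(other, n)
    vals[loops] <- loop_ratios
    ratio_profile(cbind(vals, vals), cbind(rep(1, n), rep(1, n)),
                  loop_positions = loops,
                  track_positions = setdiff(seq_len(n), loops))
  }
  wt <- mk(c(3.1, 1.2))
  mut <- mk(c(1.3, 1.1))
  call <- call_folding(wt, mut)
  expect_identical(call$verdict, "folded")
  expect_identical(call$supporting_positions, 3L)
  expect_identical(call_folding(mk(c(1.0, 1.0)), mut)$verdict, "not_folded")
  expect_identical(call_folding(mk(c(2.5, 1.0)), mk(c(2.4, 1.0)))$verdict,
                   "inconclusive")
  # control logic is symmetric: wt vs itself is inconclusive
  expect_identical(call_folding(wt, wt)$verdict, "inconclusive")
  # threshold is inclusive
  expect_identical(call_folding(mk(c(2.0, 1.0)), mut)$verdict, "folded")
  # undefined ratios at every loop position
  und <- suppressWarnings(
    ratio_profile(cbind(c(1, 1, 1)), cbind(c(1, 0, 0)),
                  loop_positions = 2:3, track_positions = 1L))
  expect_error(suppressWarnings(call_folding(und, und)), "undefined")
})

test_that("noiseless generated experiments give exact ratios and verdicts", {
  lengths <- c(3L, 4L, 3L, 1L, 3L, 26L, 3L)
  lanes <- generate_probing_experiment(lengths, folded = TRUE,
                                       noise_sigma = 0, seed = 9)
  res <- analyze_probing(lanes, lengths)
  pos <- decomposition_positions(lengths)
  expect_identical(unique(res$wt$mean_ratio[pos$loop]), 3)
  expect_identical(unique(res$wt$mean_ratio[pos$track]), 1)
  expect_identical(unique(res$mut$mean_ratio), 1)
  expect_identical(res$call$verdict, "folded")
  lanes0 <- generate_probing_experiment(lengths, folded = FALSE,
                                        noise_sigma = 0, seed = 9)
  expect_identical(analyze_probing(lanes0, lengths)$call$verdict, "not_folded")
})

test_that("folded profiles elevate loops over tracks across seeds", {
  lengths <- c(3L, 2L, 3L, 1L, 3L, 12L, 3L)
  pos <- decomposition_positions(lengths)
  wins <- 0L
  for (seed in 1:30) {
    lanes <- generate_probing_experiment(lengths, folded = TRUE, seed = seed)
    res <- analyze_probing(lanes, lengths)
    wins <- wins + (mean(res$wt$mean_ratio[pos$loop]) >
                      mean(res$wt$mean_ratio[pos$track]))
  }
  expect_gte(wins, 29L)  # sign test: >= 29/30 at p << 0.01 under a fair coin
})

test_that("analyze_probing round-trips through the long CSV format", {
  dir <- make_tempdir()
  lengths <- c(3L, 4L, 3L, 1L, 3L, 9L, 3L)
  lanes <- generate_probing_experiment(lengths, folded = TRUE, seed = 4)
  path <- file.path(dir, "lanes.csv")
  utils::write.csv(lanes, path, row.names = FALSE)
  back <- read_lanes(path)
  res <- analyze_probing(back, lengths)
  direct <- analyze_probing(lanes, lengths)
  expect_equal(res$wt$mean_ratio, direct$wt$mean_ratio)
  expect_identical(res$call$verdict, direct$call$verdict)
  # missing Li lanes is an error
  expect_error(analyze_probing(back[back$cation != "Li", ], lengths), "Li")
})
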