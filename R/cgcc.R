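# Consecutive-G over consecutive-C (cG/cC) fold-propensity score.
#
# Each residue inside a maximal run of length L contributes w(L) =
# 10 * min(L, 3): an isolated G scores 10, each G of a GG pair 20, each G of
# a run of three or more 30, mirrored for C. cG and cC are the sums over all
# G and C residues of the scored window; the score is their ratio. Longer
# G-tracks favour quadruplex folding while longer C-tracks favour competing
# Watson-Crick pairing, so a high ratio predicts folding.

#' Maximal-run decomposition of one base
#'
#' @param seq Normalized sequence.
#' @param base Single character, usually `"G"` or `"C"`.
#' @return Data frame with 0-based `offset` and `length` of each maximal run
#'   of `base`, in sequence order. Run lengths sum to the total count of
#'   `base` in `seq`.
#' @export
run_decomposition <- function(seq, base) {
  stopifnot(is.character(seq), length(seq) == 1L,
            is.character(base), nchar(base) == 1L)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(ch == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(offset = starts[keep] - 1L, length = r$lengths[keep])
}

cgcc_run_weight <- function(len) 10 * pmin(len, 3)

#' Score a window with the cG/cC system
#'
#' Computes cG and cC as the weighted sums over maximal G- and C-runs
#' (run contribution `L * 10 * min(L, 3)`), and the score `cG / cC`. A window
#' without any C yields an infinite score (reported as the "no-C" sentinel
#' `Inf`, classified `likely_folded`): a G-rich window with no cytosine is
#' legitimately maximal-confidence, never a division error.
#'
#' @param window A character scalar (the whole string is scored) or a
#'   [score_window()].
#' @param lower,upper Classification thresholds, see [classify_score()].
#' @return An object of class `cgcc_result`: list with `cG`, `cC`, `score`
#'   and `classification`.
#' @export
cgcc_score <- function(window, lower = 2.05, upper = 3.05) {
  seq <- if (inherits(window, "score_window")) window$sequence else window
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("cannot score an empty window")
  g <- run_decomposition(seq, "G")
  c_ <- run_decomposition(seq, "C")
  cG <- sum(g$length * cgcc_run_weight(g$length))
  cC <- sum(c_$length * cgcc_run_weight(c_$length))
  score <- if (cC > 0) cG / cC else Inf
  structure(list(cG = cG, cC = cC, score = score,
                 classification = classify_score(score, lower, upper)),
            class = "cgcc_result")
}

#' @export
print.cgcc_result <- function(x, ...) {
  cat(sprintf("<cgcc_result> cG = %g, cC = %g, score = %s (%s)\n",
              x$cG, x$cC,
              if (is.finite(x$score)) sprintf("%.3f", x$score) else "> max (no C)",
              x$classification))
  invisible(x)
}

#' Classify a cG/cC score against the folding thresholds
#'
#' `likely_folded` at or above `upper` (default 3.05), `unlikely` at or below
#' `lower` (default 2.05), `ambiguous` in between. Boundary values are
#' inclusive toward their named class. The no-C sentinel (`Inf`) is
#' `likely_folded`.
#'
#' @param score Numeric vector (may contain `Inf`).
#' @param lower,upper Ordered thresholds.
#' @return Character vector in `{likely_folded, ambiguous, unlikely}`.
#' @export
classify_score <- function(score, lower = 2.05, upper = 3.05) {
  stopifnot(is.numeric(score), lower <= upper)
  ifelse(score >= upper, "likely_folded",
         ifelse(score <= lower, "unlikely", "ambiguous"))
}

#' Extract the scoring window around a hit
#'
#' The scored window is the hit sequence extended by up to `flank` nt of
#' transcript context on each side, truncated silently at the transcript
#' ends; the achieved flank lengths are recorded. Flanks come from the
#' spliced transcript sequence, not the genome.
#'
#' @param record A [transcript_record()].
#' @param start,end 0-based half-open hit span on the transcript.
#' @param flank Maximum flank length per side (default 25).
#' @return An object of class `score_window`: list with `sequence`,
#'   `flank_up_len`, `flank_down_len`.
#' @export
score_window <- function(record, start, end, flank = 25L) {
  stopifnot(inherits(record, "transcript_record"))
  n <- nchar(record$sequence)
  start <- as.integer(start); end <- as.integer(end); flank <- as.integer(flank)
  if (is.na(flank) || flank < 0L) stop("'flank' must be >= 0")
  if (start < 0L || end > n || start >= end) stop("invalid hit span")
  w_start <- max(0L, start - flank)
  w_end <- min(n, end + flank)
  structure(list(
    sequence = substr(record$sequence, w_start + 1L, w_end),
    flank_up_len = start - w_start,
    flank_down_len = w_end - end), class = "score_window")
}

#' Add cG/cC columns to a hits table
#'
#' For every hit, builds the flanked [score_window()] on its transcript and
#' appends `cG`, `cC`, `cgcc_score`, `cgcc_class`, `flank_up_len` and
#' `flank_down_len` columns.
#'
#' @param hits Annotated hits data frame (must carry `accession`).
#' @param records Named list of [transcript_record()]s keyed by accession.
#' @param flank Flank length per side (default 25).
#' @param lower,upper Classification thresholds.
#' @return `hits` with the scoring columns appended.
#' @export
add_cgcc <- function(hits, records, flank = 25L, lower = 2.05, upper = 3.05) {
  cols <- c("cG", "cC", "cgcc_score", "cgcc_class",
            "flank_up_len", "flank_down_len")
  if (nrow(hits) == 0L) {
    for (cl in cols) hits[[cl]] <- if (cl %in% c("cgcc_class")) character(0) else numeric(0)
    return(hits)
  }
  acc <- vapply(records, `[[`, "", "accession")
  idx <- match(hits$accession, acc)
  if (anyNA(idx)) stop("hit accession(s) missing from 'records': ",
                       paste(unique(hits$accession[is.na(idx)]), collapse = ", "))
  res <- lapply(seq_len(nrow(hits)), function(i) {
    w <- score_window(records[[idx[i]]], hits$start[i], hits$end[i], flank)
    s <- cgcc_score(w, lower, upper)
    list(s$cG, s$cC, s$score, s$classification,
         w$flank_up_len, w$flank_down_len)
  })
  hits$cG <- vapply(res, function(x) as.numeric(x[[1]]), 0)
  hits$cC <- vapply(res, function(x) as.numeric(x[[2]]), 0)
  hits$cgcc_score <- vapply(res, function(x) as.numeric(x[[3]]), 0)
  hits$cgcc_class <- vapply(res, function(x) x[[4]], "")
  hits$flank_up_len <- vapply(res, function(x) as.integer(x[[5]]), 0L)
  hits$flank_down_len <- vapply(res, function(x) as.integer(x[[6]]), 0L)
  hits
}
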