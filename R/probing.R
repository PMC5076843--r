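# In-line probing analysis. Flexible (loop) linkages of a folded
# G-quadruplex cleave faster under K+ (which stabilizes the quadruplex) than
# under Li+ (which does not), so per-nucleotide K+/Li+ band-intensity ratios
# above a threshold at loop positions indicate folding; quartet guanines stay
# protected. The G/A mutant is the negative control: it must not respond.

#' Normalize a lane of band intensities
#'
#' @param intensities Non-negative numeric vector, one value per nucleotide
#'   (5' to 3'), with a positive sum.
#' @param mode `"total"` scales the lane to sum 1 (the in-silico analogue of
#'   loading equal radioactivity per well); `"median"` scales the lane median
#'   to 1; `"none"` is the identity.
#' @return Numeric vector of the same length.
#' @export
normalize_lane <- function(intensities, mode = c("total", "median", "none")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(intensities))
  if (any(intensities < 0, na.rm = TRUE)) stop("negative band intensity")
  if (mode == "none") return(intensities)
  denom <- switch(mode, total = sum(intensities),
                  median = stats::median(intensities))
  if (!isTRUE(denom > 0)) stop("degenerate lane: cannot normalize (sum/median is 0)")
  intensities / denom
}

#' Per-nucleotide K+/Li+ ratio profile
#'
#' For each replicate, divides the K+ lane by the paired Li+ lane (after the
#' chosen per-lane normalization), then averages across replicates: the
#' profile carries the per-nucleotide mean ratio and SD. Positions where a
#' Li+ intensity is 0 are flagged undefined (`NA`) for that replicate and
#' excluded from the mean.
#'
#' The default is `normalize = "none"`: the generators and the documented
#' input convention assume lanes already equilibrated to equal loading, in
#' which case raw ratios are the K+/Li+ ratios. Use `"total"` when lane
#' loadings differ; ratios are then invariant under any positive per-lane
#' rescaling.
#'
#' @param k,li Numeric matrices (rows = positions, columns = replicates,
#'   paired by column) or vectors for a single replicate.
#' @param sequence Optional probed sequence (length = number of positions).
#' @param loop_positions,track_positions Optional disjoint 1-based index sets
#'   from the hit decomposition (see [decomposition_positions()]).
#' @param normalize Per-lane normalization mode, see [normalize_lane()].
#' @return An object of class `ratio_profile`: data frame with `position`,
#'   `mean_ratio`, `sd_ratio`, `n_defined`; attributes `sequence`,
#'   `loop_positions`, `track_positions`, `n_replicates`.
#' @export
ratio_profile <- function(k, li, sequence = NULL, loop_positions = NULL,
                          track_positions = NULL,
                          normalize = c("none", "total", "median")) {
  normalize <- match.arg(normalize)
  k <- as.matrix(k); li <- as.matrix(li)
  if (!all(dim(k) == dim(li))) stop("K and Li lanes have mismatched dimensions")
  if (ncol(k) == 0L || nrow(k) == 0L) stop("no paired replicate lanes")
  if (!is.null(sequence) && nchar(sequence) != nrow(k)) {
    stop("'sequence' length does not match the number of positions")
  }
  if (length(intersect(loop_positions, track_positions))) {
    stop("loop and track position sets must be disjoint")
  }
  if (ncol(k) < 2L) warning("single replicate: SD is undefined")
  if (normalize != "none") {
    k <- apply(k, 2L, normalize_lane, mode = normalize)
    li <- apply(li, 2L, normalize_lane, mode = normalize)
    k <- as.matrix(k); li <- as.matrix(li)
  }
  ratios <- k / li
  ratios[li == 0] <- NA_real_
  out <- data.frame(
    position = seq_len(nrow(k)),
    mean_ratio = rowMeans(ratios, na.rm = TRUE),
    sd_ratio = apply(ratios, 1L, stats::sd, na.rm = TRUE),
    n_defined = rowSums(!is.na(ratios)))
  out$mean_ratio[out$n_defined == 0L] <- NA_real_
  structure(out, class = c("ratio_profile", "data.frame"),
            sequence = sequence,
            loop_positions = as.integer(loop_positions),
            track_positions = as.integer(track_positions),
            n_replicates = ncol(k))
}

#' 1-based track and loop position sets of a decomposition
#'
#' @param lengths Integer vector of the seven part lengths
#'   (T1, L1, T2, L2, T3, L3, T4), e.g. `c(3, 4, 3, 1, 3, 26, 3)`.
#' @return List with integer vectors `track` and `loop` (disjoint, covering
#'   `1:sum(lengths)`).
#' @export
decomposition_positions <- function(lengths) {
  lengths <- as.integer(lengths)
  stopifnot(length(lengths) == 7L, all(lengths > 0L))
  ends <- cumsum(lengths)
  starts <- c(1L, ends[-7L] + 1L)
  idx <- function(i) unlist(lapply(i, function(j) starts[j]:ends[j]))
  list(track = idx(c(1L, 3L, 5L, 7L)), loop = idx(c(2L, 4L, 6L)))
}

#' Call G-quadruplex folding from WT and mutant ratio profiles
#'
#' `folded` when at least `min_positive` loop positions of the wild type have
#' a mean K+/Li+ ratio at or above `threshold` while the G/A mutant has
#' fewer than `min_positive` such loop positions; `not_folded` when the wild
#' type has fewer than `min_positive`; `inconclusive` otherwise (the mutant
#' control is also responsive). The comparison is inclusive (`>=`).
#'
#' @param wt,mut [ratio_profile()]s aligned to the same decomposition; `wt`
#'   must carry `loop_positions`.
#' @param threshold Ratio threshold (default 2).
#' @param min_positive Minimum number of responsive loop positions
#'   (default 1).
#' @return An object of class `folding_call`: list with `verdict`,
#'   `supporting_positions` (responsive WT loop positions), `threshold`,
#'   `min_positive`.
#' @export
call_folding <- function(wt, mut, threshold = 2.0, min_positive = 1L) {
  stopifnot(inherits(wt, "ratio_profile"), inherits(mut, "ratio_profile"))
  loops <- attr(wt, "loop_positions")
  if (!length(loops)) stop("'wt' profile carries no loop positions")
  if (nrow(wt) != nrow(mut)) stop("profiles are not aligned")
  wt_loop <- wt$mean_ratio[loops]
  mut_loop <- mut$mean_ratio[loops]
  if (all(is.na(wt_loop))) stop("ratios undefined at every loop position")
  sup <- loops[!is.na(wt_loop) & wt_loop >= threshold]
  mut_pos <- sum(!is.na(mut_loop) & mut_loop >= threshold)
  verdict <- if (length(sup) < min_positive) "not_folded"
             else if (mut_pos < min_positive) "folded"
             else "inconclusive"
  structure(list(verdict = verdict,
                 supporting_positions = if (verdict == "not_folded") integer(0) else sup,
                 threshold = threshold, min_positive = as.integer(min_positive)),
            class = "folding_call")
}

#' @export
print.folding_call <- function(x, ...) {
  cat(sprintf("<folding_call> %s (threshold %.2f; supporting loop positions: %s)\n",
              x$verdict, x$threshold,
              if (length(x$supporting_positions))
                paste(x$supporting_positions, collapse = ", ") else "none"))
  invisible(x)
}

#' Read probing lanes from a long-format table
#'
#' Expected columns: `position`, `nucleotide` (optional), `construct`
#' (`WT`/`MUT`), `cation` (`K`/`Li`), `replicate`, `intensity`. Comment lines
#' starting with `#` are ignored.
#'
#' @param path CSV path.
#' @return Data frame of lanes in long format.
#' @export
read_lanes <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("position", "construct", "cation", "replicate", "intensity")
  if (!all(need %in% names(df))) {
    stop("lanes table must have columns: ", paste(need, collapse = ", "))
  }
  df$construct <- toupper(df$construct)
  df$cation <- ifelse(toupper(df$cation) %in% c("K", "K+", "KCL"), "K", "Li")
  df
}

lanes_matrix <- function(lanes, construct, cation) {
  sel <- lanes[lanes$construct == construct & lanes$cation == cation, ,
               drop = FALSE]
  if (nrow(sel) == 0L) {
    stop(sprintf("no %s/%s lanes in input", construct, cation))
  }
  reps <- sort(unique(sel$replicate))
  pos <- sort(unique(sel$position))
  m <- matrix(NA_real_, nrow = length(pos), ncol = length(reps),
              dimnames = list(NULL, paste0("rep", reps)))
  for (j in seq_along(reps)) {
    r <- sel[sel$replicate == reps[j], , drop = FALSE]
    m[match(r$position, pos), j] <- r$intensity
  }
  if (anyNA(m)) stop(sprintf("missing positions in %s/%s lanes", construct, cation))
  m
}

#' Full probing analysis of one experiment
#'
#' Builds WT and mutant [ratio_profile()]s from a long-format lanes table and
#' calls folding with [call_folding()].
#'
#' @param lanes Long-format lanes data frame (see [read_lanes()]).
#' @param lengths Seven-part decomposition lengths of the probed hit.
#' @param threshold,min_positive Passed to [call_folding()].
#' @param normalize Passed to [ratio_profile()].
#' @return List with `wt`, `mut` (ratio profiles) and `call`.
#' @export
analyze_probing <- function(lanes, lengths, threshold = 2.0,
                            min_positive = 1L, normalize = "none") {
  pos <- decomposition_positions(lengths)
  seq_chr <- if ("nucleotide" %in% names(lanes)) {
    nt <- lanes[lanes$construct == "WT" & lanes$cation == "K" &
                  lanes$replicate == min(lanes$replicate), , drop = FALSE]
    paste(nt$nucleotide[order(nt$position)], collapse = "")
  } else NULL
  wt <- ratio_profile(lanes_matrix(lanes, "WT", "K"),
                      lanes_matrix(lanes, "WT", "Li"),
                      sequence = seq_chr, loop_positions = pos$loop,
                      track_positions = pos$track, normalize = normalize)
  mut <- ratio_profile(lanes_matrix(lanes, "MUT", "K"),
                       lanes_matrix(lanes, "MUT", "Li"),
                       loop_positions = pos$loop,
                       track_positions = pos$track, normalize = normalize)
  list(wt = wt, mut = mut,
       call = call_folding(wt, mut, threshold, min_positive))
}
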