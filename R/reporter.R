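# Dual-luciferase and qPCR fold-change statistics. The reporter readout is
# the Renilla:Firefly ratio per lysate (normalizing transfection
# efficiency); the effect size is the WT construct's ratio divided by the
# G/A mutant's, with significance from an unpaired Student's t test.

#' Significance stars for a p value
#'
#' `ns` at p >= 0.05, `*` below 0.05, `**` below 0.01, `***` below 0.001,
#' `****` below 0.0001.
#'
#' @param p Numeric vector of p values (NA allowed).
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 0.05, "*", "ns")))))
}

two_sample_p <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
    # degenerate: both groups constant
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Dual-luciferase WT/mutant fold change
#'
#' Per well the ratio `rluc / fluc` is computed; technical replicates are
#' averaged within each (construct, day) first, so independent experiment
#' days are the statistical unit. The fold change is the mean of the WT
#' day-level ratios divided by the mean of the mutant day-level ratios, and
#' the p value comes from a two-sample unpaired Student's t test (equal
#' variance) on the two day-level ratio lists. Well-level units (no
#' averaging of technical replicates first) are available via `unit`.
#'
#' @param wells Data frame with columns `construct` (`WT`/`MUT`), `day`,
#'   `tech_rep`, `rluc`, `fluc` (`fluc > 0`, `rluc >= 0`).
#' @param unit `"day"` (default; technical replicates treated as
#'   pseudo-replication) or `"well"`.
#' @param var_equal Use the equal-variance Student form (default) rather than
#'   Welch.
#' @return An object of class `reporter_result`: list with `fold`, `p_value`
#'   (`NA` with a warning when either construct has a single day), `stars`,
#'   `n_days`, and the per-construct unit-level ratios.
#' @export
luciferase_fold <- function(wells, unit = c("day", "well"), var_equal = TRUE) {
  unit <- match.arg(unit)
  need <- c("construct", "day", "tech_rep", "rluc", "fluc")
  if (!all(need %in% names(wells))) {
    stop("wells table must have columns: ", paste(need, collapse = ", "))
  }
  wells$construct <- toupper(wells$construct)
  wells$construct[wells$construct %in% c("MUTANT", "G/A", "GA")] <- "MUT"
  if (!all(c("WT", "MUT") %in% wells$construct)) {
    stop("both WT and MUT constructs are required")
  }
  if (any(wells$fluc <= 0)) stop("fluc must be positive")
  if (any(wells$rluc < 0)) stop("rluc must be non-negative")
  wells$ratio <- wells$rluc / wells$fluc
  grp <- function(cst) {
    w <- wells[wells$construct == cst, , drop = FALSE]
    if (unit == "day") {
      as.numeric(tapply(w$ratio, w$day, mean))
    } else w$ratio
  }
  wt <- grp("WT"); mut <- grp("MUT")
  n_days <- min(length(unique(wells$day[wells$construct == "WT"])),
                length(unique(wells$day[wells$construct == "MUT"])))
  fold <- mean(wt) / mean(mut)
  p <- two_sample_p(wt, mut, var_equal)
  if (is.na(p)) warning("fewer than 2 units per construct: p value undefined")
  structure(list(fold = fold, p_value = p, stars = significance_stars(p),
                 n_days = n_days, wt_ratios = wt, mut_ratios = mut,
                 unit = unit),
            class = "reporter_result")
}

#' @export
print.reporter_result <- function(x, ...) {
  cat(sprintf("<reporter_result> fold (WT/mutant) = %.3f, p = %s (%s), n_days = %d\n",
              x$fold,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
              if (is.na(x$stars)) "-" else x$stars, x$n_days))
  invisible(x)
}

#' qPCR mRNA-level WT/mutant ratio
#'
#' Default mode computes, per construct, the ratio of mean threshold cycles
#' `mean CT(Rluc) / mean CT(Fluc)`, and reports the WT ratio divided by the
#' mutant ratio — a literal ratio of cycle numbers, used as a transcription
#' -level control. The conventional `2^-ddCt` quantity is available via
#' `mode = "ddct"` but is never the default.
#'
#' @param records Data frame with columns `target` (`Rluc`/`Fluc`),
#'   `construct` (`WT`/`MUT`), `replicate`, `ct` (positive threshold cycles).
#' @param mode `"ct_ratio"` (default) or `"ddct"`.
#' @return Positive number (WT over mutant).
#' @export
qpcr_fold <- function(records, mode = c("ct_ratio", "ddct")) {
  mode <- match.arg(mode)
  need <- c("target", "construct", "replicate", "ct")
  if (!all(need %in% names(records))) {
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  }
  records$construct <- toupper(records$construct)
  records$construct[records$construct %in% c("MUTANT", "G/A", "GA")] <- "MUT"
  records$target <- ifelse(toupper(records$target) == "RLUC", "Rluc", "Fluc")
  if (any(records$ct <= 0)) stop("CT values must be positive")
  m <- function(cst, tgt) {
    v <- records$ct[records$construct == cst & records$target == tgt]
    if (!length(v)) stop(sprintf("missing CT values for %s/%s", cst, tgt))
    mean(v)
  }
  if (mode == "ct_ratio") {
    (m("WT", "Rluc") / m("WT", "Fluc")) / (m("MUT", "Rluc") / m("MUT", "Fluc"))
  } else {
    ddct <- (m("WT", "Rluc") - m("WT", "Fluc")) -
      (m("MUT", "Rluc") - m("MUT", "Fluc"))
    2^(-ddct)
  }
}
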