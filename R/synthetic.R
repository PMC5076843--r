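# Seeded generators for every input the toolkit consumes, with known ground
# truth. All generators are pure functions of their arguments including the
# seed: the global RNG state is saved and restored.

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a motif to plant in a synthetic transcript
#'
#' The planted motif has the requested track and loop geometry. In the
#' default `no_g_runs` composition, loops are G-free and background editing
#' guarantees the scanner recovers the plant exactly; the recorded truth is
#' the canonical lazy parse (all tracks take their minimal 3 guanines, spare
#' track guanines are absorbed by the following loop, spare guanines of the
#' last track are left outside the match). The spec is rejected as
#' infeasible when the canonical parse would push a loop outside its pattern
#' bounds. In `adversarial_g_runs` mode, loops may contain guanine runs that
#' create multi-parse neighbourhoods; no exact-recovery guarantee is made
#' and the truth row is flagged.
#'
#' @param loop_lengths Three loop lengths.
#' @param track_lengths Four track lengths, each at least 3 (default all 3).
#' @param loop_composition `"no_g_runs"` (default) or `"adversarial_g_runs"`.
#' @param region Target region, `"utr5"` or `"utr3"`.
#' @param position Optional 1-based position within the target UTR.
#' @return An object of class `plant_spec` with the inferred built-in
#'   pattern (`PLL1` when loop 1 is long, `PLL3` when loop 3 is long,
#'   `CANONICAL` otherwise) and the canonical truth decomposition.
#' @export
plant_spec <- function(loop_lengths, track_lengths = c(3L, 3L, 3L, 3L),
                       loop_composition = c("no_g_runs", "adversarial_g_runs"),
                       region = c("utr3", "utr5"), position = NULL) {
  loop_composition <- match.arg(loop_composition)
  region <- match.arg(region)
  track_lengths <- as.integer(track_lengths)
  loop_lengths <- as.integer(loop_lengths)
  stopifnot(length(track_lengths) == 4L, length(loop_lengths) == 3L,
            all(track_lengths >= 3L), all(loop_lengths >= 1L))
  long1 <- loop_lengths[1] >= 8L
  long3 <- loop_lengths[3] >= 8L
  adversarial <- loop_composition == "adversarial_g_runs"
  if (long1 && long3 && !adversarial) {
    stop("infeasible plant: both loop 1 and loop 3 long matches no single built-in pattern")
  }
  pattern <- g4_pattern_builtin(
    if (long1) "PLL1" else if (long3) "PLL3" else "CANONICAL")
  # canonical lazy parse: tracks 3/3/3/3, spare track Gs prepended to the
  # following loop, spare Gs of track 4 left outside the match
  canon_loops <- loop_lengths + (track_lengths[1:3] - 3L)
  lb <- pattern$loop_bounds
  if (!adversarial &&
      (any(canon_loops < lb[, "min"]) || any(canon_loops > lb[, "max"]))) {
    stop(sprintf(
      "infeasible plant: canonical loops (%s) violate %s bounds",
      paste(canon_loops, collapse = ", "), pattern$name))
  }
  structure(list(track_lengths = track_lengths, loop_lengths = loop_lengths,
                 loop_composition = loop_composition, region = region,
                 position = position, pattern = pattern$name,
                 canon_loop_lengths = canon_loops,
                 planted_length = sum(track_lengths) + sum(loop_lengths),
                 truth_length = 12L + sum(canon_loops)),
            class = "plant_spec")
}

sample_bases <- function(n, gc_fraction, exclude_g = FALSE) {
  if (n == 0L) return(character(0))
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, U = (1 - gc_fraction) / 2)
  if (exclude_g) {
    p <- p[c("A", "C", "U")]
    if (sum(p) == 0) p <- c(A = 1, C = 0, U = 1)
    p <- p / sum(p)
  }
  sample(names(p), n, replace = TRUE, prob = p)
}

build_plant_sequence <- function(spec, gc_fraction) {
  loops <- lapply(seq_len(3L), function(i) {
    n <- spec$loop_lengths[i]
    if (spec$loop_composition == "no_g_runs") {
      sample_bases(n, gc_fraction, exclude_g = TRUE)
    } else {
      # deliberately G-biased loops to create multi-parse neighbourhoods
      sample(c("A", "C", "G", "U"), n, replace = TRUE,
             prob = c(0.2, 0.15, 0.45, 0.2))
    }
  })
  paste(c(rep("G", spec$track_lengths[1]), loops[[1]],
          rep("G", spec$track_lengths[2]), loops[[2]],
          rep("G", spec$track_lengths[3]), loops[[3]],
          rep("G", spec$track_lengths[4])), collapse = "")
}

# Break G-runs of >= 3 whose footprint touches [lo, hi] (1-based, clipped),
# and strip single guanines at positions `forbid`. Returns list(chars, edits).
edit_g_runs <- function(ch, lo, hi, forbid = integer(0)) {
  n <- length(ch)
  lo <- max(1L, lo); hi <- min(n, hi)
  edits <- integer(0)
  resample1 <- function() sample(c("A", "C", "U"), 1L)
  for (i in forbid) {
    if (i >= 1L && i <= n && ch[i] == "G") {
      ch[i] <- resample1(); edits <- c(edits, i)
    }
  }
  if (lo <= hi) {
    for (i in lo:hi) {
      if (ch[i] == "G" &&
          i >= 3L && ch[i - 1L] == "G" && ch[i - 2L] == "G") {
        ch[i] <- resample1(); edits <- c(edits, i)
      }
    }
    # a run entering the window from the right (window end inside a run)
    i <- hi + 1L
    while (i <= n && i <= hi + 2L && ch[i] == "G" &&
           i >= 3L && ch[i - 1L] == "G" && ch[i - 2L] == "G") {
      ch[i] <- resample1(); edits <- c(edits, i)
      i <- i + 1L
    }
  }
  list(ch = ch, edits = edits)
}

#' Generate a synthetic transcriptome with planted PG4 motifs
#'
#' Background sequence is drawn i.i.d. at the requested base composition
#' (G and C each `gc_fraction / 2`, A and U each `(1 - gc_fraction) / 2`);
#' CDS bounds are chosen so both UTRs are at least 30 nt (longer when a
#' plant requires it). Plant `j` is inserted into transcript `j` at the
#' requested or a random position inside its target UTR. In `no_g_runs`
#' composition the background is then rejection-edited so that no G-run of
#' 3 or more remains within 41 nt of a plant boundary and no guanine is
#' directly adjacent to a plant; since no loop may exceed 40 nt, no
#' background match can then bridge into a plant, which makes planted-motif
#' recall exact by construction. Deterministic for a fixed seed.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_range Two-element transcript length range (nt).
#' @param gc_fraction Background G+C fraction in `[0, 1]`.
#' @param plants List of [plant_spec()]s, at most one per transcript
#'   (plant `j` goes into transcript `j`).
#' @param seed Integer seed.
#' @return List of class `synthetic_transcriptome`: `records` (named list of
#'   [transcript_record()]), `truth` (data frame: one row per plant with the
#'   0-based span and canonical decomposition the scanner must report),
#'   `edits` (data frame logging rejection-edited positions), and the call
#'   parameters.
#' @export
generate_transcriptome <- function(n_transcripts, length_range = c(400L, 800L),
                                   gc_fraction = 0.4, plants = list(),
                                   seed = 1L) {
  stopifnot(n_transcripts >= 1L, length(length_range) == 2L,
            gc_fraction >= 0, gc_fraction <= 1)
  if (inherits(plants, "plant_spec")) plants <- list(plants)
  if (length(plants) > n_transcripts) {
    stop("more plants than transcripts (one plant per transcript)")
  }
  with_seed(seed, {
    records <- vector("list", n_transcripts)
    truth <- list()
    edits <- list()
    for (i in seq_len(n_transcripts)) {
      spec <- if (i <= length(plants)) plants[[i]] else NULL
      need_utr <- if (is.null(spec)) 30L else max(30L, spec$planted_length + 4L)
      L <- sample(length_range[1]:length_range[2], 1L)
      L <- max(L, 2L * need_utr + 60L)
      utr5 <- if (!is.null(spec) && spec$region == "utr5") need_utr else 30L
      utr3 <- if (!is.null(spec) && spec$region == "utr3") need_utr else 30L
      utr5 <- max(utr5, 30L); utr3 <- max(utr3, 30L)
      cds_start <- utr5
      cds_end <- L - utr3
      ch <- sample_bases(L, gc_fraction)
      acc <- sprintf("SYNT%04d", i)
      gene <- sprintf("SYNGENE%03d", i)
      if (!is.null(spec)) {
        plen <- spec$planted_length
        ur <- if (spec$region == "utr5") c(0L, cds_start) else c(cds_end, L)
        pos_in_utr <- if (!is.null(spec$position)) as.integer(spec$position)
                      else sample(seq_len(ur[2] - ur[1] - plen + 1L), 1L)
        ps <- ur[1] + pos_in_utr  # 1-based plant start
        if (ps < 1L || ps + plen - 1L > ur[2]) {
          stop(sprintf("infeasible plant for transcript %d: does not fit its %s",
                       i, spec$region))
        }
        pseq <- strsplit(build_plant_sequence(spec, gc_fraction), "")[[1]]
        ch[ps:(ps + plen - 1L)] <- pseq
        ed1 <- edit_g_runs(ch, ps - 41L, ps - 1L, forbid = ps - 1L)
        ch <- ed1$ch
        ed2 <- edit_g_runs(ch, ps + plen, ps + plen + 40L, forbid = ps + plen)
        ch <- ed2$ch
        ed_pos <- c(ed1$edits, ed2$edits)
        if (length(ed_pos)) {
          edits[[length(edits) + 1L]] <- data.frame(
            accession = acc, position = ed_pos - 1L)
        }
        start0 <- ps - 1L
        truth[[length(truth) + 1L]] <- data.frame(
          accession = acc, gene = gene, pattern = spec$pattern,
          region_kind = spec$region,
          start = start0, end = start0 + spec$truth_length,
          t1 = 3L, l1 = spec$canon_loop_lengths[1],
          t2 = 3L, l2 = spec$canon_loop_lengths[2],
          t3 = 3L, l3 = spec$canon_loop_lengths[3], t4 = 3L,
          utr_position = if (spec$region == "utr5")
            utr_position(start0, 0L) else utr_position(start0, cds_end),
          adversarial = spec$loop_composition == "adversarial_g_runs",
          stringsAsFactors = FALSE)
      }
      records[[i]] <- transcript_record(acc, gene, paste(ch, collapse = ""),
                                        cds_start, cds_end)
    }
    names(records) <- vapply(records, `[[`, "", "accession")
    structure(list(
      records = records,
      truth = if (length(truth)) do.call(rbind, truth) else NULL,
      edits = if (length(edits)) do.call(rbind, edits) else NULL,
      params = list(n_transcripts = n_transcripts,
                    length_range = length_range,
                    gc_fraction = gc_fraction, seed = seed)),
      class = "synthetic_transcriptome")
  })
}

#' Write a synthetic transcriptome to disk
#'
#' Emits `transcripts.fa`, `annotation.tsv` and (when plants exist)
#' `truth.tsv` under `dir`.
#'
#' @param sim A [generate_transcriptome()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_transcriptome <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_transcriptome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcripts(sim$records, file.path(dir, "transcripts.fa"),
                    file.path(dir, "annotation.tsv"))
  if (!is.null(sim$truth)) {
    utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Generate a synthetic in-line probing experiment
#'
#' Emulates the loop-elevated K+/Li+ pattern of a folded quadruplex: Li+
#' lanes are lognormal noise around a common baseline; K+ lanes additionally
#' carry a `loop_ratio`-fold intensity gain at loop positions if and only if
#' the construct is WT and `folded` is `TRUE`. The mutant is always
#' unfolded. With `noise_sigma = 0` the K+/Li+ ratios are exactly
#' `loop_ratio` at WT loop positions and 1 elsewhere.
#'
#' `noise_sigma` is calibrated in ratio space: it is the lognormal sdlog of
#' the per-replicate K+/Li+ ratio, so each individual lane draws noise with
#' sdlog `noise_sigma / sqrt(2)`. All other contracts of this generator
#' (centres, the noiseless limit) are likewise stated on the ratio scale.
#'
#' @param lengths Seven-part decomposition lengths of the probed hit.
#' @param folded Does the WT construct fold?
#' @param noise_sigma Lognormal sdlog of the per-replicate K+/Li+ ratio
#'   (default 0.25); each lane draws `noise_sigma / sqrt(2)`.
#' @param loop_ratio K+/Li+ ratio at loop positions of a folded WT
#'   (default 3).
#' @param n_replicates Independent replicates per lane pair (default 2).
#' @param seed Integer seed.
#' @return Long-format lanes data frame (`position`, `nucleotide`,
#'   `construct`, `cation`, `replicate`, `intensity`) with attributes
#'   `lengths`, `folded`, `loop_positions`, `track_positions`.
#' @export
generate_probing_experiment <- function(lengths, folded = TRUE,
                                        noise_sigma = 0.25, loop_ratio = 3.0,
                                        n_replicates = 2L, seed = 1L) {
  pos <- decomposition_positions(lengths)
  n <- sum(as.integer(lengths))
  nt <- rep("A", n)
  nt[pos$track] <- "G"
  lane_sigma <- noise_sigma / sqrt(2)
  with_seed(seed, {
    rows <- list()
    for (construct in c("WT", "MUT")) {
      for (cation in c("K", "Li")) {
        for (rep_i in seq_len(n_replicates)) {
          base <- stats::rlnorm(n, meanlog = 0, sdlog = lane_sigma)
          if (construct == "WT" && cation == "K" && folded) {
            base[pos$loop] <- base[pos$loop] * loop_ratio
          }
          rows[[length(rows) + 1L]] <- data.frame(
            position = seq_len(n), nucleotide = nt, construct = construct,
            cation = cation, replicate = rep_i, intensity = base,
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "lengths") <- as.integer(lengths)
    attr(out, "folded") <- folded
    attr(out, "loop_positions") <- pos$loop
    attr(out, "track_positions") <- pos$track
    out
  })
}

#' Generate synthetic dual-luciferase wells
#'
#' The mutant Renilla:Firefly ratio is centred at 1 and the WT at
#' `true_fold`, with multiplicative lognormal noise at coefficient of
#' variation `cv` applied independently at the day level and at the
#' technical-replicate level. Firefly counts are lognormal around
#' `fluc_mean`. With `cv = 0` the estimated fold equals `true_fold` exactly.
#'
#' @param true_fold True WT/mutant fold change (> 0).
#' @param cv Coefficient of variation of each noise level (default 0.1).
#' @param n_days Independent experiment days (default 3).
#' @param n_tech Technical replicates per day (default 3).
#' @param seed Integer seed.
#' @param fluc_mean Mean Firefly counts (default 1e6).
#' @return Wells data frame accepted by [luciferase_fold()].
#' @export
generate_reporter_data <- function(true_fold, cv = 0.1, n_days = 3L,
                                   n_tech = 3L, seed = 1L, fluc_mean = 1e6) {
  stopifnot(true_fold > 0, cv >= 0, n_days >= 1L, n_tech >= 1L)
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    rows <- list()
    for (construct in c("WT", "MUT")) {
      centre <- if (construct == "WT") true_fold else 1
      for (d in seq_len(n_days)) {
        day_eff <- stats::rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        for (tr in seq_len(n_tech)) {
          tech_eff <- stats::rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
          fluc <- stats::rlnorm(1L, meanlog = log(fluc_mean), sdlog = sdlog)
          rows[[length(rows) + 1L]] <- data.frame(
            construct = construct, day = d, tech_rep = tr,
            rluc = centre * day_eff * tech_eff * fluc, fluc = fluc,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
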