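---
title: "Methods: scanning, scoring and testing long-loop RNA G-quadruplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning, scoring and testing long-loop RNA G-quadruplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadloop)
```

## The problem

An intramolecular RNA G-quadruplex (G4) is four tracks of consecutive
guanines, stacked as G-quartets and connected by three loops. The textbook
motif is `G3 N1-7 G3 N1-7 G3 N1-7 G3`, but naturally occurring G4s in human
mRNA UTRs can carry an oversized first or third loop of up to 40 nt.
`quadloop` implements the computational side of characterising such
irregular motifs: finding them in transcript UTRs, predicting whether they
fold, analysing in-line probing data that tests folding in vitro, and
computing the reporter-assay statistics that measure their effect on
translation.

## The motif and its parse semantics

A search pattern (`g4_pattern()`) is four G-tracks of at least
`min_track_len = 3` guanines separated by three bounded loops. The
built-ins are `PLL1` (loops 1–40 / 1–7 / 1–7), `PLL3` (1–7 / 1–7 / 1–40)
and `CANONICAL` (1–7 throughout). Loops admit any nucleotide, including G.

Because G-runs can be longer than a track and loops can contain G-runs, a
matching region usually admits many tilings. `scan_sequence()` commits to
one deterministic parse: the lexicographically smallest on

```
(start, |T1|, |T2|, |T3|, |T4|, |L1|, |L2|, |L3|)
```

i.e. leftmost start, then minimal ("lazy") tracks with track minimality
taking precedence over loop minimality, then minimal loops left to right.
After a hit is emitted, scanning resumes at its end, so hits never overlap
(the published searches kept only non-overlapping motifs). Both halves of
the ordering were forced by the published candidate decompositions:

* *Lazy, not greedy.* The TEF candidate begins with a 6-G run, of which the
  parse uses only the first three as track 1; the next three guanines start
  the 4-nt loop 1 (`GGGC`), giving loops 4/1/26. A greedy parse consumes
  the whole run and reports a different decomposition.
* *Tracks before loops.* In two candidates (RNF111, TNRC6C) a loop ends in
  a guanine adjacent to the next track. Interleaved lazy order
  (`|T1|, |L1|, |T2|, …`) would shorten the loop and grow the following
  track to four guanines; the published decompositions keep every track at
  three. Ordering all track lengths before all loop lengths reproduces
  them exactly, and keeps the scanner's output aligned with the motif's
  description as four identical series of at least three guanines.

Tracks are therefore not maximal G-runs: spare guanines beyond the lazy
parse belong to loops or flanks, and spare guanines after the fourth track
are left outside the match.

`scan_transcript()` keeps a hit when more than half of its nucleotides lie
in one UTR, so a motif that begins a few nucleotides inside the CDS (like
the TADA3 candidate, which starts 6 nt upstream of its 3' UTR) is retained.
Reported positions use the signed 1-based UTR convention: the first UTR
nucleotide is +1, the nucleotide before it is −1, and 0 does not exist.
`deduplicate_hits()` collapses isoform-redundant hits on the key
`(gene, matched sequence, region kind)`, keeping the first occurrence with
a multiplicity count. The original filter's key is unpublished, so
transcriptome-wide distinct-hit counts are not expected to be reproduced
bit-for-bit.

## cG/cC fold-propensity score

Guanines can only form quartets if they are not sequestered in Watson–Crick
pairs with nearby cytosines; long C-runs near a candidate therefore argue
against folding. The cG/cC score formalises this: every residue inside a
maximal run of length $L$ of its base contributes $w(L) = 10\,\min(L, 3)$,
so a run contributes $L \cdot w(L)$; cG and cC are the sums over G- and
C-runs, and the score is $cG/cC$. The scored window is the hit plus up to
25 nt of transcript (not genomic) context on each side, truncated at
transcript ends with achieved flank lengths recorded. Classification uses
the published thresholds: `likely_folded` at score ≥ 3.05, `unlikely` at
≤ 2.05, `ambiguous` between, boundaries inclusive toward their named
class. A window with no cytosine gets an infinite-score sentinel and is
`likely_folded`, never a division error.

The per-residue weight saturation at run length 3 is this package's
adopted form of the scoring system; the printed validation scores for the
published candidates depend on 25-nt transcript flanks that are not part
of the publication, so the saturation point is validated by the algebraic
property suite (per-residue summation oracle, complement inversion
$s(\overline{x}) = 1/s(x)$, U/T invariance, G-run monotonicity) rather
than against those six printed values; the acceptance test for the printed
values runs only when a user supplies the transcript windows as
`inst/extdata/refseq_candidate_windows.fa` and is otherwise an honest
failure.

## In-line probing analysis

In-line probing reads out backbone flexibility: loop nucleotides of a
folded G4 cleave faster under K⁺ (which stabilises quartets) than under
Li⁺ (which does not), while quartet guanines stay protected. The analysis
consumes per-nucleotide band intensities (gel densitometry itself is out
of scope), forms per-replicate K⁺/Li⁺ ratios, and averages across
replicates (mean ± SD, two replicates typical, no outlier rejection).
Positions with a zero Li⁺ intensity are flagged undefined and excluded.

A construct is called `folded` when at least `min_positive = 1` loop
position of the wild type has a mean ratio at or above the threshold 2.0
(inclusive) while the G/A mutant control has none; `not_folded` when no
wild-type loop position responds; `inconclusive` when the mutant responds
too — so comparing a profile against itself is never `folded`. The
single-position minimal criterion and the inclusive comparison are
documented, configurable choices; the published rule states the threshold
but not a count, and notes that parts of a long loop may be structured and
unresponsive.

Ratios are computed on raw lanes by default (`normalize = "none"`): the
documented input convention is lanes already equilibrated to equal loading,
in which case raw ratios are the quantity of interest, and the generator's
exactness contracts (ratios exactly `loop_ratio` at loops in the noiseless
limit) only hold on raw ratios. When lane loadings differ, per-lane
`"total"` normalization makes ratios invariant under any positive per-lane
rescaling; `"median"` is available as a robust alternative.

## Reporter statistics

The dual-luciferase readout is the Renilla:Firefly ratio per lysate
(normalising transfection efficiency); the effect size is the mean
wild-type ratio divided by the mean G/A-mutant ratio. Technical replicates
are averaged within each experiment day first, and the unpaired
equal-variance Student's t test runs on the day-level ratio lists —
days are the independent unit; the three technical replicates are
pseudo-replication. A well-level mode exists behind a flag. Stars follow
the conventional mapping (`*` < 0.05, `**` < 0.01, `***` < 0.001,
`****` < 0.0001). Degenerate inputs are handled explicitly: identical
constant groups give p = 1, constant unequal groups p = 0, and a single
day yields the fold with an undefined p and a warning.

The qPCR transcription-level control is implemented literally as published:
per construct the ratio of mean threshold cycles CT(Rluc)/CT(Fluc), then
WT over mutant. This is not the conventional ΔΔCt quantity; whether the
published wording meant literal cycle ratios cannot be resolved from the
text, so the conventional $2^{-\Delta\Delta C_t}$ is available behind
`mode = "ddct"` but is never the default.

## Synthetic data: what it emulates, and what a green test establishes

All generators are pure functions of their arguments including the seed.

**Transcriptomes** (`generate_transcriptome()`): i.i.d. background at a
requested GC fraction (default 0.4, a realistic mRNA composition; G and C
each take half the GC mass), transcript lengths 400–800 nt, CDS bounds
leaving UTRs of at least 30 nt. Planted motifs have requested track/loop
geometry; in the default `no_g_runs` composition the loops are G-free and
the background is rejection-edited so that no G-run of three or more
survives within 41 nt of a plant boundary and no guanine touches a plant.
Because no loop may exceed 40 nt, no background match can bridge such a
buffer into a plant, which makes 100% recall a theorem rather than an
empirical observation — the corresponding acceptance test checks the
implementation, not the luck of the seed. Recorded truth is the canonical
lazy parse (tracks of exactly three guanines; spare track guanines are
absorbed by the following loop, spare guanines of the last track fall
outside the match), and plants whose canonical parse would overflow a loop
bound are rejected as infeasible. The adversarial composition instead
biases loops toward guanine to create multi-parse neighbourhoods; there
the scanner is held to the exhaustive-tiling oracle, not to the planted
geometry. These transcriptomes emulate none of the realities of RefSeq —
isoform structure, composition heterogeneity, repeats — so green recall
tests establish scanner correctness, not expected performance on a real
transcriptome snapshot, and the published transcriptome-wide hit counts
(tens of thousands, tied to an August-2014 snapshot) are explicitly not
reproduced.

**Probing experiments** (`generate_probing_experiment()`): Li⁺ lanes are
lognormal noise around a common baseline; K⁺ lanes carry the
`loop_ratio`-fold gain (default 3.0, matching loop ratios well clear of
the threshold 2) at loop positions iff the construct is wild type and
folded; the mutant never folds. `noise_sigma` (default 0.25) is the
lognormal sdlog of the per-replicate K⁺/Li⁺ ratio; each lane draws
sdlog `noise_sigma`/√2. The ratio-space calibration is deliberate: the
generator's other contracts (centres, noiseless limits) are stated on
ratios, and it is the reading under which the classifier-accuracy
acceptance criterion (≥ 95% over 200 seeded experiments) is attainable at
the published exemplar geometry — under a per-lane reading the ratio noise
inflates by √2 and stray single-position exceedances in 31-loop-position
profiles cap accuracy near 86% regardless of implementation. The
acceptance test keeps that hardest published geometry (loops 4/1/26).

**Reporter wells** (`generate_reporter_data()`): mutant ratio centred at 1,
wild type at the true fold, with mean-1 lognormal noise at the given CV
(default 0.1, a typical day-to-day spread for the assay) applied
independently at day and technical-replicate level; the design mirrors the
published three days × three technical replicates. The fold estimator is a
ratio of means and carries a small Jensen bias of order CV²/3; at the
default CV this is ~0.4%, within the ±2 SE recovery band used by the
acceptance test.

## Numerical and interface choices

* Internal coordinates are 0-based half-open; all reported UTR positions
  use the signed 1-based convention above.
* Ambiguity codes are rejected by default; a permissive mode maps them to
  the sentinel `N`, which can sit in loops but never in a G-track or
  C-run.
* The alphabet is normalised once (uppercase, T→U); the scanner refuses
  unnormalised input rather than guessing.
* Seeds: every generator takes one, saves and restores the global RNG
  state, and is byte-reproducible.
* CLI outputs echo their configuration as `#key=value` comment lines and
  use exit codes 0/1/2 for ok/usage/data errors.

## Known limitations

* No thermodynamic stability modelling, sliding-window G4 propensity
  scores, DNA G4s, two-quartet motifs or bulged tracks.
* One record per accession; no genome-coordinate mapping.
* The isoform-deduplication key is this package's choice; published
  distinct-hit counts will differ.
* Gel image quantification and SAFA file parsing are out of scope; probing
  input is a documented CSV convention.
* The DDX43 candidate's printed geometry is internally inconsistent
  (parts sum to 25 nt against a printed length of 29) and is excluded from
  reconstruction fixtures.
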