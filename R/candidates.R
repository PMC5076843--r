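# The 20 manually selected long-loop PG4 candidates used as worked examples.
# Tracks and loop sequences are transcribed from the published candidate
# tables (all four G-tracks are GGG for every candidate); loops are stored
# normalized (uppercase RNA). The DDX43 row is length-inconsistent as
# printed (tracks + loops sum to 25, printed length 29) and is flagged
# `length_consistent = FALSE`; its true track lengths are unrecoverable, so
# it is excluded from reconstruction fixtures.

#' Built-in long-loop PG4 candidate table
#'
#' Twenty manually curated UTR PG4 candidates (ten with an oversized loop 1,
#' ten with an oversized loop 3), with their transcript accession, UTR,
#' signed UTR position, printed total length and the three loop sequences.
#' All four G-tracks are `GGG`. The TADA3 candidate starts 6 nt upstream of
#' its 3' UTR (`utr_position = -6`), so the first 6 nt of its match lie in
#' the CDS.
#'
#' @return Data frame with columns `gene`, `accession`, `pattern`
#'   (`PLL1`/`PLL3`), `region_kind`, `utr_length`, `utr_position`, `length`
#'   (printed total length), `loop1`, `loop2`, `loop3`,
#'   `length_consistent`.
#' @export
pg4_candidates <- function() {
  df <- rbind(
    # gene, accession, region, utr_len, pos, len, loop1, loop2, loop3
    c("BNIP1", "NM_013978", "PLL1", "utr5", 104, 7, 30,
      "cgcugccccgagacu", "u", "ga"),
    c("DDX43", "NM_018665", "PLL1", "utr5", 344, 190, 29,
      "auagagagcgu", "c", "g"),
    c("AVPR1B", "NM_000707", "PLL1", "utr3", 340, 61, 33,
      "cacuggaaaugagagcu", "a", "uaa"),
    c("B3GNT8", "NM_198540", "PLL1", "utr3", 226, 45, 55,
      "gccggccccuggcucagccccuccuuccaggucuugau", "a", "agga"),
    c("CYSRT1", "NM_199001", "PLL1", "utr3", 255, 18, 65,
      "ccaggacccagacuucagcaaauguggcucacacagugcc", "acaugcc", "acaugc"),
    c("DAG1", "NM_004393", "PLL1", "utr3", 2419, 1612, 54,
      "aggaaugccuuucgcaauaauguauccauucccugauuga", "u", "u"),
    c("DUSP15", "NM_001012644", "PLL1", "utr3", 336, 189, 52,
      "ccggccugcugcagccaccuggugccuuaguccuu", "cu", "gga"),
    c("KIF26A", "NM_15656", "PLL1", "utr3", 1101, 119, 40,
      "agucucagagaggagacggagugu", "gga", "a"),
    c("SPHK2", "NM_001243876", "PLL1", "utr3", 633, 477, 54,
      "gccggcgcuaggauuugcacuaauguuccucuccccgc", "u", "ggc"),
    c("TADA3", "NM_006354", "PLL1", "utr3", 393, -6, 55,
      "uagcccucaccccugccucaggcugauuaucuggccua", "ga", "gaa"),
    c("GRIA1", "NM_000827", "PLL3", "utr5", 365, 297, 41,
      "aaa", "g", "aaacaccaaaucuaugauuggaccu"),
    c("RNF111", "NM_001270530", "PLL3", "utr5", 279, 151, 61,
      "agugu", "ugag", "auuucucucccacuuccgacucucccuagagucucaggau"),
    c("TEF", "NM_003216", "PLL3", "utr5", 116, 69, 43,
      "gggc", "c", "ggaggcgaggugcgcgagccgagucc"),
    c("DCTN5", "NM_032486", "PLL3", "utr3", 6603, 5366, 43,
      "a", "a", "aggaagcaagcaagugaacaaaugagucu"),
    c("DOK1", "NM_001197260", "PLL3", "utr3", 437, 91, 33,
      "u", "a", "gccaugcugugugagacca"),
    c("MTF1", "NM_005955", "PLL3", "utr3", 5569, 3473, 54,
      "u", "u", "uuuuccugagagacuuuguauaaugcugaauguguccaga"),
    c("PLXNB1", "NM_001130082", "PLL3", "utr3", 632, 250, 58,
      "aguu", "gacuaa", "cuuccagagaguggcuggaagagacuccaggccccu"),
    c("PTPRU", "NM_133178", "PLL3", "utr3", 1152, 965, 30,
      "u", "u", "aaggucucuuuaaaau"),
    c("STRIP2", "NM_020704", "PLL3", "utr3", 2569, 95, 42,
      "cucuucu", "ggcucuu", "ccuaaagauggugcaa"),
    c("TNRC6C", "NM_018996", "PLL3", "utr3", 3990, 3775, 54,
      "aacucg", "gacagga", "cagcacaguguaagcuaaagcccugugua"))
  out <- data.frame(
    gene = df[, 1], accession = df[, 2], pattern = df[, 3],
    region_kind = df[, 4],
    utr_length = as.integer(df[, 5]), utr_position = as.integer(df[, 6]),
    length = as.integer(df[, 7]),
    loop1 = toupper(df[, 8]), loop2 = toupper(df[, 9]),
    loop3 = toupper(df[, 10]),
    stringsAsFactors = FALSE)
  out$length_consistent <- 12L + nchar(out$loop1) + nchar(out$loop2) +
    nchar(out$loop3) == out$length
  out
}

#' Reconstruct a candidate PG4 sequence from its tracks and loops
#'
#' Concatenates `track1 + loop1 + track2 + loop2 + track3 + loop3 + track4`
#' (all tracks `GGG`) for the named candidate gene.
#'
#' @param gene Candidate gene symbol present in [pg4_candidates()].
#' @return Normalized RNA string of the reconstructed PG4.
#' @export
candidate_sequence <- function(gene) {
  cand <- pg4_candidates()
  i <- match(gene, cand$gene)
  if (is.na(i)) stop(sprintf("unknown candidate gene '%s'", gene))
  paste0("GGG", cand$loop1[i], "GGG", cand$loop2[i], "GGG",
         cand$loop3[i], "GGG")
}
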