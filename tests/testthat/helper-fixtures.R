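`%+%` <- function(a, b) paste0(a, b)

make_tempdir <- function() {
  d <- tempfile("quadloop-test-")
  dir.create(d)
  d
}

# transcript with a given PG4 sequence planted at a 0-based offset; the
# background is G/C-free so the plant is the only possible match
fixture_transcript <- function(pg4, at, total = at + nchar(pg4) + 30L,
                               cds_start = 30L, cds_end = total - 60L,
                               accession = "NM_TEST", gene = "TESTG") {
  stopifnot(at + nchar(pg4) <= total)
  set.seed(at + total)
  bg <- sample(c("A", "U"), total, replace = TRUE)
  bg[(at + 1L):(at + nchar(pg4))] <- strsplit(pg4, "")[[1]]
  transcript_record(accession, gene, paste(bg, collapse = ""),
                    cds_start, cds_end)
}
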