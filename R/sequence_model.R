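RNA_ALPHABET <- c("A", "C", "G", "U")
# IUPAC ambiguity codes collapsed to the generic sentinel "N" in permissive
# mode; "N" can never be part of a G-track or a C-run.
IUPAC_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases the input and maps T to U so that both RNA sequences and DNA
#' templates can be fed to the scanner. By default any character outside
#' `A/C/G/T/U` (either case) is rejected with an error naming the first
#' offending position. In permissive mode IUPAC ambiguity codes are mapped to
#' the sentinel `"N"`, which is treated as a generic loop nucleotide and can
#' never belong to a G-track or a C-run.
#'
#' @param raw Non-empty character scalar.
#' @param permissive Logical; map ambiguity codes to `"N"` instead of failing.
#' @return A character scalar over `A/C/G/U` (plus `N` in permissive mode).
#' @examples
#' normalize_alphabet("ggaTTu")  # "GGAUUU"
#' @export
normalize_alphabet <- function(raw, permissive = FALSE) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("'raw' must be a non-empty character scalar")
  }
  s <- chartr("t", "u", toupper(raw))
  s <- chartr("T", "U", s)
  if (permissive) {
    s <- chartr(paste(IUPAC_AMBIGUITY, collapse = ""),
                strrep("N", length(IUPAC_AMBIGUITY)), s)
  }
  ok <- c(RNA_ALPHABET, if (permissive) "N")
  bad <- regexpr(sprintf("[^%s]", paste(ok, collapse = "")), s)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d",
                 substr(s, bad, bad), bad))
  }
  s
}

#' Transcript record with CDS boundaries
#'
#' A transcript is a normalized RNA sequence together with 0-based half-open
#' CDS boundaries, from which the 5' UTR `[0, cds_start)` and the 3' UTR
#' `[cds_end, length)` are derived. Either UTR may be empty.
#'
#' @param accession Transcript identifier (RefSeq-style), unique per record.
#' @param gene Gene symbol.
#' @param sequence Nucleotide string; normalized via [normalize_alphabet()].
#' @param cds_start,cds_end 0-based half-open CDS offsets,
#'   `0 <= cds_start <= cds_end <= nchar(sequence)`.
#' @param permissive Passed to [normalize_alphabet()].
#' @return An object of class `transcript_record`.
#' @export
transcript_record <- function(accession, gene, sequence, cds_start, cds_end,
                              permissive = FALSE) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession),
            is.character(gene), length(gene) == 1L)
  sequence <- normalize_alphabet(sequence, permissive = permissive)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  n <- nchar(sequence)
  if (is.na(cds_start) || is.na(cds_end) ||
      cds_start < 0L || cds_start > cds_end || cds_end > n) {
    stop(sprintf(
      "invalid CDS bounds [%s, %s) for '%s' (sequence length %d)",
      cds_start, cds_end, accession, n))
  }
  structure(
    list(accession = accession, gene = gene, sequence = sequence,
         cds_start = cds_start, cds_end = cds_end),
    class = "transcript_record")
}

#' @export
print.transcript_record <- function(x, ...) {
  n <- nchar(x$sequence)
  cat(sprintf("<transcript_record> %s (%s), %d nt; 5'UTR %d nt | CDS %d nt | 3'UTR %d nt\n",
              x$accession, x$gene, n, x$cds_start,
              x$cds_end - x$cds_start, n - x$cds_end))
  invisible(x)
}

#' Regions tiling a transcript
#'
#' Returns the (possibly empty-filtered) 5' UTR, CDS and 3' UTR regions of a
#' transcript as a data frame of 0-based half-open intervals that tile
#' `[0, length)` without overlap.
#'
#' @param record A [transcript_record()].
#' @return Data frame with columns `transcript_accession`, `start`, `end`,
#'   `kind` (one of `utr5`, `cds`, `utr3`); zero-width regions are dropped.
#' @export
transcript_regions <- function(record) {
  stopifnot(inherits(record, "transcript_record"))
  n <- nchar(record$sequence)
  out <- data.frame(
    transcript_accession = record$accession,
    start = c(0L, record$cds_start, record$cds_end),
    end = c(record$cds_start, record$cds_end, n),
    kind = c("utr5", "cds", "utr3"),
    stringsAsFactors = FALSE)
  out[out$start < out$end, , drop = FALSE]
}

#' Signed 1-based position relative to a UTR start
#'
#' Converts a 0-based transcript offset to the signed 1-based coordinate
#' convention used for reporting positions within a UTR: the first UTR
#' nucleotide is position 1, and offsets upstream of the UTR start count back
#' from -1 with no position 0 (a hit starting 6 nt before the UTR reports -6).
#'
#' @param offset 0-based transcript offset(s).
#' @param utr_start 0-based transcript offset of the first UTR nucleotide.
#' @return Integer vector of signed positions (never 0).
#' @export
utr_position <- function(offset, utr_start) {
  offset <- as.integer(offset)
  utr_start <- as.integer(utr_start)
  ifelse(offset >= utr_start, offset - utr_start + 1L, offset - utr_start)
}

parse_fallback_header <- function(ids) {
  # convenience fallback: "accession|gene|cds_start..cds_end"
  m <- regmatches(ids, regexec("^([^|]+)\\|([^|]+)\\|(\\d+)\\.\\.(\\d+)$", ids))
  ok <- lengths(m) == 5L
  data.frame(
    accession = ifelse(ok, vapply(m, function(x) x[2], "", USE.NAMES = FALSE), NA),
    gene = ifelse(ok, vapply(m, function(x) x[3], "", USE.NAMES = FALSE), NA),
    cds_start = ifelse(ok, as.integer(vapply(m, function(x) x[4], "", USE.NAMES = FALSE)), NA),
    cds_end = ifelse(ok, as.integer(vapply(m, function(x) x[5], "", USE.NAMES = FALSE)), NA),
    stringsAsFactors = FALSE)
}

#' Read transcripts from FASTA plus a CDS annotation table
#'
#' Reads a (wrapped or unwrapped) FASTA file and joins it with a tab-delimited
#' annotation table with header `accession<TAB>gene<TAB>cds_start<TAB>cds_end`
#' (0-based half-open CDS bounds). FASTA records without an annotation row are
#' skipped with a warning. If `annotation_path` is `NULL`, CDS bounds are
#' parsed from FASTA headers of the form `accession|gene|cds_start..cds_end`.
#'
#' @param fasta_path Path to a FASTA file with unique record IDs.
#' @param annotation_path Path to the annotation TSV, or `NULL` for the
#'   header-parsing fallback.
#' @param permissive Passed to [normalize_alphabet()].
#' @return Named list of [transcript_record()] objects (names = accessions).
#' @export
read_transcripts <- function(fasta_path, annotation_path = NULL,
                             permissive = FALSE) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate FASTA record IDs")
  if (is.null(annotation_path)) {
    ann <- parse_fallback_header(ids)
    if (all(is.na(ann$accession))) {
      stop("no annotation table given and FASTA headers are not in ",
           "'accession|gene|cds_start..cds_end' form")
    }
    idx <- seq_along(ids)
    idx[is.na(ann$accession)] <- NA_integer_
  } else {
    ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
    need <- c("accession", "gene", "cds_start", "cds_end")
    if (!all(need %in% names(ann))) {
      stop("annotation table must have columns: ", paste(need, collapse = ", "))
    }
    idx <- match(ids, ann$accession)
  }
  missing_ann <- is.na(idx)
  if (any(missing_ann)) {
    warning(sprintf("skipping %d FASTA record(s) without annotation: %s",
                    sum(missing_ann),
                    paste(ids[missing_ann], collapse = ", ")))
  }
  keep <- which(!missing_ann)
  out <- lapply(keep, function(i) {
    j <- idx[i]
    transcript_record(
      accession = ann$accession[j], gene = ann$gene[j],
      sequence = as.character(seqs[[i]]),
      cds_start = ann$cds_start[j], cds_end = ann$cds_end[j],
      permissive = permissive)
  })
  names(out) <- vapply(out, `[[`, "", "accession")
  out
}

#' Write transcripts to FASTA plus an annotation table
#'
#' Inverse of [read_transcripts()]: writes the sequences to FASTA (one record
#' per transcript, header = accession) and the CDS bounds to a TSV so that a
#' read/write round trip reproduces sequences and CDS bounds exactly.
#'
#' @param records Named list of [transcript_record()] objects.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, `fasta_path`.
#' @export
write_transcripts <- function(records, fasta_path, annotation_path) {
  stopifnot(length(records) > 0L)
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "accession")
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- data.frame(
    accession = vapply(records, `[[`, "", "accession"),
    gene = vapply(records, `[[`, "", "gene"),
    cds_start = vapply(records, `[[`, 0L, "cds_start"),
    cds_end = vapply(records, `[[`, 0L, "cds_end"),
    stringsAsFactors = FALSE)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta_path)
}
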