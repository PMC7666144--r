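# UMI extraction and mosaic-end trimming of raw paired FASTQ.

#' Extract the UMI prefix from read 1 sequences
#'
#' The UMI is the first `umi_length` bases of the read; the returned
#' sequence/quality have that prefix removed. Reads whose length is not
#' strictly greater than `umi_length` yield `NA` (there would be no
#' remainder) and are meant to be rejected by the caller.
#'
#' @param seq1 Character vector of read-1 sequences.
#' @param qual1 Optional character vector of per-base qualities (same widths).
#' @param umi_length UMI length in bases (default 6).
#' @return A list with elements `umi`, `seq` and `qual` (each a character
#'   vector aligned with the input; `NA` where the read was too short).
#' @examples
#' extract_umi(paste0("ACGTTT", me_sequence(), "GGGG"))$umi
#' @export
extract_umi <- function(seq1, qual1 = NULL, umi_length = 6L) {
  stopifnot(umi_length >= 1L)
  w <- nchar(seq1)
  ok <- w > umi_length
  umi <- ifelse(ok, substr(seq1, 1L, umi_length), NA_character_)
  rem <- ifelse(ok, substring(seq1, umi_length + 1L), NA_character_)
  remq <- if (is.null(qual1)) NULL else
    ifelse(ok, substring(qual1, umi_length + 1L), NA_character_)
  list(umi = umi, seq = rem, qual = remq)
}

#' Locate the mosaic-end anchor in read sequences
#'
#' Finds the smallest start offset (0-based) at or before `max_offset` where
#' the ME sequence matches with at most `max_mismatches` mismatches.
#'
#' @param sequences Character vector (or `DNAStringSet`) of sequences.
#' @param max_offset Largest allowed 0-based start offset of the match.
#' @param max_mismatches Mismatch tolerance (default 0, exact match).
#' @param me_seq The anchor sequence; see [me_sequence()].
#' @return Integer vector of 0-based offsets, `NA` where no match was found.
#' @examples
#' locate_me(paste0("NNNNNN", me_sequence(), "ACGT"))
#' @export
locate_me <- function(sequences, max_offset = 50L, max_mismatches = 0L,
                      me_seq = me_sequence()) {
  subj <- if (inherits(sequences, "DNAStringSet")) sequences
          else Biostrings::DNAStringSet(sequences)
  off <- rep(NA_integer_, length(subj))
  wide <- Biostrings::width(subj) >= nchar(me_seq)
  if (any(wide)) {
    m <- Biostrings::vmatchPattern(me_seq, subj[wide],
                                   max.mismatch = max_mismatches,
                                   fixed = TRUE)
    st <- Biostrings::startIndex(m)
    first <- vapply(st, function(s)
      if (is.null(s) || length(s) == 0L) NA_integer_ else min(s) - 1L,
      integer(1))
    off[wide] <- first
  }
  off[!is.na(off) & off > max_offset] <- NA_integer_
  off
}

#' Trim a UMI-stripped read to the first genomic base after the ME anchor
#'
#' @param seq Character vector of UMI-stripped read-1 sequences.
#' @param qual Optional matching quality strings.
#' @param me_offset 0-based ME offsets from [locate_me()] (NA = no anchor).
#' @param min_length Minimum trimmed length to keep (default 30; shorter
#'   reads are rejected and reported as `NA`).
#' @param me_seq Anchor sequence (its width sets the trim point).
#' @return List with `seq` and `qual`; `NA` entries mark rejected reads.
#' @export
trim_to_me <- function(seq, qual = NULL, me_offset, min_length = 30L,
                       me_seq = me_sequence()) {
  gstart <- me_offset + nchar(me_seq) + 1L
  trimmed <- substring(seq, gstart)
  trimmed[is.na(me_offset)] <- NA_character_
  trimmed[!is.na(trimmed) & nchar(trimmed) < min_length] <- NA_character_
  tq <- NULL
  if (!is.null(qual)) {
    tq <- substring(qual, gstart)
    tq[is.na(trimmed)] <- NA_character_
  }
  list(seq = trimmed, qual = tq)
}

#' Preprocess a UMI-tagged paired FASTQ library
#'
#' Extracts the UMI from read 1 (optionally from both mates), locates the
#' mosaic-end anchor, trims read 1 to genomic sequence, appends the UMI to
#' the read name (`<name><sep><UMI>`) so it survives alignment, and writes
#' the tagged, trimmed pair. Every input pair is either kept or counted in
#' exactly one rejection category.
#'
#' @param r1,r2 Paths to the raw mate FASTQ files (gzip transparent).
#' @param out1,out2 Output FASTQ paths (compressed when ending in `.gz`).
#' @param umi_length UMI length in bases (default 6).
#' @param umi_from `"read1"` (default) takes the UMI from read 1 only;
#'   `"both"` concatenates the prefixes of both mates (and strips read 2).
#' @param me_seq,me_max_offset,me_max_mismatches Anchor search parameters,
#'   see [locate_me()].
#' @param min_length Minimum trimmed read-1 length (default 30).
#' @param umi_sep Separator between read name and UMI (default `"_"`).
#' @param stats_file Optional path for a one-row TSV of the statistics.
#' @return A `preprocess_stats` list: `pairs_in`, `pairs_kept`,
#'   `pairs_no_me`, `pairs_too_short` (and the output paths).
#' @export
process_fastq <- function(r1, r2, out1, out2,
                          umi_length = 6L,
                          umi_from = c("read1", "both"),
                          me_seq = me_sequence(),
                          me_max_offset = 50L,
                          me_max_mismatches = 0L,
                          min_length = 30L,
                          umi_sep = "_",
                          stats_file = NULL) {
  umi_from <- match.arg(umi_from)
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(s1) != length(s2))
    stop("truncated input: mate files differ in record count (",
         length(s1), " vs ", length(s2), ")")
  tok1 <- sub("\\s.*$", "", names(s1))
  tok2 <- sub("\\s.*$", "", names(s2))
  bad <- which(tok1 != tok2)
  if (length(bad))
    stop("mate-name mismatch at record ", bad[1], ": '", tok1[bad[1]],
         "' vs '", tok2[bad[1]], "'")

  n <- length(s1)
  seq1 <- unname(as.character(s1))
  q1 <- unname(as.character(S4Vectors::mcols(s1)$qualities))
  seq2 <- unname(as.character(s2))
  q2 <- unname(as.character(S4Vectors::mcols(s2)$qualities))

  too_short <- nchar(seq1) <= umi_length
  if (umi_from == "both") too_short <- too_short | nchar(seq2) <= umi_length

  ex1 <- extract_umi(seq1, q1, umi_length)
  umi <- ex1$umi
  rem <- ex1$seq
  remq <- ex1$qual
  if (umi_from == "both") {
    ex2 <- extract_umi(seq2, q2, umi_length)
    umi <- paste0(umi, ex2$umi)
    seq2 <- ex2$seq
    q2 <- ex2$qual
  }

  off <- rep(NA_integer_, n)
  idx <- which(!too_short)
  if (length(idx))
    off[idx] <- locate_me(rem[idx], max_offset = me_max_offset,
                          max_mismatches = me_max_mismatches, me_seq = me_seq)
  no_me <- !too_short & is.na(off)

  tr <- trim_to_me(rem, remq, off, min_length = min_length, me_seq = me_seq)
  trim_short <- !too_short & !no_me & is.na(tr$seq)
  keep <- !too_short & !no_me & !trim_short

  if (any(keep)) {
    nm <- paste0(tok1[keep], umi_sep, umi[keep])
    o1 <- Biostrings::DNAStringSet(tr$seq[keep])
    names(o1) <- nm
    o2 <- Biostrings::DNAStringSet(seq2[keep])
    names(o2) <- nm
    Biostrings::writeXStringSet(o1, out1, format = "fastq",
                                qualities = Biostrings::BStringSet(tr$qual[keep]),
                                compress = grepl("\\.gz$", out1))
    Biostrings::writeXStringSet(o2, out2, format = "fastq",
                                qualities = Biostrings::BStringSet(q2[keep]),
                                compress = grepl("\\.gz$", out2))
  } else {
    # still emit empty files so downstream tooling finds them
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), out1,
                                format = "fastq",
                                qualities = Biostrings::BStringSet(),
                                compress = grepl("\\.gz$", out1))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), out2,
                                format = "fastq",
                                qualities = Biostrings::BStringSet(),
                                compress = grepl("\\.gz$", out2))
  }

  stats <- structure(list(
    pairs_in = n,
    pairs_kept = sum(keep),
    pairs_no_me = sum(no_me),
    pairs_too_short = sum(too_short) + sum(trim_short),
    out1 = out1, out2 = out2
  ), class = "preprocess_stats")
  if (!is.null(stats_file))
    data.table::fwrite(as.data.frame(unclass(stats)[1:4]), stats_file,
                       sep = "\t")
  stats
}

#' @export
print.preprocess_stats <- function(x, ...) {
  cat("UMI preprocessing:\n")
  cat(sprintf("  pairs in:        %d\n", x$pairs_in))
  cat(sprintf("  pairs kept:      %d\n", x$pairs_kept))
  cat(sprintf("  no ME anchor:    %d\n", x$pairs_no_me))
  cat(sprintf("  too short:       %d\n", x$pairs_too_short))
  invisible(x)
}
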