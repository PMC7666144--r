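# Seeded simulator: genome, accessibility landscape with embedded
# footprints, Tn5 fragment libraries with UMIs, PCR amplification, FASTQ and
# alignment emission, and a complete ground-truth ledger.

#' Simulate a random genome
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @param gc GC fraction (default 0.5).
#' @param seed Optional integer seed (deterministic output).
#' @return Named `DNAStringSet`.
#' @export
sim_genome <- function(contig_lengths, gc = 0.5, seed = NULL) {
  stopifnot(all(contig_lengths >= 1), gc >= 0, gc <= 1)
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("chr", seq_along(contig_lengths))
  run_seeded(seed, {
    seqs <- vapply(contig_lengths, function(len) {
      paste0(sample(c("A", "T", "G", "C"), len, replace = TRUE,
                    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
             collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(contig_lengths)
    out
  })
}

#' Accessibility model for library simulation
#'
#' Describes the per-bp Tn5 insertion-rate landscape: a background rate,
#' peak intervals with rate multipliers, footprint intervals (inside peaks)
#' where the rate is depleted, and the fragment-length mixture.
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @param peaks `data.table(contig, start, end, multiplier)` (0-based
#'   half-open) or NULL for a flat landscape.
#' @param background_rate Relative insertion rate outside peaks (default 1).
#' @param footprints `data.table(contig, start, end, depletion)` with
#'   depletion in `[0, 1]` (1 = complete shielding), or NULL.
#' @param frag_mix Fragment-length mixture: list with `means`, `sds`,
#'   `weights`. The default emulates ATAC-seq insert sizes with a
#'   sub-nucleosomal component (mean 60, sd 15) and a mono-nucleosomal
#'   component (mean 200, sd 25), equally weighted.
#' @param min_frag_length Lower truncation of fragment lengths (default 40).
#' @return An `accessibility_model` list.
#' @export
sim_model <- function(contig_lengths, peaks = NULL, background_rate = 1,
                      footprints = NULL,
                      frag_mix = list(means = c(60, 200), sds = c(15, 25),
                                      weights = c(0.5, 0.5)),
                      min_frag_length = 40L) {
  stopifnot(background_rate >= 0, min_frag_length >= 10L,
            abs(sum(frag_mix$weights) - 1) < 1e-8)
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("chr", seq_along(contig_lengths))
  if (!is.null(peaks)) {
    peaks <- data.table::as.data.table(peaks)
    stopifnot(all(peaks$multiplier >= 0),
              all(peaks$contig %in% names(contig_lengths)),
              all(peaks$start >= 0),
              all(peaks$end <= contig_lengths[peaks$contig]))
  }
  if (!is.null(footprints)) {
    footprints <- data.table::as.data.table(footprints)
    stopifnot(all(footprints$depletion >= 0 & footprints$depletion <= 1))
    if (!is.null(peaks)) {
      inside <- IRanges::overlapsAny(dt_to_granges(footprints),
                                     dt_to_granges(peaks),
                                     type = "within")
      stopifnot(all(inside))
    }
  }
  structure(list(contig_lengths = contig_lengths, peaks = peaks,
                 background_rate = background_rate, footprints = footprints,
                 frag_mix = frag_mix,
                 min_frag_length = as.integer(min_frag_length)),
            class = "accessibility_model")
}

#' Convenience constructor: evenly spaced peaks with embedded footprints
#'
#' Places `n_peaks` peaks of width `peak_width` evenly along the first
#' contig, assigns them the given multipliers (recycled), and embeds
#' `footprints_per_peak` footprints of length `footprint_length` at evenly
#' spaced offsets inside each peak.
#'
#' @inheritParams sim_model
#' @param n_peaks,peak_width,multipliers Peak layout.
#' @param footprints_per_peak,footprint_length,depletion Footprint layout.
#' @return An `accessibility_model`.
#' @export
sim_peak_model <- function(contig_lengths, n_peaks, peak_width = 1000L,
                           multipliers = 10, background_rate = 1,
                           footprints_per_peak = 0L, footprint_length = 15L,
                           depletion = 0.9, ...) {
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("chr", seq_along(contig_lengths))
  cg <- names(contig_lengths)[1]
  len <- contig_lengths[[1]]
  gap <- (len - n_peaks * peak_width) / (n_peaks + 1)
  stopifnot(gap >= 0)
  ps <- as.integer(round(gap * seq_len(n_peaks) +
                           peak_width * (seq_len(n_peaks) - 1L)))
  peaks <- data.table::data.table(
    contig = cg, start = ps, end = ps + peak_width,
    multiplier = rep_len(multipliers, n_peaks))
  fps <- NULL
  if (footprints_per_peak > 0L) {
    off <- as.integer(round(peak_width * seq_len(footprints_per_peak) /
                              (footprints_per_peak + 1L)))
    fs <- as.vector(outer(off, ps, "+"))
    fps <- data.table::data.table(
      contig = cg, start = fs, end = fs + footprint_length,
      depletion = depletion)
  }
  sim_model(contig_lengths, peaks = peaks, background_rate = background_rate,
            footprints = fps, ...)
}

# Per-bp insertion-rate vectors, one per contig.
rate_field <- function(model) {
  out <- lapply(names(model$contig_lengths), function(cg) {
    r <- rep(model$background_rate, model$contig_lengths[[cg]])
    if (!is.null(model$peaks)) {
      pk <- model$peaks[contig == cg]
      for (i in seq_len(nrow(pk)))
        r[(pk$start[i] + 1L):pk$end[i]] <-
          model$background_rate * pk$multiplier[i]
    }
    if (!is.null(model$footprints)) {
      fp <- model$footprints[contig == cg]
      for (i in seq_len(nrow(fp))) {
        span <- (fp$start[i] + 1L):fp$end[i]
        r[span] <- r[span] * (1 - fp$depletion[i])
      }
    }
    r
  })
  names(out) <- names(model$contig_lengths)
  out
}

#' Draw true (pre-PCR) fragments from an accessibility model
#'
#' Both fragment ends are insertion events drawn from the per-bp rate field
#' (peak multiplier x background, depleted inside footprints): the
#' plus-strand insertion position is sampled from the field, the fragment
#' length from the mixture, and the resulting minus-strand insertion
#' position is accepted by thinning proportional to the field. UMIs are
#' i.i.d. uniform over the 4^6 6-mers.
#'
#' @param model An `accessibility_model`.
#' @param n Number of fragments.
#' @param seed Optional integer seed.
#' @return `data.table(frag_id, contig, start, end, umi)` with 0-based
#'   half-open fragment intervals.
#' @export
draw_fragments <- function(model, n, seed = NULL) {
  fields <- rate_field(model)
  cw <- vapply(fields, sum, numeric(1))
  if (sum(cw) <= 0) stop("total insertion rate is zero")
  maxr <- vapply(fields, max, numeric(1))
  mix <- model$frag_mix
  if (n == 0L)
    return(data.table::data.table(frag_id = integer(), contig = character(),
                                  start = integer(), end = integer(),
                                  umi = character()))
  run_seeded(seed, {
    parts <- list()
    got <- 0L
    while (got < n) {
      m <- as.integer(ceiling((n - got) * 1.5) + 100L)
      cg <- sample(names(fields), m, replace = TRUE, prob = cw)
      dt <- data.table::data.table(cg = cg)
      dt[, x1 := {
        f <- fields[[cg[1]]]
        sample.int(length(f), .N, replace = TRUE, prob = f) - 1L
      }, by = cg]
      comp <- sample.int(length(mix$weights), m, replace = TRUE,
                         prob = mix$weights)
      dt[, len := as.integer(round(stats::rnorm(m, mix$means[comp],
                                                mix$sds[comp])))]
      dt[, x2 := x1 + len - 10L]
      clen <- model$contig_lengths[dt$cg]
      # lengths below the floor are rejected (truncated mixture, no atom)
      valid <- dt$len >= model$min_frag_length &
        dt$x1 >= 4L & dt$x2 <= clen - 6L
      rate2 <- numeric(m)
      for (c2 in unique(dt$cg)) {
        idx <- which(dt$cg == c2 & valid)
        if (length(idx)) rate2[idx] <- fields[[c2]][dt$x2[idx] + 1L]
      }
      acc <- valid & stats::runif(m) < rate2 / maxr[dt$cg]
      hit <- dt[acc]
      if (nrow(hit)) {
        parts[[length(parts) + 1L]] <- hit
        got <- got + nrow(hit)
      }
    }
    all <- data.table::rbindlist(parts)[seq_len(n)]
    umis <- umi_universe(6L)[sample.int(4096L, n, replace = TRUE)]
    out <- data.table::data.table(
      frag_id = seq_len(n),
      contig = all$cg,
      start = all$x1 - 4L,
      end = all$x2 + 6L,
      umi = umis
    )
    out[]
  })
}

#' PCR-amplify fragments and sample sequenced reads
#'
#' Per-fragment copy numbers follow `1 + NegBinom(mu = mean_copies - 1,
#' size = dispersion)` (minimum one copy, mean exactly `mean_copies`);
#' `depth` reads are then sampled without replacement from the copy pool.
#' The first sampled copy of each fragment is the original
#' (`is_pcr_copy = FALSE`); later copies are PCR duplicates. Each read gets
#' a UMI-adapter spacer length drawn from \{6, 13, 20, 25\} bp.
#'
#' @param fragments Output of [draw_fragments()].
#' @param mean_copies Mean copy number per fragment (>= 1, default 3).
#' @param dispersion Negative-binomial size parameter (default 2; large
#'   values approach a shifted Poisson, small values are overdispersed).
#' @param depth Number of reads to sample; default: the whole copy pool
#'   (saturating).
#' @param seed Optional integer seed.
#' @return `data.table(read, frag_id, contig, start, end, umi, is_pcr_copy,
#'   spacer)`, one row per sequenced read pair.
#' @export
amplify <- function(fragments, mean_copies = 3, dispersion = 2,
                    depth = NULL, seed = NULL) {
  stopifnot(mean_copies >= 1)
  f <- data.table::as.data.table(fragments)
  run_seeded(seed, {
    copies <- if (mean_copies == 1) rep(1L, nrow(f))
              else 1L + stats::rnbinom(nrow(f), size = dispersion,
                                       mu = mean_copies - 1)
    pool <- rep.int(f$frag_id, copies)
    if (is.null(depth)) depth <- length(pool)
    if (depth > length(pool))
      stop("requested depth (", depth, ") exceeds the copy pool (",
           length(pool), ")")
    sel <- sample(pool, depth)
    reads <- data.table::data.table(
      read = sprintf("sim%08d", seq_len(depth)),
      frag_id = sel,
      is_pcr_copy = duplicated(sel),
      spacer = sample(c(6L, 13L, 20L, 25L), depth, replace = TRUE)
    )
    reads <- f[reads, on = "frag_id"]
    data.table::setcolorder(reads, c("read", "frag_id", "contig", "start",
                                     "end", "umi", "is_pcr_copy", "spacer"))
    reads[]
  })
}

#' Ground-truth ledger of a simulated library
#'
#' @param fragments True fragments from [draw_fragments()].
#' @param reads Sequenced reads from [amplify()].
#' @param model Optional `accessibility_model` (adds the embedded
#'   footprints).
#' @return A `sim_truth` list: the inputs, the per-coordinate duplicate
#'   classes (`n_reads`, `n_parents`, `n_umi_classes`), the true
#'   PCR-duplicate fraction, the natural-duplicate surplus (UMI classes
#'   beyond the first per coordinate), the number of distinct true
#'   fragments sampled, and the embedded footprints.
#' @export
sim_truth <- function(fragments, reads, model = NULL) {
  r <- data.table::as.data.table(reads)
  coord <- r[, .(n_reads = .N,
                 n_parents = data.table::uniqueN(frag_id),
                 n_umi_classes = data.table::uniqueN(umi)),
             by = .(contig, start, end)]
  structure(list(
    fragments = fragments,
    reads = r,
    coordinate_classes = coord,
    pcr_duplicate_fraction = mean(r$is_pcr_copy),
    natural_surplus = sum(coord$n_umi_classes - 1L),
    distinct_coordinate_umi_classes = sum(coord$n_umi_classes),
    true_unique_sampled = data.table::uniqueN(r$frag_id),
    footprints = if (!is.null(model)) model$footprints else NULL
  ), class = "sim_truth")
}

#' Write the simulated library as a UMI-tagged paired FASTQ
#'
#' Read 1 is `UMI (6 bp) + random spacer padding to the read's spacer
#' length + ME + genomic prefix of the fragment`; read 2 is the reverse
#' complement of the genomic suffix. Base qualities are constant ("I").
#'
#' @param reads Reads from [amplify()].
#' @param genome Named `DNAStringSet` from [sim_genome()].
#' @param r1,r2 Output FASTQ paths (compressed when ending in `.gz`).
#' @param read_length Genomic bases per mate (default 50; clipped to the
#'   fragment length for short fragments).
#' @param truth_file Optional TSV path for the per-read truth ledger.
#' @param seed Optional integer seed (spacer padding bases).
#' @return Invisibly, the truth `data.table` keyed by read name.
#' @export
emit_fastq <- function(reads, genome, r1, r2, read_length = 50L,
                       truth_file = NULL, seed = NULL) {
  r <- data.table::as.data.table(reads)
  gchar <- as.character(genome)
  run_seeded(seed, {
    flen <- r$end - r$start
    g1 <- pmin(read_length, flen)
    seq1g <- substring(gchar[r$contig], r$start + 1L, r$start + g1)
    g2 <- pmin(read_length, flen)
    seq2g <- substring(gchar[r$contig], r$end - g2 + 1L, r$end)
    seq2 <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq2g)))
    pads <- character(nrow(r))
    for (pl in setdiff(unique(r$spacer - 6L), 0L)) {
      idx <- which(r$spacer - 6L == pl)
      mat <- matrix(sample(c("A", "C", "G", "T"), pl * length(idx),
                           replace = TRUE), ncol = pl)
      pads[idx] <- do.call(paste0, as.data.frame(mat))
    }
    seq1 <- paste0(r$umi, pads, me_sequence(), seq1g)
    s1 <- Biostrings::DNAStringSet(seq1)
    names(s1) <- r$read
    s2 <- Biostrings::DNAStringSet(seq2)
    names(s2) <- r$read
    Biostrings::writeXStringSet(
      s1, r1, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seq1))),
      compress = grepl("\\.gz$", r1))
    Biostrings::writeXStringSet(
      s2, r2, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seq2))),
      compress = grepl("\\.gz$", r2))
    truth <- r[, .(read, frag_id, contig, start, end, umi, is_pcr_copy,
                   spacer)]
    if (!is.null(truth_file)) data.table::fwrite(truth, truth_file, sep = "\t")
    invisible(truth)
  })
}

#' Emit coordinate-sorted alignments for simulated reads
#'
#' Bypasses an external aligner: every read pair becomes a properly-paired
#' record pair at its exact simulated coordinates with MAPQ 60 and the UMI
#' appended to the query name. Optionally writes a coordinate-sorted SAM
#' file; always returns the fragment table ready for
#' [classify_fragments()].
#'
#' @param reads Reads from [amplify()].
#' @param contig_lengths Named contig lengths (for the SAM header).
#' @param sam_path Optional output SAM path.
#' @param read_length Mate length in bp (default 50, clipped to fragment).
#' @param umi_sep Separator for the query-name UMI suffix (default `"_"`).
#' @return List with `fragments` (`name`, `contig`, `start`, `end`, `umi`,
#'   `mapq`, `qualsum`) and `sam` (the path or NULL).
#' @export
emit_alignments <- function(reads, contig_lengths, sam_path = NULL,
                            read_length = 50L, umi_sep = "_") {
  r <- data.table::as.data.table(reads)
  frags <- r[, .(name = read, contig, start, end, umi,
                 mapq = 60L, qualsum = 0L)]
  data.table::setorder(frags, contig, start, end, name)
  if (!is.null(sam_path)) {
    flen <- r$end - r$start
    l1 <- pmin(read_length, flen)
    qname <- paste0(r$read, umi_sep, r$umi)
    rec1 <- data.table::data.table(
      qname = qname, flag = 99L, rname = r$contig, pos = r$start + 1L,
      mapq = 60L, cigar = paste0(l1, "M"), rnext = "=",
      pnext = r$end - l1 + 1L, tlen = flen, seq = "*", qual = "*")
    rec2 <- data.table::data.table(
      qname = qname, flag = 147L, rname = r$contig, pos = r$end - l1 + 1L,
      mapq = 60L, cigar = paste0(l1, "M"), rnext = "=",
      pnext = r$start + 1L, tlen = -flen, seq = "*", qual = "*")
    recs <- data.table::rbindlist(list(rec1, rec2))
    recs[, rname := factor(rname, levels = names(contig_lengths))]
    data.table::setorder(recs, rname, pos)
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                        as.integer(contig_lengths)))
    writeLines(header, sam_path)
    data.table::fwrite(recs, sam_path, sep = "\t", append = TRUE,
                       col.names = FALSE, quote = FALSE)
  }
  list(fragments = frags[], sam = sam_path)
}
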