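# Tn5 insertion counting, binning, duplication-rate diagnostics and QC.

#' Convert fragments to Tn5 insertion events
#'
#' Each properly paired fragment evidences two transposition events, one per
#' end. With 0-based half-open fragments `[start, end)`, the plus-strand
#' event sits at `start + 4` and the minus-strand event at `end - 6`
#' (the standard "forward strand +4 bp, negative strand -5 bp" shift
#' expressed in 0-based coordinates). Fragments shorter than 10 bp, for
#' which the two shifted events would cross, are skipped and counted.
#'
#' @param frags `data.table` with `contig`, `start`, `end`.
#' @return `data.table(contig, pos, strand)` with 0-based positions;
#'   attribute `"n_skipped"` counts skipped fragments.
#' @examples
#' insertions_from_fragments(data.table::data.table(
#'   contig = "chr1", start = 1000L, end = 1200L))
#' @export
insertions_from_fragments <- function(frags) {
  f <- data.table::as.data.table(frags)
  ok <- (f$end - f$start) >= 10L
  n_skipped <- sum(!ok)
  f <- f[ok]
  ev <- data.table::data.table(
    contig = rep(f$contig, 2L),
    pos = c(f$start + 4L, f$end - 6L),
    strand = rep(c("+", "-"), each = nrow(f))
  )
  data.table::setorder(ev, contig, pos)
  data.table::setattr(ev, "n_skipped", n_skipped)
  ev[]
}

#' Bin insertion events into fixed-width genomic bins
#'
#' Bins are half-open `[i*b, (i+1)*b)`; an event at position `p` falls in
#' bin `floor(p / b)`. All bins of every contig are reported, including
#' empty ones.
#'
#' @param events `data.table(contig, pos)` of 0-based insertion positions.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param bin_size Bin width in bp (default 250).
#' @return `data.table(contig, bin, count)`, dense over all bins.
#' @export
bin_track <- function(events, contig_lengths, bin_size = 250L) {
  ev <- data.table::as.data.table(events)
  unknown <- setdiff(unique(ev$contig), names(contig_lengths))
  if (length(unknown))
    stop("events on contigs without a declared length: ",
         paste(unknown, collapse = ", "))
  out <- data.table::rbindlist(lapply(names(contig_lengths), function(cg) {
    len <- contig_lengths[[cg]]
    nb <- as.integer(ceiling(len / bin_size))
    sub <- ev[contig == cg]
    if (nrow(sub) && (min(sub$pos) < 0L || max(sub$pos) >= len))
      stop("insertion position outside contig ", cg,
           " (length ", len, "): coordinate mishandling?")
    cnt <- if (nrow(sub)) tabulate(sub$pos %/% bin_size + 1L, nbins = nb)
           else integer(nb)
    data.table::data.table(contig = cg, bin = seq_len(nb) - 1L, count = cnt)
  }))
  out[]
}

#' Binned insertion counts under the three deduplication modes
#'
#' @param frags Classified fragments from [classify_fragments()].
#' @param contig_lengths Named integer vector of contig lengths.
#' @param bin_size Bin width in bp (default 250).
#' @param unit `"insertions"` counts both Tn5 insertion events per fragment
#'   (default); `"reads"` counts each fragment once, assigned to the bin of
#'   its plus-strand insertion site.
#' @return `data.table(contig, bin, nd, cd, ud)`.
#' @export
binned_modes <- function(frags, contig_lengths, bin_size = 250L,
                         unit = c("insertions", "reads")) {
  unit <- match.arg(unit)
  one_mode <- function(sub) {
    ev <- insertions_from_fragments(sub)
    if (unit == "reads") ev <- ev[strand == "+"]
    bin_track(ev, contig_lengths, bin_size)$count
  }
  base <- bin_track(data.table::data.table(contig = character(),
                                           pos = integer()),
                    contig_lengths, bin_size)
  base[, count := NULL]
  base[, nd := one_mode(frags)]
  base[, cd := one_mode(dedup_fragments(frags, "cd"))]
  base[, ud := one_mode(dedup_fragments(frags, "ud"))]
  base[]
}

#' Presumed PCR duplication rate
#'
#' `(nd - kept) / nd`, the fraction of counts removed by a deduplication
#' mode; 0 where `nd` is 0 (no evidence). Computed with `kept` from CD this
#' is the coordinate-based presumed PCR duplication rate; with `kept` from
#' UD it is the UMI duplication rate.
#'
#' @param nd,kept Non-negative count vectors with `kept <= nd`.
#' @return Numeric vector of rates in `[0, 1]`.
#' @export
duplication_rate <- function(nd, kept) {
  if (any(kept > nd)) stop("kept counts exceed ND counts")
  if (any(nd < 0 | kept < 0)) stop("counts must be non-negative")
  ifelse(nd == 0, 0, (nd - kept) / nd)
}

#' Duplication rates across accessibility deciles
#'
#' Ranks bins by ND accessibility (descending, ties broken by genomic
#' order), selects the most accessible bins either as a top fraction or by
#' a minimum ND count, splits the selection into `n_groups` contiguous rank
#' groups, and summarises per-bin duplication rates per group. Bins with
#' `nd == 0` are excluded (their rate is undefined). Decile 1 is the least
#' accessible group of the selection, decile `n_groups` the most accessible.
#'
#' @param bins `data.table(contig, bin, nd, cd, ud)` from [binned_modes()].
#' @param mode Which kept counts define the rate: `"cd"` or `"ud"`.
#' @param top_fraction Fraction of all bins to select (default 0.1).
#' @param min_count Alternative selection rule: keep bins with `nd >
#'   min_count` (overrides `top_fraction` when given).
#' @param n_groups Number of groups (default 10).
#' @return A `decile_summary` list with `summary`
#'   (`decile`, `n_bins`, `mean_rate`) and the per-bin table `bins`.
#' @export
decile_analysis <- function(bins, mode = c("cd", "ud"),
                            top_fraction = 0.1, min_count = NULL,
                            n_groups = 10L) {
  mode <- match.arg(mode)
  b <- data.table::as.data.table(bins)
  b <- b[nd > 0L]
  data.table::setorder(b, -nd, contig, bin)
  if (!is.null(min_count)) {
    sel <- b[nd > min_count]
  } else {
    k <- round(top_fraction * nrow(bins))
    sel <- head(b, k)
  }
  if (nrow(sel) < n_groups)
    stop("fewer than ", n_groups, " selected bins (", nrow(sel), ")")
  n <- nrow(sel)
  # rank 1 = most accessible; decile n_groups = most accessible
  sel[, decile := n_groups + 1L - as.integer(ceiling(seq_len(n) * n_groups / n))]
  sel[, kept := sel[[mode]]]
  sel[, rate := duplication_rate(nd, kept)]
  summary <- sel[, .(n_bins = .N, mean_rate = mean(rate)), by = decile]
  data.table::setorder(summary, decile)
  structure(list(summary = summary[], bins = sel[], mode = mode),
            class = "decile_summary")
}

#' @export
print.decile_summary <- function(x, ...) {
  cat(sprintf("Duplication rate by accessibility decile (%s mode):\n",
              toupper(x$mode)))
  print(x$summary)
  invisible(x)
}

#' Correlation between two binned tracks on the log2 scale
#'
#' Pearson correlation of `log2(count + pseudocount)`.
#'
#' @param a,b Equal-length count vectors.
#' @param pseudocount Added before the log transform (default 1).
#' @return List with `r` and `r_squared` (`NA` when either vector has zero
#'   variance).
#' @export
compare_tracks <- function(a, b, pseudocount = 1) {
  stopifnot(length(a) == length(b))
  la <- log2(a + pseudocount)
  lb <- log2(b + pseudocount)
  if (stats::sd(la) == 0 || stats::sd(lb) == 0) {
    warning("zero variance in a track; correlation undefined")
    return(list(r = NA_real_, r_squared = NA_real_))
  }
  r <- stats::cor(la, lb)
  list(r = r, r_squared = r^2)
}

#' Fraction of insertion events inside peaks (FRiP)
#'
#' @param events `data.table(contig, pos)` of 0-based insertion positions.
#' @param peaks Peak intervals (`GRanges`, or a table with `contig`,
#'   `start`, `end` in 0-based half-open coordinates); merged internally.
#' @return Fraction in `[0, 1]`; `NA` for an empty event set.
#' @export
frip <- function(events, peaks) {
  if (nrow(events) == 0L) {
    warning("empty event set; FRiP undefined")
    return(NA_real_)
  }
  gr <- GenomicRanges::reduce(as_interval_granges(peaks))
  mean(IRanges::overlapsAny(events_granges(events), gr))
}

#' TSS enrichment score
#'
#' Aggregates the insertion profile over `+/- flank` around transcription
#' start sites, normalises by the mean of the two outermost `edge_window`
#' segments, smooths with a centred moving average, and reports the
#' normalised value at the TSS. This is a documented standard convention
#' (ENCODE-style); a uniform background scores ~1.
#'
#' @param events `data.table(contig, pos)` of 0-based insertion positions.
#' @param tss TSS positions: `GRanges` (starts are used) or a table with
#'   `contig` and 0-based `pos`.
#' @param flank Half-width of the profile in bp (default 1000).
#' @param edge_window Width of each normalising edge segment (default 100).
#' @param smooth Moving-average window in bp (default 51).
#' @return List with `score` and the normalised `profile` (length
#'   `2*flank + 1`); `score` is `NA` when the edges have zero coverage.
#' @export
tss_enrichment <- function(events, tss, flank = 1000L, edge_window = 100L,
                           smooth = 51L) {
  if (inherits(tss, "GRanges")) {
    tpos <- GenomicRanges::start(tss) - 1L
    tcontig <- as.character(GenomicRanges::seqnames(tss))
  } else {
    tss <- data.table::as.data.table(tss)
    tpos <- tss$pos
    tcontig <- tss$contig
  }
  stopifnot(length(tpos) >= 1L)
  win <- GenomicRanges::GRanges(
    tcontig, IRanges::IRanges(pmax(1L, tpos + 1L - flank), tpos + 1L + flank))
  hits <- GenomicRanges::findOverlaps(events_granges(events), win)
  off <- events$pos[S4Vectors::queryHits(hits)] -
    tpos[S4Vectors::subjectHits(hits)] + flank + 1L
  width <- 2L * flank + 1L
  prof <- tabulate(off[off >= 1L & off <= width], nbins = width)
  edges <- mean(prof[c(seq_len(edge_window),
                       seq.int(width - edge_window + 1L, width))])
  if (edges == 0) {
    warning("zero edge coverage; TSS enrichment undefined")
    return(list(score = NA_real_, profile = rep(NA_real_, width)))
  }
  norm <- prof / edges
  sm <- as.numeric(stats::filter(norm, rep(1 / smooth, smooth), sides = 2))
  list(score = sm[flank + 1L], profile = norm)
}

#' Insert-size distribution of fragments
#'
#' @param frags Table with `start`, `end`.
#' @return `data.table(size, count)` sorted by size; counts sum to the
#'   number of fragments.
#' @export
insert_size_distribution <- function(frags) {
  f <- data.table::as.data.table(frags)
  if (nrow(f) == 0L)
    return(data.table::data.table(size = integer(), count = integer()))
  out <- f[, .(count = .N), by = .(size = end - start)]
  data.table::setorder(out, size)
  out[]
}

#' Match two peak sets by reciprocal overlap
#'
#' Pairs of peaks whose overlap length is at least `min_reciprocal` of each
#' peak's own length, matched greedily by descending overlap with every
#' peak used at most once.
#'
#' @param set_a,set_b Peak interval sets (`GRanges` or 0-based tables).
#' @param min_reciprocal Reciprocal overlap fraction (default 0.5).
#' @return `data.table(a, b, overlap)` of matched indices.
#' @export
match_peaks <- function(set_a, set_b, min_reciprocal = 0.5) {
  a <- as_interval_granges(set_a)
  b <- as_interval_granges(set_b)
  h <- GenomicRanges::findOverlaps(a, b)
  if (length(h) == 0L)
    return(data.table::data.table(a = integer(), b = integer(),
                                  overlap = integer()))
  qh <- S4Vectors::queryHits(h)
  sh <- S4Vectors::subjectHits(h)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(a[qh], b[sh]))
  ok <- ov >= min_reciprocal * GenomicRanges::width(a[qh]) &
    ov >= min_reciprocal * GenomicRanges::width(b[sh])
  qh <- qh[ok]; sh <- sh[ok]; ov <- ov[ok]
  o <- order(-ov)
  used_a <- logical(length(a)); used_b <- logical(length(b))
  keep <- logical(length(o))
  for (i in o) {
    if (!used_a[qh[i]] && !used_b[sh[i]]) {
      keep[i] <- TRUE
      used_a[qh[i]] <- TRUE
      used_b[sh[i]] <- TRUE
    }
  }
  data.table::data.table(a = qh[keep], b = sh[keep], overlap = ov[keep])
}
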