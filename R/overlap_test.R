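# Shuffle-within-peaks significance test for footprint/motif overlap.
#
# The hot path (one overlap evaluation per shuffle, n_shuffles + 1 per test)
# runs on plain integer vectors: the reference set is merged once per contig
# and overlap lengths are read off its cumulative-coverage function with
# findInterval. The public functions accept and return GRanges/tables.

# Merged, sorted reference intervals per contig with cumulative coverage.
# x: data.table(contig, start, end), 0-based half-open.
prep_reference <- function(x) {
  gr <- GenomicRanges::reduce(as_interval_granges(x))
  dt <- granges_to_dt(gr)
  lapply(split(dt, dt$contig), function(d) {
    d <- d[order(d$start)]
    list(rs = d$start, re = d$end, cum = cumsum(c(0, d$end - d$start)))
  })
}

# Total covered length of [a, b) against one contig's merged reference.
covered_at <- function(x, ref) {
  i <- findInterval(x, ref$rs)
  out <- numeric(length(x))
  nz <- i > 0L
  out[nz] <- ref$cum[i[nz]] + pmin(x[nz], ref$re[i[nz]]) - ref$rs[i[nz]]
  # x below the first interval or inside a gap after interval i:
  # pmin(x, re) - rs could exceed the interval width only if x > re (capped),
  # and is >= 0 because rs[i] <= x by construction.
  out
}

overlap_lengths <- function(contig, qs, qe, refs) {
  ov <- numeric(length(qs))
  for (cg in unique(contig)) {
    idx <- which(contig == cg)
    ref <- refs[[cg]]
    if (is.null(ref)) next
    ov[idx] <- covered_at(qe[idx], ref) - covered_at(qs[idx], ref)
  }
  ov
}

#' Fraction of query intervals overlapping a reference set
#'
#' A query interval counts as overlapping when the total length it shares
#' with the (merged) reference set is at least `min_frac` of the query's own
#' length. The fraction is measured against the query by default; set
#' `reciprocal = TRUE` to additionally require the same fraction of an
#' overlapped reference interval.
#'
#' @param query,reference Interval sets (`GRanges` or 0-based tables).
#' @param min_frac Required overlap fraction (default 0.5).
#' @param reciprocal Require the fraction on both sides (default FALSE).
#' @return Fraction of query intervals in `[0, 1]`.
#' @export
overlap_fraction <- function(query, reference, min_frac = 0.5,
                             reciprocal = FALSE) {
  q <- if (inherits(query, "GRanges")) granges_to_dt(query)
       else data.table::as.data.table(query)
  if (nrow(q) == 0L) stop("empty query set")
  if (reciprocal) {
    qgr <- as_interval_granges(query)
    r <- GenomicRanges::reduce(as_interval_granges(reference))
    h <- GenomicRanges::findOverlaps(qgr, r)
    if (length(h) == 0L) return(0)
    qh <- S4Vectors::queryHits(h)
    sh <- S4Vectors::subjectHits(h)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(qgr[qh], r[sh]))
    ok <- ov >= min_frac * GenomicRanges::width(qgr[qh]) &
      ov >= min_frac * GenomicRanges::width(r[sh])
    return(sum(tabulate(qh[ok], nbins = length(qgr)) > 0) / length(qgr))
  }
  refs <- prep_reference(reference)
  ov <- overlap_lengths(q$contig, q$start, q$end, refs)
  mean(ov >= min_frac * (q$end - q$start))
}

# Vectorised placement core: for each interval width w, pick a feasible peak
# with probability proportional to its number of start slots, then a uniform
# start. peaks: data.table(contig, start, end). Returns data.table.
shuffle_core <- function(w, peaks) {
  pw <- peaks$end - peaks$start
  out_contig <- character(length(w))
  out_start <- integer(length(w))
  for (uw in unique(w)) {
    idx <- which(w == uw)
    feas <- which(pw >= uw)
    if (!length(feas))
      stop("interval of length ", uw, " (e.g. #", idx[1], ") fits in no peak")
    slots <- pw[feas] - uw + 1L
    pick <- if (length(feas) == 1L) rep(feas, length(idx))
            else feas[sample.int(length(feas), length(idx),
                                 replace = TRUE, prob = slots)]
    out_contig[idx] <- peaks$contig[pick]
    out_start[idx] <- peaks$start[pick] +
      as.integer(floor(stats::runif(length(idx)) * (pw[pick] - uw + 1L)))
  }
  data.table::data.table(contig = out_contig, start = out_start,
                         end = out_start + w)
}

#' Shuffle intervals uniformly within a peak set
#'
#' Each interval is independently re-placed: a peak that can contain it is
#' chosen with probability proportional to the number of feasible start
#' positions (`peak length - interval length + 1`), and the start is uniform
#' within the feasible range. Interval lengths are preserved; shuffled
#' intervals may overlap each other; each placement lies entirely within a
#' single peak.
#'
#' @param intervals Intervals to shuffle (`GRanges` or 0-based table).
#' @param peaks Peak set (`GRanges` or 0-based table).
#' @param seed Optional integer seed for reproducible placement.
#' @return Shuffled `GRanges` with the same widths as the input.
#' @export
shuffle_within_peaks <- function(intervals, peaks, seed = NULL) {
  iv <- if (inherits(intervals, "GRanges")) granges_to_dt(intervals)
        else data.table::as.data.table(intervals)
  pk <- if (inherits(peaks, "GRanges")) granges_to_dt(peaks)
        else data.table::as.data.table(peaks)
  out <- run_seeded(seed, shuffle_core(iv$end - iv$start, pk))
  dt_to_granges(out)
}

#' Shuffle-based Z-test for footprint/motif overlap
#'
#' Computes the observed fraction of footprints overlapping motif sites
#' (by at least `min_frac` of the footprint length), builds a null
#' distribution by re-placing the footprints uniformly within the peaks
#' `n_shuffles` times, and reports a one-sided upper-tail Z-test for
#' enrichment.
#'
#' @param footprints,motif_sites,peaks Interval sets (`GRanges` or 0-based
#'   tables).
#' @param n_shuffles Number of shuffles (default 100).
#' @param min_frac Overlap fraction counted as a hit (default 0.5).
#' @param seed Optional integer seed; identical seeds give identical
#'   results.
#' @return A `shuffle_result` list: `observed_fraction`, `null_fractions`,
#'   `null_mean`, `null_sd`, `z`, `p` (one-sided upper) and `ci95` of the
#'   null mean. With a degenerate null (`null_sd == 0`), `z` and `p` are
#'   `NA` with a warning.
#' @export
shuffle_test <- function(footprints, motif_sites, peaks, n_shuffles = 100L,
                         min_frac = 0.5, seed = NULL) {
  fp <- if (inherits(footprints, "GRanges")) granges_to_dt(footprints)
        else data.table::as.data.table(footprints)
  if (nrow(fp) == 0L) stop("empty footprint set")
  pk <- if (inherits(peaks, "GRanges")) granges_to_dt(peaks)
        else data.table::as.data.table(peaks)
  refs <- prep_reference(motif_sites)
  w <- fp$end - fp$start
  frac_of <- function(d) {
    ov <- overlap_lengths(d$contig, d$start, d$end, refs)
    mean(ov >= min_frac * (d$end - d$start))
  }
  run_seeded(seed, {
    observed <- frac_of(fp)
    nulls <- vapply(seq_len(n_shuffles),
                    function(i) frac_of(shuffle_core(w, pk)),
                    numeric(1))
    m <- mean(nulls)
    s <- stats::sd(nulls)
    if (s == 0) {
      warning("degenerate null distribution (zero variance)")
      z <- NA_real_
      p <- NA_real_
    } else {
      z <- (observed - m) / s
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    ci <- m + c(-1, 1) * stats::qnorm(0.975) * s / sqrt(n_shuffles)
    structure(list(
      observed_fraction = observed,
      null_fractions = nulls,
      null_mean = m,
      null_sd = s,
      z = z,
      p = p,
      ci95 = ci,
      n_shuffles = n_shuffles
    ), class = "shuffle_result")
  })
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat("Shuffle-within-peaks overlap test:\n")
  cat(sprintf("  observed fraction: %.4f\n", x$observed_fraction))
  cat(sprintf("  null mean (sd):    %.4f (%.4f), n = %d shuffles\n",
              x$null_mean, x$null_sd, x$n_shuffles))
  cat(sprintf("  z = %.2f, one-sided P = %.3g\n", x$z, x$p))
  invisible(x)
}
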