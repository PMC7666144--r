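# Wellington-style binomial footprint scoring, footprint calling,
# footprint depth and cross-mode comparison.

#' Wellington binomial footprint P-value
#'
#' For a candidate footprint of length `l_fp` with shoulders of length
#' `l_sh` on each side, the P-value is the product of two lower-tail
#' binomial CDFs, one per strand:
#' \deqn{P = F(FP^+; FP^+ + SH^+, q)\; F(FP^-; FP^- + SH^-, q),\quad
#'       q = l_{fp} / (l_{fp} + l_{sh})}
#' where `FP` counts strand-specific Tn5 insertions inside the footprint,
#' `SH^+` counts plus-strand insertions in the upstream shoulder and `SH^-`
#' minus-strand insertions in the downstream shoulder. The lower tail makes
#' depletion inside the footprint significant. A zero-trial CDF is 1.
#'
#' @param fp_plus,sh_plus,fp_minus,sh_minus Non-negative insertion counts.
#' @param l_fp Footprint length in bp.
#' @param l_sh Shoulder length in bp (default 35).
#' @param log10 Return the base-10 logarithm of the P-value instead
#'   (numerically safe far below double precision).
#' @return Numeric vector of P-values (or log10 P-values). All arguments
#'   recycle.
#' @examples
#' wellington_pvalue(0, 10, 0, 10, l_fp = 11)  # (35/46)^20
#' @export
wellington_pvalue <- function(fp_plus, sh_plus, fp_minus, sh_minus,
                              l_fp, l_sh = 35L, log10 = FALSE) {
  stopifnot(all(l_fp >= 1), all(l_sh >= 1))
  if (any(c(fp_plus, sh_plus, fp_minus, sh_minus) < 0))
    stop("counts must be non-negative")
  q <- l_fp / (l_fp + l_sh)
  lp <- stats::pbinom(fp_plus, fp_plus + sh_plus, q, log.p = TRUE) +
    stats::pbinom(fp_minus, fp_minus + sh_minus, q, log.p = TRUE)
  if (log10) lp / log(10) else exp(lp)
}

#' Footprint score transform
#'
#' `score = log10(-log10(P))`, monotone decreasing in the P-value. The
#' outer logarithm is taken base 10 (the transform is monotone either way,
#' so footprint calling is unaffected by the base). `P >= 1` maps to
#' `-Inf`; `P = 0` maps to `+Inf` with a warning (use
#' [footprint_score_log10()] for underflow-safe scoring).
#'
#' @param p_value Numeric vector of P-values.
#' @return Numeric vector of scores.
#' @examples
#' footprint_score(1e-10)  # 1
#' @export
footprint_score <- function(p_value) {
  if (any(p_value < 0)) stop("P-values must be non-negative")
  if (any(p_value == 0))
    warning("P-value of 0: score is +Inf (underflow?)")
  footprint_score_log10(log10(p_value))
}

#' Footprint score from a base-10 log P-value
#'
#' @param log10p `log10` of the P-value (finite for P-values far below
#'   double-precision underflow).
#' @return `log10(-log10p)`; `-Inf` where `log10p >= 0`.
#' @export
footprint_score_log10 <- function(log10p) {
  ifelse(log10p >= 0, -Inf, log10(-log10p))
}

#' Merge two peak sets and enforce a minimum width
#'
#' Union-merges the peak sets; any merged interval shorter than `min_width`
#' is extended symmetrically about its midpoint to exactly `min_width`
#' (shifted right if that would cross the contig start), then re-merged.
#'
#' @param peaks_a,peaks_b Peak sets (`GRanges` or 0-based tables).
#' @param min_width Minimum interval width in bp (default 100).
#' @return Merged `GRanges`.
#' @export
prepare_regions <- function(peaks_a, peaks_b = NULL, min_width = 100L) {
  gr <- as_interval_granges(peaks_a)
  if (!is.null(peaks_b))
    gr <- c(gr, as_interval_granges(peaks_b))
  gr <- GenomicRanges::reduce(gr)
  short <- GenomicRanges::width(gr) < min_width
  if (any(short)) {
    ext <- GenomicRanges::resize(gr[short], min_width, fix = "center")
    shift <- pmax(0L, 1L - GenomicRanges::start(ext))
    ext <- GenomicRanges::shift(ext, shift)
    gr <- GenomicRanges::reduce(c(gr[!short], ext))
  }
  sort(gr)
}

# Per-position stranded insertion counts over [start, end) of one contig.
stranded_track <- function(events, contig, start, end) {
  w <- end - start
  sub <- events[events$contig == contig &
                  events$pos >= start & events$pos < end, ]
  idx <- sub$pos - start + 1L
  list(
    plus = tabulate(idx[sub$strand == "+"], nbins = w),
    minus = tabulate(idx[sub$strand == "-"], nbins = w),
    start = start
  )
}

#' Scan regions for transcription-factor footprints
#'
#' For every candidate start within a region and every footprint length in
#' `l_range`, computes the Wellington P-value with the upstream plus-strand
#' shoulder and downstream minus-strand shoulder of length `l_sh`; keeps the
#' minimal P-value per start; and accepts candidates below `p_threshold` in
#' ascending P-value order with greedy suppression of overlapping calls
#' (a called footprint blocks overlapping weaker candidates).
#'
#' @param events Stranded insertion events from
#'   [insertions_from_fragments()].
#' @param regions Regions to scan (`GRanges` from [prepare_regions()], or a
#'   0-based table). Shoulders may extend beyond a region; candidates whose
#'   shoulders would cross a contig boundary are skipped.
#' @param contig_lengths Named contig lengths (used to bound shoulders);
#'   inferred loosely from the events when omitted.
#' @param p_threshold Calling threshold (default `1e-30`).
#' @param l_range Candidate footprint lengths in bp (default `11:26`).
#' @param l_sh Shoulder length in bp (default 35).
#' @return `data.table(contig, start, end, l, log10p, p_value, score)` of
#'   non-overlapping footprints, sorted by coordinates.
#' @export
scan_footprints <- function(events, regions, contig_lengths = NULL,
                            p_threshold = 1e-30, l_range = 11:26,
                            l_sh = 35L) {
  reg <- if (inherits(regions, "GRanges")) granges_to_dt(regions)
         else data.table::as.data.table(regions)
  ev <- data.table::as.data.table(events)
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(split(c(ev$pos + 1L, reg$end),
                                   c(ev$contig, reg$contig)), max, 0)
  }
  log10_thr <- log10(p_threshold)
  calls <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    calls[[i]] <- scan_one_region(ev, reg$contig[i], reg$start[i], reg$end[i],
                                  contig_lengths[[reg$contig[i]]],
                                  log10_thr, l_range, l_sh)
  }
  out <- data.table::rbindlist(calls)
  if (nrow(out) == 0L)
    return(data.table::data.table(contig = character(), start = integer(),
                                  end = integer(), l = integer(),
                                  log10p = numeric(), p_value = numeric(),
                                  score = numeric()))
  data.table::setorder(out, contig, start)
  out[]
}

scan_one_region <- function(ev, contig, rs, re, contig_len,
                            log10_thr, l_range, l_sh) {
  if (re - rs < min(l_range)) return(NULL)
  ts <- max(0L, rs - l_sh)
  te <- min(contig_len, re + l_sh)
  tr <- stranded_track(ev, contig, ts, te)
  cp <- c(0, cumsum(tr$plus))
  cm <- c(0, cumsum(tr$minus))
  starts <- rs:(re - min(l_range))
  best_lp <- rep(Inf, length(starts))
  best_l <- rep(NA_integer_, length(starts))
  for (l in l_range) {
    s <- starts
    ok <- (s + l <= re) & (s - l_sh >= ts) & (s + l + l_sh <= te)
    if (!any(ok)) next
    idx <- s[ok] - ts            # 0-based offset into track
    fp_p <- cp[idx + l + 1L] - cp[idx + 1L]
    sh_p <- cp[idx + 1L] - cp[idx - l_sh + 1L]
    fp_m <- cm[idx + l + 1L] - cm[idx + 1L]
    sh_m <- cm[idx + l + l_sh + 1L] - cm[idx + l + 1L]
    lp <- wellington_pvalue(fp_p, sh_p, fp_m, sh_m, l_fp = l, l_sh = l_sh,
                            log10 = TRUE)
    better <- lp < best_lp[ok]
    if (any(better)) {
      w <- which(ok)[better]
      best_lp[w] <- lp[better]
      best_l[w] <- l
    }
  }
  cand <- which(best_lp < log10_thr)
  if (!length(cand)) return(NULL)
  cand <- cand[order(best_lp[cand], starts[cand])]
  accepted_s <- integer(0)
  accepted_e <- integer(0)
  keep <- integer(0)
  for (j in cand) {
    s <- starts[j]; e <- s + best_l[j]
    if (!length(accepted_s) || all(e <= accepted_s | s >= accepted_e)) {
      keep <- c(keep, j)
      accepted_s <- c(accepted_s, s)
      accepted_e <- c(accepted_e, e)
    }
  }
  data.table::data.table(
    contig = contig,
    start = starts[keep],
    end = starts[keep] + best_l[keep],
    l = best_l[keep],
    log10p = best_lp[keep],
    p_value = 10^best_lp[keep],
    score = footprint_score_log10(best_lp[keep])
  )
}

#' Footprint depth (FPD)
#'
#' Normalised contrast between flank insertion density and footprint
#' insertion density:
#' \deqn{FPD = (FKI/(2f) - FPI/L) / (FKI/(2f) + FPI/L)}
#' where `FKI` counts insertions (both strands) in the `f` bp upstream plus
#' the `f` bp downstream of the footprint (default `f = 50`, giving the
#' conventional `FKI/100`), `FPI` counts insertions inside the footprint
#' and `L` is its length. Bounded in `[-1, 1]`; `0/0` is defined as 0
#' (no evidence either way); invariant under uniform scaling of counts.
#'
#' @param events Insertion events (`contig`, `pos`).
#' @param footprints Footprint intervals (0-based table or `GRanges`).
#' @param flank Flank width `f` in bp (default 50).
#' @return Numeric vector of depths, one per footprint.
#' @export
fpd <- function(events, footprints, flank = 50L) {
  fp <- if (inherits(footprints, "GRanges")) granges_to_dt(footprints)
        else data.table::as.data.table(footprints)
  stopifnot(all(fp$end > fp$start))
  ev <- events_granges(events)
  inside <- GenomicRanges::GRanges(fp$contig,
                                   IRanges::IRanges(fp$start + 1L, fp$end))
  left <- GenomicRanges::GRanges(fp$contig,
                                 IRanges::IRanges(pmax(1L, fp$start - flank + 1L),
                                                  fp$start))
  right <- GenomicRanges::GRanges(fp$contig,
                                  IRanges::IRanges(fp$end + 1L, fp$end + flank))
  fpi <- GenomicRanges::countOverlaps(inside, ev)
  fki <- GenomicRanges::countOverlaps(left, ev) +
    GenomicRanges::countOverlaps(right, ev)
  l <- fp$end - fp$start
  a <- fki / (2 * flank)
  b <- fpi / l
  ifelse(a + b == 0, 0, (a - b) / (a + b))
}

# Rescore fixed intervals under one event set; footprint length for q is the
# interval width clipped to [l_min, l_max].
rescore_intervals <- function(events, intervals, l_sh = 35L,
                              l_min = 11L, l_max = 26L) {
  iv <- data.table::as.data.table(intervals)
  ev <- events_granges(events)
  plus <- ev[events$strand == "+"]
  minus <- ev[events$strand == "-"]
  inside <- GenomicRanges::GRanges(iv$contig,
                                   IRanges::IRanges(iv$start + 1L, iv$end))
  up <- GenomicRanges::GRanges(iv$contig,
                               IRanges::IRanges(pmax(1L, iv$start - l_sh + 1L),
                                                iv$start))
  down <- GenomicRanges::GRanges(iv$contig,
                                 IRanges::IRanges(iv$end + 1L, iv$end + l_sh))
  fp_p <- GenomicRanges::countOverlaps(inside, plus)
  sh_p <- GenomicRanges::countOverlaps(up, plus)
  fp_m <- GenomicRanges::countOverlaps(inside, minus)
  sh_m <- GenomicRanges::countOverlaps(down, minus)
  l_fp <- clamp(iv$end - iv$start, l_min, l_max)
  lp <- wellington_pvalue(fp_p, sh_p, fp_m, sh_m, l_fp = l_fp, l_sh = l_sh,
                          log10 = TRUE)
  list(log10p = lp, score = footprint_score_log10(lp))
}

#' Compare footprint sets called under two deduplication modes
#'
#' Classifies footprints as common (overlapping by at least one base) or
#' exclusive to either set, then merges the two sets and recomputes the
#' footprint score of every merged interval under both insertion tracks at
#' that fixed interval (footprint length clipped to `[11, 26]` bp for the
#' binomial success probability).
#'
#' @param a,b Footprint tables from [scan_footprints()].
#' @param events_a,events_b The stranded insertion events the two sets were
#'   called from.
#' @param l_sh Shoulder length used for rescoring (default 35).
#' @return List with `a_common`, `b_common`, `a_only`, `b_only` (row indices
#'   into `a`/`b`) and `rescored`:
#'   `data.table(contig, start, end, in_a, in_b, score_a, score_b)`.
#' @export
compare_footprint_sets <- function(a, b, events_a, events_b, l_sh = 35L) {
  gra <- dt_to_granges(a)
  grb <- dt_to_granges(b)
  a_common <- which(IRanges::overlapsAny(gra, grb))
  b_common <- which(IRanges::overlapsAny(grb, gra))
  union <- GenomicRanges::reduce(c(gra, grb))
  udt <- granges_to_dt(union)
  ra <- rescore_intervals(events_a, udt, l_sh = l_sh)
  rb <- rescore_intervals(events_b, udt, l_sh = l_sh)
  udt[, `:=`(in_a = IRanges::overlapsAny(union, gra),
             in_b = IRanges::overlapsAny(union, grb),
             score_a = ra$score, score_b = rb$score,
             log10p_a = ra$log10p, log10p_b = rb$log10p)]
  list(
    a_common = a_common,
    b_common = b_common,
    a_only = setdiff(seq_len(nrow(a)), a_common),
    b_only = setdiff(seq_len(nrow(b)), b_common),
    rescored = udt[]
  )
}

#' Mean insertion profile around a set of sites
#'
#' Averages per-position insertion counts across sites, aligned on each
#' site's centre; minus-strand sites are reversed before averaging.
#'
#' @param events Insertion events (`contig`, `pos`).
#' @param sites Site table with `contig`, `start`, `end` and optionally
#'   `strand` (0-based half-open), or a `GRanges`.
#' @param flank Half-width of the profile in bp (default 50).
#' @return Numeric vector of length `2*flank + 1`: mean insertions per site
#'   at each offset from the site centre.
#' @export
aggregate_profile <- function(events, sites, flank = 50L) {
  st <- if (inherits(sites, "GRanges")) {
    dt <- granges_to_dt(sites)
    dt$strand <- as.character(GenomicRanges::strand(sites))
    dt
  } else data.table::as.data.table(sites)
  stopifnot(nrow(st) >= 1L)
  if (!"strand" %in% names(st)) st$strand <- "+"
  center <- (st$start + st$end) %/% 2L
  win <- GenomicRanges::GRanges(
    st$contig, IRanges::IRanges(pmax(1L, center + 1L - flank),
                                center + 1L + flank))
  hits <- GenomicRanges::findOverlaps(events_granges(events), win)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  rel <- events$pos[qh] - center[sh]
  rel[st$strand[sh] == "-"] <- -rel[st$strand[sh] == "-"]
  width <- 2L * flank + 1L
  idx <- rel + flank + 1L
  tabulate(idx[idx >= 1L & idx <= width], nbins = width) / nrow(st)
}
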