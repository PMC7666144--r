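test_that("wellington_pvalue matches closed forms and boundary cases", {
  # zero insertions in the footprint, 10 per shoulder strand:
  # F(0; 10, q)^2 = ((1-q)^10)^2 with q = 11/46
  expect_equal(wellington_pvalue(0, 10, 0, 10, l_fp = 11),
               ((35 / 46)^10)^2, tolerance = 1e-12)
  # empty shoulders: CDF at n is 1 on both strands
  expect_equal(wellington_pvalue(5, 0, 5, 0, l_fp = 15), 1)
  # zero-trial CDF is 1
  expect_equal(wellington_pvalue(0, 0, 0, 0, l_fp = 15), 1)
  # symmetric in the two strand terms
  expect_equal(wellington_pvalue(2, 30, 3, 28, l_fp = 15),
               wellington_pvalue(3, 28, 2, 30, l_fp = 15))
  expect_error(wellington_pvalue(-1, 2, 0, 0, l_fp = 15), "non-negative")
})

test_that("wellington_pvalue agrees with the exhaustive pmf-summation oracle", {
  # every single-strand (FP, SH) pair with counts <= 30, every l_fp in 11:26
  grid <- expand.grid(fp = 0:30, sh = 0:30, l = 11:26)
  mine <- wellington_pvalue(grid$fp, grid$sh, 0, 0, l_fp = grid$l,
                            log10 = TRUE) * log(10)
  ora <- mapply(function(fp, sh, l) oracle_log_wellington(fp, sh, 0, 0, l),
                grid$fp, grid$sh, grid$l)
  expect_lt(max(abs(expm1(mine - ora))), 1e-9)

  # two-strand combinations on a fixed sample
  withr::with_seed(5, {
    idx <- data.frame(fp_p = sample(0:30, 300, TRUE), sh_p = sample(0:30, 300, TRUE),
                      fp_m = sample(0:30, 300, TRUE), sh_m = sample(0:30, 300, TRUE),
                      l = sample(11:26, 300, TRUE))
  })
  mine2 <- wellington_pvalue(idx$fp_p, idx$sh_p, idx$fp_m, idx$sh_m,
                             l_fp = idx$l, log10 = TRUE) * log(10)
  ora2 <- mapply(oracle_log_wellington, idx$fp_p, idx$sh_p, idx$fp_m,
                 idx$sh_m, idx$l)
  expect_lt(max(abs(expm1(mine2 - ora2))), 1e-9)

  # hand-checked spec-style case: FP+=2, SH+=30, FP-=3, SH-=28, l=15
  expect_equal(log(wellington_pvalue(2, 30, 3, 28, l_fp = 15)),
               oracle_log_wellington(2, 30, 3, 28, 15), tolerance = 1e-12)
})

test_that("decreasing footprint counts never increases the P-value", {
  for (fp in 1:20) {
    expect_lte(wellington_pvalue(fp - 1, 20, 5, 20, l_fp = 15, log10 = TRUE),
               wellington_pvalue(fp, 20, 5, 20, l_fp = 15, log10 = TRUE))
  }
})

test_that("footprint score transform and threshold equivalence", {
  expect_equal(footprint_score(1e-10), 1)
  expect_equal(footprint_score(0.1), 0)
  expect_equal(footprint_score(1e-30), log10(30))
  expect_equal(footprint_score(1), -Inf)
  expect_warning(inf <- footprint_score(0), "0")
  expect_equal(inf, Inf)
  # p < 1e-30  <=>  score > log10(30)
  ps <- 10^seq(-60, -1, by = 0.5)
  expect_identical(ps < 1e-30, footprint_score(ps) > log10(30))
})

test_that("prepare_regions merges peaks and extends short ones to 100 bp", {
  # 60-bp peak centred at 1000 -> [950, 1050)
  g <- prepare_regions(interval_table(970, 60))
  expect_equal(GenomicRanges::start(g) - 1L, 950L)
  expect_equal(GenomicRanges::end(g), 1050L)
  # 150-bp peak unchanged
  g2 <- prepare_regions(interval_table(0, 150))
  expect_equal(GenomicRanges::width(g2), 150L)
  # overlapping peaks merge
  g3 <- prepare_regions(interval_table(0, 150), interval_table(100, 150))
  expect_equal(length(g3), 1L)
  expect_equal(GenomicRanges::width(g3), 250L)
})

# Dense flat shoulders with notches of zero insertions.
notch_events <- function(notches, lo = 0L, hi = 400L, depth = 6L) {
  pos <- setdiff(lo:(hi - 1L), unlist(lapply(notches, function(n) n[1]:(n[2] - 1L))))
  rbind(dense_events(pos, "+", depth), dense_events(pos, "-", depth))
}

test_that("footprint scanning calls a constructed notch and nothing on flat tracks", {
  region <- interval_table(60, 280)
  flat <- notch_events(list(), depth = 6L)
  expect_equal(nrow(scan_footprints(flat, region, c(chr1 = 400L))), 0L)

  one <- notch_events(list(c(200L, 215L)), depth = 6L)
  fp <- scan_footprints(one, region, c(chr1 = 400L))
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$start, 200L)
  expect_equal(fp$end, 215L)
  expect_lt(fp$p_value, 1e-30)
})

test_that("greedy suppression yields non-overlapping calls, best P first", {
  two <- notch_events(list(c(150L, 165L), c(170L, 185L)), depth = 6L)
  fp <- scan_footprints(two, interval_table(60, 280), c(chr1 = 400L))
  expect_gte(nrow(fp), 2L)
  # pairwise non-overlapping
  o <- fp[order(start)]
  expect_true(all(o$start[-1] >= o$end[-nrow(o)]))
  # both notches are covered by calls
  gr <- dt_to_granges(fp)
  expect_true(all(IRanges::overlapsAny(dt_to_granges(
    interval_table(c(150, 170), 15)), gr)))
})

test_that("footprint depth hits its closed-form extremes and scaling invariance", {
  # flanks full, footprint empty -> 1
  ev_max <- rbind(dense_events(100:149, "+"), dense_events(170:219, "-"))
  fp <- data.table::data.table(contig = "chr1", start = 150L, end = 170L)
  expect_equal(fpd(ev_max, fp), 1)
  # footprint full, flanks empty -> -1
  ev_min <- dense_events(150:169, "+")
  expect_equal(fpd(ev_min, fp), -1)
  # uniform density -> 0 (FPI/L == FKI/100)
  ev_unif <- dense_events(100:219, "+", count = 2L)
  expect_equal(fpd(ev_unif, fp), 0)
  # no events at all -> 0 by convention
  expect_equal(fpd(ev_unif[0], fp), 0)
  # invariant under uniform count scaling
  ev1 <- rbind(dense_events(100:149, "+"), dense_events(155:160, "+"),
               dense_events(170:219, "-"))
  ev5 <- rbind(dense_events(100:149, "+", 5L), dense_events(155:160, "+", 5L),
               dense_events(170:219, "-", 5L))
  expect_equal(fpd(ev1, fp), fpd(ev5, fp))
  expect_true(all(abs(fpd(ev1, fp)) <= 1))
})

test_that("footprint set comparison classifies by >=1 bp overlap and rescores", {
  a <- data.table::data.table(contig = "chr1", start = c(100L, 300L),
                              end = c(115L, 315L))
  b <- data.table::data.table(contig = "chr1", start = c(114L, 500L),
                              end = c(129L, 515L))
  ev <- notch_events(list(c(100L, 129L)), lo = 0L, hi = 700L, depth = 4L)
  cmp <- compare_footprint_sets(a, b, ev, ev)
  expect_equal(cmp$a_common, 1L)  # one-base overlap counts
  expect_equal(cmp$b_common, 1L)
  expect_equal(cmp$a_only, 2L)
  expect_equal(cmp$b_only, 2L)
  # identical event sets give identical rescored scores
  expect_equal(cmp$rescored$score_a, cmp$rescored$score_b)
  # identical sets are all common
  cmp2 <- compare_footprint_sets(a, a, ev, ev)
  expect_equal(cmp2$a_common, seq_len(nrow(a)))
  expect_equal(length(cmp2$a_only), 0L)
})

test_that("aggregate_profile averages site-centred insertion counts", {
  ev <- dense_events(c(95, 100, 105), "+")
  site <- data.table::data.table(contig = "chr1", start = 90L, end = 110L,
                                 strand = "+")
  p <- aggregate_profile(ev, site, flank = 10L)
  expect_equal(length(p), 21L)
  expect_equal(p[11], 1)          # centre (pos 100)
  expect_equal(p[6], 1)           # pos 95 at offset -5
  # two identical sites: same mean profile
  p2 <- aggregate_profile(rbind(ev, dense_events(c(495, 500, 505), "+")),
                          rbind(site, data.table::data.table(
                            contig = "chr1", start = 490L, end = 510L,
                            strand = "+")), flank = 10L)
  expect_equal(p2, p)
  # minus-strand site is reversed
  pm <- aggregate_profile(dense_events(104, "+"),
                          data.table::data.table(contig = "chr1", start = 90L,
                                                 end = 110L, strand = "-"),
                          flank = 10L)
  expect_equal(which(pm == 1), 7L)  # offset +4 flips to -4
})
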