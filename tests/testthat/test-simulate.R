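test_that("simulated genomes are seed-deterministic with controlled GC", {
  a <- sim_genome(c(chr1 = 1000L), seed = 1)
  b <- sim_genome(c(chr1 = 1000L), seed = 1)
  expect_identical(as.character(a), as.character(b))
  # gc = 0: no G or C anywhere
  at <- sim_genome(c(chr1 = 2000L), gc = 0, seed = 2)
  expect_equal(sum(Biostrings::letterFrequency(at, c("G", "C"))), 0)
  # gc = 0.5 at length 1e5: binomial 3-sigma bound ~ 0.005
  g <- sim_genome(c(chr1 = 100000L), gc = 0.5, seed = 3)
  gc_frac <- sum(Biostrings::letterFrequency(g, c("G", "C"))) / 100000
  expect_lt(abs(gc_frac - 0.5), 3 * sqrt(0.25 / 100000))
})

test_that("model validation enforces rates, weights and footprint placement", {
  expect_error(sim_model(c(chr1 = 1000L),
                         frag_mix = list(means = 60, sds = 10, weights = 0.4)))
  expect_error(sim_model(c(chr1 = 1000L),
                         peaks = data.table::data.table(
                           contig = "chr1", start = 0L, end = 2000L,
                           multiplier = 2)))
  # footprint outside any peak is rejected
  expect_error(sim_model(c(chr1 = 1000L),
                         peaks = interval_table(100, 200)[, multiplier := 5][],
                         footprints = data.table::data.table(
                           contig = "chr1", start = 500L, end = 520L,
                           depletion = 0.9)))
})

test_that("fragment ends follow the accessibility field", {
  model <- sim_peak_model(c(chr1 = 50000L), n_peaks = 5L, peak_width = 1000L,
                          multipliers = 10)
  fr <- draw_fragments(model, 20000L, seed = 41)
  expect_equal(nrow(fr), 20000L)
  expect_true(all(fr$start < fr$end))
  expect_true(all(fr$start >= 0 & fr$end <= 50000))
  expect_true(all(grepl("^[ACGT]{6}$", fr$umi)))
  # both fragment ends are drawn from the rate field, so deep inside a
  # peak the end density scales with multiplier^2 relative to deep
  # background (both ends see the peak rate); use 300-bp interior margins
  # to avoid boundary mixing
  ev <- insertions_from_fragments(fr)
  interior <- function(dt, margin) dt_to_granges(
    data.table::data.table(contig = dt$contig, start = dt$start + margin,
                           end = dt$end - margin))
  pk_in <- interior(model$peaks, 300L)
  bg <- data.table::data.table(
    contig = "chr1",
    start = c(0L, model$peaks$end),
    end = c(model$peaks$start, 50000L))
  bg_in <- interior(bg, 300L)
  evg <- events_granges(ev)
  dens_pk <- sum(IRanges::overlapsAny(evg, pk_in)) /
    sum(GenomicRanges::width(pk_in))
  dens_bg <- sum(IRanges::overlapsAny(evg, bg_in)) /
    sum(GenomicRanges::width(bg_in))
  expect_gt(dens_pk / dens_bg, 60)
  expect_lt(dens_pk / dens_bg, 140)
  # n = 0 gives an empty table
  expect_equal(nrow(draw_fragments(model, 0L)), 0L)
})

test_that("full depletion leaves no insertion events inside footprints", {
  model <- sim_peak_model(c(chr1 = 20000L), n_peaks = 2L, peak_width = 1000L,
                          multipliers = 10, footprints_per_peak = 2L,
                          footprint_length = 20L, depletion = 1.0)
  fr <- draw_fragments(model, 5000L, seed = 42)
  ev <- insertions_from_fragments(fr)
  hits <- IRanges::overlapsAny(events_granges(ev),
                               dt_to_granges(model$footprints))
  expect_equal(sum(hits), 0L)
})

test_that("amplification bookkeeping matches the ledger exactly", {
  model <- sim_peak_model(c(chr1 = 20000L), n_peaks = 2L, peak_width = 1000L,
                          multipliers = 10)
  fr <- draw_fragments(model, 3000L, seed = 43)
  # mean_copies = 1: no PCR duplicates at all
  r1 <- amplify(fr, mean_copies = 1, seed = 44)
  expect_equal(nrow(r1), 3000L)
  expect_false(any(r1$is_pcr_copy))
  # mean 3: realized PCR fraction is 1 - unique parents / depth
  r3 <- amplify(fr, mean_copies = 3, dispersion = 2, seed = 45)
  tr <- sim_truth(fr, r3, model)
  expect_equal(tr$pcr_duplicate_fraction,
               1 - tr$true_unique_sampled / nrow(r3))
  expect_true(all(r3$spacer %in% c(6L, 13L, 20L, 25L)))
  # depth beyond the pool errors
  expect_error(amplify(fr, mean_copies = 1, depth = 3001L, seed = 46),
               "exceeds the copy pool")
  # seed determinism
  expect_identical(amplify(fr, mean_copies = 3, seed = 47),
                   amplify(fr, mean_copies = 3, seed = 47))
})

test_that("forced natural duplicates survive UD but not CD", {
  # two distinct fragments sharing coordinates with distinct UMIs
  fr <- data.table::data.table(frag_id = 1:2, contig = "chr1",
                               start = 100L, end = 300L,
                               umi = c("AAAAAA", "CCCCCC"))
  reads <- amplify(fr, mean_copies = 2, dispersion = 1, seed = 48)
  cf <- classify_fragments(emit_alignments(reads, c(chr1 = 1000L))$fragments)
  st <- dedup_stats(cf)
  expect_equal(st$kept_ud, 2L)
  expect_equal(st$kept_cd, 1L)
  expect_equal(st$rescued, 1L)
})

test_that("emitted alignments reproduce the simulated fragments exactly", {
  dir <- withr::local_tempdir()
  model <- sim_peak_model(c(chr1 = 20000L), n_peaks = 2L, peak_width = 1000L,
                          multipliers = 10)
  fr <- draw_fragments(model, 1000L, seed = 51)
  reads <- amplify(fr, mean_copies = 2, dispersion = 2, seed = 52)
  sam <- file.path(dir, "x.sam")
  al <- emit_alignments(reads, c(chr1 = 20000L), sam_path = sam)
  # record count: two mates per read pair
  n_rec <- sum(!startsWith(readLines(sam), "@"))
  expect_equal(n_rec, 2L * nrow(reads))
  # parsing the SAM recovers the same fragment set
  fr_sam <- read_fragments(sam)
  key <- function(x) data.table::setorder(
    data.table::as.data.table(x)[, .(contig, start, end, umi)],
    contig, start, end, umi)
  expect_equal(key(fr_sam), key(al$fragments))
  # CD keeps exactly one fragment per distinct coordinate key
  cf <- classify_fragments(fr_sam)
  expect_equal(sum(cf$keep_cd),
               nrow(unique(reads[, c("contig", "start", "end")])))
})

test_that("insert sizes reflect the bimodal fragment-length mixture", {
  model <- sim_model(c(chr1 = 200000L))   # flat landscape, default mixture
  fr <- draw_fragments(model, 30000L, seed = 53)
  h <- insert_size_distribution(fr)
  expect_equal(sum(h$count), 30000L)
  # modes near the component means (sub-nucleosomal 60, mono-nucleosomal 200)
  sub <- h[size >= 40 & size <= 120]
  mono <- h[size >= 150 & size <= 260]
  expect_lt(abs(sub[which.max(count)]$size - 60), 10)
  expect_lt(abs(mono[which.max(count)]$size - 200), 10)
})
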