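# Shared helpers: seeding, constants, small conversions.

#' The Tn5 mosaic-end (ME) anchor sequence
#'
#' 19-bp Tn5 recognition sequence that separates the UMI/spacer prefix from
#' genomic bases in read 1 of a UMI-tagged ATAC-seq library.
#'
#' @return A single character string, `"AGATGTGTATAAGAGACAG"`.
#' @export
me_sequence <- function() "AGATGTGTATAAGAGACAG"

# Evaluate `code` under a temporary RNG seed; NULL uses the current stream.
run_seeded <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# All 4^k DNA k-mers, cached. Index i corresponds to code i-1.
umi_universe <- local({
  cache <- list()
  function(k = 6L) {
    key <- as.character(k)
    if (is.null(cache[[key]])) {
      g <- do.call(expand.grid,
                   c(rep(list(c("A", "C", "G", "T")), k),
                     stringsAsFactors = FALSE))
      cache[[key]] <<- do.call(paste0, g)
    }
    cache[[key]]
  }
})

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# data.table(contig, start, end) [0-based half-open] -> GRanges (1-based).
dt_to_granges <- function(dt) {
  GenomicRanges::GRanges(dt$contig,
                         IRanges::IRanges(dt$start + 1L, dt$end))
}

# GRanges -> data.table(contig, start, end) [0-based half-open].
granges_to_dt <- function(gr) {
  data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Point GRanges for 0-based insertion positions.
events_granges <- function(events) {
  GenomicRanges::GRanges(events$contig,
                         IRanges::IRanges(events$pos + 1L, width = 1L))
}

as_interval_granges <- function(x) {
  if (methods::is(x, "GRanges")) x else dt_to_granges(data.table::as.data.table(x))
}
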