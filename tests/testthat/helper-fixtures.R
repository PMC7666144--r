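# Shared fixture builders. Everything is generated in code; no files ship
# with the package.

# Minimal fragment table for dedup tests.
frag_table <- function(starts, ends, umis, contig = "chr1",
                       qualsum = NULL, names = NULL) {
  n <- length(starts)
  data.table::data.table(
    name = if (is.null(names)) sprintf("r%02d", seq_len(n)) else names,
    contig = contig,
    start = as.integer(starts),
    end = as.integer(ends),
    umi = umis,
    mapq = 60L,
    qualsum = if (is.null(qualsum)) rep(0L, n) else as.integer(qualsum)
  )
}

# Stranded event table with `count` events at each position.
dense_events <- function(positions, strand, count = 1L, contig = "chr1") {
  data.table::data.table(
    contig = contig,
    pos = rep(as.integer(positions), each = count),
    strand = strand
  )
}

# Evenly spaced intervals, 0-based half-open.
interval_table <- function(starts, width, contig = "chr1") {
  data.table::data.table(contig = contig, start = as.integer(starts),
                         end = as.integer(starts + width))
}

# Independent log-space binomial-CDF oracle: exhaustive pmf summation.
oracle_log_binom_cdf <- function(k, n, q) {
  if (n == 0L) return(0)
  lp <- stats::dbinom(0:k, n, q, log = TRUE)
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

oracle_log_wellington <- function(fp_p, sh_p, fp_m, sh_m, l_fp, l_sh = 35L) {
  q <- l_fp / (l_fp + l_sh)
  oracle_log_binom_cdf(fp_p, fp_p + sh_p, q) +
    oracle_log_binom_cdf(fp_m, fp_m + sh_m, q)
}

# The simulated study conditions used by the ground-truth and end-to-end
# acceptance experiments: 100-kb genome, ten 1-kb peaks at 10x background,
# two embedded footprints per peak.
truth_recovery_model <- function() {
  sim_peak_model(c(chr1 = 100000L), n_peaks = 10L, peak_width = 1000L,
                 multipliers = 10, footprints_per_peak = 2L,
                 footprint_length = 15L, depletion = 0.9)
}
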