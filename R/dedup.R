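# Fragment-level duplicate classification: PCR duplicates vs rescued
# (natural) duplicates, and the three counting modes ND / CD / UD.

#' Read properly-paired fragments from a SAM/BAM file
#'
#' Keeps only properly paired, primary, both-mates-mapped templates whose
#' mates both have mapping quality at or above `min_mapq` and that do not map
#' to an excluded contig (e.g. organellar genomes). One fragment row is
#' returned per template, with the 0-based half-open fragment interval
#' reconstructed from the leftmost mate's position and template length.
#' The UMI is parsed from the query-name suffix after the last `umi_sep`.
#'
#' @param file Path to a coordinate-sorted SAM or BAM file.
#' @param min_mapq Minimum mapping quality kept; the default 31 encodes the
#'   strict filter "MAPQ > 30".
#' @param excluded_contigs Contig names to drop (e.g. `c("ChrM", "ChrC")`).
#' @param umi_sep Separator between read name and UMI in the query name.
#' @return `data.table` with columns `name`, `contig`, `start`, `end`,
#'   `umi`, `mapq` (minimum over mates) and `qualsum` (summed base
#'   qualities of both mates). Attribute `"dropped"` counts templates
#'   removed by each filter.
#' @export
read_fragments <- function(file, min_mapq = 31L,
                           excluded_contigs = character(),
                           umi_sep = "_") {
  bam <- ensure_bam(file)
  flags <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE,
    isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "rname", "pos", "mapq", "isize", "qual")
  )
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  dt <- data.table::data.table(
    qname = b$qname,
    rname = as.character(b$rname),
    pos = b$pos,
    mapq = b$mapq,
    isize = b$isize,
    qual = as.character(b$qual)
  )
  dropped <- c(excluded_contig = 0L, low_mapq = 0L, unpaired = 0L)

  if (length(excluded_contigs)) {
    drop <- dt$rname %in% excluded_contigs
    dropped["excluded_contig"] <- length(unique(dt$qname[drop]))
    dt <- dt[!drop]
  }
  lowq <- unique(dt$qname[dt$mapq < min_mapq])
  dropped["low_mapq"] <- length(lowq)
  if (length(lowq)) dt <- dt[!qname %in% lowq]

  dt[, n_mates := .N, by = qname]
  dropped["unpaired"] <- length(unique(dt$qname[dt$n_mates != 2L]))
  dt <- dt[n_mates == 2L]

  # per-record summed base qualities ("*" or missing -> 0)
  qs <- integer(nrow(dt))
  has_q <- !is.na(dt$qual) & dt$qual != "*" & nzchar(dt$qual)
  if (any(has_q)) {
    il <- methods::as(Biostrings::PhredQuality(dt$qual[has_q]), "IntegerList")
    qs[has_q] <- sum(il)
  }
  dt[, qualsum := qs]

  left <- dt[isize > 0L]
  mateq <- dt[, .(mapq = min(mapq), qualsum = sum(qualsum)), by = qname]
  frags <- left[, .(qname, contig = rname, start = pos - 1L,
                    end = pos - 1L + isize)][mateq, on = "qname", nomatch = NULL]
  bad_tlen <- nrow(mateq) - nrow(frags)
  if (bad_tlen > 0L)
    dropped["unpaired"] <- dropped["unpaired"] + bad_tlen

  frags[, umi := sub(paste0(".*\\", umi_sep), "", qname)]
  frags[, name := sub(paste0("\\", umi_sep, "[^", umi_sep, "]*$"), "", qname)]
  out <- frags[, .(name, contig, start, end, umi, mapq, qualsum)]
  data.table::setorder(out, contig, start, end, name)
  data.table::setattr(out, "dropped", dropped)
  out[]
}

# Convert SAM to a temporary BAM when needed; BAM paths pass through.
ensure_bam <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(file, dest, overwrite = TRUE, indexDestination = FALSE)
  } else file
}

#' Pick the representative read of a UMI class
#'
#' Deterministic rule: highest summed base quality of both mates, ties
#' broken by the lexicographically smallest read name.
#'
#' @param umi_class `data.frame`/`data.table` with columns `qualsum`, `name`.
#' @return Integer index of the representative row.
#' @export
select_representative <- function(umi_class) {
  stopifnot(nrow(umi_class) >= 1L)
  order(-umi_class$qualsum, umi_class$name)[1L]
}

# Single-linkage collapse of UMIs within a coordinate group under a Hamming
# distance threshold. UMIs containing N never merge with a different UMI.
collapse_umis <- function(umis, max_hamming) {
  u <- unique(umis)
  if (length(u) == 1L) return(umis)
  cls <- seq_along(u)
  mergeable <- !grepl("N", u, fixed = TRUE)
  m <- strsplit(u, "")
  for (i in seq_along(u)) {
    if (!mergeable[i]) next
    for (j in seq_len(i - 1L)) {
      if (!mergeable[j]) next
      if (nchar(u[i]) != nchar(u[j])) next
      if (sum(m[[i]] != m[[j]]) <= max_hamming) {
        old <- cls[i]
        cls[cls == old] <- cls[j]
      }
    }
  }
  u[match(cls, seq_along(u))][match(umis, u)]
}

#' Classify fragments into unique / PCR-duplicate / rescued
#'
#' Fragments are grouped by exact mapping coordinates `(contig, start, end)`.
#' Within a group, members are partitioned into UMI classes (exact string
#' equality by default; optional Hamming-distance collapsing). One
#' representative per UMI class is kept under UMI-based deduplication (UD);
#' the remaining class members are PCR duplicates. Among representatives,
#' the best one is the coordinate-deduplication (CD) survivor (`"unique"`)
#' and every additional representative is `"rescued"` -- an independent Tn5
#' insertion event that coordinate deduplication would have discarded.
#'
#' @param frags `data.table` with columns `contig`, `start`, `end`, `umi`
#'   (and optionally `name`, `qualsum`), e.g. from [read_fragments()].
#' @param umi_hamming Maximum Hamming distance at which two UMIs are merged
#'   into one class (default 0 = exact equality).
#' @return The input with added columns `class`
#'   (`unique`/`rescued`/`pcr_duplicate`), `keep_cd` and `keep_ud`, sorted
#'   by coordinates. Classification is invariant to input row order.
#' @export
classify_fragments <- function(frags, umi_hamming = 0L) {
  f <- data.table::as.data.table(frags)
  need <- c("contig", "start", "end", "umi")
  if (!all(need %in% names(f)))
    stop("fragments need columns: ", paste(need, collapse = ", "))
  stopifnot(all(f$start < f$end))
  if (!"qualsum" %in% names(f)) f[, qualsum := 0]
  if (!"name" %in% names(f)) f[, name := sprintf("frag%09d", seq_len(.N))]
  data.table::setorder(f, contig, start, end, -qualsum, name)
  f[, grp := .GRP, by = .(contig, start, end)]
  if (umi_hamming > 0L) {
    f[, uclass := collapse_umis(umi, umi_hamming), by = grp]
  } else {
    f[, uclass := umi]
  }
  f[, rep_rank := seq_len(.N), by = .(grp, uclass)]
  f[, class := "pcr_duplicate"]
  f[rep_rank == 1L, cls_rank := seq_len(.N), by = grp]
  f[rep_rank == 1L, class := data.table::fifelse(cls_rank == 1L,
                                                 "unique", "rescued")]
  f[, keep_cd := class == "unique"]
  f[, keep_ud := rep_rank == 1L]
  f[, c("grp", "uclass", "rep_rank", "cls_rank") := NULL]
  f[]
}

#' Deduplication statistics
#'
#' @param frags Classified fragments from [classify_fragments()].
#' @return A `dedup_stats` list with `fragments_total`, `kept_nd`,
#'   `kept_cd`, `kept_ud`, `pcr_duplicates`, `rescued`,
#'   `rescue_rate_of_presumed_dups` and `rescue_rate_of_total`.
#' @export
dedup_stats <- function(frags) {
  total <- nrow(frags)
  kept_cd <- sum(frags$keep_cd)
  kept_ud <- sum(frags$keep_ud)
  rescued <- sum(frags$class == "rescued")
  presumed <- total - kept_cd
  structure(list(
    fragments_total = total,
    kept_nd = total,
    kept_cd = kept_cd,
    kept_ud = kept_ud,
    pcr_duplicates = total - kept_ud,
    rescued = rescued,
    rescue_rate_of_presumed_dups = if (presumed > 0) rescued / presumed else NA_real_,
    rescue_rate_of_total = if (total > 0) rescued / total else NA_real_
  ), class = "dedup_stats")
}

#' @export
print.dedup_stats <- function(x, ...) {
  cat("Fragment deduplication:\n")
  cat(sprintf("  fragments (ND):  %d\n", x$fragments_total))
  cat(sprintf("  kept CD:         %d\n", x$kept_cd))
  cat(sprintf("  kept UD:         %d\n", x$kept_ud))
  cat(sprintf("  PCR duplicates:  %d\n", x$pcr_duplicates))
  cat(sprintf("  rescued:         %d (%.1f%% of presumed duplicates, %.1f%% of total)\n",
              x$rescued, 100 * x$rescue_rate_of_presumed_dups,
              100 * x$rescue_rate_of_total))
  invisible(x)
}

#' Subset classified fragments by deduplication mode
#'
#' @param frags Classified fragments from [classify_fragments()].
#' @param mode `"nd"` (all fragments), `"cd"` (one per coordinate key) or
#'   `"ud"` (one per coordinate key and UMI class).
#' @return The kept subset.
#' @export
dedup_fragments <- function(frags, mode = c("ud", "cd", "nd")) {
  mode <- match.arg(mode)
  switch(mode,
         nd = frags,
         cd = frags[frags$keep_cd, ],
         ud = frags[frags$keep_ud, ])
}

#' Deduplicate an alignment file
#'
#' Reads, filters and classifies fragments from a coordinate-sorted SAM/BAM
#' file, and optionally writes the kept records of the requested mode to a
#' filtered BAM.
#'
#' @inheritParams read_fragments
#' @param output Optional output BAM path for the kept records.
#' @param mode Deduplication mode, see [dedup_fragments()].
#' @param require_sorted Abort when the header does not declare coordinate
#'   sorting (default TRUE).
#' @return List with `fragments` (classified, all modes) and `stats`.
#' @export
dedup_alignments <- function(file, output = NULL, mode = c("ud", "cd", "nd"),
                             min_mapq = 31L, excluded_contigs = character(),
                             umi_sep = "_", require_sorted = TRUE) {
  mode <- match.arg(mode)
  bam <- ensure_bam(file)
  if (require_sorted) {
    hd <- Rsamtools::scanBamHeader(bam)[[1]]$text
    so <- hd[["@HD"]]
    if (is.null(so) || !any(grepl("^SO:coordinate$", so)))
      stop("input is not coordinate-sorted (header lacks 'SO:coordinate'): ",
           file)
  }
  frags <- read_fragments(bam, min_mapq = min_mapq,
                          excluded_contigs = excluded_contigs,
                          umi_sep = umi_sep)
  frags <- classify_fragments(frags)
  stats <- dedup_stats(frags)
  if (!is.null(output)) {
    if (!file.exists(paste0(bam, ".bai"))) Rsamtools::indexBam(bam)
    kept <- dedup_fragments(frags, mode)
    keep_names <- paste0(kept$name, umi_sep, kept$umi)
    rules <- S4Vectors::FilterRules(list(
      keep = function(df) df$qname %in% keep_names))
    Rsamtools::filterBam(bam, output, filter = rules,
                         param = Rsamtools::ScanBamParam(what = "qname"),
                         indexDestination = FALSE)
  }
  list(fragments = frags, stats = stats)
}
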