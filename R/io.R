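# Standard-format I/O: BED / narrowPeak peaks, footprint BED6/TSV,
# bedGraph insertion tracks. Thin wrappers around rtracklayer.

#' Read peak or motif intervals from BED or narrowPeak
#'
#' @param path BED, BED6 or narrowPeak file.
#' @return `GRanges`.
#' @export
read_peaks <- function(path) {
  if (grepl("\\.narrowPeak(\\.gz)?$", path)) {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric",
                                      pValue = "numeric",
                                      qValue = "numeric",
                                      peak = "integer"))
  } else {
    rtracklayer::import(path)
  }
}

#' Write footprints as BED6 (and optionally a full TSV)
#'
#' The BED score column is the footprint score scaled by 1000 and clamped
#' to `[0, 1000]`.
#'
#' @param footprints Table from [scan_footprints()].
#' @param bed_path Output BED path.
#' @param tsv_path Optional TSV with P-value, score and any extra columns.
#' @export
write_footprints <- function(footprints, bed_path, tsv_path = NULL) {
  fp <- data.table::as.data.table(footprints)
  bed <- data.table::data.table(
    chrom = fp$contig,
    chromStart = fp$start,
    chromEnd = fp$end,
    name = sprintf("footprint_%d", seq_len(nrow(fp))),
    score = as.integer(clamp(round(fp$score * 1000), 0, 1000)),
    strand = "."
  )
  data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  if (!is.null(tsv_path)) data.table::fwrite(fp, tsv_path, sep = "\t")
  invisible(bed_path)
}

#' Write a per-position insertion-count track as bedGraph
#'
#' One file per strand when `by_strand = TRUE`, otherwise combined counts.
#'
#' @param events Insertion events (`contig`, `pos`, `strand`).
#' @param path Output bedGraph path (with `by_strand`, `+`/`-` files get
#'   suffixes `.plus`/`.minus` before the extension).
#' @param by_strand Write separate stranded tracks (default FALSE).
#' @export
write_insertion_bedgraph <- function(events, path, by_strand = FALSE) {
  ev <- data.table::as.data.table(events)
  write_one <- function(sub, p) {
    cnt <- sub[, .(score = .N), by = .(contig, pos)]
    gr <- GenomicRanges::GRanges(cnt$contig,
                                 IRanges::IRanges(cnt$pos + 1L, width = 1L),
                                 score = cnt$score)
    rtracklayer::export(sort(gr), p, format = "bedGraph")
  }
  if (by_strand) {
    p1 <- sub("(\\.[^.]+)$", ".plus\\1", path)
    p2 <- sub("(\\.[^.]+)$", ".minus\\1", path)
    write_one(ev[strand == "+"], p1)
    write_one(ev[strand == "-"], p2)
    invisible(c(p1, p2))
  } else {
    write_one(ev, path)
    invisible(path)
  }
}
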