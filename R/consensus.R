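#' Consensus-building parameters
#'
#' @param min_overlap_fraction fraction of a peak's own length that must be
#'   covered by a peak from another cell line for the peak to be retained
#'   (default 0.5, i.e. "at least 50% of its length", `>=` at the boundary).
#' @param min_supporting_cell_lines minimum number of distinct cell lines a
#'   region's evidence must come from (default 2, "detected in at least two
#'   cell lines"). A peak needs qualifying partners in at least
#'   `min_supporting_cell_lines - 1` other cell lines.
#' @param merge_bookended coalesce touching retained peaks during the final
#'   merge (default TRUE; see [merge_intervals()]).
#' @param reciprocal require the overlap to also cover
#'   `min_overlap_fraction` of the partner peak's length (stricter,
#'   symmetric variant; default FALSE - retention is deliberately
#'   asymmetric, relative to the candidate peak's own length).
#' @return a list of class `ConsensusConfig`.
#' @examples
#' consensus_config()
#' @export
consensus_config <- function(min_overlap_fraction = 0.5,
                             min_supporting_cell_lines = 2L,
                             merge_bookended = TRUE,
                             reciprocal = FALSE) {
  stopifnot(min_overlap_fraction > 0, min_overlap_fraction <= 1,
            min_supporting_cell_lines >= 2)
  structure(list(min_overlap_fraction = min_overlap_fraction,
                 min_supporting_cell_lines = as.integer(min_supporting_cell_lines),
                 merge_bookended = isTRUE(merge_bookended),
                 reciprocal = isTRUE(reciprocal)),
            class = "ConsensusConfig")
}

check_peaksets <- function(peak_sets) {
  stopifnot(length(peak_sets) >= 1,
            all(vapply(peak_sets, function(p) is(p, "PeakSet"), TRUE)))
  assays <- unique(vapply(peak_sets, `[[`, "", "assay"))
  if (length(assays) != 1)
    stop("mixed assays in one consensus run: ", paste(assays, collapse = ", "))
  cls <- vapply(peak_sets, `[[`, "", "cell_line")
  if (anyDuplicated(cls)) {
    # merge multiple PeakSets from the same cell line so "other cell line"
    # means what it says
    peak_sets <- lapply(split(peak_sets, cls), function(ps) {
      peak_set(ps[[1]]$cell_line, ps[[1]]$assay,
               do.call(c, lapply(ps, `[[`, "intervals")))
    })
  }
  peak_sets
}

pool_peaks <- function(peak_sets) {
  # one fresh GRanges instead of c()-ing per-set objects: markedly cheaper
  # when consensus building runs over many small instances
  n <- vapply(peak_sets, function(p) length(p$intervals), 0L)
  gr <- GenomicRanges::GRanges(
    S4Vectors::Rle(unlist(lapply(peak_sets, function(p)
      as.character(GenomicRanges::seqnames(p$intervals))))),
    IRanges::IRanges(
      unlist(lapply(peak_sets, function(p)
        GenomicRanges::start(p$intervals))),
      unlist(lapply(peak_sets, function(p)
        GenomicRanges::end(p$intervals)))))
  gr$cell_line <- rep(vapply(peak_sets, `[[`, "", "cell_line"), n)
  gr
}

#' Retain peaks supported in another cell line
#'
#' Step (i) of consensus building: a peak P from cell line i is retained iff
#' some peak Q from a different cell line overlaps at least
#' `min_overlap_fraction` of P's own length (and, with `reciprocal = TRUE`,
#' of Q's length too); with `min_supporting_cell_lines = k`, qualifying
#' partners must come from at least k-1 distinct other cell lines. Retained
#' peaks keep their original coordinates and cell-line provenance.
#'
#' @param peak_sets a list of [peak_set()]s for one assay, one or more per
#'   cell line.
#' @param cfg a [consensus_config()].
#' @return a sorted `GRanges` of retained peaks with a `cell_line` metadata
#'   column (a subset of the input peaks, verbatim).
#' @examples
#' a <- peak_set("A", "H3K4me1", granges0("chr1", 100, 200))
#' b <- peak_set("B", "H3K4me1", granges0("chr1", 150, 300))
#' retain_supported_peaks(list(a, b))  # only A's peak passes 50% of own length
#' @export
retain_supported_peaks <- function(peak_sets, cfg = consensus_config()) {
  peak_sets <- check_peaksets(peak_sets)
  pooled <- pool_peaks(peak_sets)
  if (length(pooled) == 0 || length(peak_sets) < 2) return(pooled[0])
  hits <- GenomicRanges::findOverlaps(pooled, pooled, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  other <- pooled$cell_line[q] != pooled$cell_line[s]
  q <- q[other]; s <- s[other]
  # overlap widths by arithmetic (1-based closed internally); cheaper than
  # materialising pintersect ranges
  st <- GenomicRanges::start(pooled); en <- GenomicRanges::end(pooled)
  ov <- pmin(en[q], en[s]) - pmax(st[q], st[s]) + 1L
  ok <- ov >= cfg$min_overlap_fraction * GenomicRanges::width(pooled[q])
  if (cfg$reciprocal)
    ok <- ok & ov >= cfg$min_overlap_fraction * GenomicRanges::width(pooled[s])
  q <- q[ok]; s <- s[ok]
  n_partner_lines <- tapply(pooled$cell_line[s], factor(q, seq_along(pooled)),
                            function(x) length(unique(x)))
  n_partner_lines[is.na(n_partner_lines)] <- 0L
  GenomicRanges::sort(pooled[n_partner_lines >= cfg$min_supporting_cell_lines - 1L],
                      ignore.strand = TRUE)
}

#' Build per-marker consensus regulatory regions
#'
#' The full three-step algorithm: (i) retain peaks supported in a second
#' cell line ([retain_supported_peaks()]), (ii) concatenate the retained
#' peaks across cell lines, (iii) sort and merge them
#' ([merge_intervals()]). The result is the merge of all peak regions
#' detected in at least two cell lines; provenance records which cell lines
#' and original peaks contributed to each merged region.
#'
#' @inheritParams retain_supported_peaks
#' @return an object of class `ConsensusRegions`: `assay`, `regions` (a
#'   disjoint sorted `GRanges`), `provenance` (one `data.frame` of
#'   `cell_line`, `start`, `end` - 0-based half-open original peaks - per
#'   region), and `cfg`.
#' @examples
#' a <- peak_set("A", "H3K4me1", granges0("chr1", 100, 200))
#' b <- peak_set("B", "H3K4me1", granges0("chr1", 150, 300))
#' build_consensus(list(a, b))$regions  # chr1:[100,200)
#' @export
build_consensus <- function(peak_sets, cfg = consensus_config()) {
  peak_sets <- check_peaksets(peak_sets)
  retained <- retain_supported_peaks(peak_sets, cfg)
  regions <- merge_intervals(retained, cfg$merge_bookended)
  hits <- GenomicRanges::findOverlaps(regions, retained, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  cl <- retained$cell_line; st <- GenomicRanges::start(retained) - 1L
  en <- GenomicRanges::end(retained)
  prov <- lapply(seq_along(regions), function(i) {
    j <- sh[qh == i]
    data.frame(cell_line = cl[j], start = st[j], end = en[j],
               stringsAsFactors = FALSE)
  })
  structure(list(assay = peak_sets[[1]]$assay, regions = regions,
                 provenance = prov, cfg = cfg),
            class = "ConsensusRegions")
}

#' @export
print.ConsensusRegions <- function(x, ...) {
  nlines <- length(unique(unlist(lapply(x$provenance, `[[`, "cell_line"))))
  cat(sprintf("ConsensusRegions: %s, %d region(s) from %d cell line(s), %s bp\n",
              x$assay, length(x$regions), nlines,
              format(sum(GenomicRanges::width(x$regions)), big.mark = ",")))
  invisible(x)
}

#' Write consensus regions and their provenance
#'
#' Regions go to a BED file; provenance (supporting cell line and original
#' peak per region) to a sidecar TSV `<path>.provenance.tsv`.
#'
#' @param cons a `ConsensusRegions`.
#' @param path BED output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(cons, path) {
  gr <- cons$regions
  if (length(gr))
    S4Vectors::mcols(gr)$name <- sprintf("%s_consensus_%d", cons$assay,
                                         seq_along(gr))
  write_intervals(gr, path)
  prov <- do.call(rbind, lapply(seq_along(cons$provenance), function(i) {
    p <- cons$provenance[[i]]
    if (!nrow(p)) return(NULL)
    cbind(region = sprintf("%s_consensus_%d", cons$assay, i), p)
  }))
  if (is.null(prov))
    prov <- data.frame(region = character(0), cell_line = character(0),
                       start = integer(0), end = integer(0))
  write.table(prov, paste0(path, ".provenance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
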