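CROSSTAB_ROWS <- c("H3K4me1", "H3K4me1+H3K4me3", "H3K27ac", "H3K9ac",
                   "DNase", "FAIRE", "Union")

cons_regions <- function(x) {
  if (is(x, "ConsensusRegions")) x$regions
  else if (is(x, "PeakSet")) x$intervals
  else { stopifnot(is(x, "GRanges")); x }
}

#' Chromatin-state class of a SNP position
#'
#' Enhancers carry H3K4me1 without H3K4me3; promoters carry both. A
#' position inside the H3K4me1 consensus only is `enhancer`; inside both
#' the H3K4me1 and H3K4me3 consensus, `promoter`; anything else (including
#' H3K4me3 alone) is `unclassified`.
#'
#' @param chrom,pos chromosome and 0-based position of the SNP.
#' @param me1,me3 H3K4me1 / H3K4me3 consensus (`ConsensusRegions` or
#'   `GRanges`).
#' @return one of `"enhancer"`, `"promoter"`, `"unclassified"`.
#' @examples
#' me1 <- granges0("chr1", 100, 200)
#' classify_snp_context("chr1", 150, me1, GenomicRanges::GRanges())
#' @export
classify_snp_context <- function(chrom, pos, me1, me3) {
  p <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  in1 <- length(GenomicRanges::findOverlaps(p, cons_regions(me1))) > 0
  in3 <- length(GenomicRanges::findOverlaps(p, cons_regions(me3))) > 0
  if (in1 && in3) "promoter" else if (in1) "enhancer" else "unclassified"
}

state_from_markers <- function(markers) {
  if ("H3K4me1" %in% markers)
    return(if ("H3K4me3" %in% markers) "promoter" else "enhancer")
  if (any(c("H3K9ac", "H3K27ac") %in% markers)) return("acetylation")
  if (any(c("DNase", "FAIRE") %in% markers)) return("open_chromatin")
  "unclassified"
}

# per-marker attachment: region index per SNP (NA when not attached) and
# the distance convention: 0 inside, else positional gap in bp where the
# nearest inside base counts as distance 1
attach_marker <- function(snp_gr, regions, proximity_bp) {
  idx <- rep(NA_integer_, length(snp_gr))
  dist <- rep(NA_integer_, length(snp_gr))
  if (length(regions) == 0) return(list(idx = idx, dist = dist))
  ov <- GenomicRanges::findOverlaps(snp_gr, regions, ignore.strand = TRUE)
  idx[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  dist[S4Vectors::queryHits(ov)] <- 0L
  if (proximity_bp > 0) {
    near <- GenomicRanges::distanceToNearest(snp_gr, regions,
                                             ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(near)
    d <- S4Vectors::mcols(near)$distance + 1L
    take <- is.na(idx[qh]) & d <= proximity_bp
    idx[qh[take]] <- S4Vectors::subjectHits(near)[take]
    dist[qh[take]] <- d[take]
  }
  list(idx = idx, dist = dist)
}

#' Annotate SNPs with consensus regions and bound TFs
#'
#' The PRR discovery step: each SNP is attached to every marker whose
#' consensus contains it (or lies within `proximity_bp`); a TF is recorded
#' as bound either when one of its peaks overlaps a containing consensus
#' region by at least 1 bp (`mode = "region_overlap"`, the default - the
#' SNP itself need only be inside the region) or when the SNP position
#' falls inside a TF peak (`mode = "snp_in_peak"`, stricter). SNPs hitting
#' no marker are not emitted. SNPs on chromosomes absent from every
#' consensus set are skipped with a message.
#'
#' @param snps a SNP `data.frame` (see [read_snps()]).
#' @param consensus_by_marker named list (marker -> `ConsensusRegions` or
#'   `GRanges`).
#' @param tf_peaks named list (TF symbol -> `PeakSet` or `GRanges`); may be
#'   empty.
#' @param mode TF attachment semantics, see above.
#' @param proximity_bp attach SNPs up to this many bp from a region edge
#'   (default 0 = strict containment). The first base inside a region is at
#'   distance 1 from the base book-ending it.
#' @return a `data.frame` of PRR records: the SNP columns plus `reg_class`
#'   (`enhancer`/`promoter`/`acetylation`/`open_chromatin`/`unclassified`),
#'   `markers` and `bound_tfs` (comma-joined, sorted), `distance` (bp; 0
#'   when inside some region) and `regions`
#'   (`marker=chrom:start-end` 0-based, semicolon-joined).
#' @export
annotate_snps <- function(snps, consensus_by_marker, tf_peaks = list(),
                          mode = c("region_overlap", "snp_in_peak"),
                          proximity_bp = 0L) {
  mode <- match.arg(mode)
  stopifnot(proximity_bp >= 0)
  if (!length(consensus_by_marker) || is.null(names(consensus_by_marker)))
    stop("consensus_by_marker must be a non-empty named list")
  reg_by_marker <- lapply(consensus_by_marker, cons_regions)
  known_chroms <- unique(unlist(lapply(reg_by_marker, function(g)
    unique(as.character(GenomicRanges::seqnames(g))))))
  unknown <- !(snps$chrom %in% known_chroms)
  if (any(unknown)) {
    message(sprintf("annotate_snps: skipping %d SNP(s) on chromosome(s) absent from all consensus sets: %s",
                    sum(unknown),
                    paste(unique(snps$chrom[unknown]), collapse = ", ")))
    snps <- snps[!unknown, , drop = FALSE]
  }
  if (!nrow(snps)) return(empty_prr())
  snp_gr <- snps_granges(snps)

  att <- lapply(reg_by_marker, attach_marker, snp_gr = snp_gr,
                proximity_bp = as.integer(proximity_bp))
  hit_any <- Reduce(`|`, lapply(att, function(a) !is.na(a$idx)))
  if (!any(hit_any)) return(empty_prr())

  tf_gr <- lapply(tf_peaks, cons_regions)
  # region_overlap: precompute, per marker, which consensus regions each TF
  # touches
  tf_region_hit <- lapply(tf_gr, function(g)
    lapply(reg_by_marker, function(r)
      unique(S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(g, r, ignore.strand = TRUE)))))
  # snp_in_peak: which SNPs sit inside each TF's peaks
  tf_snp_hit <- lapply(tf_gr, function(g)
    unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(snp_gr, g, ignore.strand = TRUE))))

  keep <- which(hit_any)
  rec <- snps[keep, , drop = FALSE]
  markers <- character(length(keep)); tfs <- character(length(keep))
  regs <- character(length(keep)); dists <- integer(length(keep))
  classes <- character(length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    mk <- names(att)[vapply(att, function(a) !is.na(a$idx[i]), TRUE)]
    markers[k] <- paste(mk, collapse = ",")
    dists[k] <- min(vapply(att[mk], function(a) a$dist[i], 0L))
    classes[k] <- state_from_markers(mk)
    regs[k] <- paste(vapply(mk, function(m) {
      r <- reg_by_marker[[m]][att[[m]]$idx[i]]
      sprintf("%s=%s:%d-%d", m, as.character(GenomicRanges::seqnames(r)),
              GenomicRanges::start(r) - 1L, GenomicRanges::end(r))
    }, ""), collapse = ";")
    bound <- vapply(names(tf_gr), function(tf) {
      if (mode == "snp_in_peak") i %in% tf_snp_hit[[tf]]
      else any(vapply(mk, function(m)
        att[[m]]$idx[i] %in% tf_region_hit[[tf]][[m]], TRUE))
    }, TRUE)
    tfs[k] <- paste(sort(names(tf_gr)[bound]), collapse = ",")
  }
  out <- cbind(rec,
               data.frame(reg_class = classes, markers = markers,
                          bound_tfs = tfs, distance = dists, regions = regs,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

empty_prr <- function() {
  data.frame(rsid = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), maf = numeric(0),
             on_array = logical(0), reg_class = character(0),
             markers = character(0), bound_tfs = character(0),
             distance = integer(0), regions = character(0),
             stringsAsFactors = FALSE)
}

split_field <- function(x) {
  x[is.na(x)] <- ""
  strsplit(as.character(x), ",", fixed = TRUE)
}

#' Marker-by-TF cross-tabulation of PRR SNPs
#'
#' Counts distinct rsIDs per marker row and TF column, in the layout of the
#' published summary table: rows `H3K4me1`, `H3K4me1+H3K4me3` (the promoter
#' pattern - SNPs in both consensuses), `H3K27ac`, `H3K9ac`, `DNase`,
#' `FAIRE`, and `Union` (SNPs in at least one of those six categories);
#' one column per TF plus an intersection column requiring all listed TFs.
#'
#' @param records output of [annotate_snps()].
#' @param tfs ordered character vector of TF symbols (>= 1).
#' @return an integer matrix of class `MarkerCrossTab` with the rows above
#'   and columns `tfs` followed by `"<tf1>+<tf2>+..."` when more than one
#'   TF is given.
#' @examples
#' marker_crosstab(empty_prr_records(), c("AR", "ER"))
#' @export
marker_crosstab <- function(records, tfs) {
  stopifnot(length(tfs) >= 1)
  mk <- split_field(records$markers)
  tf <- split_field(records$bound_tfs)
  in_row <- function(row) switch(row,
    "H3K4me1+H3K4me3" = vapply(mk, function(m)
      all(c("H3K4me1", "H3K4me3") %in% m), TRUE),
    "Union" = vapply(mk, function(m)
      any(c("H3K4me1", "H3K27ac", "H3K9ac", "DNase", "FAIRE") %in% m), TRUE),
    vapply(mk, function(m) row %in% m, TRUE))
  cols <- as.list(tfs)
  cn <- tfs
  if (length(tfs) > 1) {
    cols <- c(cols, list(tfs))
    cn <- c(cn, paste(tfs, collapse = "+"))
  }
  m <- matrix(0L, nrow = length(CROSSTAB_ROWS), ncol = length(cols),
              dimnames = list(CROSSTAB_ROWS, cn))
  if (nrow(records))
    for (r in CROSSTAB_ROWS) {
      rowsel <- in_row(r)
      for (j in seq_along(cols)) {
        colsel <- vapply(tf, function(x) all(cols[[j]] %in% x), TRUE)
        m[r, j] <- length(unique(records$rsid[rowsel & colsel]))
      }
    }
  structure(m, class = c("MarkerCrossTab", class(m)))
}

#' @export
print.MarkerCrossTab <- function(x, ...) {
  cat("SNP counts per marker consensus and bound TF\n")
  print(unclass(x), ...)
  invisible(x)
}

#' An empty PRR record table
#'
#' Template for the columns [annotate_snps()] emits; handy for tests and
#' for building tables by hand.
#' @return a zero-row PRR `data.frame`.
#' @export
empty_prr_records <- function() empty_prr()

#' Prioritize PRR records for validation
#'
#' Keeps records with minor-allele frequency at least `min_maf` (records
#' lacking a MAF are dropped whenever `min_maf > 0`) and, optionally, only
#' SNPs tracked on the genotyping array; sorts by descending MAF then rsID.
#'
#' @param records output of [annotate_snps()].
#' @param min_maf MAF threshold in `[0, 0.5]` (default 0 = keep all).
#' @param require_array keep only records with `on_array = TRUE`.
#' @return the filtered, re-sorted `data.frame`.
#' @export
prioritize_records <- function(records, min_maf = 0, require_array = FALSE) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  keep <- if (min_maf > 0) !is.na(records$maf) & records$maf >= min_maf
          else rep(TRUE, nrow(records))
  if (require_array) keep <- keep & records$on_array
  out <- records[keep, , drop = FALSE]
  out <- out[order(-ifelse(is.na(out$maf), -Inf, out$maf), out$rsid), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read PRR record tables
#'
#' Plain TSV with the [annotate_snps()] columns; positions stay 0-based.
#' @param records a PRR `data.frame`.
#' @param path file path.
#' @return `path` (write) / the `data.frame` (read).
#' @export
write_prr_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prr_records
#' @export
read_prr_records <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(rsid = "character", chrom = "character",
                                  ref = "character", alt = "character",
                                  reg_class = "character",
                                  markers = "character",
                                  bound_tfs = "character",
                                  regions = "character"))
  for (col in c("markers", "bound_tfs", "regions"))
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  df$maf <- as.numeric(df$maf)
  df$on_array <- as.logical(df$on_array)
  df$pos <- as.integer(df$pos)
  df$distance <- as.integer(df$distance)
  df
}
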