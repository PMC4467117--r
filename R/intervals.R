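MARKER_ASSAYS <- c("H3K4me1", "H3K4me3", "H3K9ac", "H3K27ac", "DNase", "FAIRE")

#' Build a GRanges from 0-based half-open intervals
#'
#' prrtools speaks BED coordinates (0-based start, exclusive end) at every
#' user-facing surface and stores intervals internally as
#' [GenomicRanges::GRanges] (1-based closed). This pair of helpers converts
#' between the two conventions.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `start < end`
#'   required.
#' @param name,score optional per-interval label and numeric score.
#' @return `granges0()`: a `GRanges`, sorted. `as_bed0()`: a `data.frame`
#'   with columns `chrom`, `start`, `end` (0-based half-open) and any
#'   metadata columns.
#' @examples
#' gr <- granges0("chr1", 100, 200)
#' as_bed0(gr)
#' @export
granges0 <- function(chrom, start, end, name = NULL, score = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!length(start)) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(name)) S4Vectors::mcols(gr)$name <- character(0)
    if (!is.null(score)) S4Vectors::mcols(gr)$score <- numeric(0)
    return(gr)
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop("invalid interval(s) at index ", paste(head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- score
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @param gr a `GRanges`.
#' @rdname granges0
#' @export
as_bed0 <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end   = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(S4Vectors::mcols(gr)))
}

#' A per-cell-line, per-assay set of peaks
#'
#' Groups one cell line's peaks for one assay (a histone mark, an
#' open-chromatin assay, or a TF symbol). Intervals are sorted on
#' construction; exact duplicate intervals are tolerated but counted in
#' `n_duplicates` so upstream double-loading is visible.
#'
#' @param cell_line cell-line identifier.
#' @param assay marker or TF name.
#' @param intervals a `GRanges` (see [granges0()]).
#' @return an object of class `PeakSet` with fields `cell_line`, `assay`,
#'   `intervals`, `n_duplicates`.
#' @examples
#' peak_set("GM12878", "H3K4me1", granges0("chr1", c(100, 500), c(200, 700)))
#' @export
peak_set <- function(cell_line, assay, intervals) {
  stopifnot(is(intervals, "GRanges"))
  if (length(intervals) > 1)
    intervals <- GenomicRanges::sort(intervals, ignore.strand = TRUE)
  ndup <- if (length(intervals) > 1) sum(duplicated(intervals)) else 0L
  structure(list(cell_line = as.character(cell_line),
                 assay = as.character(assay),
                 intervals = intervals,
                 n_duplicates = ndup),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %s / %s, %d peaks%s\n", x$cell_line, x$assay,
              length(x$intervals),
              if (x$n_duplicates) sprintf(" (%d duplicated)", x$n_duplicates)
              else ""))
  invisible(x)
}

#' Overlap length of two intervals
#'
#' Number of shared bases between two single intervals given as
#' `c(start, end)` in 0-based half-open coordinates, optionally with
#' chromosome names. Book-ended intervals (`end == start`) share nothing.
#'
#' @param a,b numeric length-2 vectors `c(start, end)`, 0-based half-open.
#' @param chrom_a,chrom_b chromosome names; overlap is 0 when they differ.
#' @return integer number of overlapping bases (>= 0).
#' @examples
#' overlap_length(c(100, 200), c(150, 300))  # 50
#' overlap_length(c(100, 200), c(200, 300))  # 0
#' @export
overlap_length <- function(a, b, chrom_a = "chr", chrom_b = "chr") {
  stopifnot(length(a) == 2, length(b) == 2, a[1] < a[2], b[1] < b[2])
  if (chrom_a != chrom_b) return(0L)
  as.integer(max(0, min(a[2], b[2]) - max(a[1], b[1])))
}

#' Merge intervals into a disjoint sorted set
#'
#' The "sort and merge" step of consensus building: the union of the input
#' bases, reported as maximal runs. With `merge_bookended = TRUE` (default)
#' touching intervals such as `[100,200)` and `[200,300)` coalesce into one.
#'
#' @param gr a `GRanges`.
#' @param merge_bookended merge intervals that touch but do not overlap?
#' @return a sorted, pairwise-disjoint `GRanges` covering the same bases.
#' @examples
#' merge_intervals(granges0("chr1", c(100, 150, 250), c(200, 250, 300)))
#' @export
merge_intervals <- function(gr, merge_bookended = TRUE) {
  stopifnot(is(gr, "GRanges"))
  GenomicRanges::reduce(gr, min.gapwidth = if (merge_bookended) 1L else 0L,
                        ignore.strand = TRUE)
}

# ---- file I/O --------------------------------------------------------------

read_tab <- function(path, ncol_min, what) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep))
    return(list(fields = list(), lineno = integer(0)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  short <- which(vapply(fields, length, 1L) < ncol_min)
  if (length(short))
    stop(sprintf("%s: malformed %s line %d (fewer than %d columns)",
                 path, what, lineno[short[1]], ncol_min))
  list(fields = fields, lineno = lineno)
}

#' Read a BED3+ or narrowPeak file into a PeakSet
#'
#' BED is already 0-based half-open, so coordinates are stored as given.
#' narrowPeak name (col 4) and signal (col 7, falling back to score col 5)
#' are retained as metadata; extra BED columns beyond the first three are
#' kept as `name`/`score` when present. Unsorted input is sorted on load;
#' lines with `start >= end` or non-numeric coordinates are rejected with
#' their line number.
#'
#' @param path file path.
#' @param cell_line,assay identifiers attached to the returned [peak_set()].
#' @param format `"bed3"` (also accepts BED4-6) or `"narrowPeak"`.
#' @return a `PeakSet`.
#' @export
read_peaks <- function(path, cell_line, assay, format = c("bed3", "narrowPeak")) {
  format <- match.arg(format)
  tb <- read_tab(path, if (format == "narrowPeak") 10L else 3L, format)
  if (!length(tb$fields))
    return(peak_set(cell_line, assay, GenomicRanges::GRanges()))
  chrom <- vapply(tb$fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(tb$fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(tb$fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("%s: malformed coordinates at line %d", path,
                 tb$lineno[bad[1]]))
  nm <- sc <- NULL
  ncols <- vapply(tb$fields, length, 1L)
  if (all(ncols >= 4)) nm <- vapply(tb$fields, `[`, "", 4L)
  if (format == "narrowPeak") {
    sc <- suppressWarnings(as.numeric(vapply(tb$fields, `[`, "", 7L)))
    if (anyNA(sc))
      sc <- suppressWarnings(as.numeric(vapply(tb$fields, `[`, "", 5L)))
  } else if (all(ncols >= 5)) {
    sc <- suppressWarnings(as.numeric(vapply(tb$fields, `[`, "", 5L)))
  }
  peak_set(cell_line, assay, granges0(chrom, start, end, name = nm, score = sc))
}

#' Write intervals as BED
#'
#' @param gr a `GRanges` (or `PeakSet`); written 0-based half-open. A
#'   `name` metadata column becomes BED column 4, `score` column 5.
#' @param path output path.
#' @param one_based write 1-based inclusive starts instead (non-BED; for
#'   interop with 1-based tooling).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path, one_based = FALSE) {
  if (is(gr, "PeakSet")) gr <- gr$intervals
  df <- as_bed0(gr)
  if (one_based) df$start <- df$start + 1L
  cols <- c("chrom", "start", "end")
  if (!is.null(df$name) || !is.null(df$score)) {
    df$name <- if (is.null(df$name)) "." else ifelse(is.na(df$name), ".", df$name)
    cols <- c(cols, "name")
    if (!is.null(df$score)) {
      df$score <- ifelse(is.na(df$score), 0, df$score)
      cols <- c(cols, "score")
    }
  }
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_snps <- function(df, source = "snp input") {
  bases <- c("A", "C", "G", "T")
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  keep <- df$ref %in% bases & df$alt %in% bases & df$ref != df$alt
  if (any(!keep)) {
    warning(sprintf("%s: skipping %d non-SNV or degenerate record(s) (indels/multi-allelic are unsupported)",
                    source, sum(!keep)), call. = FALSE)
    df <- df[keep, , drop = FALSE]
  }
  if (!is.null(df$maf)) {
    bad <- !is.na(df$maf) & (df$maf < 0 | df$maf > 0.5)
    if (any(bad)) stop(source, ": maf outside [0, 0.5]")
  } else df$maf <- NA_real_
  if (is.null(df$on_array)) df$on_array <- FALSE
  df$pos <- as.integer(df$pos)
  rownames(df) <- NULL
  df[order(df$chrom, df$pos, df$rsid),
     c("rsid", "chrom", "pos", "ref", "alt", "maf", "on_array")]
}

#' Read a SNP catalog from VCF or TSV
#'
#' Accepts either a VCF v4.x (columns CHROM/POS/ID/REF/ALT are used; the
#' 1-based POS is converted to a 0-based `pos`) or a headered 6-7 column TSV
#' `rsid chrom pos ref alt [maf] [on_array]` whose `pos` is already 0-based.
#' Only single-nucleotide ref/alt pairs are kept; indels and multi-allelic
#' records are skipped with a warning.
#'
#' @param path file path; format sniffed from the `##fileformat=VCF` header
#'   or the `.vcf` extension unless given.
#' @param format `"auto"`, `"vcf"` or `"tsv"`.
#' @return a `data.frame` with columns `rsid`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `maf` (NA when absent), `on_array`, sorted by position.
#' @export
read_snps <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^##fileformat=VCF", first) || grepl("\\.vcf$", path))
      "vcf" else "tsv"
  }
  if (format == "vcf") {
    tb <- read_tab(path, 5L, "VCF")
    if (!length(tb$fields))
      return(validate_snps(data.frame(rsid = character(0), chrom = character(0),
                                      pos = integer(0), ref = character(0),
                                      alt = character(0))))
    df <- data.frame(
      rsid = vapply(tb$fields, `[`, "", 3L),
      chrom = vapply(tb$fields, `[`, "", 1L),
      pos = as.integer(vapply(tb$fields, `[`, "", 2L)) - 1L,
      ref = vapply(tb$fields, `[`, "", 4L),
      alt = vapply(tb$fields, `[`, "", 5L),
      stringsAsFactors = FALSE)
  } else {
    # ref/alt must stay character: a bare "T" would otherwise parse as TRUE
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = c(rsid = "character", chrom = "character",
                                    ref = "character", alt = "character"))
    need <- c("rsid", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(df)))
      stop(path, ": TSV SNP table needs columns ", paste(need, collapse = ", "))
  }
  validate_snps(df, path)
}

#' Write a SNP table as TSV
#'
#' Positions stay 0-based (see [read_snps()]).
#' @param snps a SNP `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snps <- function(snps, path) {
  write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

snps_granges <- function(snps) {
  GenomicRanges::GRanges(snps$chrom,
                         IRanges::IRanges(snps$pos + 1L, width = 1L))
}
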