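IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' An IUPAC degenerate consensus motif
#'
#' Plain consensus strings over the 15-letter IUPAC nucleotide alphabet,
#' e.g. the androgen-response-element half site `RGNACR` or the
#' estrogen-response element `RGGTCANNNTGASCY`.
#'
#' @param name motif label.
#' @param pattern IUPAC string (characters `ACGTRYSWKMBDHVN`).
#' @return a list of class `ConsensusMotif` with `name`, `pattern`,
#'   `length`.
#' @examples
#' consensus_motif("ARE", "RGNACR")
#' @export
consensus_motif <- function(name, pattern) {
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  if (!length(chars) || !all(chars %in% names(IUPAC_SETS)))
    stop("consensus_motif: pattern must be a non-empty IUPAC string (ACGTRYSWKMBDHVN)")
  structure(list(name = as.character(name), pattern = pattern,
                 length = length(chars)),
            class = "ConsensusMotif")
}

#' Built-in response-element consensus motifs
#'
#' The androgen-response-element half site (`RGNACR`) and the palindromic
#' estrogen-response element (`RGGTCANNNTGASCY`).
#' @return named list of [consensus_motif()] objects `ARE`, `ERE`.
#' @export
default_motifs <- function() {
  list(ARE = consensus_motif("ARE", "RGNACR"),
       ERE = consensus_motif("ERE", "RGGTCANNNTGASCY"))
}

check_dna <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop(what, ": only A/C/G/T/N allowed")
  seq
}

revcomp <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

# match matrix for one strand: windows x pattern positions. A query base
# matches iff it belongs to the code's degeneracy set; a query N is an
# unknown base and matches nothing except pattern N.
scan_one_strand <- function(chars, pat) {
  w <- length(pat); L <- length(chars)
  nwin <- L - w + 1L
  hit <- matrix(FALSE, nwin, w)
  for (j in seq_len(w)) {
    sj <- chars[j:(j + nwin - 1L)]
    hit[, j] <- if (pat[j] == "N") TRUE & sj != "" # N matches any incl. query N
                else sj %in% IUPAC_SETS[[pat[j]]]
  }
  hit
}

#' Scan a sequence against an IUPAC consensus on both strands
#'
#' Every window of pattern length on the forward and reverse strand is
#' scored by the number of positions whose base lies in the degeneracy set
#' of the corresponding IUPAC code (a query `N` matches only a pattern
#' `N`). Offsets are always reported in forward-strand coordinates of the
#' query; a minus-strand match means the reverse complement of that window
#' matches the pattern.
#'
#' @param seq DNA string over `A/C/G/T/N`, at least as long as the
#'   pattern.
#' @param motif a [consensus_motif()] (or an IUPAC string).
#' @param min_matches report only windows with at least this many matching
#'   positions (default: perfect matches only).
#' @param snp_offset optional 0-based query position of a SNP; fills the
#'   `covers_snp` / `snp_offset_in_site` columns (site coordinates, read
#'   in pattern orientation).
#' @return a `data.frame` sorted by (`matches` desc, `offset` asc, `+`
#'   before `-`): `motif`, `offset` (0-based), `strand`, `matches`,
#'   `mismatch_positions` (comma-joined 0-based pattern positions),
#'   `covers_snp`, `snp_offset_in_site`.
#' @examples
#' iupac_scan("AGTACA", "RGNACR")           # 6/6 on +
#' iupac_scan("TGTACT", "RGNACR")           # 6/6 on -
#' @export
iupac_scan <- function(seq, motif, min_matches = NULL, snp_offset = NULL) {
  if (!is(motif, "ConsensusMotif")) motif <- consensus_motif(motif, motif)
  seq <- check_dna(seq)
  w <- motif$length
  if (nchar(seq) < w)
    stop("iupac_scan: sequence shorter than the pattern")
  if (is.null(min_matches)) min_matches <- w
  pat <- strsplit(motif$pattern, "")[[1]]
  fwd <- strsplit(seq, "")[[1]]
  rev <- strsplit(revcomp(seq), "")[[1]]
  L <- length(fwd); nwin <- L - w + 1L

  one <- function(chars, strand) {
    hit <- scan_one_strand(chars, pat)
    off_rc <- 0:(nwin - 1L)
    offset <- if (strand == "+") off_rc else (L - w) - off_rc
    data.frame(motif = motif$name, offset = offset, strand = strand,
               matches = as.integer(rowSums(hit)),
               mismatch_positions = apply(hit, 1, function(h)
                 paste(which(!h) - 1L, collapse = ",")),
               stringsAsFactors = FALSE)
  }
  res <- rbind(one(fwd, "+"), one(rev, "-"))
  res <- res[res$matches >= min_matches, , drop = FALSE]
  if (!is.null(snp_offset)) {
    stopifnot(snp_offset >= 0, snp_offset < L)
    res$covers_snp <- snp_offset >= res$offset & snp_offset < res$offset + w
    in_site <- snp_offset - res$offset
    res$snp_offset_in_site <- ifelse(!res$covers_snp, NA_integer_,
                                     ifelse(res$strand == "+", in_site,
                                            w - 1L - in_site))
  } else {
    res$covers_snp <- FALSE
    res$snp_offset_in_site <- NA_integer_
  }
  # explicit strand key: "+" before "-" independent of collation locale
  res <- res[order(-res$matches, res$offset, res$strand == "-"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-allele impact of a SNP on the best-matching motif site
#'
#' Substitutes each allele into the flank, scans both allelic sequences
#' against the consensus, and compares them at the shared best site
#' covering the SNP (the window/strand maximising the better of the two
#' allelic scores; ties broken by smaller offset, then `+` strand).
#' `delta = matches(alt) - matches(ref)` there: a negative delta means the
#' alternate allele breaks consensus positions.
#'
#' @param flank DNA string carrying the SNP.
#' @param snp_offset 0-based position of the SNP within `flank`.
#' @param ref,alt the two alleles (single bases).
#' @param motif a [consensus_motif()] (or IUPAC string).
#' @return a list of class `AlleleImpact`: `delta`, `site` (offset/strand
#'   of the shared best site with both allelic scores), `ref_best` and
#'   `alt_best` (each allele's own best SNP-covering match, one-row
#'   `data.frame`s), `ref_matches`, `alt_matches` (at the shared site).
#' @examples
#' allele_impact("TTGGTACGTT", 7, "G", "A", consensus_motif("ARE", "RGNACR"))
#' @export
allele_impact <- function(flank, snp_offset, ref, alt, motif) {
  if (!is(motif, "ConsensusMotif")) motif <- consensus_motif(motif, motif)
  flank <- check_dna(flank, "flank")
  L <- nchar(flank)
  if (!(snp_offset >= 0 && snp_offset < L))
    stop("allele_impact: snp_offset outside the flank")
  ref <- check_dna(ref, "ref"); alt <- check_dna(alt, "alt")
  stopifnot(nchar(ref) == 1, nchar(alt) == 1)
  sub_at <- function(base) {
    s <- strsplit(flank, "")[[1]]; s[snp_offset + 1L] <- base
    paste(s, collapse = "")
  }
  scan_all <- function(s)
    iupac_scan(s, motif, min_matches = 0L, snp_offset = snp_offset)
  mr <- scan_all(sub_at(ref)); ma <- scan_all(sub_at(alt))
  mr <- mr[mr$covers_snp, , drop = FALSE]
  ma <- ma[ma$covers_snp, , drop = FALSE]
  if (!nrow(mr))
    stop("allele_impact: no window of the pattern covers the SNP")
  key <- function(d) paste(d$offset, d$strand)
  ma <- ma[match(key(mr), key(ma)), , drop = FALSE]  # align site-wise
  best_of <- pmax(mr$matches, ma$matches)
  ord <- order(-best_of, mr$offset, mr$strand == "-")
  i <- ord[1]
  structure(list(
    delta = ma$matches[i] - mr$matches[i],
    site = list(offset = mr$offset[i], strand = mr$strand[i]),
    ref_matches = mr$matches[i], alt_matches = ma$matches[i],
    ref_best = mr[which.max(mr$matches), , drop = FALSE],
    alt_best = ma[which.max(ma$matches), , drop = FALSE],
    motif = motif$name), class = "AlleleImpact")
}

#' @export
print.AlleleImpact <- function(x, ...) {
  cat(sprintf("%s site at offset %d (%s): ref %d vs alt %d matches, delta %+d\n",
              x$motif, x$site$offset, x$site$strand,
              x$ref_matches, x$alt_matches, x$delta))
  invisible(x)
}

#' Read SNP-flank sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' character strings named by record.
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_flanks <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
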