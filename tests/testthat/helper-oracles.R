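# Independent oracles: deliberately naive implementations (plain loops,
# base-by-base marking, closed-form enumeration) that never touch the
# package's own code paths.

# -- consensus: base-by-base brute force -------------------------------------

# peaks: data.frame(cell, start, end), 0-based half-open on one chromosome
bf_retained <- function(peaks, frac = 0.5, min_lines = 2, reciprocal = FALSE) {
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    partners <- character(0)
    for (j in seq_len(nrow(peaks))) {
      if (peaks$cell[j] == peaks$cell[i]) next
      ov <- max(0, min(peaks$end[i], peaks$end[j]) -
                   max(peaks$start[i], peaks$start[j]))
      ok <- ov >= frac * (peaks$end[i] - peaks$start[i])
      if (reciprocal)
        ok <- ok && ov >= frac * (peaks$end[j] - peaks$start[j])
      if (ok) partners <- union(partners, peaks$cell[j])
    }
    keep[i] <- length(partners) >= min_lines - 1
  }
  peaks[keep, , drop = FALSE]
}

bf_consensus <- function(peaks, chrom_len, frac = 0.5, min_lines = 2) {
  ret <- bf_retained(peaks, frac, min_lines)
  cover <- logical(chrom_len)
  for (i in seq_len(nrow(ret)))
    cover[(ret$start[i] + 1):ret$end[i]] <- TRUE
  r <- rle(cover)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# package PeakSets from the flat data.frame form the oracle uses
peaksets_from_df <- function(peaks, assay = "H3K4me1", chrom = "chrT") {
  # one GRanges construction, then per-cell subsets: cheaper than one
  # GRanges per cell when this runs over hundreds of random instances.
  # Pre-sorting the rows keeps row i paired with the i-th interval.
  ord <- order(peaks$start, peaks$end)
  gr <- granges0(chrom, peaks$start[ord], peaks$end[ord])
  cells <- peaks$cell[ord]
  lapply(split(seq_along(gr), cells), function(idx)
    peak_set(cells[idx[1]], assay, gr[idx]))
}

random_peak_df <- function(n_cells, n_peaks, chrom_len = 10000,
                           len_range = c(5, 500)) {
  len <- sample(len_range[1]:len_range[2], n_peaks, replace = TRUE)
  start <- vapply(len, function(l) sample.int(chrom_len - l, 1) - 1L, 0L)
  data.frame(cell = sample(sprintf("c%d", seq_len(n_cells)), n_peaks,
                           replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

# -- Fisher: exhaustive enumeration with closed-form table probabilities ----

enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  pobs <- probs[xs == a]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# -- motif: positionwise double-loop scorer ----------------------------------

iupac_map <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

bf_match_count <- function(window, pat_chars) {
  s <- strsplit(window, "")[[1]]
  sum(vapply(seq_along(pat_chars), function(j) {
    if (s[j] == "N") pat_chars[j] == "N"
    else s[j] %in% iupac_map[[pat_chars[j]]]
  }, TRUE))
}

bf_scan <- function(seq, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  w <- length(pat); L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rows <- list()
  for (off in 0:(L - w)) {
    win <- substr(seq, off + 1, off + w)
    rows[[length(rows) + 1]] <- data.frame(offset = off, strand = "+",
                                           matches = bf_match_count(win, pat))
    rc_off <- L - w - off
    win_rc <- substr(rc, rc_off + 1, rc_off + w)
    rows[[length(rows) + 1]] <- data.frame(offset = off, strand = "-",
                                           matches = bf_match_count(win_rc, pat))
  }
  do.call(rbind, rows)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# -- SNP annotation: exhaustive per-SNP scan ---------------------------------

# consensus: named list marker -> data.frame(start, end); tf: named list of
# data.frame(start, end); snps: data.frame(rsid, pos)
bf_annotate <- function(snps, consensus, tf, proximity = 0,
                        mode = "region_overlap") {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    p <- snps$pos[i]
    markers <- character(0); regions <- list()
    for (m in names(consensus)) {
      cr <- consensus[[m]]
      for (k in seq_len(nrow(cr))) {
        d <- if (p >= cr$start[k] && p < cr$end[k]) 0
             else if (p < cr$start[k]) cr$start[k] - p else p - (cr$end[k] - 1)
        if (d <= proximity) {
          markers <- c(markers, m)
          regions[[m]] <- cr[k, ]
          break
        }
      }
    }
    if (!length(markers)) next
    bound <- character(0)
    for (t in names(tf)) {
      hit <- FALSE
      for (k in seq_len(nrow(tf[[t]]))) {
        if (mode == "snp_in_peak") {
          if (p >= tf[[t]]$start[k] && p < tf[[t]]$end[k]) hit <- TRUE
        } else {
          for (m in markers) {
            r <- regions[[m]]
            if (max(0, min(r$end, tf[[t]]$end[k]) -
                       max(r$start, tf[[t]]$start[k])) > 0) hit <- TRUE
          }
        }
      }
      if (hit) bound <- c(bound, t)
    }
    out[[length(out) + 1]] <- data.frame(
      rsid = snps$rsid[i], markers = paste(sort(markers), collapse = ","),
      bound_tfs = paste(sort(bound), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(rsid = character(0),
                                      markers = character(0),
                                      bound_tfs = character(0)))
  do.call(rbind, out)
}

sort_markers <- function(x) vapply(strsplit(x, ","), function(m)
  paste(sort(m), collapse = ","), "")
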