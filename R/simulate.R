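#' Configuration of the synthetic-data generators
#'
#' The generators emulate the statistical structure of the real inputs: a
#' multi-cell-line peak landscape in which shared "true" regulatory
#' elements reappear (with peak-caller edge jitter and imperfect
#' detection) across cell lines on top of cell-line-specific noise peaks;
#' a SNP catalog planted inside and outside those elements; TF binding
#' regions covering a known subset of elements; allele quantification with
#' a planted ChIP bias; and Ct tables following a stated fold-change
#' model. One seed fixes every draw.
#'
#' `n_true_regions` counts planted regulatory *elements*; every element
#' carries H3K4me1, promoter elements (fraction `promoter_frac`) also
#' carry H3K4me3, and each auxiliary mark (H3K9ac, H3K27ac, DNase, FAIRE)
#' decorates an element independently with probability `aux_mark_prob`, so
#' the per-marker landscapes are co-located and the enhancer/promoter
#' truth labels are coherent.
#'
#' @param seed RNG seed (fixes all output).
#' @param n_cell_lines number of cell lines.
#' @param chrom,chrom_length toy chromosome name and length (bp).
#' @param n_true_regions number of planted regulatory elements.
#' @param region_length_range `c(min, max)` element length (bp).
#' @param peak_jitter_sd Gaussian sd (bp) applied to each emitted peak
#'   edge, truncated so start < end.
#' @param peak_detection_prob probability a cell line emits a peak at an
#'   element it marks.
#' @param n_noise_peaks_per_line noise peaks per cell line per marker (and
#'   per TF track), placed away from elements.
#' @param n_snps,frac_snps_in_regions SNP catalog size and the fraction
#'   planted inside elements; background SNPs keep a guard band of
#'   `3 * peak_jitter_sd` bp from element edges so truth labels are
#'   unambiguous under jitter.
#' @param tf_overlap_prob probability a TF binds (covers) an element.
#' @param tfs TF symbols to simulate.
#' @param promoter_frac fraction of elements with the promoter signature.
#' @param aux_mark_prob per-element probability of each auxiliary mark.
#' @param allele_bias P(allele A) in the ChIP sample (input is 0.5).
#' @param read_depth quantification units per allele-count sample.
#' @param ct_noise_sd Gaussian noise sd on simulated Ct values (cycles).
#' @return a list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L, n_cell_lines = 5L, chrom = "chrS",
                       chrom_length = 1e6, n_true_regions = 40L,
                       region_length_range = c(300L, 1000L),
                       peak_jitter_sd = 20, peak_detection_prob = 0.9,
                       n_noise_peaks_per_line = 20L, n_snps = 200L,
                       frac_snps_in_regions = 0.5, tf_overlap_prob = 0.6,
                       tfs = c("AR", "ER"), promoter_frac = 0.4,
                       aux_mark_prob = 0.5, allele_bias = 0.5,
                       read_depth = 200L, ct_noise_sd = 0.2) {
  probs <- c(peak_detection_prob, frac_snps_in_regions, tf_overlap_prob,
             promoter_frac, aux_mark_prob, allele_bias)
  stopifnot(all(probs >= 0 & probs <= 1), chrom_length > 0,
            n_true_regions >= 0, region_length_range[1] > 0,
            region_length_range[1] <= region_length_range[2],
            peak_jitter_sd >= 0, read_depth > 0, ct_noise_sd >= 0)
  structure(as.list(environment())[
    c("seed", "n_cell_lines", "chrom", "chrom_length", "n_true_regions",
      "region_length_range", "peak_jitter_sd", "peak_detection_prob",
      "n_noise_peaks_per_line", "n_snps", "frac_snps_in_regions",
      "tf_overlap_prob", "tfs", "promoter_frac", "aux_mark_prob",
      "allele_bias", "read_depth", "ct_noise_sd")],
    class = "SimConfig")
}

# non-overlapping element placement with a fixed gap on both sides
place_elements <- function(n, lengths, chrom_length, guard) {
  if (n == 0) return(integer(0))
  free <- chrom_length - sum(lengths) - guard * (n + 1)
  if (free < 0)
    stop("simulate_landscape: infeasible placement - element demand exceeds the chromosome")
  slack <- sort(runif(n, 0, free))
  starts <- floor(guard + slack + cumsum(c(0, lengths[-n])) +
                    guard * (seq_len(n) - 1))
  as.integer(starts)
}

sample_avoiding <- function(n, len_range, chrom_length, forbidden, guard) {
  # forbidden: matrix-like df with start,end (0-based half-open)
  out_start <- integer(0); out_end <- integer(0)
  pad_s <- forbidden$start - guard; pad_e <- forbidden$end + guard
  tries <- 0L
  while (length(out_start) < n && tries < n * 200L) {
    tries <- tries + 1L
    len <- round(runif(1, len_range[1], len_range[2]))
    s <- floor(runif(1, 0, chrom_length - len))
    e <- s + len
    if (!any(s < pad_e & e > pad_s)) {
      out_start <- c(out_start, s); out_end <- c(out_end, e)
    }
  }
  if (length(out_start) < n)
    stop("simulate_landscape: infeasible placement of noise peaks/background SNPs")
  data.frame(start = as.integer(out_start), end = as.integer(out_end))
}

jitter_peak <- function(s, e, sd, chrom_length) {
  repeat {
    js <- s + round(rnorm(1, 0, sd)); je <- e + round(rnorm(1, 0, sd))
    js <- max(0, js); je <- min(chrom_length, je)
    if (js < je) return(c(js, je))
  }
}

#' Simulate a multi-cell-line regulatory landscape with ground truth
#'
#' See [sim_config()] for the generative model. All randomness is drawn
#' after `set.seed(cfg$seed)`, so the output (including any files written
#' by [write_landscape()]) is byte-reproducible.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `SimulatedLandscape`:
#' \describe{
#'   \item{peak_sets}{list marker -> list of [peak_set()] (one per cell
#'     line).}
#'   \item{tf_peaks}{named list TF -> [peak_set()] (binding regions pooled
#'     across cell lines, as TF inputs are in practice).}
#'   \item{snps}{SNP catalog `data.frame` (see [read_snps()]).}
#'   \item{truth}{`elements` (`data.frame`: start, end, class, markers,
#'     tfs) and `snps` (`data.frame`: rsid, element 0-based index or NA,
#'     in_region, markers, reg_class, bound_tfs) - the planted labels,
#'     recomputable from the planted coordinates.}
#' }
#' @export
simulate_landscape <- function(cfg = sim_config()) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg$seed)
  guard <- 3 * cfg$peak_jitter_sd + 100
  n <- cfg$n_true_regions
  lens <- as.integer(round(runif(n, cfg$region_length_range[1],
                                 cfg$region_length_range[2])))
  starts <- place_elements(n, lens, cfg$chrom_length, guard)
  ends <- starts + lens

  is_promoter <- runif(n) < cfg$promoter_frac
  marks <- lapply(seq_len(n), function(i) {
    m <- "H3K4me1"
    if (is_promoter[i]) m <- c(m, "H3K4me3")
    for (aux in c("H3K9ac", "H3K27ac", "DNase", "FAIRE"))
      if (runif(1) < cfg$aux_mark_prob) m <- c(m, aux)
    m
  })
  tf_bound <- lapply(seq_len(n), function(i)
    cfg$tfs[runif(length(cfg$tfs)) < cfg$tf_overlap_prob])

  elements <- data.frame(
    start = starts, end = ends,
    class = ifelse(is_promoter, "promoter", "enhancer"),
    markers = vapply(marks, paste, "", collapse = ","),
    tfs = vapply(tf_bound, paste, "", collapse = ","),
    stringsAsFactors = FALSE)

  cells <- sprintf("cell%02d", seq_len(cfg$n_cell_lines))
  markers_all <- MARKER_ASSAYS
  peak_sets <- lapply(markers_all, function(mk) {
    lapply(cells, function(cl) {
      ss <- integer(0); ee <- integer(0)
      for (i in seq_len(n)) {
        if (!(mk %in% marks[[i]])) next
        if (runif(1) >= cfg$peak_detection_prob) next
        p <- jitter_peak(starts[i], ends[i], cfg$peak_jitter_sd,
                         cfg$chrom_length)
        ss <- c(ss, p[1]); ee <- c(ee, p[2])
      }
      if (cfg$n_noise_peaks_per_line > 0) {
        nz <- sample_avoiding(cfg$n_noise_peaks_per_line,
                              cfg$region_length_range, cfg$chrom_length,
                              elements, guard)
        ss <- c(ss, nz$start); ee <- c(ee, nz$end)
      }
      peak_set(cl, mk, if (length(ss)) granges0(cfg$chrom, ss, ee)
                       else GenomicRanges::GRanges())
    })
  })
  names(peak_sets) <- markers_all

  tf_peaks <- lapply(cfg$tfs, function(tf) {
    ss <- integer(0); ee <- integer(0)
    for (i in seq_len(n)) {
      if (!(tf %in% tf_bound[[i]])) next
      pad <- round(runif(2, 20, 100))
      ss <- c(ss, max(0, starts[i] - pad[1]))
      ee <- c(ee, min(cfg$chrom_length, ends[i] + pad[2]))
    }
    if (cfg$n_noise_peaks_per_line > 0) {
      nz <- sample_avoiding(cfg$n_noise_peaks_per_line,
                            cfg$region_length_range, cfg$chrom_length,
                            elements, guard)
      ss <- c(ss, nz$start); ee <- c(ee, nz$end)
    }
    peak_set("pooled", tf, if (length(ss)) granges0(cfg$chrom, ss, ee)
                           else GenomicRanges::GRanges())
  })
  names(tf_peaks) <- cfg$tfs

  n_in <- round(cfg$n_snps * cfg$frac_snps_in_regions)
  n_out <- cfg$n_snps - n_in
  pos_in <- integer(0); elem_in <- integer(0)
  if (n_in > 0 && n > 0) {
    elem_in <- sample.int(n, n_in, replace = TRUE)
    pos_in <- vapply(elem_in, function(i) {
      margin <- min(floor((lens[i] - 1) / 2), ceiling(3 * cfg$peak_jitter_sd))
      as.integer(floor(runif(1, starts[i] + margin, ends[i] - margin)))
    }, 0L)
  }
  pos_out <- integer(0)
  if (n_out > 0) {
    bg <- sample_avoiding(n_out, c(1L, 1L), cfg$chrom_length, elements, guard)
    pos_out <- bg$start
  }
  pos <- c(pos_in, pos_out)
  elem <- c(elem_in, rep(NA_integer_, n_out))
  ord <- order(pos)
  pos <- pos[ord]; elem <- elem[ord]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  snps <- data.frame(
    rsid = sprintf("rs%06d", seq_along(pos)),
    chrom = cfg$chrom, pos = pos, ref = ref, alt = unname(alt),
    maf = round(runif(length(pos), 0.01, 0.5), 4),
    on_array = runif(length(pos)) < 0.3,
    stringsAsFactors = FALSE)

  truth_snps <- data.frame(
    rsid = snps$rsid, element = elem, in_region = !is.na(elem),
    markers = ifelse(is.na(elem), "", elements$markers[elem]),
    reg_class = ifelse(is.na(elem), "unclassified", elements$class[elem]),
    bound_tfs = ifelse(is.na(elem), "", elements$tfs[elem]),
    stringsAsFactors = FALSE)

  structure(list(cfg = cfg, peak_sets = peak_sets, tf_peaks = tf_peaks,
                 snps = snps,
                 truth = list(elements = elements, snps = truth_snps)),
            class = "SimulatedLandscape")
}

#' @export
print.SimulatedLandscape <- function(x, ...) {
  cat(sprintf("SimulatedLandscape: %d element(s), %d cell line(s), %d SNP(s), TFs: %s (seed %d)\n",
              nrow(x$truth$elements), x$cfg$n_cell_lines, nrow(x$snps),
              paste(x$cfg$tfs, collapse = ","), x$cfg$seed))
  invisible(x)
}

#' Write a simulated landscape to disk
#'
#' Emits one BED per marker per cell line (`<marker>.<cell>.bed`), one BED
#' per TF (`tf_<TF>.bed`), the SNP catalog as both TSV (`snps.tsv`,
#' 0-based) and VCF (`snps.vcf`, 1-based), and the truth table as
#' `truth.json`.
#'
#' @param sim a [simulate_landscape()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_landscape <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (mk in names(sim$peak_sets))
    for (ps in sim$peak_sets[[mk]]) {
      p <- file.path(dir, sprintf("%s.%s.bed", mk, ps$cell_line))
      write_intervals(ps, p); paths[basename(p)] <- p
    }
  for (tf in names(sim$tf_peaks)) {
    p <- file.path(dir, sprintf("tf_%s.bed", tf))
    write_intervals(sim$tf_peaks[[tf]], p); paths[basename(p)] <- p
  }
  p <- file.path(dir, "snps.tsv"); write_snps(sim$snps, p)
  paths["snps.tsv"] <- p
  p <- file.path(dir, "snps.vcf")
  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", sim$cfg$chrom,
                   as.integer(sim$cfg$chrom_length)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", sim$snps$chrom,
                   sim$snps$pos + 1L, sim$snps$rsid, sim$snps$ref,
                   sim$snps$alt))
  writeLines(vcf, p); paths["snps.vcf"] <- p
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, p, dataframe = "columns", na = "null",
                       auto_unbox = FALSE, digits = NA)
  paths["truth.json"] <- p
  invisible(paths)
}

#' Simulate allele quantification with a planted ChIP bias
#'
#' Input units are binomial with P(A) = 0.5 at `read_depth` total units;
#' ChIP units are binomial with P(A) = `allele_bias`.
#'
#' @param cfg a [sim_config()]; `allele_bias` and `read_depth` are used.
#'   Pass `seed = NULL` inside loops that manage the RNG themselves.
#' @return a list: `input` and `chip` ([allele_counts()]) plus `truth`
#'   (`allele_bias`, `read_depth`).
#' @export
simulate_allele_counts <- function(cfg = sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  d <- cfg$read_depth
  ia <- rbinom(1, d, 0.5); ca <- rbinom(1, d, cfg$allele_bias)
  inp <- allele_counts("input", ia, d - ia)
  # degenerate chip draws (all one allele) are legal; allele_counts only
  # rejects an all-zero sample, impossible here since d > 0
  chip <- allele_counts("ChIP", max(ca, 0), d - ca)
  list(input = inp, chip = chip,
       truth = list(allele_bias = cfg$allele_bias, read_depth = d))
}

#' Simulate a Ct table from planted fold changes
#'
#' `Ct(target, condition) = base_ct - log2(fold) + N(0, ct_noise_sd)`;
#' reference genes keep their base Ct (up to noise) in every condition.
#'
#' @param cfg a [sim_config()]; `ct_noise_sd` and `seed` are used.
#' @param fold_changes named numeric: planted fold change per condition
#'   (relative to the condition with fold 1, typically the control).
#' @param target,reference_genes gene names.
#' @param n_replicates technical replicates per (gene, condition).
#' @param base_ct named numeric baseline Ct per gene (defaults: target 25,
#'   references 20, 22, ...).
#' @return a Ct `data.frame` (gene, condition, replicate, ct) suitable for
#'   [ddct_expression()].
#' @export
simulate_ct <- function(cfg = sim_config(),
                        fold_changes = c(EtOH = 1, DHT = 2),
                        target = "TARGET",
                        reference_genes = c("GAPDH", "B2M"),
                        n_replicates = 3L, base_ct = NULL) {
  stopifnot(all(fold_changes > 0), n_replicates >= 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  genes <- c(target, reference_genes)
  if (is.null(base_ct))
    base_ct <- setNames(c(25, 20 + 2 * (seq_along(reference_genes) - 1)),
                        genes)
  rows <- list()
  for (cond in names(fold_changes))
    for (g in genes) {
      mu <- base_ct[[g]] - if (g == target) log2(fold_changes[[cond]]) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond, replicate = seq_len(n_replicates),
        ct = mu + rnorm(n_replicates, 0, cfg$ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}

#' Simulate SNP flanks with a planted motif instance
#'
#' Builds random flanking sequences in which a concrete instance of the
#' consensus motif covers the SNP at a non-degenerate pattern position:
#' the reference allele completes the site, the alternate allele breaks
#' it. Used to exercise [allele_impact()] with a known answer.
#'
#' @param cfg a [sim_config()] (seed).
#' @param n number of flanks.
#' @param motif a [consensus_motif()].
#' @param flank_halfwidth bases on each side of the SNP (default 25).
#' @return a list of `n` lists: `name`, `flank`, `snp_offset`, `ref`,
#'   `alt`, `site_offset` (planted + strand site start, 0-based).
#' @export
simulate_flanks <- function(cfg = sim_config(), n = 5L,
                            motif = consensus_motif("ARE", "RGNACR"),
                            flank_halfwidth = 25L) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pat <- strsplit(motif$pattern, "")[[1]]
  w <- length(pat); L <- 2L * flank_halfwidth + 1L
  stopifnot(L >= w)
  bases <- c("A", "C", "G", "T")
  # pattern positions where some base falls outside the degeneracy set
  breakable <- which(vapply(pat, function(p)
    length(setdiff(bases, IUPAC_SETS[[p]])) > 0, TRUE))
  stopifnot(length(breakable) > 0)
  lapply(seq_len(n), function(k) {
    snp_off <- flank_halfwidth
    pos_in_site <- unname(sample(breakable, 1))
    site_off <- snp_off - (pos_in_site - 1L)
    if (site_off < 0 || site_off + w > L) site_off <- max(0L, min(L - w, site_off))
    pos_in_site <- snp_off - site_off + 1L
    alt <- sample(setdiff(bases, IUPAC_SETS[[pat[pos_in_site]]]), 1)
    # redraw the background until the planted site is the strict best
    # SNP-covering window under either allele, so the truth label
    # (delta < 0 at the planted site) is unambiguous
    for (try in 1:100) {
      seq <- sample(bases, L, replace = TRUE)
      site <- vapply(pat, function(p) sample(IUPAC_SETS[[p]], 1), "")
      seq[(site_off + 1L):(site_off + w)] <- site
      covering <- function(s) {
        h <- iupac_scan(paste(s, collapse = ""), motif, min_matches = 0L,
                        snp_offset = snp_off)
        h <- h[h$covers_snp, ]
        h$matches[!(h$offset == site_off & h$strand == "+")]
      }
      alt_seq <- seq; alt_seq[snp_off + 1L] <- alt
      if (all(covering(seq) < w) && all(covering(alt_seq) < w)) break
    }
    ref <- seq[snp_off + 1L]
    list(name = sprintf("flank%03d", k), flank = paste(seq, collapse = ""),
         snp_offset = snp_off, ref = ref, alt = alt,
         site_offset = site_off)
  })
}

#' Write simulated flanks as FASTA
#'
#' Record names carry the SNP metadata as `name|snp_offset|ref|alt`.
#' @param flanks result of [simulate_flanks()].
#' @param path FASTA output path.
#' @return `path`, invisibly.
#' @export
write_flanks <- function(flanks, path) {
  lines <- unlist(lapply(flanks, function(f)
    c(sprintf(">%s|%d|%s|%s", f$name, f$snp_offset, f$ref, f$alt), f$flank)))
  writeLines(lines, path)
  invisible(path)
}
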