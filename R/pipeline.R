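#' Read a run configuration (YAML or JSON)
#'
#' A run config drives [run_pipeline()]. Recognised keys:
#' `out_dir` (required), `seed`, `simulate` (logical or a list of
#' [sim_config()] overrides), `peaks` (marker -> cell line -> BED path,
#' when not simulating), `tf_peaks` (TF -> BED path), `snps` (path),
#' `consensus` (`min_overlap_fraction`, `min_supporting_cell_lines`,
#' `merge_bookended`, `reciprocal`), `discover` (`mode`, `proximity_bp`),
#' `prioritize` (`min_maf`, `require_array`), `motifs` (name -> IUPAC
#' pattern), `allele` (`input`/`chip` as `[A, G]` pairs). Unknown top-level
#' keys are rejected.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return the config as a named list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("out_dir", "seed", "simulate", "peaks", "tf_peaks", "snps",
             "consensus", "discover", "prioritize", "motifs", "allele")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("run config: unknown key(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$out_dir)) stop("run config: out_dir is required")
  cfg
}

cfg_or <- function(x, default) if (is.null(x)) default else x

#' Run the whole pipeline from a config
#'
#' Executes simulate (optional) -> consensus per marker -> SNP annotation
#' -> cross-tabulation -> prioritisation -> motif scan (when motifs and
#' flanks are available) -> allele test (when counts are given), writing
#' every artifact under `cfg$out_dir` and finishing with a
#' `manifest.json` listing each output with its MD5 hash. Reruns with
#' identical config and inputs reproduce identical hashes. Progress goes
#' to standard error.
#'
#' @param cfg a config list (see [read_run_config()]) or a path to one.
#' @return invisibly, a list: `status` (0 on success), `manifest` (named
#'   MD5s), `records` (the PRR table), `crosstab`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) message("[prr] ", sprintf(...))
  artifacts <- character(0)
  add <- function(p) artifacts <<- c(artifacts, p)

  ccfg <- do.call(consensus_config, cfg_or(cfg$consensus, list()))
  simulated <- !is.null(cfg$simulate) && !identical(cfg$simulate, FALSE)

  if (simulated) {
    overrides <- if (is.list(cfg$simulate)) cfg$simulate else list()
    if (!is.null(cfg$seed)) overrides$seed <- cfg$seed
    scfg <- do.call(sim_config, overrides)
    note("simulating landscape (seed %d)", scfg$seed)
    sim <- simulate_landscape(scfg)
    simdir <- file.path(out, "simulated")
    for (p in write_landscape(sim, simdir)) add(p)
    peak_sets <- sim$peak_sets
    tf_peaks <- sim$tf_peaks
    snps <- sim$snps
  } else {
    if (is.null(cfg$peaks) || is.null(cfg$snps))
      stop("run config: peaks and snps are required when simulate is off")
    peak_sets <- lapply(names(cfg$peaks), function(mk)
      lapply(names(cfg$peaks[[mk]]), function(cl) {
        path <- cfg$peaks[[mk]][[cl]]
        if (!file.exists(path)) stop("peak file not found: ", path)
        read_peaks(path, cl, mk,
                   format = if (grepl("narrowPeak$", path)) "narrowPeak"
                            else "bed3")
      }))
    names(peak_sets) <- names(cfg$peaks)
    tf_peaks <- lapply(names(cfg_or(cfg$tf_peaks, list())), function(tf) {
      path <- cfg$tf_peaks[[tf]]
      if (!file.exists(path)) stop("TF peak file not found: ", path)
      read_peaks(path, "pooled", tf)
    })
    names(tf_peaks) <- names(cfg_or(cfg$tf_peaks, list()))
    if (!file.exists(cfg$snps)) stop("SNP file not found: ", cfg$snps)
    snps <- read_snps(cfg$snps)
  }

  note("building consensus for %d marker(s)", length(peak_sets))
  consensus <- lapply(names(peak_sets), function(mk)
    build_consensus(peak_sets[[mk]], ccfg))
  names(consensus) <- names(peak_sets)
  for (mk in names(consensus)) {
    p <- file.path(out, sprintf("consensus_%s.bed", mk))
    write_consensus(consensus[[mk]], p)
    add(p); add(paste0(p, ".provenance.tsv"))
  }

  dcfg <- cfg_or(cfg$discover, list())
  note("annotating %d SNP(s)", nrow(snps))
  records <- annotate_snps(snps, consensus, tf_peaks,
                           mode = cfg_or(dcfg$mode, "region_overlap"),
                           proximity_bp = cfg_or(dcfg$proximity_bp, 0L))
  p <- file.path(out, "prr.tsv"); write_prr_records(records, p); add(p)

  xtab <- marker_crosstab(records, names(tf_peaks))
  p <- file.path(out, "table1.tsv")
  write.table(cbind(marker = rownames(xtab), as.data.frame(unclass(xtab))),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  add(p)

  pcfg <- cfg_or(cfg$prioritize, list())
  prio <- prioritize_records(records, cfg_or(pcfg$min_maf, 0),
                             cfg_or(pcfg$require_array, FALSE))
  p <- file.path(out, "prr_prioritized.tsv"); write_prr_records(prio, p)
  add(p)

  motifs <- cfg_or(cfg$motifs,
                   list(ARE = "RGNACR", ERE = "RGGTCANNNTGASCY"))
  if (simulated && length(motifs)) {
    note("motif scan on simulated flanks")
    fl <- simulate_flanks(scfg, n = 10L,
                          motif = consensus_motif(names(motifs)[1],
                                                  motifs[[1]]))
    p <- file.path(out, "flanks.fa"); write_flanks(fl, p); add(p)
    rows <- do.call(rbind, lapply(fl, function(f) {
      do.call(rbind, lapply(names(motifs), function(mn) {
        imp <- allele_impact(f$flank, f$snp_offset, f$ref, f$alt,
                             consensus_motif(mn, motifs[[mn]]))
        data.frame(name = f$name, motif = mn, ref = f$ref, alt = f$alt,
                   site_offset = imp$site$offset, strand = imp$site$strand,
                   ref_matches = imp$ref_matches,
                   alt_matches = imp$alt_matches, delta = imp$delta,
                   stringsAsFactors = FALSE)
      }))
    }))
    p <- file.path(out, "motif.tsv")
    write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
    add(p)
  }

  if (simulated) {
    ac <- simulate_allele_counts(scfg)
    res <- fisher_allele_test(ac$input, ac$chip)
  } else if (!is.null(cfg$allele)) {
    res <- fisher_allele_test(unlist(cfg$allele$input),
                              unlist(cfg$allele$chip))
  } else res <- NULL
  if (!is.null(res)) {
    p <- file.path(out, "allele.json")
    jsonlite::write_json(list(fraction_a_pct = as.list(res$fraction_a_pct),
                              p_value = res$p_value,
                              odds_ratio = res$odds_ratio),
                         p, auto_unbox = TRUE, digits = NA)
    add(p)
  }

  manifest <- tools::md5sum(artifacts)
  names(manifest) <- sub(paste0("^", out, "/?"), "", names(manifest))
  p <- file.path(out, "manifest.json")
  jsonlite::write_json(as.list(manifest), p, auto_unbox = TRUE)
  note("done: %d artifact(s), manifest at %s", length(artifacts), p)
  invisible(list(status = 0L, manifest = manifest, records = records,
                 crosstab = xtab))
}
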