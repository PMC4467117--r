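mk_ps <- function(cell, start, end, assay = "H3K4me1")
  peak_set(cell, assay, granges0("chrT", start, end))

test_that("retention is relative to the candidate peak's own length (>= at 50%)", {
  ret <- retain_supported_peaks(list(mk_ps("A", 100, 200),
                                     mk_ps("B", 150, 300)))
  # A's peak: overlap 50 = 50% of 100 -> retained; B's: 50/150 fails
  expect_identical(as_bed0(ret)[, c("start", "end", "cell_line")],
                   data.frame(start = 100L, end = 200L, cell_line = "A"))
  # identical peaks in two lines: both retained
  ret2 <- retain_supported_peaks(list(mk_ps("A", 500, 600),
                                      mk_ps("B", 500, 600)))
  expect_identical(nrow(as_bed0(ret2)), 2L)
  # a single cell line has no second line: nothing retained
  expect_length(retain_supported_peaks(list(mk_ps("A", 100, 200))), 0)
  # reciprocal variant rejects the asymmetric pair entirely
  cfg <- consensus_config(reciprocal = TRUE)
  expect_length(retain_supported_peaks(list(mk_ps("A", 100, 200),
                                            mk_ps("B", 150, 300)), cfg), 0)
})

test_that("mixed assays are rejected and same-line peaks never support each other", {
  expect_error(build_consensus(list(mk_ps("A", 1, 10),
                                    mk_ps("B", 1, 10, assay = "H3K4me3"))),
               "mixed assays")
  # two overlapping peaks in the SAME cell line are not mutual support
  expect_length(retain_supported_peaks(list(mk_ps("A", c(100, 120), c(200, 220)),
                                            mk_ps("B", 5000, 5100))), 0)
})

test_that("build_consensus composes retention and merge, with provenance", {
  cons <- build_consensus(list(mk_ps("A", 100, 200), mk_ps("B", 150, 300)))
  expect_identical(as_bed0(cons$regions)[, c("start", "end")],
                   data.frame(start = 100L, end = 200L))
  expect_identical(cons$provenance[[1]]$cell_line, "A")
  # unsupported third line drops out
  cons2 <- build_consensus(list(mk_ps("A", 100, 200), mk_ps("B", 100, 200),
                                mk_ps("C", 1000, 1100)))
  expect_identical(nrow(as_bed0(cons2$regions)), 1L)
  expect_setequal(cons2$provenance[[1]]$cell_line, c("A", "B"))
  # empty input
  expect_length(build_consensus(list(mk_ps("A", numeric(0), numeric(0))))$regions, 0)
})

test_that("retained peaks are input peaks verbatim and coverage is within the input union", {
  set.seed(101)
  for (i in 1:20) {
    df <- random_peak_df(n_cells = sample(2:5, 1), n_peaks = 60)
    ps <- peaksets_from_df(df)
    cfg <- consensus_config()
    ret <- as_bed0(retain_supported_peaks(ps, cfg))
    if (nrow(ret))
      expect_true(all(paste(ret$start, ret$end) %in%
                        paste(df$start, df$end)))
    cons <- build_consensus(ps, cfg)
    inp_union <- merge_intervals(granges0("chrT", df$start, df$end))
    ov <- GenomicRanges::intersect(cons$regions, inp_union)
    expect_identical(sum(GenomicRanges::width(ov)),
                     sum(GenomicRanges::width(cons$regions)))
  }
})

test_that("evidence monotonicity: duplicating a cell line never removes regions", {
  set.seed(202)
  for (i in 1:10) {
    df <- random_peak_df(n_cells = 3, n_peaks = 40)
    ps <- peaksets_from_df(df)
    cons <- build_consensus(ps)
    dup <- df[df$cell == df$cell[1], ]
    dup$cell <- "dup"
    cons2 <- build_consensus(peaksets_from_df(rbind(df, dup)))
    # every old region is covered by a new region
    if (length(cons$regions))
      expect_identical(
        sum(GenomicRanges::width(GenomicRanges::intersect(cons$regions,
                                                          cons2$regions))),
        sum(GenomicRanges::width(cons$regions)))
  }
})

test_that("relabeling cell lines leaves the consensus unchanged", {
  set.seed(303)
  df <- random_peak_df(n_cells = 4, n_peaks = 80)
  cons <- build_consensus(peaksets_from_df(df))
  relab <- df
  relab$cell <- chartr("1234", "4321", relab$cell)
  cons2 <- build_consensus(peaksets_from_df(relab))
  expect_identical(as_bed0(cons$regions), as_bed0(cons2$regions))
})

test_that("min_supporting_cell_lines > 2 requires partners in that many lines", {
  # peak in A supported by B only: passes k=2, fails k=3
  ps <- list(mk_ps("A", 100, 200), mk_ps("B", 100, 200),
             mk_ps("C", 5000, 5100))
  expect_identical(length(build_consensus(ps, consensus_config())$regions), 1L)
  cfg3 <- consensus_config(min_supporting_cell_lines = 3)
  expect_length(build_consensus(ps, cfg3)$regions, 0)
  ps3 <- list(mk_ps("A", 100, 200), mk_ps("B", 100, 200),
              mk_ps("C", 100, 200))
  expect_identical(length(build_consensus(ps3, cfg3)$regions), 1L)
})

test_that("write_consensus emits the BED and a provenance sidecar", {
  cons <- build_consensus(list(mk_ps("A", 100, 200), mk_ps("B", 100, 200)))
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_consensus(cons, tmp)
  expect_true(file.exists(paste0(tmp, ".provenance.tsv")))
  prov <- read.table(paste0(tmp, ".provenance.tsv"), header = TRUE, sep = "\t")
  expect_setequal(prov$cell_line, c("A", "B"))
  expect_identical(as_bed0(read_peaks(tmp, "x", "m")$intervals)$start, 100L)
})
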