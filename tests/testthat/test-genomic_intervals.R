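test_that("overlap_length handles overlap, book-ended and cross-chromosome cases", {
  expect_identical(overlap_length(c(100, 200), c(150, 300)), 50L)
  expect_identical(overlap_length(c(100, 200), c(200, 300)), 0L)
  expect_identical(overlap_length(c(100, 200), c(150, 300),
                                  chrom_a = "chr1", chrom_b = "chr2"), 0L)
  # symmetry on random pairs
  set.seed(11)
  for (i in 1:50) {
    a <- sort(sample.int(1000, 2)); b <- sort(sample.int(1000, 2))
    if (a[1] == a[2]) a[2] <- a[2] + 1L
    if (b[1] == b[2]) b[2] <- b[2] + 1L
    expect_identical(overlap_length(a, b), overlap_length(b, a))
  }
})

test_that("granges0 validates and round-trips 0-based half-open coordinates", {
  gr <- granges0("chr1", 100, 200)
  expect_identical(GenomicRanges::start(gr), 101L)
  expect_identical(GenomicRanges::end(gr), 200L)
  expect_identical(as_bed0(gr)$start, 100L)
  expect_identical(as_bed0(gr)$end, 200L)
  expect_error(granges0("chr1", 200, 200), "invalid interval")
  expect_error(granges0("chr1", -1, 10), "invalid interval")
})

test_that("merge_intervals merges, respects the book-ended flag, and is idempotent", {
  gr <- granges0("chr1", c(100, 150, 250), c(200, 250, 300))
  m <- merge_intervals(gr, merge_bookended = TRUE)
  expect_identical(as_bed0(m)[, 1:3],
                   data.frame(chrom = "chr1", start = 100L, end = 300L))
  m2 <- merge_intervals(gr, merge_bookended = FALSE)
  expect_identical(as_bed0(m2)$start, c(100L, 250L))
  # disjoint input unchanged; empty input empty
  d <- granges0("chr1", c(10, 30), c(20, 40))
  expect_identical(as_bed0(merge_intervals(d)), as_bed0(d))
  expect_length(merge_intervals(GenomicRanges::GRanges()), 0)
  # properties on random inputs: idempotence and total-length bound
  set.seed(42)
  for (i in 1:25) {
    s <- sample.int(5000, 40); len <- sample.int(300, 40)
    g <- granges0("chrT", s, s + len)
    m <- merge_intervals(g)
    expect_identical(as_bed0(merge_intervals(m)), as_bed0(m))
    expect_lte(sum(GenomicRanges::width(m)), sum(GenomicRanges::width(g)))
    expect_true(all(GenomicRanges::countOverlaps(m, m) == 1))
  }
  # equality iff pairwise disjoint and non-book-ended
  expect_identical(sum(GenomicRanges::width(merge_intervals(d))),
                   sum(GenomicRanges::width(d)))
})

test_that("BED/narrowPeak reading stores coordinates as given and rejects bad lines", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr2\t0\t50"), tmp)
  ps <- read_peaks(tmp, "cellA", "H3K4me1")
  expect_s3_class(ps, "PeakSet")
  expect_identical(as_bed0(ps$intervals)$start, c(100L, 0L))
  # unsorted tolerated, sorted on load
  writeLines(c("chr1\t500\t600", "chr1\t100\t200"), tmp)
  expect_identical(as_bed0(read_peaks(tmp, "a", "m")$intervals)$start,
                   c(100L, 500L))
  # start >= end rejected with line number
  writeLines(c("chr1\t100\t200", "chr1\t300\t300"), tmp)
  expect_error(read_peaks(tmp, "a", "m"), "line 2")
  # narrowPeak: 10 columns, signalValue (col 7) kept as score
  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t200\tpeak1\t850\t.\t12.5\t30.1\t28.2\t55", np)
  p <- read_peaks(np, "a", "m", format = "narrowPeak")
  expect_identical(S4Vectors::mcols(p$intervals)$score, 12.5)
  expect_identical(S4Vectors::mcols(p$intervals)$name, "peak1")
})

test_that("interval write/read round-trip preserves coordinates exactly", {
  set.seed(7)
  s <- sample.int(100000, 60)
  gr <- granges0(sample(c("chr1", "chr2"), 60, replace = TRUE),
                 s, s + sample.int(1000, 60))
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_intervals(gr, tmp)
  back <- read_peaks(tmp, "x", "m")$intervals
  expect_identical(as_bed0(back)[, c("chrom", "start", "end")],
                   as_bed0(gr)[, c("chrom", "start", "end")])
})

test_that("SNP ingest converts VCF 1-based POS, keeps TSV 0-based, skips indels", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t151\trs1\tA\tG\t.\t.\t.",
               "chr1\t300\trs2\tAT\tA\t.\t.\t.",      # indel: skipped
               "chr1\t400\trs3\tC\tC\t.\t.\t."),      # ref == alt: skipped
             vcf)
  expect_warning(snps <- read_snps(vcf), "non-SNV")
  expect_identical(snps$rsid, "rs1")
  expect_identical(snps$pos, 150L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_snps(snps, tsv)
  again <- read_snps(tsv)
  expect_identical(again$pos, 150L)
  expect_true(is.na(again$maf))
  # maf outside [0, 0.5] rejected
  df <- data.frame(rsid = "rs9", chrom = "chr1", pos = 5, ref = "A",
                   alt = "T", maf = 0.7, on_array = FALSE)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_snps(tsv), "maf")
})

test_that("duplicate peaks are tolerated but flagged", {
  ps <- peak_set("a", "m", granges0("chr1", c(10, 10), c(20, 20)))
  expect_identical(ps$n_duplicates, 1L)
})
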