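toy_snps <- function(pos, rsid = sprintf("rs%d", seq_along(pos)),
                     chrom = "chrT")
  data.frame(rsid = rsid, chrom = chrom, pos = as.integer(pos), ref = "A",
             alt = "G", maf = NA_real_, on_array = FALSE,
             stringsAsFactors = FALSE)

test_that("classify_snp_context implements the enhancer/promoter signature", {
  me1 <- granges0("chrT", 100, 200)
  me3 <- granges0("chrT", 140, 160)
  none <- GenomicRanges::GRanges()
  expect_identical(classify_snp_context("chrT", 150, me1, none), "enhancer")
  expect_identical(classify_snp_context("chrT", 150, me1, me3), "promoter")
  expect_identical(classify_snp_context("chrT", 500, me1, me3), "unclassified")
  expect_identical(classify_snp_context("chrT", 150, none, me3), "unclassified")
})

test_that("annotate_snps: TF semantics differ between region_overlap and snp_in_peak", {
  cons <- list(H3K4me1 = granges0("chrT", 100, 200))
  tf <- list(AR = granges0("chrT", 180, 400))
  rec <- annotate_snps(toy_snps(150), cons, tf, mode = "region_overlap")
  expect_identical(rec$bound_tfs, "AR")
  expect_identical(rec$reg_class, "enhancer")
  rec2 <- annotate_snps(toy_snps(150), cons, tf, mode = "snp_in_peak")
  expect_identical(rec2$bound_tfs, "")
  # SNP outside every region is not emitted
  expect_identical(nrow(annotate_snps(toy_snps(5000), cons, tf)), 0L)
})

test_that("proximity attachment and the distance convention", {
  cons <- list(H3K4me1 = granges0("chrT", 100, 200))
  # last inside base is 199; SNP at 205 sits 6 bp away
  rec <- annotate_snps(toy_snps(205), cons, proximity_bp = 10)
  expect_identical(rec$distance, 6L)
  expect_identical(nrow(annotate_snps(toy_snps(205), cons)), 0L)
  expect_identical(nrow(annotate_snps(toy_snps(205), cons,
                                      proximity_bp = 5)), 0L)
  rec2 <- annotate_snps(toy_snps(94), cons, proximity_bp = 10)
  expect_identical(rec2$distance, 6L)
  expect_identical(annotate_snps(toy_snps(150), cons)$distance, 0L)
})

test_that("SNPs on unknown chromosomes are skipped with a message", {
  cons <- list(H3K4me1 = granges0("chrT", 100, 200))
  expect_message(rec <- annotate_snps(toy_snps(c(150, 150),
                                               chrom = c("chrT", "chrZ")),
                                      cons),
                 "chrZ")
  expect_identical(nrow(rec), 1L)
})

test_that("annotate_snps equals the exhaustive per-SNP oracle on random instances", {
  set.seed(404)
  markers <- c("H3K4me1", "H3K4me3", "H3K27ac")
  for (rep in 1:15) {
    cons_df <- lapply(markers, function(m) {
      s <- sort(sample(seq(0, 9000, by = 60), sample(3:12, 1)))
      data.frame(start = s, end = s + sample(20:50, length(s), replace = TRUE))
    })
    names(cons_df) <- markers
    tf_df <- lapply(1:2, function(i) {
      s <- sort(sample(seq(0, 9500, by = 25), 15))
      data.frame(start = s, end = s + sample(10:200, 15, replace = TRUE))
    })
    names(tf_df) <- c("AR", "ER")
    snps <- toy_snps(sample.int(10000, 300) - 1L)
    mode <- sample(c("region_overlap", "snp_in_peak"), 1)
    cons <- lapply(cons_df, function(d) granges0("chrT", d$start, d$end))
    tf <- lapply(tf_df, function(d) granges0("chrT", d$start, d$end))
    got <- annotate_snps(snps, cons, tf, mode = mode)
    want <- bf_annotate(snps, cons_df, tf_df, mode = mode)
    got <- got[order(got$rsid), ]
    want <- want[order(want$rsid), ]
    expect_identical(got$rsid, want$rsid)
    expect_identical(sort_markers(got$markers), want$markers)
    expect_identical(got$bound_tfs, want$bound_tfs)
    # every emitted record lies inside at least one region
    expect_true(all(got$distance == 0L))
  }
})

test_that("marker_crosstab bookkeeping matches the generator truth", {
  # 4 enhancer SNPs bound by AR only, 3 promoter SNPs bound by both,
  # 3 SNPs outside everything
  cons <- list(H3K4me1 = granges0("chrT", c(100, 1000), c(200, 1100)),
               H3K4me3 = granges0("chrT", 1000, 1100))
  tf <- list(AR = granges0("chrT", c(100, 1000), c(200, 1100)),
             ER = granges0("chrT", 1050, 1100))
  pos <- c(110, 120, 130, 140, 1010, 1020, 1030, 5000, 6000, 7000)
  rec <- annotate_snps(toy_snps(pos), cons, tf)
  xt <- marker_crosstab(rec, c("AR", "ER"))
  expect_identical(xt["H3K4me1", "AR"], 7L)
  expect_identical(xt["H3K4me1+H3K4me3", "AR+ER"], 3L)
  expect_gte(xt["H3K4me1+H3K4me3", "AR+ER"], 3L)
  expect_identical(xt["Union", "AR"], 7L)
  expect_identical(xt["Union", "ER"], 3L)
  # zero records -> all-zero table
  expect_true(all(marker_crosstab(empty_prr_records(), c("AR", "ER")) == 0L))
  # one SNP in H3K27ac only, bound by both
  rec1 <- annotate_snps(toy_snps(50),
                        list(H3K27ac = granges0("chrT", 0, 100)),
                        list(AR = granges0("chrT", 0, 100),
                             ER = granges0("chrT", 0, 100)))
  xt1 <- marker_crosstab(rec1, c("AR", "ER"))
  expect_identical(unname(xt1["H3K27ac", ]), c(1L, 1L, 1L))
  expect_identical(unname(xt1["Union", ]), c(1L, 1L, 1L))
  expect_identical(sum(xt1), 6L)
  expect_identical(rec1$reg_class, "acetylation")
})

test_that("prioritize_records filters by MAF and array membership, then sorts", {
  rec <- empty_prr_records()[rep(1, 0), ]
  rec <- rbind(rec, data.frame(
    rsid = c("rs3", "rs1", "rs2"), chrom = "chrT", pos = c(1L, 2L, 3L),
    ref = "A", alt = "G", maf = c(0.30, 0.05, NA), on_array = c(TRUE, FALSE, TRUE),
    reg_class = "enhancer", markers = "H3K4me1", bound_tfs = "AR",
    distance = 0L, regions = "", stringsAsFactors = FALSE))
  expect_identical(prioritize_records(rec)$rsid, c("rs3", "rs1", "rs2"))
  expect_identical(prioritize_records(rec, min_maf = 0.10)$rsid, "rs3")
  expect_identical(prioritize_records(rec, require_array = TRUE)$rsid,
                   c("rs3", "rs2"))
  expect_identical(nrow(prioritize_records(rec, min_maf = 0.10,
                                           require_array = TRUE)), 1L)
  off <- rec; off$on_array <- FALSE
  expect_identical(nrow(prioritize_records(off, require_array = TRUE)), 0L)
})

test_that("PRR tables round-trip through TSV byte-identically", {
  cons <- list(H3K4me1 = granges0("chrT", 100, 200))
  tf <- list(AR = granges0("chrT", 150, 400))
  rec <- annotate_snps(toy_snps(c(150, 160)), cons, tf)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_prr_records(rec, tmp)
  h1 <- unname(tools::md5sum(tmp))
  expect_identical(read_prr_records(tmp), rec)
  write_prr_records(read_prr_records(tmp), tmp)
  expect_identical(unname(tools::md5sum(tmp)), h1)
})
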