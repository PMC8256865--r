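test_that("peak intersection honours the 1-bp half-open overlap rule", {
  a <- peak_set("chr1", 100, 200)
  b <- peak_set("chr1", 199, 300)
  out <- intersect_peaks(a, b)
  expect_equal(length(out), 1L)
  expect_equal(GenomicRanges::start(out), 101L)  # a's coordinates retained
  expect_equal(GenomicRanges::end(out), 200L)

  # end-abutting intervals do not overlap under the half-open convention
  expect_equal(length(intersect_peaks(a, peak_set("chr1", 200, 300))), 0L)
  # different chromosomes never overlap
  expect_equal(length(intersect_peaks(a, peak_set("chr2", 100, 200))), 0L)
})

test_that("intersecting a set with itself is the identity and results are subsets", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 30
    df_a <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                       start = sample(0:500, n))
    df_a$end <- df_a$start + sample(1:80, n, TRUE)
    df_b <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                       start = sample(0:500, n))
    df_b$end <- df_b$start + sample(1:80, n, TRUE)
    a <- peak_set(df_a$chrom, df_a$start, df_a$end)
    b <- peak_set(df_b$chrom, df_b$start, df_b$end)

    expect_equal(intersect_peaks(a, a), a, ignore_attr = TRUE)
    out <- intersect_peaks(a, b)
    key <- function(g) paste(GenomeInfoDb::seqnames(g),
                             GenomicRanges::start(g),
                             GenomicRanges::end(g))
    expect_true(all(key(out) %in% key(a)))

    # count agrees with brute-force pairwise interval arithmetic
    da <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(a)),
                     start = GenomicRanges::start(a) - 1,
                     end = GenomicRanges::end(a))
    db <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(b)),
                     start = GenomicRanges::start(b) - 1,
                     end = GenomicRanges::end(b))
    expect_equal(length(out), sum(oracle_overlap(da, db)))
  }
})

test_that("enhancers are H3K27ac peaks supported by H3K4me1, coordinates retained", {
  k27 <- peak_set("chr1", c(100, 1000), c(500, 1200), label = "H3K27ac")
  k4 <- peak_set("chr1", 300, 700, label = "H3K4me1")
  enh <- define_enhancers(k27, k4)
  expect_equal(length(enh), 1L)
  expect_equal(GenomicRanges::start(enh) - 1L, 100)
  expect_equal(GenomicRanges::end(enh), 500)
  # disjoint marks give no enhancers; covering H3K4me1 keeps everything
  expect_equal(length(define_enhancers(k27, peak_set("chr2", 1, 2))), 0L)
  expect_equal(length(define_enhancers(k27, peak_set("chr1", 0, 2000))), 2L)
})

test_that("BED and promoter TSV round-trip through their readers", {
  pk <- peak_set(c("chr1", "chr1", "chr2"), c(10, 500, 0),
                 c(110, 700, 50), label = "demo")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(pk, bed)
  back <- read_bed(bed)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(pk))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(pk))

  pm <- promoter_map(c("gA", "gB"), c("chr1", "chr2"), c(100, 9000),
                     c("+", "-"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_promoter_map(pm, tsv)
  expect_equal(read_promoter_map(tsv), pm)
  expect_error(promoter_map(c("gA", "gA"), "chr1", c(1, 2)), "unique")
  expect_error(promoter_map("gA", "chr1", -5), ">= 0")
})

test_that("peaks map to the nearest promoter with deterministic tie-breaking", {
  pm <- promoter_map(c("g1", "g2"), "chr1", c(100, 400))
  ann <- annotate_nearest_promoter(peak_set("chr1", 140, 160), pm)
  expect_equal(ann$center, 150)
  expect_equal(ann$gene_id, "g1")  # distance 50 beats 250
  expect_equal(ann$distance, 50)

  # equidistant tie -> lexicographically smallest gene id
  pm_tie <- promoter_map(c("gB", "gA"), "chr1", c(100, 200))
  tie <- annotate_nearest_promoter(peak_set("chr1", 100, 200), pm_tie)
  expect_equal(tie$gene_id, "gA")

  # chromosome without promoters -> unannotated, empty bound set
  none <- annotate_nearest_promoter(peak_set("chrX", 10, 20), pm)
  expect_true(is.na(none$gene_id))
  expect_equal(bound_genes(none), character(0))
})

test_that("nearest-promoter annotation matches a brute-force distance scan", {
  set.seed(7)
  for (rep in 1:3) {
    n_pk <- 150
    n_pr <- 150
    pm <- promoter_map(sprintf("g%03d", sample(999, n_pr)),
                       sample(c("c1", "c2", "c3"), n_pr, TRUE),
                       sample(0:5e4, n_pr))
    start <- sample(0:5e4, n_pk)
    pk <- peak_set(sample(c("c1", "c2", "c3"), n_pk, TRUE),
                   start, start + sample(1:300, n_pk, TRUE))
    ann <- annotate_nearest_promoter(pk, pm)
    expect_equal(ann$gene_id,
                 oracle_nearest(ann$center, ann$chrom, pm))
  }
})

test_that("spike-in scale factor follows the input/IP ratio-of-ratios", {
  # input spike/hg = 0.1, IP spike/hg = 0.2 -> signal halved
  expect_equal(spikein_scale_factor(1e6, 1e5, 1e6, 2e5), 0.5)
  # equal spike:target ratios -> no adjustment
  expect_equal(spikein_scale_factor(2e6, 1e5, 4e6, 2e5), 1)
  expect_error(spikein_scale_factor(1e6, 1e5, 1e6, 0), "positive")
  # invariant to rescaling all four counts
  set.seed(1)
  for (i in 1:20) {
    x <- stats::runif(4, 1, 1e6)
    k <- stats::runif(1, 0.1, 50)
    expect_equal(spikein_scale_factor(x[1] * k, x[2] * k, x[3] * k, x[4] * k),
                 spikein_scale_factor(x[1], x[2], x[3], x[4]))
  }
})

test_that("tags-per-ten-million normalization is linear with the stated scale", {
  expect_equal(tags_per_ten_million(5, 5e6), 10)
  expect_equal(tags_per_ten_million(123, 1e7), 123)  # identity at 1e7 tags
  expect_equal(tags_per_ten_million(0, 5e6), 0)
  expect_error(tags_per_ten_million(5, 0), "positive")
  expect_equal(tags_per_ten_million(c(1, 2, 4), 2e6),
               2 * tags_per_ten_million(c(1, 2, 4), 4e6))
})
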