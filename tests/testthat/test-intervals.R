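test_that("overlap counting respects the half-open boundary convention", {
  a <- data.frame(chrom = "chr1", start = 0L, end = 10L)
  touching <- data.frame(chrom = "chr1", start = 10L, end = 20L)
  overlapping <- data.frame(chrom = "chr1", start = 9L, end = 20L)
  expect_equal(overlap_count(a, touching)$n, 0L)
  expect_equal(overlap_count(a, overlapping)$n, 1L)
  expect_equal(overlap_count(a, a[0, ])$n, 0L)
})

test_that("overlap counting equals the brute-force oracle", {
  set.seed(21)
  for (i in 1:100) {
    a <- random_regions(sample(1:40, 1))
    b <- random_regions(sample(1:40, 1))
    res <- overlap_count(a, b)
    oracle <- brute_overlap_flags(a, b)
    expect_identical(res$flags, oracle)
    expect_identical(res$n, sum(oracle))
  }
})

test_that("merging regions is idempotent and never gains coverage", {
  set.seed(22)
  for (i in 1:20) {
    r <- random_regions(30)
    m1 <- merge_regions(r)
    m2 <- merge_regions(m1)
    expect_equal(m1, m2)
    expect_lte(covered_bases(m1), sum(r$end - r$start))
    expect_equal(covered_bases(m1), covered_bases(r))
  }
})

test_that("region classification applies promoter > exonic precedence", {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(1000L, 3500L), end = c(7000L, 6000L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  # midpoint 2500 lies in gA's body only (single-exon gene) -> exonic
  r1 <- data.frame(chrom = "chr1", start = 2400L, end = 2600L)
  expect_equal(as.character(classify_regions(r1, genes)$category), "exonic")
  # midpoint 6500 is inside gA's exon AND gB's promoter (minus strand,
  # upstream = higher coordinates): promoter takes precedence
  r2 <- data.frame(chrom = "chr1", start = 6400L, end = 6600L)
  expect_equal(as.character(classify_regions(r2, genes)$category), "promoter")
  # midpoint 500 sits in gA's 2-kb upstream window
  r3 <- data.frame(chrom = "chr1", start = 400L, end = 600L)
  expect_equal(as.character(classify_regions(r3, genes)$category), "promoter")
  # gene-free chromosome is intergenic; fractions sum to one
  r4 <- data.frame(chrom = "chrZ", start = 0L, end = 100L)
  cl <- classify_regions(rbind(r1, r2, r3, r4), genes)
  expect_equal(as.character(cl$category[4]), "intergenic")
  expect_equal(sum(attr(cl, "fractions")), 1)
  # strand-less genes are rejected and counted
  g2 <- rbind(genes, data.frame(gene_id = "gC", chrom = "chr1",
                                start = 0L, end = 10L, strand = "."))
  expect_equal(attr(classify_regions(r1, g2), "n_rejected_genes"), 1L)
})

test_that("classification matches the generator's category bookkeeping", {
  gt <- sim_fixture()
  cl <- classify_regions(gt$planted_lmrs, gt$genes)
  expect_equal(as.character(cl$category), gt$categories)
})

test_that("histone-mark overlap report recovers planted fractions", {
  gt <- sim_fixture()
  calls <- read_cgmap(gt$files$cgmap_tol1)
  lmrs <- call_lmrs(calls[calls$chrom != "lambda", ], sample = "tol1")
  rep_ <- mark_overlap_report(lmrs,
                              read_bed(gt$files$peaks_tol1_H3K4me3),
                              read_bed(gt$files$peaks_tol1_H3K27me3))
  planted_frac <- gt$peak_cover[["tol1.H3K27me3"]] / sum(gt$presence[, "tol1"])
  expect_lt(abs(rep_$frac_k27 - planted_frac), 0.03)
  expect_gt(rep_$ratio, 5)
  expect_lt(rep_$ratio, 9)
  # identity and empty edge cases
  expect_equal(mark_overlap_report(lmrs, lmrs[0, ], lmrs)$frac_k27, 1.0)
  empty <- mark_overlap_report(lmrs, lmrs[0, ], lmrs[0, ])
  expect_equal(empty$count_k27, 0L)
  expect_equal(empty$frac_k27, 0)
})

test_that("SNP density handles empty input and recovers planted enrichment", {
  sizes <- data.frame(chrom = "chr1", size = 1e6)
  none <- snp_density(data.frame(chrom = character(), pos = integer()),
                      data.frame(chrom = "chr1", start = 0L, end = 1000L),
                      sizes)
  expect_equal(none$density_inside, 0)
  expect_true(is.na(none$ratio))
  # off-chromosome SNPs are rejected and counted
  d <- snp_density(data.frame(chrom = c("chr1", "chrX"), pos = c(500L, 5L)),
                   data.frame(chrom = "chr1", start = 0L, end = 1000L),
                   sizes)
  expect_equal(d$n_rejected, 1L)
  expect_equal(d$n_inside, 1L)

  gt <- sim_fixture()
  snps <- read_vcf_sites(gt$files$vcf)
  sizes <- read.table(gt$files$chrom_sizes, sep = "\t",
                      col.names = c("chrom", "size"))
  dens <- snp_density(snps, gt$planted_lmrs, sizes)
  expect_lt(abs(dens$ratio - gt$config$snp_enrichment) /
              gt$config$snp_enrichment, 0.10)
})

test_that("realized SNP placement is within 3 binomial SDs of the rates", {
  gt <- sim_fixture()
  cfg <- gt$config
  sc <- gt$snp_counts
  lam_in <- cfg$snp_rate_bg * cfg$snp_enrichment / 1000 * sc$bp_inside
  lam_out <- cfg$snp_rate_bg / 1000 * sc$bp_outside
  expect_lt(abs(sc$n_inside - lam_in), 3 * sqrt(lam_in))
  expect_lt(abs(sc$n_outside - lam_out), 3 * sqrt(lam_out))
})

test_that("BED round-trip preserves regions and extra columns", {
  r <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 50L),
                  end = c(10L, 99L), n_cpg = c(5L, 8L),
                  mean_meth = c(0.1, 0.05))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(r, f, extra = c("n_cpg", "mean_meth"))
  back <- read_bed(f)
  expect_equal(back$chrom, r$chrom)
  expect_equal(back$start, r$start)
  expect_equal(back$end, r$end)
  expect_equal(back[[7]], r$n_cpg)
})

test_that("region recovery scores precision and recall by reciprocal overlap", {
  truth <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                      end = c(100L, 1100L))
  # one good call, one fragment covering only 30% of its truth region
  called <- data.frame(chrom = "chr1", start = c(10L, 1000L),
                       end = c(95L, 1030L))
  r <- region_recovery(called, truth)
  expect_equal(r$recall, 0.5)
  expect_equal(r$precision, 0.5)
  expect_equal(region_recovery(truth, truth)$precision, 1)
})
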