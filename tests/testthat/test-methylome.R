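test_that("CGmap parsing handles direct, empty, and malformed input", {
  f <- withr::local_tempfile()
  writeLines("chr1\tC\t101\tCG\tCG\t0.5\t5\t10", f)
  calls <- read_cgmap(f)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$chrom, "chr1")
  expect_equal(calls$pos, 101L)
  expect_equal(calls$context, "CG")
  expect_equal(calls$meth_count, 5L)
  expect_equal(calls$total_count, 10L)

  empty <- withr::local_tempfile()
  file.create(empty)
  e <- read_cgmap(empty)
  expect_equal(nrow(e), 0L)
  expect_equal(attr(e, "n_malformed"), 0L)

  bad <- withr::local_tempfile()
  writeLines(c("chr1\tC\t10\tCG\tCG\t1.0\t12\t10",   # meth > total
               "chr1\tC\t20\tCG\tCG\t0.1\t1\t10"), bad)
  b <- read_cgmap(bad)
  expect_equal(nrow(b), 1L)
  expect_equal(attr(b, "n_rejected"), 1L)
})

test_that("CGmap round-trips through the synthetic generator", {
  gt <- sim_fixture()
  calls <- read_cgmap(gt$files$cgmap_tol1)
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$meth_count <= calls$total_count))
  expect_false(is.unsorted(calls$pos[calls$chrom == "chr1"]))
  # conservation: one record per simulated cytosine, identical across samples
  calls2 <- read_cgmap(gt$files$cgmap_sus1)
  expect_equal(nrow(calls), nrow(calls2))
  expect_equal(calls$pos, calls2$pos)
})

test_that("region methylation is the pooled methyl-cytosine percentage", {
  calls <- make_calls(c(10, 20), meth = c(0, 0), total = c(10, 5))
  expect_equal(region_methylation(calls, "chr1", 0, 100), 0.0)
  calls <- make_calls(c(10, 20), meth = c(3, 1), total = c(10, 10))
  expect_equal(region_methylation(calls, "chr1", 0, 100), 0.2)  # 4/20
  # missing data is a sentinel, not zero
  expect_true(is.na(region_methylation(calls, "chr1", 500, 600)))
  # half-open boundary: pos 10 is inside [9,10), pos 20 excluded from [9,19)
  expect_equal(region_methylation(calls, "chr1", 9, 19), 0.3)
})

test_that("conversion rate estimates the spike-in failure fraction", {
  expect_equal(conversion_rate(make_calls(1:2, c(1, 0), c(50, 50))), 0.99)
  expect_equal(conversion_rate(make_calls(1, 0, 100)), 1.0)
  expect_true(is.na(conversion_rate(make_calls(1, 0, 0))))
  # binomial simulation: 0.5% failure over 1e5 cytosines
  set.seed(11)
  n <- 1e5
  cov <- rep(1L, n)
  meth <- rbinom(n, 1, 0.005)
  est <- conversion_rate(make_calls(seq_len(n), meth, cov))
  expect_lt(abs(est - 0.995), 0.002)
})

test_that("a planted hypomethylated block becomes exactly one LMR", {
  # 10 CpGs at 0/10 inside a 0.9-methylated background
  pos_bg1 <- seq(100, 1000, by = 100)
  pos_lmr <- seq(1100, 2000, by = 100)
  pos_bg2 <- seq(2100, 3000, by = 100)
  calls <- make_calls(c(pos_bg1, pos_lmr, pos_bg2),
                      meth = c(rep(9, 10), rep(0, 10), rep(9, 10)),
                      total = rep(10, 30))
  lmrs <- call_lmrs(calls)
  expect_equal(nrow(lmrs), 1L)
  expect_equal(lmrs$mean_meth, 0.0)
  # the centered 3-CpG smoothing window reaches into the methylated
  # background at both block edges ((0.9 + 0 + 0)/3 > 0.2), so the run
  # covers the 8 interior CpGs and the segment is [2nd CpG - 1, 9th CpG)
  expect_equal(lmrs$n_cpg, 8L)
  expect_equal(lmrs$start, 1200 - 1)
  expect_equal(lmrs$end, 1900)
  # without smoothing the full planted block is recovered
  raw <- call_lmrs(calls, smooth_k = 1L)
  expect_equal(raw$n_cpg, 10L)
  expect_equal(raw$start, 1100 - 1)
  expect_equal(raw$end, 2000)
})

test_that("CpG-rich unmethylated segments are UMRs, not LMRs", {
  pos <- seq(100, 4000, by = 100)
  calls <- make_calls(pos, meth = rep(0, 40), total = rep(10, 40))
  lmrs <- call_lmrs(calls)
  expect_equal(nrow(lmrs), 0L)
  umrs <- attr(lmrs, "umrs")
  expect_equal(nrow(umrs), 1L)
  expect_equal(umrs$n_cpg, 40L)
})

test_that("segmentation is translation-invariant and threshold-monotone", {
  set.seed(5)
  pos <- sort(sample.int(50000, 300))
  lev <- ifelse(runif(300) < 0.3, 0.05, 0.85)
  calls <- make_calls(pos, meth = round(lev * 20), total = rep(20, 300))
  base <- call_lmrs(calls)
  shifted <- make_calls(pos + 1000L, meth = round(lev * 20),
                        total = rep(20, 300))
  sh <- call_lmrs(shifted)
  expect_equal(sh$start, base$start + 1000L)
  expect_equal(sh$end, base$end + 1000L)
  # raising the threshold never loses covered bases
  cov_at <- function(th) {
    x <- call_lmrs(calls, lmr_threshold = th, umr_cpg_cutoff = 1000L)
    sum(x$end - x$start)
  }
  covs <- vapply(c(0.1, 0.2, 0.3, 0.5), cov_at, numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("LMR output satisfies its declared invariants", {
  gt <- sim_fixture()
  calls <- read_cgmap(gt$files$cgmap_tol1)
  lmrs <- call_lmrs(calls[calls$chrom != "lambda", ], sample = "tol1")
  expect_true(all(lmrs$end > lmrs$start))
  expect_true(all(lmrs$mean_meth >= 0 & lmrs$mean_meth <= 1))
  expect_true(all(lmrs$n_cpg >= 4 & lmrs$n_cpg < 30))
})

test_that("DMR calling: identity gives none, extreme contrast is found", {
  set.seed(3)
  pos <- seq(10, 4000, by = 40)
  a <- make_calls(pos, meth = rbinom(length(pos), 20, 0.5),
                  total = rep(20, length(pos)))
  expect_equal(nrow(call_dmrs(a, a)), 0L)

  # one window with A = 0/50 vs B = 45/50
  pos2 <- seq(10, 200, by = 40)
  a2 <- make_calls(pos2, meth = 0, total = 10)
  b2 <- make_calls(pos2, meth = 9, total = 10)
  dm <- call_dmrs(a2, b2)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$direction, "hypo")
  expect_lt(dm$p, 1e-10)
  # matches the exact Fisher p on the pooled 2x2 table
  expect_equal(dm$p, fisher.test(matrix(c(0, 50, 45, 5), 2))$p.value)
})

test_that("DMR window p-values match the hypergeometric-tail oracle", {
  set.seed(9)
  for (i in 1:25) {
    m1 <- sample(0:15, 1); u1 <- sample(0:15, 1)
    m2 <- sample(0:15, 1); u2 <- sample(0:15, 1)
    if (m1 + u1 < 5 || m2 + u2 < 5) next
    a <- make_calls(10, m1, m1 + u1)
    b <- make_calls(10, m2, m2 + u2)
    dm <- call_dmrs(a, b, alpha_q = 1.1, min_delta = 0)
    # two-sided Fisher equals the sum of hypergeometric point masses no
    # more probable than the observed table
    d <- dhyper(0:(m1 + m2), m1 + u1, m2 + u2, m1 + m2)
    p_oracle <- sum(d[d <= d[m1 + 1] * (1 + 1e-7)])
    expect_equal(dm$p, p_oracle, tolerance = 1e-8)
  }
})
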