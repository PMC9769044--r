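test_that("JASPAR counts convert with pseudocount; MEME round-trips", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1 TF1",
               "A [ 8 0 ]",
               "C [ 0 8 ]",
               "G [ 0 0 ]",
               "T [ 0 0 ]"), f)
  m <- read_motifs(f)[["M1"]]
  expect_equal(m$width, 2L)
  expect_equal(unname(m$probs[1, "A"]), 8.1 / 8.4)
  expect_equal(unname(m$probs[1, "C"]), 0.1 / 8.4)
  expect_equal(unname(m$probs[2, "C"]), 8.1 / 8.4)
  expect_equal(unname(rowSums(m$probs)), c(1, 1), tolerance = 1e-9)

  # width-1 uniform MEME motif
  f2 <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF U1 U1",
               "letter-probability matrix: alength= 4 w= 1 nsites= 20 E= 0",
               "0.25 0.25 0.25 0.25"), f2)
  u <- read_motifs(f2)[["U1"]]
  expect_equal(unname(u$probs[1, ]), rep(0.25, 4))

  # write -> read round trip preserves matrices
  motifs <- default_motif_set()
  f3 <- withr::local_tempfile(fileext = ".meme")
  write_meme(motifs, f3)
  back <- read_motifs(f3)
  expect_equal(names(back), names(motifs))
  for (id in names(motifs)) {
    expect_equal(back[[id]]$probs, motifs[[id]]$probs, tolerance = 1e-5)
  }
})

test_that("an uninformative motif yields no hits", {
  m <- pwm(matrix(0.25, 6, 4), "flat")
  h <- scan_pwm(random_seq(500), m)
  expect_equal(nrow(h), 0L)
})

test_that("scanner hits and p-values match the enumeration oracle", {
  set.seed(61)
  for (w in 4:8) {
    m <- random_pwm(w, sprintf("rnd%d", w))
    s <- random_seq(800)
    got <- scan_pwm(s, m, p_threshold = 1e-3)
    oracle <- enum_scan_oracle(s, m, p_threshold = 1e-3)
    # same hit set up to discretization at the threshold boundary: every
    # hit clearly below threshold on one side must appear on the other
    key <- function(df) paste(df$offset, df$strand)
    core_o <- oracle[oracle$p < 1e-3 / 1.02, ]
    expect_true(all(key(core_o) %in% key(got)))
    core_g <- got[got$p < 1e-3 / 1.02, ]
    expect_true(all(key(core_g) %in% key(oracle[oracle$p < 1e-3 * 1.02, ])))
    # p-values agree within the documented discretization tolerance (2%)
    both <- merge(got, oracle, by = c("offset", "strand"))
    if (nrow(both) > 0) {
      expect_lt(max(abs(log(both$p.x) - log(both$p.y))), log(1.02))
      expect_equal(both$score.x, both$score.y, tolerance = 1e-8)
    }
  }
})

test_that("p-values are monotone in score; hits monotone in threshold", {
  set.seed(62)
  m <- random_pwm(6, "mono")
  s <- random_seq(2000)
  h <- scan_pwm(s, m, p_threshold = 0.05)
  # monotone up to discretization: a clearly higher score never gets a
  # larger p-value (scores within one bin of each other may swap)
  rng <- diff(range(h$score))
  for (i in seq_len(nrow(h))) {
    higher <- h$score > h$score[i] + rng / 100
    expect_true(all(h$p[higher] <= h$p[i] + 1e-12))
  }
  n_hits <- vapply(c(1e-4, 1e-3, 1e-2, 5e-2),
                   function(t) nrow(scan_pwm(s, m, p_threshold = t)),
                   numeric(1))
  expect_true(all(diff(n_hits) >= 0))
})

test_that("scanning obeys reverse-complement symmetry", {
  revcomp_str <- function(s) {
    paste(rev(c(A = "T", C = "G", G = "C", T = "A")[
      strsplit(s, "")[[1]]]), collapse = "")
  }
  set.seed(63)
  m <- random_pwm(7, "sym")
  s <- random_seq(600)
  a <- scan_pwm(s, m, p_threshold = 1e-3)
  b <- scan_pwm(revcomp_str(s), pwm_revcomp(m), p_threshold = 1e-3)
  # a hit at offset i in a maps to offset L - w - i in b with the same
  # strand label (the motif and the sequence are both complemented, so the
  # two flips cancel); the two scans build their discretization grids
  # independently, so only hits clearly inside the threshold must appear
  # on both sides
  L <- nchar(s); w <- m$width
  a_keys <- paste(a$offset, a$strand)
  b_mapped <- paste(L - w - b$offset, b$strand)
  core_a <- paste(a$offset, a$strand)[a$p < 1e-3 / 1.02]
  core_b <- b_mapped[b$p < 1e-3 / 1.02]
  expect_true(all(core_a %in% b_mapped))
  expect_true(all(core_b %in% a_keys))
  # scores of matched hits agree exactly
  m1 <- merge(data.frame(key = a_keys, score = a$score),
              data.frame(key = b_mapped, score = b$score), by = "key")
  expect_equal(m1$score.x, m1$score.y, tolerance = 1e-9)
})

test_that("masked windows are skipped under the skip policy", {
  m <- default_motif_set()$M_NAC
  cons <- pwm_consensus(m)
  s <- paste0(random_seq(100), cons, random_seq(100))
  expect_equal(nrow(scan_pwm(s, m)[scan_pwm(s, m)$offset == 100, ]), 1L)
  masked <- paste0(substr(s, 1, 100), tolower(cons),
                   substr(s, 109, nchar(s)))
  expect_equal(nrow(scan_pwm(masked, m)), 0L)
  expect_equal(nrow(scan_pwm(masked, m, mask = "ignore")), 1L)
  # N always blocks scoring
  withN <- paste0(substr(s, 1, 100), "N", substr(s, 102, nchar(s)))
  expect_equal(sum(scan_pwm(withN, m)$offset == 100), 0L)
})

test_that("planted consensus instances are recovered at offset and strand", {
  gt <- sim_fixture()
  seqs <- region_sequences(gt$files$genome, gt$planted_lmrs)
  motifs <- read_motifs(gt$files$motifs)
  inst <- gt$planted_motif_instances
  hits <- scan_regions(seqs, motifs)
  for (i in seq_len(nrow(inst))) {
    hit <- hits[hits$region_id == inst$region_id[i] &
                  hits$motif_id == inst$motif_id[i] &
                  hits$offset == inst$offset[i], ]
    expect_gte(nrow(hit), 1L)
    expect_true(inst$strand[i] %in% hit$strand)
  }
})

test_that("motif enrichment: null identity, Fisher oracle, planted recovery", {
  set.seed(64)
  motifs <- default_motif_set()
  seqs <- setNames(replicate(30, random_seq(300)), sprintf("r%d", 1:30))
  same <- enrich_motifs(seqs, seqs, motifs)
  expect_true(all(same$p[same$testable] > 0.05))

  # Fisher p equals the hypergeometric tail oracle on given counts
  p_fun <- function(fg_hit, fg_tot, bg_hit, bg_tot) {
    fisher.test(matrix(c(fg_hit, fg_tot - fg_hit, bg_hit, bg_tot - bg_hit),
                       2), alternative = "greater")$p.value
  }
  oracle <- sum(dhyper(50:55, 55, 495, 100))
  expect_equal(p_fun(50, 50, 5, 500), oracle, tolerance = 1e-10)

  # planted enrichment: fixture's first motif in 80% of specific LMRs
  gt <- sim_fixture()
  lmrs <- gt$planted_lmrs
  fg <- lmrs[lmrs$type == "specific", ]
  bg <- lmrs[lmrs$type != "specific", ]
  enr <- enrich_motifs(region_sequences(gt$files$genome, fg),
                       region_sequences(gt$files$genome, bg),
                       read_motifs(gt$files$motifs))
  expect_equal(enr$motif_id[1], names(gt$config$motif_set)[1])
  expect_lt(enr$q[1], 0.05)

  # a motif wider than every foreground region is flagged untestable
  wide <- pwm(matrix(0.25, 400, 4), "wide")
  enr2 <- enrich_motifs(setNames(random_seq(300), "a"),
                        setNames(random_seq(300), "b"), list(wide))
  expect_false(enr2$testable[1])
})

test_that("tolerant-specific LMRs are an overlap-based set difference", {
  a <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L),
                  end = c(50L, 150L, 250L))
  expect_equal(nrow(tolerant_specific_lmrs(a, a)), 0L)
  b <- data.frame(chrom = "chr1", start = 500L, end = 600L)
  expect_equal(nrow(tolerant_specific_lmrs(a, b)), 3L)
  set.seed(65)
  for (i in 1:30) {
    x <- random_regions(20)
    y <- random_regions(20)
    got <- tolerant_specific_lmrs(x, y)
    expect_equal(nrow(got), sum(!brute_overlap_flags(x, y)))
  }
  # optional hypo-DMR intersection keeps only overlapping LMRs
  dmr <- data.frame(chrom = "chr1", start = 120L, end = 130L,
                    direction = "hypo")
  expect_equal(tolerant_specific_lmrs(a, b, dmr)$start, 100L)
})
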