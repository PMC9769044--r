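# Shared synthetic fixture: generated once per test run, reused across files.
.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (is.null(.fixture_env$gt)) {
    dir <- file.path(tempdir(), "regland_fixture")
    .fixture_env$gt <- suppressMessages(
      generate_dataset(sim_config(seed = 1L), dir))
  }
  .fixture_env$gt
}

# Build a call data.frame from explicit per-CpG levels at fixed coverage.
make_calls <- function(pos, meth, total, chrom = "chr1", context = "CG") {
  data.frame(chrom = chrom, pos = as.integer(pos), context = context,
             dinuc = "CG", meth_count = as.integer(meth),
             total_count = as.integer(total), stringsAsFactors = FALSE)
}

# Brute-force overlap oracle: O(n*m) all-pairs comparison on half-open
# intervals, independent of the GenomicRanges-backed implementation.
brute_overlap_flags <- function(a, b, min_overlap = 1L) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] &
          pmin(b$end, a$end[i]) - pmax(b$start, a$start[i]) >= min_overlap)
  }, logical(1))
}

random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L,
                           max_len = 50L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Exhaustive PWM-scan oracle: enumerates all 4^width words, computes each
# word's exact log-odds score and exact tail p-value under the background,
# then scans the sequence literally (both strands). Widths <= 8 only.
enum_scan_oracle <- function(seq, pwm, p_threshold = 1e-4,
                             background = NULL) {
  stopifnot(pwm$width <= 8)
  bg <- if (is.null(background)) pwm$background else
    setNames(as.numeric(background), c("A", "C", "G", "T"))
  S <- log2(sweep(pwm$probs, 2, bg, "/"))
  words <- as.matrix(expand.grid(rep(list(1:4), pwm$width)))[,
    rev(seq_len(pwm$width)), drop = FALSE]
  scores <- rowSums(vapply(seq_len(pwm$width),
                           function(j) S[j, words[, j]],
                           numeric(nrow(words))))
  probs <- apply(words, 1, function(w) prod(bg[w]))
  pval_of <- function(s) sum(probs[scores >= s - 1e-12])
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  codes <- match(chars, c("A", "C", "G", "T"))
  comp <- c(4L, 3L, 2L, 1L)
  hits <- list()
  for (i in seq_len(length(codes) - pwm$width + 1L)) {
    win <- codes[i:(i + pwm$width - 1L)]
    if (anyNA(win)) next
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else rev(comp[win])
      s <- sum(S[cbind(seq_len(pwm$width), w)])
      p <- pval_of(s)
      if (p < p_threshold) {
        hits[[length(hits) + 1L]] <- data.frame(
          offset = i - 1L, strand = strand, score = s, p = p)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), p = numeric()))
  }
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), ]
}

random_pwm <- function(width, motif_id = "rnd", concentration = 0.5) {
  mat <- matrix(stats::rgamma(width * 4, concentration), width, 4)
  mat <- mat / rowSums(mat)
  pwm(mat, motif_id)
}

random_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
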