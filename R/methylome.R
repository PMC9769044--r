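#' Read per-cytosine methylation calls in CGmap format
#'
#' CGmap is the tab-separated per-cytosine format with columns: chromosome,
#' nucleotide on the Watson strand, 1-based position, context (CG/CHG/CHH),
#' dinucleotide, methylation level, methylated read count, total read count.
#'
#' Records with `meth_count > total_count` are rejected and tallied; files
#' not sorted by position within chromosome are sorted in memory with a
#' warning. Malformed lines (wrong column count, non-numeric counts) are
#' dropped and counted.
#'
#' @param path Path to a CGmap file (plain text).
#' @return A data.frame with columns `chrom`, `pos` (1-based), `context`,
#'   `dinuc`, `meth_count`, `total_count`, sorted by chromosome then
#'   position, with attributes `n_malformed` and `n_rejected`.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\tC\t101\tCG\tCG\t0.5\t5\t10", f)
#' read_cgmap(f)
#' @export
read_cgmap <- function(path) {
  stopifnot(file.exists(path))
  empty <- data.frame(chrom = character(), pos = integer(),
                      context = character(), dinuc = character(),
                      meth_count = integer(), total_count = integer(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) {
    attr(empty, "n_malformed") <- 0L
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1:2))
  n_raw <- nrow(dt)
  malformed <- ncol(dt) < 8
  if (malformed) {
    attr(empty, "n_malformed") <- n_raw
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  df <- data.frame(
    chrom = as.character(dt[[1]]),
    pos = suppressWarnings(as.integer(dt[[3]])),
    context = as.character(dt[[4]]),
    dinuc = as.character(dt[[5]]),
    meth_count = suppressWarnings(as.integer(dt[[7]])),
    total_count = suppressWarnings(as.integer(dt[[8]])),
    stringsAsFactors = FALSE
  )
  ok <- stats::complete.cases(df[c("pos", "meth_count", "total_count")]) &
    df$pos >= 1
  n_malformed <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  bad <- df$meth_count > df$total_count | df$meth_count < 0
  n_rejected <- sum(bad)
  df <- df[!bad, , drop = FALSE]
  ord <- order(df$chrom, df$pos)
  if (!identical(ord, seq_len(nrow(df)))) {
    df <- df[ord, , drop = FALSE]
    warning("CGmap records were not position-sorted; sorted in memory")
  }
  rownames(df) <- NULL
  attr(df, "n_malformed") <- n_malformed
  attr(df, "n_rejected") <- n_rejected
  df
}

#' Pooled methylation level of a genomic interval
#'
#' Returns the methyl-cytosine percentage as a fraction:
#' sum of methylated reads over sum of total reads, across calls of the
#' requested context falling in the 0-based half-open interval
#' `[start, end)`. When no covered call lies in the region the result is
#' `NA_real_` (missing signal), never 0.
#'
#' @param calls data.frame as returned by [read_cgmap()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @param context Context filter, default `"CG"`.
#' @return Fraction in \[0,1\], or `NA_real_` when total coverage is zero.
#' @export
region_methylation <- function(calls, chrom, start, end, context = "CG") {
  sel <- calls$chrom == chrom & calls$context %in% context &
    calls$pos >= start + 1L & calls$pos <= end
  tot <- sum(calls$total_count[sel])
  if (tot == 0) return(NA_real_)
  sum(calls$meth_count[sel]) / tot
}

#' Bisulfite conversion rate from an unmethylated spike-in
#'
#' The unmethylated lambda-phage spike-in has no true methylation, so any
#' methylated call on it is a conversion failure. The conversion rate is
#' 1 - sum(meth)/sum(total) over all contexts of the spike-in contig.
#'
#' @param lambda_calls Calls restricted to the spike-in contig.
#' @return Fraction in \[0,1\]; `NA_real_` when total coverage is zero.
#' @export
conversion_rate <- function(lambda_calls) {
  tot <- sum(lambda_calls$total_count)
  if (tot == 0) return(NA_real_)
  1 - sum(lambda_calls$meth_count) / tot
}

# centered running mean over a window of k values, truncated at the ends
smooth_levels <- function(x, k) {
  if (k <= 1 || length(x) <= 1) return(x)
  half <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Segment a methylome into lowly methylated regions (LMRs)
#'
#' Candidate distal regulatory elements are CpG-poor segments whose CG
#' methylation falls below a threshold (default 20 %). Per chromosome, each
#' covered CG's level is smoothed over a centered window of `smooth_k`
#' CpGs (truncated at chromosome ends); maximal runs of consecutive CpGs
#' with smoothed level strictly below `lmr_threshold` become segments
#' spanning `[first CpG - 1, last CpG)` (0-based half-open). Segments with
#' `min_cpg <= n_cpg < umr_cpg_cutoff` are LMRs; CpG-rich segments
#' (`n_cpg >= umr_cpg_cutoff`) are unmethylated regions (UMRs), typically
#' promoter-associated, and are reported separately via the `"umrs"`
#' attribute. Runs are never merged across an interrupting CpG.
#'
#' Note the threshold convention is strict (`< lmr_threshold`): a CpG at
#' exactly the threshold does not qualify. The default of 0.20 follows the
#' common definition of LMRs at under 20 % methylation; parts of the LMR
#' literature use 30 % instead, which can be selected via `lmr_threshold`.
#'
#' @param calls data.frame of cytosine calls (see [read_cgmap()]).
#' @param lmr_threshold Methylation level below which a CpG is hypomethylated.
#' @param smooth_k Centered smoothing window, in CpGs.
#' @param min_cpg Minimum CpGs for an LMR.
#' @param umr_cpg_cutoff CpG count at or above which a segment is a UMR.
#' @param min_cov Minimum read coverage for a CG call to participate.
#' @param sample Optional sample label stored in the output.
#' @return data.frame of LMRs with columns `chrom`, `start`, `end`,
#'   `n_cpg`, `mean_meth`, `sample`; UMRs in `attr(, "umrs")` with the same
#'   columns.
#' @export
call_lmrs <- function(calls, lmr_threshold = 0.20, smooth_k = 3L,
                      min_cpg = 4L, umr_cpg_cutoff = 30L, min_cov = 1L,
                      sample = NA_character_) {
  stopifnot(lmr_threshold > 0, lmr_threshold < 1, smooth_k >= 1,
            min_cpg >= 1, umr_cpg_cutoff > min_cpg)
  cg <- calls[calls$context == "CG" & calls$total_count >= min_cov, ,
              drop = FALSE]
  out <- list()
  for (chr in unique(cg$chrom)) {
    cc <- cg[cg$chrom == chr, , drop = FALSE]
    cc <- cc[order(cc$pos), , drop = FALSE]
    if (nrow(cc) == 0) {
      warning("no covered CG calls on ", chr)
      next
    }
    lev <- cc$meth_count / cc$total_count
    sm <- smooth_levels(lev, smooth_k)
    low <- sm < lmr_threshold
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep) == 0) next
    seg <- data.frame(
      chrom = chr,
      start = cc$pos[starts[keep]] - 1L,
      end = cc$pos[ends[keep]],
      n_cpg = r$lengths[keep],
      mean_meth = vapply(keep, function(i) {
        idx <- starts[i]:ends[i]
        sum(cc$meth_count[idx]) / sum(cc$total_count[idx])
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
    out[[chr]] <- seg
  }
  seg <- if (length(out)) do.call(rbind, out) else
    empty_regions(c("n_cpg", "mean_meth"))
  seg$sample <- rep(sample, nrow(seg))
  rownames(seg) <- NULL
  lmrs <- seg[seg$n_cpg >= min_cpg & seg$n_cpg < umr_cpg_cutoff, ,
              drop = FALSE]
  umrs <- seg[seg$n_cpg >= umr_cpg_cutoff, , drop = FALSE]
  rownames(lmrs) <- rownames(umrs) <- NULL
  attr(lmrs, "umrs") <- umrs
  lmrs
}

#' Call differentially methylated regions between two samples
#'
#' The genome is tiled into fixed non-overlapping windows; in each window
#' the CG read counts of each sample are pooled and compared by Fisher's
#' exact test on the 2x2 table (methylated/unmethylated x sample A/B).
#' P-values are Benjamini-Hochberg adjusted across all tested windows;
#' windows pass when `q < alpha_q` and the absolute methylation difference
#' is at least `min_delta`. Direction is `"hypo"` when sample A is the less
#' methylated (`meth_a < meth_b`), `"hyper"` otherwise.
#'
#' Windows with pooled coverage below `min_cov_per_window` in either sample
#' are skipped (not tested, not part of the multiple-testing family); the
#' number skipped is reported in `attr(, "n_skipped")`.
#'
#' @param calls_a,calls_b Call data.frames for the two samples, on the same
#'   coordinate system.
#' @param window,step Window size and step in bp (defaults tile the genome
#'   with non-overlapping 200-bp windows).
#' @param min_cov_per_window Minimum pooled CG coverage per sample.
#' @param alpha_q BH-adjusted significance cutoff.
#' @param min_delta Minimum absolute methylation difference.
#' @param context Context filter, default CG.
#' @return data.frame of DMRs: `chrom`, `start`, `end`, `meth_a`, `meth_b`,
#'   `direction`, `p`, `q`; attributes `n_tested`, `n_skipped`.
#' @export
call_dmrs <- function(calls_a, calls_b, window = 200L, step = 200L,
                      min_cov_per_window = 5L, alpha_q = 0.05,
                      min_delta = 0.1, context = "CG") {
  a <- calls_a[calls_a$context %in% context, , drop = FALSE]
  b <- calls_b[calls_b$context %in% context, , drop = FALSE]
  chroms <- union(unique(a$chrom), unique(b$chrom))
  rows <- list()
  n_skipped <- 0L
  for (chr in chroms) {
    ca <- a[a$chrom == chr, , drop = FALSE]
    cb <- b[b$chrom == chr, , drop = FALSE]
    maxpos <- max(c(ca$pos, cb$pos, 0L))
    if (maxpos == 0) next
    win_a <- (ca$pos - 1L) %/% step
    win_b <- (cb$pos - 1L) %/% step
    ma <- tapply(ca$meth_count, win_a, sum)
    ta <- tapply(ca$total_count, win_a, sum)
    mb <- tapply(cb$meth_count, win_b, sum)
    tb <- tapply(cb$total_count, win_b, sum)
    wins <- union(names(ta), names(tb))
    for (w in wins) {
      Ta <- if (w %in% names(ta)) ta[[w]] else 0L
      Tb <- if (w %in% names(tb)) tb[[w]] else 0L
      if (Ta < min_cov_per_window || Tb < min_cov_per_window) {
        n_skipped <- n_skipped + 1L
        next
      }
      Ma <- if (w %in% names(ma)) ma[[w]] else 0L
      Mb <- if (w %in% names(mb)) mb[[w]] else 0L
      w0 <- as.integer(w) * step
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chr, start = w0, end = w0 + window,
        meth_a = Ma / Ta, meth_b = Mb / Tb,
        p = stats::fisher.test(matrix(c(Ma, Ta - Ma, Mb, Tb - Mb), 2))$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    res <- empty_regions(c("meth_a", "meth_b", "p", "q"))
    res$direction <- character()
    attr(res, "n_tested") <- 0L
    attr(res, "n_skipped") <- n_skipped
    return(res)
  }
  res <- do.call(rbind, rows)
  res$q <- bh(res$p)
  res$direction <- ifelse(res$meth_a < res$meth_b, "hypo", "hyper")
  n_tested <- nrow(res)
  res <- res[res$q < alpha_q & abs(res$meth_a - res$meth_b) >= min_delta, ,
             drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Summarise sequencing-run read counts
#'
#' Sums per-sample raw/clean read counts from a run-summary table, the
#' bookkeeping that accompanies a multi-sample bisulfite experiment. The
#' package ships the summary of an eight-variety run as
#' `system.file("extdata", "bsseq_run_summary.tsv", package = "regland")`.
#'
#' @param summary_df data.frame with columns `sample` and one or more
#'   numeric count columns (e.g. `raw_reads`, `clean_reads`).
#' @return Named list of column totals (as doubles; totals exceed 2^31).
#' @export
sequencing_totals <- function(summary_df) {
  num <- vapply(summary_df, is.numeric, logical(1))
  lapply(summary_df[num], function(x) sum(as.numeric(x)))
}
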