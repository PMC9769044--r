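#' Candidate target genes of an enhancer
#'
#' Returns up to `n_each_side` genes whose TSS lies upstream (TSS strictly
#' below the enhancer midpoint, in genomic coordinates) and up to
#' `n_each_side` downstream (TSS at or above the midpoint), nearest first.
#' Ties are broken deterministically by smaller TSS, then lexicographic
#' `gene_id`.
#'
#' @param lmr One-row region data.frame (or list) with `chrom`, `start`,
#'   `end`.
#' @param genes Gene data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param n_each_side Genes to keep per side (default 10).
#' @return Gene data.frame subset, with columns `tss`, `distance` and
#'   `side` added, ordered by distance.
#' @export
candidate_genes <- function(lmr, genes, n_each_side = 10L) {
  g <- genes[genes$chrom == lmr$chrom, , drop = FALSE]
  if (nrow(g) == 0) return(cbind(genes[0, ], tss = integer(),
                                 distance = integer(), side = character()))
  mid <- (lmr$start + lmr$end) %/% 2L
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g$distance <- abs(g$tss - mid)
  g$side <- ifelse(g$tss < mid, "upstream", "downstream")
  g <- g[order(g$distance, g$tss, g$gene_id), , drop = FALSE]
  up <- head(g[g$side == "upstream", , drop = FALSE], n_each_side)
  dn <- head(g[g$side == "downstream", , drop = FALSE], n_each_side)
  out <- rbind(up, dn)
  out <- out[order(out$distance, out$tss, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-sample LMRs into consensus enhancers
#'
#' LMRs from different samples that overlap by at least 1 bp are unified
#' into a single consensus enhancer spanning their union, so that a
#' methylation value can be computed for every sample at a common
#' interval.
#'
#' @param lmr_list Named list of per-sample LMR data.frames.
#' @return Region data.frame with an `lmr_id` column (`enh_...`) and
#'   `n_samples`, the number of samples contributing an LMR.
#' @export
consensus_enhancers <- function(lmr_list) {
  all_lmrs <- do.call(rbind, lapply(names(lmr_list), function(s) {
    x <- lmr_list[[s]][c("chrom", "start", "end")]
    x$sample <- s
    x
  }))
  if (is.null(all_lmrs) || nrow(all_lmrs) == 0) {
    out <- empty_regions()
    out$lmr_id <- character()
    out$n_samples <- integer()
    return(out)
  }
  merged <- merge_regions(all_lmrs)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(regions_to_gr(all_lmrs),
                                                     regions_to_gr(merged)))
  n_samples <- tapply(all_lmrs$sample[S4Vectors::queryHits(ov)],
                      S4Vectors::subjectHits(ov),
                      function(s) length(unique(s)))
  merged$n_samples <- 0L
  merged$n_samples[as.integer(names(n_samples))] <- as.integer(n_samples)
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  merged$lmr_id <- sprintf("enh_%05d", seq_len(nrow(merged)))
  rownames(merged) <- NULL
  merged[c("chrom", "start", "end", "lmr_id", "n_samples")]
}

#' Methylation matrix of enhancers across samples
#'
#' Recomputes the pooled CG methylation of each consensus enhancer in each
#' sample from the per-cytosine calls, so that samples lacking a called
#' LMR at that locus still contribute a value.
#'
#' @param enhancers Region data.frame with `lmr_id`.
#' @param calls_by_sample Named list of call data.frames.
#' @return Numeric matrix, enhancers x samples, with `NA` where a sample
#'   has no covered CG in the interval.
#' @export
enhancer_methylation <- function(enhancers, calls_by_sample) {
  samples <- names(calls_by_sample)
  m <- matrix(NA_real_, nrow(enhancers), length(samples),
              dimnames = list(enhancers$lmr_id, samples))
  for (s in samples) {
    calls <- calls_by_sample[[s]]
    cg <- calls[calls$context == "CG", , drop = FALSE]
    gr_calls <- GenomicRanges::GRanges(
      cg$chrom, IRanges::IRanges(cg$pos, width = 1L))
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(regions_to_gr(enhancers), gr_calls))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    meth <- tapply(cg$meth_count[sh], qh, sum)
    tot <- tapply(cg$total_count[sh], qh, sum)
    idx <- as.integer(names(tot))
    m[idx, s] <- as.numeric(meth) / as.numeric(tot)
  }
  m
}

#' Link enhancers to target genes by negative correlation
#'
#' For every enhancer and each of its candidate genes (the nearest
#' `n_each_side` per side, see [candidate_genes()]), the enhancer's
#' methylation is correlated with the gene's expression across samples. A
#' pair is retained when the correlation is negative and significant: a
#' gene positively regulated by an enhancer is expected to be expressed
#' more when the enhancer is less methylated.
#'
#' Expression is transformed by `log2(x + 1)` before Pearson correlation
#' (Spearman uses ranks, so the transform is immaterial there). The test
#' is one-sided for negative correlation; `correction = "BH"` additionally
#' adjusts across all tested pairs and filters on `q < alpha`.
#'
#' @param meth Enhancer x sample methylation matrix (see
#'   [enhancer_methylation()]); rownames are `lmr_id`s.
#' @param enhancers Region data.frame with `lmr_id` matching `meth` rows.
#' @param expr Gene x sample expression matrix (TPM); rownames are gene
#'   ids. Columns are matched to `meth` columns by name.
#' @param genes Gene data.frame.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha Significance level (default 0.05).
#' @param correction `"none"` (raw one-sided p, default) or `"BH"`.
#' @param n_each_side Candidate genes per side (default 10).
#' @param expr_transform Function applied to expression before correlating.
#' @param min_samples Minimum shared samples with defined methylation.
#' @return data.frame of retained pairs: `lmr_id`, `gene_id`, `distance`
#'   (enhancer midpoint to TSS), `r`, `p`, `q`, `nearest_tss`. Attributes:
#'   `n_tested`, `n_skipped_lmrs` (undefined methylation in more than half
#'   the samples), `n_skipped_zero_var`.
#' @export
link_enhancers <- function(meth, enhancers, expr, genes,
                           method = c("pearson", "spearman"),
                           alpha = 0.05, correction = c("none", "BH"),
                           n_each_side = 10L,
                           expr_transform = function(x) log2(x + 1),
                           min_samples = 3L) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  shared <- intersect(colnames(meth), colnames(expr))
  stopifnot(length(shared) >= min_samples)
  meth <- meth[, shared, drop = FALSE]
  ex <- expr_transform(as.matrix(expr)[, shared, drop = FALSE])
  gene_tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  names(gene_tss) <- genes$gene_id
  n_skipped_lmrs <- 0L
  n_skipped_zero_var <- 0L
  rows <- list()
  for (i in seq_len(nrow(enhancers))) {
    lmr <- enhancers[i, ]
    mv <- meth[lmr$lmr_id, ]
    if (sum(!is.na(mv)) < max(min_samples, length(shared) / 2)) {
      n_skipped_lmrs <- n_skipped_lmrs + 1L
      next
    }
    cand <- candidate_genes(lmr, genes, n_each_side)
    cand <- cand[cand$gene_id %in% rownames(ex), , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      gid <- cand$gene_id[j]
      ev <- ex[gid, ]
      ok <- !is.na(mv) & !is.na(ev)
      if (sum(ok) < min_samples) next
      if (stats::sd(mv[ok]) == 0 || stats::sd(ev[ok]) == 0) {
        n_skipped_zero_var <- n_skipped_zero_var + 1L
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(mv[ok], ev[ok], method = method,
                        alternative = "less", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        lmr_id = lmr$lmr_id, gene_id = gid,
        distance = cand$distance[j], r = unname(ct$estimate),
        p = ct$p.value, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(lmr_id = character(), gene_id = character(),
                      distance = integer(), r = numeric(), p = numeric(),
                      q = numeric(), nearest_tss = logical())
    attr(out, "n_tested") <- 0L
    attr(out, "n_skipped_lmrs") <- n_skipped_lmrs
    attr(out, "n_skipped_zero_var") <- n_skipped_zero_var
    return(out)
  }
  res <- do.call(rbind, rows)
  res$q <- bh(res$p)
  n_tested <- nrow(res)
  keep <- if (correction == "BH") {
    res$r < 0 & res$q < alpha
  } else {
    res$r < 0 & res$p < alpha
  }
  res <- res[keep, , drop = FALSE]
  # nearest-TSS flag: is the linked gene the enhancer's closest TSS overall?
  if (nrow(res) > 0) {
    enh_mid <- (enhancers$start + enhancers$end) %/% 2L
    names(enh_mid) <- enhancers$lmr_id
    enh_chrom <- setNames(enhancers$chrom, enhancers$lmr_id)
    nearest <- vapply(unique(res$lmr_id), function(id) {
      g <- genes[genes$chrom == enh_chrom[id], , drop = FALSE]
      tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
      g$gene_id[which.min(abs(tss - enh_mid[id]))]
    }, character(1))
    res$nearest_tss <- res$gene_id == nearest[res$lmr_id]
  } else {
    res$nearest_tss <- logical(0)
  }
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  attr(res, "n_skipped_lmrs") <- n_skipped_lmrs
  attr(res, "n_skipped_zero_var") <- n_skipped_zero_var
  res
}

#' Summary statistics of enhancer-gene pairs
#'
#' Either pass the pairs table, or pass the printed totals
#' (`n_pairs`, `n_enhancers`, `n_genes`, optionally `n_tfbs`) to reproduce
#' the headline ratios of a published pair set.
#'
#' @param pairs data.frame from [link_enhancers()] (may be `NULL` when
#'   totals are given directly).
#' @param n_pairs,n_enhancers,n_genes,n_tfbs Optional totals overriding
#'   counts derived from `pairs`; `n_tfbs` is the total number of binding
#'   sites found in the enhancers, enabling `tfbs_per_enhancer`.
#' @param within_kb Distance used for the "short-range" fraction (default
#'   150 kb).
#' @param bin_kb Histogram bin width for pair distances (default 50 kb,
#'   half-open bins).
#' @return List: `n_pairs`, `n_enhancers`, `n_genes`,
#'   `genes_per_enhancer`, `enhancers_per_gene`, `tfbs_per_enhancer`
#'   (`NA` without `n_tfbs`), `median_distance`, `frac_within`,
#'   `hist` (named counts per bin), `frac_single_target`,
#'   `frac_nearest_tss_among_single`. Distance-based entries are `NA` when
#'   only totals are supplied. Empty input gives an all-zero report with
#'   `empty = TRUE`.
#' @export
pair_stats <- function(pairs = NULL, n_pairs = NULL, n_enhancers = NULL,
                       n_genes = NULL, n_tfbs = NULL,
                       within_kb = 150, bin_kb = 50) {
  have_pairs <- !is.null(pairs) && nrow(pairs) > 0
  if (!have_pairs && is.null(n_pairs)) {
    return(list(n_pairs = 0, n_enhancers = 0, n_genes = 0,
                genes_per_enhancer = 0, enhancers_per_gene = 0,
                tfbs_per_enhancer = NA_real_, median_distance = NA_real_,
                frac_within = NA_real_, hist = numeric(),
                frac_single_target = NA_real_,
                frac_nearest_tss_among_single = NA_real_, empty = TRUE))
  }
  if (is.null(n_pairs)) n_pairs <- nrow(pairs)
  if (is.null(n_enhancers)) n_enhancers <- length(unique(pairs$lmr_id))
  if (is.null(n_genes)) n_genes <- length(unique(pairs$gene_id))
  out <- list(
    n_pairs = n_pairs, n_enhancers = n_enhancers, n_genes = n_genes,
    genes_per_enhancer = n_pairs / n_enhancers,
    enhancers_per_gene = n_pairs / n_genes,
    tfbs_per_enhancer = if (is.null(n_tfbs)) NA_real_ else n_tfbs / n_enhancers,
    median_distance = NA_real_, frac_within = NA_real_, hist = numeric(),
    frac_single_target = NA_real_,
    frac_nearest_tss_among_single = NA_real_, empty = FALSE
  )
  if (have_pairs) {
    d <- pairs$distance
    out$median_distance <- stats::median(d)
    out$frac_within <- mean(d < within_kb * 1000)
    bins <- (d %/% (bin_kb * 1000))
    h <- table(bins)
    names(h) <- sprintf("[%d,%d)kb", as.integer(names(h)) * bin_kb,
                        (as.integer(names(h)) + 1L) * bin_kb)
    out$hist <- as.numeric(h) |> setNames(names(h))
    per_enh <- table(pairs$lmr_id)
    single <- names(per_enh)[per_enh == 1]
    out$frac_single_target <- length(single) / length(per_enh)
    if ("nearest_tss" %in% names(pairs) && length(single) > 0) {
      sp <- pairs[pairs$lmr_id %in% single, , drop = FALSE]
      out$frac_nearest_tss_among_single <- mean(sp$nearest_tss)
    }
  }
  out
}
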