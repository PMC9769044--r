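#' Built-in demonstration motif set
#'
#' Three plant-TF-like motifs with strong consensus (NAC-, bHLH/E-box- and
#' bZIP-like), width 8, suitable both for planting into synthetic
#' enhancers and for exhaustive-enumeration checks.
#'
#' @param n_strong Count given to the consensus base at each position.
#' @return Named list of `pwm` objects.
#' @export
default_motif_set <- function(n_strong = 18) {
  mk <- function(consensus, id, tf) {
    idx <- match(strsplit(consensus, "")[[1]], DNA_BASES)
    mat <- matrix(0, length(idx), 4)
    mat[cbind(seq_along(idx), idx)] <- n_strong
    pwm(mat, id, tf)
  }
  list(
    M_NAC = mk("TTGCGTGT", "M_NAC", "NAC_TF"),
    M_BHLH = mk("CACGTGAC", "M_BHLH", "bHLH_TF"),
    M_BZIP = mk("TGACGTCA", "M_BZIP", "bZIP_TF")
  )
}

#' Configuration for the synthetic multi-sample dataset
#'
#' Defaults emulate an eight-variety (four tolerant/susceptible pairs)
#' whole-genome bisulfite design at desk scale: two 2-Mb chromosomes, a
#' highly methylated CG background with planted hypomethylated segments, a
#' subset of which is tolerant-specific or carries a planted
#' methylation-expression link; histone peaks covering set fractions of
#' the planted LMRs; SNPs at 6/kb outside and 2-fold enriched inside LMRs
#' (matching typical regulatory-region enrichment); and planted motif
#' instances in enhancer sequence.
#'
#' @param n_chroms,chrom_len Number and length (bp) of chromosomes.
#' @param n_samples Number of samples; must be even, arranged as
#'   tolerant/susceptible pairs (`tol1`, `sus1`, ...).
#' @param n_genes Genes placed over the genome.
#' @param cpg_spacing Mean bp between background CpGs.
#' @param background_meth Background CG methylation fraction.
#' @param n_lmrs Planted hypomethylated segments.
#' @param lmr_meth Methylation inside planted LMRs.
#' @param lmr_len Length range (bp) of planted LMRs.
#' @param lmr_cpg_spacing CpG spacing inside planted LMRs.
#' @param frac_specific Fraction of LMRs planted only in tolerant samples.
#' @param n_linked_pairs Planted enhancer-gene links (on shared LMRs whose
#'   methylation varies across samples on an evenly spaced grid in
#'   `link_meth_range`).
#' @param link_meth_range Methylation range of link-carrying LMRs.
#' @param link_effect Slope of log2-expression on methylation (negative).
#' @param noise_sd Expression noise SD (log2 scale).
#' @param coverage Mean per-cytosine read coverage (Poisson, floor 1).
#' @param peak_overlap_frac Named fractions of present LMRs covered by
#'   planted peaks per mark.
#' @param n_bg_peaks Background (non-LMR) peaks per sample per mark.
#' @param snp_rate_bg SNPs per kb outside LMRs.
#' @param snp_enrichment Multiplicative SNP-rate factor inside LMRs.
#' @param motif_set List of `pwm`s to plant (default
#'   [default_motif_set()]).
#' @param motif_fg_prob Probability a tolerant-specific LMR carries the
#'   first motif (foreground for enrichment).
#' @param motif_bg_prob Probability any other LMR carries it.
#' @param conversion_failure Bisulfite conversion-failure rate emulated on
#'   the unmethylated lambda spike-in contig.
#' @param repeat_frac Approximate fraction of the genome lowercase-masked
#'   as repeats (placed outside LMRs).
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L, chrom_len = 2e6, n_samples = 8L,
                       n_genes = 200L, cpg_spacing = 100, background_meth = 0.8,
                       n_lmrs = 60L, lmr_meth = 0.1, lmr_len = c(800, 1500),
                       lmr_cpg_spacing = 80, frac_specific = 0.25,
                       n_linked_pairs = 40L, link_meth_range = c(0.02, 0.18),
                       link_effect = -10, noise_sd = 0.1, coverage = 20,
                       peak_overlap_frac = c(H3K27me3 = 0.35, H3K4me3 = 0.05),
                       n_bg_peaks = 20L, snp_rate_bg = 6, snp_enrichment = 2,
                       motif_set = NULL, motif_fg_prob = 0.8,
                       motif_bg_prob = 0.05, conversion_failure = 0.005,
                       repeat_frac = 0.05, seed = 1L) {
  if (is.null(motif_set)) motif_set <- default_motif_set()
  cfg <- list(n_chroms = as.integer(n_chroms), chrom_len = as.integer(chrom_len),
              n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              cpg_spacing = cpg_spacing, background_meth = background_meth,
              n_lmrs = as.integer(n_lmrs), lmr_meth = lmr_meth,
              lmr_len = lmr_len, lmr_cpg_spacing = lmr_cpg_spacing,
              frac_specific = frac_specific,
              n_linked_pairs = as.integer(n_linked_pairs),
              link_meth_range = link_meth_range, link_effect = link_effect,
              noise_sd = noise_sd, coverage = coverage,
              peak_overlap_frac = peak_overlap_frac,
              n_bg_peaks = as.integer(n_bg_peaks),
              snp_rate_bg = snp_rate_bg, snp_enrichment = snp_enrichment,
              motif_set = motif_set, motif_fg_prob = motif_fg_prob,
              motif_bg_prob = motif_bg_prob,
              conversion_failure = conversion_failure,
              repeat_frac = repeat_frac, seed = as.integer(seed))
  stopifnot(cfg$lmr_meth < cfg$background_meth, cfg$background_meth <= 1,
            cfg$lmr_meth >= 0, cfg$snp_enrichment >= 1,
            cfg$n_samples %% 2 == 0,
            cfg$n_linked_pairs <= cfg$n_lmrs - round(cfg$frac_specific * cfg$n_lmrs),
            max(cfg$link_meth_range) < 1)
  class(cfg) <- "sim_config"
  cfg
}

# place n disjoint intervals of length in len_range on the chromosomes,
# with a clearance gap; errors out with counts when placement keeps failing
place_intervals <- function(n, chroms, chrom_len, len_range, gap = 2000,
                            margin = 10000, max_tries = 1000) {
  placed <- empty_regions()
  tries <- 0L
  while (nrow(placed) < n) {
    tries <- tries + 1L
    if (tries > max_tries * max(n, 1)) {
      stop(sprintf("interval placement failed: %d of %d placed after %d tries",
                   nrow(placed), n, tries))
    }
    len <- round(runif(1, len_range[1], len_range[2]))
    chr <- sample(chroms, 1)
    start <- round(runif(1, margin, chrom_len - margin - len))
    clash <- any(placed$chrom == chr & placed$start < start + len + gap &
                   start - gap < placed$end)
    if (!clash) {
      placed <- rbind(placed,
                      data.frame(chrom = chr, start = start, end = start + len))
    }
  }
  placed <- placed[order(placed$chrom, placed$start), , drop = FALSE]
  rownames(placed) <- NULL
  placed
}

#' Plant methylation-expression links into an expression matrix
#'
#' For each planted pair, the gene's expression (log2 scale) is
#' `baseline + effect * methylation + noise`; unlinked genes receive a
#' methylation-independent gene-level baseline plus noise. Pairs whose
#' gene is outside the enhancer's candidate neighborhood (the nearest
#' `n_each_side` genes per side) are rejected with a message when `lmrs`
#' coordinates are supplied.
#'
#' @param meth_by_sample LMR x sample methylation matrix (rownames are
#'   lmr ids).
#' @param genes Gene data.frame.
#' @param pairs data.frame (`lmr_id`, `gene_id`) of links to plant.
#' @param effect Slope of expression on methylation (negative for
#'   enhancer-like behaviour).
#' @param noise_sd Noise SD.
#' @param baseline Intercept for linked genes (log2 scale).
#' @param null_range Range of gene-level baselines for unlinked genes.
#' @param lmrs Optional region data.frame with `lmr_id` enabling the
#'   neighborhood validity check.
#' @param n_each_side Neighborhood size used for validation.
#' @return Gene x sample matrix of log2-scale expression; rejected pairs
#'   (if any) in `attr(, "rejected_pairs")`.
#' @export
plant_expression_links <- function(meth_by_sample, genes, pairs, effect = -10,
                                   noise_sd = 0.1, baseline = 10,
                                   null_range = c(2, 8), lmrs = NULL,
                                   n_each_side = 10L) {
  samples <- colnames(meth_by_sample)
  if (is.null(pairs)) {
    pairs <- data.frame(lmr_id = character(), gene_id = character())
  }
  rejected <- character()
  if (!is.null(lmrs) && nrow(pairs) > 0) {
    ok <- vapply(seq_len(nrow(pairs)), function(i) {
      lmr <- lmrs[lmrs$lmr_id == pairs$lmr_id[i], , drop = FALSE]
      cand <- candidate_genes(lmr[1, ], genes, n_each_side)
      pairs$gene_id[i] %in% cand$gene_id
    }, logical(1))
    if (any(!ok)) {
      rejected <- sprintf("%s->%s", pairs$lmr_id[!ok], pairs$gene_id[!ok])
      message("rejected ", sum(!ok),
              " planted pair(s) outside the candidate neighborhood: ",
              paste(rejected, collapse = ", "))
      pairs <- pairs[ok, , drop = FALSE]
    }
  }
  expr <- matrix(NA_real_, nrow(genes), length(samples),
                 dimnames = list(genes$gene_id, samples))
  mu <- runif(nrow(genes), null_range[1], null_range[2])
  for (g in seq_len(nrow(genes))) {
    expr[g, ] <- mu[g] + rnorm(length(samples), 0, noise_sd)
  }
  for (i in seq_len(nrow(pairs))) {
    m <- meth_by_sample[pairs$lmr_id[i], ]
    expr[pairs$gene_id[i], ] <- baseline + effect * m +
      rnorm(length(samples), 0, noise_sd)
  }
  attr(expr, "rejected_pairs") <- rejected
  expr
}

write_cgmap <- function(df, path) {
  out <- data.frame(chrom = df$chrom, nuc = "C", pos = df$pos,
                    context = df$context, dinuc = df$dinuc,
                    level = ifelse(df$total_count > 0,
                                   round(df$meth_count / df$total_count, 4), 0),
                    meth = df$meth_count, total = df$total_count)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
}

write_vcf_sites <- function(snps, chrom_sizes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(sprintf("##contig=<ID=%s,length=%d>", chrom_sizes$chrom,
                     chrom_sizes$size), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(snps) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", snps$chrom,
                       snps$pos, snps$ref, snps$alt), con)
  }
  invisible(path)
}

write_narrowpeak <- function(peaks, path) {
  out <- data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                    name = peaks$name, score = 0L, strand = ".",
                    signal = round(peaks$signal, 3), p = -1, q = -1,
                    peak = (peaks$end - peaks$start) %/% 2L)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
}

write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tregland_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end, genes$strand,
                     genes$gene_id), con)
  invisible(path)
}

#' Read gene models from a GFF3 or BED file
#' @param path GFF3 (gene features with ID) or BED6 path.
#' @return Gene data.frame (`gene_id`, `chrom`, `start`, `end`, `strand`),
#'   0-based half-open.
#' @export
read_genes <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^##gff", first) || grepl("\\.gff3?$", path)) {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    df <- gr_to_regions(gr)
    data.frame(gene_id = as.character(df$ID), chrom = df$chrom,
               start = df$start, end = df$end,
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  } else {
    bed <- read_bed(path)
    data.frame(gene_id = bed$name, chrom = bed$chrom, start = bed$start,
               end = bed$end, strand = bed$strand, stringsAsFactors = FALSE)
  }
}

#' Generate a synthetic multi-sample regulatory-landscape dataset
#'
#' Writes, under `outdir`: per-sample CGmap files (CG context, including
#' an unmethylated `lambda` spike-in contig), the genome FASTA (lowercase
#' repeat masking), GFF3 gene models, a TPM expression matrix, per-sample
#' narrowPeak files for H3K4me3 and H3K27me3, a sites-only VCF, a
#' MEME-format motif file, motif-to-TF and TF-family TSV maps, and a
#' chrom.sizes table. Identical seeds give byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if absent).
#' @return Ground-truth list: `samples` (data.frame with tolerance
#'   labels), `planted_lmrs` (with per-LMR `type`), `presence` (LMR x
#'   sample logical), `meth_levels` (LMR x sample true levels),
#'   `planted_pairs`, `planted_motif_instances`, `planted_edges`,
#'   `snp_counts`, `peak_cover` (per sample per mark planted LMR counts),
#'   `categories` (per-LMR genomic category from generator bookkeeping),
#'   `files` (paths), `config`.
#' @export
generate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  chrom_sizes <- data.frame(chrom = chroms, size = config$chrom_len)

  ## planted LMRs and their types -------------------------------------------
  lmrs <- place_intervals(config$n_lmrs, chroms, config$chrom_len,
                          config$lmr_len)
  lmrs$lmr_id <- sprintf("lmr_%03d", seq_len(nrow(lmrs)))
  n_spec <- round(config$frac_specific * config$n_lmrs)
  type <- rep("shared", config$n_lmrs)
  idx <- sample(config$n_lmrs)
  spec_idx <- idx[seq_len(n_spec)]
  link_idx <- idx[n_spec + seq_len(config$n_linked_pairs)]
  type[spec_idx] <- "specific"
  type[link_idx] <- "linked"
  lmrs$type <- type

  ## samples: tolerant/susceptible pairs ------------------------------------
  n_pairs_samples <- config$n_samples %/% 2L
  samples <- data.frame(
    sample_id = as.vector(rbind(sprintf("tol%d", seq_len(n_pairs_samples)),
                                sprintf("sus%d", seq_len(n_pairs_samples)))),
    pair = rep(seq_len(n_pairs_samples), each = 2),
    tolerance = rep(c("tolerant", "susceptible"), n_pairs_samples),
    stringsAsFactors = FALSE
  )

  ## true methylation level per LMR per sample ------------------------------
  meth_levels <- matrix(config$lmr_meth, config$n_lmrs, config$n_samples,
                        dimnames = list(lmrs$lmr_id, samples$sample_id))
  is_tol <- samples$tolerance == "tolerant"
  meth_levels[spec_idx, !is_tol] <- config$background_meth
  grid <- seq(config$link_meth_range[1], config$link_meth_range[2],
              length.out = config$n_samples)
  for (i in link_idx) meth_levels[i, ] <- sample(grid)
  presence <- meth_levels < 0.5  # planted (hypomethylated) in that sample

  ## CpG positions: background spacing, denser inside planted LMRs ----------
  cpg <- list()
  for (chr in chroms) {
    pos <- cumsum(2 + stats::rgeom(ceiling(config$chrom_len /
                                             config$cpg_spacing) * 2,
                                   1 / config$cpg_spacing)) + 500
    pos <- pos[pos < config$chrom_len - 500]
    inlmr <- lmrs[lmrs$chrom == chr, , drop = FALSE]
    if (nrow(inlmr) > 0) {
      flags <- overlap_count(data.frame(chrom = chr, start = pos - 1L,
                                        end = pos), inlmr)$flags
      pos <- pos[!flags]
      extra <- unlist(lapply(seq_len(nrow(inlmr)), function(i) {
        seq(inlmr$start[i] + 40L, inlmr$end[i] - 40L,
            by = config$lmr_cpg_spacing)
      }))
      pos <- sort(unique(c(pos, extra)))
    }
    cpg[[chr]] <- as.integer(pos)
  }

  ## per-sample CGmap files ---------------------------------------------------
  lmr_by_chr <- split(lmrs, lmrs$chrom)
  files <- list()
  for (s in seq_len(config$n_samples)) {
    sid <- samples$sample_id[s]
    recs <- list()
    for (chr in chroms) {
      pos <- cpg[[chr]]
      lev <- rep(config$background_meth, length(pos))
      lc <- lmr_by_chr[[chr]]
      if (!is.null(lc)) for (i in seq_len(nrow(lc))) {
        inside <- pos > lc$start[i] & pos <= lc$end[i]
        lev[inside] <- meth_levels[lc$lmr_id[i], sid]
      }
      cov <- pmax(1L, rpois(length(pos), config$coverage))
      meth <- rbinom(length(pos), cov, lev)
      recs[[chr]] <- data.frame(chrom = chr, pos = pos, context = "CG",
                                dinuc = "CG", meth_count = meth,
                                total_count = cov, stringsAsFactors = FALSE)
    }
    # unmethylated lambda spike-in with a fixed conversion-failure rate
    lpos <- seq(11L, 19991L, by = 50L)
    lcov <- pmax(1L, rpois(length(lpos), config$coverage))
    recs[["lambda"]] <- data.frame(
      chrom = "lambda", pos = lpos, context = "CG", dinuc = "CG",
      meth_count = rbinom(length(lpos), lcov, config$conversion_failure),
      total_count = lcov, stringsAsFactors = FALSE)
    df <- do.call(rbind, recs)
    f <- file.path(outdir, sprintf("%s.cgmap", sid))
    write_cgmap(df, f)
    files[[sprintf("cgmap_%s", sid)]] <- f
  }

  ## genome sequence with CpGs, planted motifs, repeat masking ---------------
  genome <- lapply(chroms, function(chr) {
    s <- sample(DNA_BASES, config$chrom_len, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    s[cpg[[chr]]] <- "C"
    s[pmin(cpg[[chr]] + 1L, config$chrom_len)] <- "G"
    s
  })
  names(genome) <- chroms

  motifs <- config$motif_set
  plant_motif <- function(chr, at, m, strand) {
    cons <- strsplit(pwm_consensus(m), "")[[1]]
    if (strand == "-") {
      cons <- rev(c(A = "T", C = "G", G = "C", T = "A")[cons])
    }
    genome[[chr]][at:(at + m$width - 1L)] <<- cons
  }
  instances <- list()
  first_id <- names(motifs)[1]
  for (i in seq_len(nrow(lmrs))) {
    lmr <- lmrs[i, ]
    plant_first <- if (lmrs$type[i] == "specific")
      runif(1) < config$motif_fg_prob else runif(1) < config$motif_bg_prob
    chosen <- character()
    if (plant_first) chosen <- first_id
    if (lmrs$type[i] == "linked") {
      # exactly one (possibly additional) instance drives a network edge
      chosen <- unique(c(chosen, sample(names(motifs), 1)))
    }
    used <- integer()
    for (mid in chosen) {
      m <- motifs[[mid]]
      repeat {  # keep instances within one LMR disjoint
        off <- sample(seq(50L, lmr$end - lmr$start - 50L - m$width), 1)
        if (!length(used) || all(abs(off - used) > m$width)) break
      }
      used <- c(used, off)
      strand <- sample(c("+", "-"), 1)
      plant_motif(lmr$chrom, lmr$start + off + 1L, m, strand)
      instances[[length(instances) + 1L]] <- data.frame(
        motif_id = mid, region_id = lmr$lmr_id, offset = off,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  planted_instances <- if (length(instances)) do.call(rbind, instances) else
    data.frame(motif_id = character(), region_id = character(),
               offset = integer(), strand = character())

  n_rep <- round(config$repeat_frac * config$n_chroms * config$chrom_len / 2000)
  repeats <- place_intervals(n_rep, chroms, config$chrom_len,
                             c(1500, 2500), gap = 100, max_tries = 200)
  # keep repeats clear of planted LMRs so enhancer sequence stays scannable
  repeats <- repeats[!overlap_count(repeats, lmrs)$flags, , drop = FALSE]
  for (i in seq_len(nrow(repeats))) {
    rng <- (repeats$start[i] + 1L):repeats$end[i]
    genome[[repeats$chrom[i]]][rng] <- tolower(genome[[repeats$chrom[i]]][rng])
  }
  fasta <- file.path(outdir, "genome.fa")
  dss <- Biostrings::DNAStringSet(vapply(genome, paste, character(1),
                                         collapse = ""))
  names(dss) <- chroms
  Biostrings::writeXStringSet(dss, fasta, width = 80)
  files$genome <- fasta

  ## genes -------------------------------------------------------------------
  gene_iv <- place_intervals(config$n_genes, chroms, config$chrom_len,
                             c(1000, 3000), gap = 500, max_tries = 500)
  genes <- data.frame(gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
                      chrom = gene_iv$chrom, start = gene_iv$start,
                      end = gene_iv$end,
                      strand = sample(c("+", "-"), config$n_genes,
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
  gff <- file.path(outdir, "genes.gff3")
  write_gff3(genes, gff)
  files$genes <- gff

  # generator-side category bookkeeping (midpoint rule, brute force)
  categories <- vapply(seq_len(nrow(lmrs)), function(i) {
    mid <- (lmrs$start[i] + lmrs$end[i]) %/% 2L
    g <- genes[genes$chrom == lmrs$chrom[i], , drop = FALSE]
    tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
    in_prom <- any(ifelse(g$strand == "+",
                          mid >= tss - 2000L & mid < tss,
                          mid > tss & mid <= tss + 2000L))
    if (in_prom) return("promoter")
    if (any(mid >= g$start & mid < g$end)) return("exonic")
    "intergenic"
  }, character(1))

  ## planted expression links ------------------------------------------------
  pairs <- list()
  used_genes <- character()
  for (i in link_idx) {
    cand <- candidate_genes(lmrs[i, ], genes, 10L)
    # one target gene per link: a gene driven by two enhancers would carry
    # only the most recently planted signal
    avail <- setdiff(cand$gene_id, used_genes)
    if (length(avail) == 0) next
    g <- avail[sample.int(length(avail), 1)]
    used_genes <- c(used_genes, g)
    pairs[[length(pairs) + 1L]] <- data.frame(
      lmr_id = lmrs$lmr_id[i], gene_id = g, stringsAsFactors = FALSE)
  }
  planted_pairs <- do.call(rbind, pairs)
  expr_log2 <- plant_expression_links(meth_levels, genes, planted_pairs,
                                      effect = config$link_effect,
                                      noise_sd = config$noise_sd,
                                      lmrs = lmrs)
  tpm <- round(2^expr_log2 - 1, 4)
  expr_file <- file.path(outdir, "expression.tsv")
  data.table::fwrite(data.table::data.table(gene_id = rownames(tpm), tpm),
                     expr_file, sep = "\t")
  files$expression <- expr_file

  ## histone peaks ------------------------------------------------------------
  peak_cover <- list()
  for (s in seq_len(config$n_samples)) {
    sid <- samples$sample_id[s]
    present <- which(presence[, sid])
    for (mark in names(config$peak_overlap_frac)) {
      n_cov <- round(config$peak_overlap_frac[[mark]] * length(present))
      cov_idx <- present[sample.int(length(present), n_cov)]
      pk <- lmrs[cov_idx, c("chrom", "start", "end"), drop = FALSE]
      if (nrow(pk) > 0) {
        pk$start <- pmax(0L, pk$start - 200L)
        pk$end <- pk$end + 200L
      }
      bg <- place_intervals(config$n_bg_peaks, chroms, config$chrom_len,
                            c(500, 2000), gap = 100, max_tries = 200)
      bg <- bg[!overlap_count(bg, lmrs)$flags, , drop = FALSE]
      all_pk <- rbind(pk, bg)
      all_pk <- all_pk[order(all_pk$chrom, all_pk$start), , drop = FALSE]
      all_pk$name <- sprintf("%s_%s_peak%d", sid, mark, seq_len(nrow(all_pk)))
      all_pk$signal <- runif(nrow(all_pk), 2, 10)
      f <- file.path(outdir, sprintf("%s_%s.narrowPeak", sid, mark))
      write_narrowpeak(all_pk, f)
      files[[sprintf("peaks_%s_%s", sid, mark)]] <- f
      peak_cover[[sprintf("%s.%s", sid, mark)]] <- n_cov
    }
  }

  ## SNPs ---------------------------------------------------------------------
  lmr_bp <- covered_bases(lmrs)
  genome_bp <- config$n_chroms * as.numeric(config$chrom_len)
  rate_in <- config$snp_rate_bg * config$snp_enrichment / 1000
  rate_bg <- config$snp_rate_bg / 1000
  n_in <- rpois(1, rate_in * lmr_bp)
  n_out <- rpois(1, rate_bg * (genome_bp - lmr_bp))
  # inside: uniform over concatenated LMR bp
  offs <- sort(sample.int(as.integer(lmr_bp), n_in, replace = TRUE))
  cum <- cumsum(lmrs$end - lmrs$start)
  which_lmr <- findInterval(offs - 1L, c(0L, cum), rightmost.closed = FALSE)
  pos_in <- lmrs$start[which_lmr] + (offs - c(0L, cum)[which_lmr])
  snps_in <- data.frame(chrom = lmrs$chrom[which_lmr], pos = pos_in)
  # outside: uniform over genome, rejecting in-LMR draws
  acc <- data.frame(chrom = character(), pos = integer())
  while (nrow(acc) < n_out) {
    need <- n_out - nrow(acc)
    draw <- data.frame(chrom = sample(chroms, 2 * need, replace = TRUE),
                       pos = sample.int(config$chrom_len - 1L, 2 * need,
                                        replace = TRUE))
    flags <- overlap_count(data.frame(chrom = draw$chrom,
                                      start = draw$pos - 1L, end = draw$pos),
                           lmrs)$flags
    acc <- rbind(acc, draw[!flags, , drop = FALSE])
  }
  snps_out <- acc[seq_len(n_out), , drop = FALSE]
  snps <- rbind(snps_in, snps_out)
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  snps <- snps[!duplicated(snps[c("chrom", "pos")]), , drop = FALSE]
  snps$ref <- vapply(seq_len(nrow(snps)), function(i)
    toupper(genome[[snps$chrom[i]]][snps$pos[i]]), character(1))
  snps$alt <- vapply(snps$ref, function(r)
    sample(setdiff(DNA_BASES, r), 1), character(1))
  vcf <- file.path(outdir, "variants.vcf")
  write_vcf_sites(snps, chrom_sizes, vcf)
  files$vcf <- vcf

  ## motif library and TF maps ------------------------------------------------
  meme <- file.path(outdir, "motifs.meme")
  write_meme(motifs, meme)
  files$motifs <- meme
  tf_gene_ids <- genes$gene_id[seq_len(min(30L, nrow(genes)))]
  motif_map <- data.frame(motif_id = names(motifs),
                          tf_gene_id = tf_gene_ids[seq_along(motifs)],
                          stringsAsFactors = FALSE)
  fam_pool <- c("NAC", "bHLH", "bZIP", "TCP", "YABBY", "MYB")
  tf_fams <- data.frame(tf_gene_id = tf_gene_ids,
                        family = rep(fam_pool,
                                     length.out = length(tf_gene_ids)),
                        stringsAsFactors = FALSE)
  map_file <- file.path(outdir, "motif_to_tf.tsv")
  fam_file <- file.path(outdir, "tf_families.tsv")
  data.table::fwrite(motif_map, map_file, sep = "\t")
  data.table::fwrite(tf_fams, fam_file, sep = "\t")
  files$motif_map <- map_file
  files$tf_families <- fam_file
  sizes_file <- file.path(outdir, "chrom.sizes")
  data.table::fwrite(chrom_sizes, sizes_file, sep = "\t", col.names = FALSE)
  files$chrom_sizes <- sizes_file

  ## planted network edges ----------------------------------------------------
  tf_of <- setNames(motif_map$tf_gene_id, motif_map$motif_id)
  planted_edges <- NULL
  if (!is.null(planted_pairs) && nrow(planted_instances) > 0) {
    j <- merge(planted_instances[c("motif_id", "region_id")],
               planted_pairs, by.x = "region_id", by.y = "lmr_id")
    if (nrow(j) > 0) {
      j$source_tf <- tf_of[j$motif_id]
      planted_edges <- unique(j[c("source_tf", "gene_id")])
      names(planted_edges)[2] <- "target_gene"
      planted_edges <- planted_edges[order(planted_edges$source_tf,
                                           planted_edges$target_gene), ]
      rownames(planted_edges) <- NULL
    }
  }

  list(samples = samples, planted_lmrs = lmrs, presence = presence,
       meth_levels = meth_levels, planted_pairs = planted_pairs,
       planted_motif_instances = planted_instances,
       planted_edges = planted_edges,
       snp_counts = list(n_inside = n_in, n_outside = n_out,
                         bp_inside = lmr_bp,
                         bp_outside = genome_bp - lmr_bp),
       peak_cover = peak_cover, categories = categories,
       genes = genes, files = files, config = config)
}
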