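#' Load and validate a pipeline run configuration
#'
#' The configuration is a YAML (or already-parsed list) with entries:
#' `genome`, `genes`, `expression`, `motifs`, `motif_map`, `tf_families`,
#' `vcf` (optional), `chrom_sizes`, `outdir`, `seed`, a `samples` list
#' (each with `sample_id`, `pair`, `tolerance`, `cgmap` and optional
#' `peaks` paths per mark), and an optional `params` block overriding
#' stage defaults (`lmr`, `dmr`, `link`, `scan`).
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated config list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$samples))
  ids <- vapply(config$samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids in config")
  tol <- vapply(config$samples, `[[`, character(1), "tolerance")
  pair <- vapply(config$samples, function(s) as.integer(s$pair), integer(1))
  for (p in unique(pair[tol == "tolerant"])) {
    if (!any(pair == p & tol == "susceptible")) {
      stop("tolerant sample of pair ", p, " has no susceptible partner")
    }
  }
  req <- c("genome", "genes", "expression", "motifs", "motif_map",
           "tf_families", "chrom_sizes")
  for (k in req) {
    if (is.null(config[[k]]) || !file.exists(config[[k]])) {
      stop("missing required input: ", k)
    }
  }
  for (s in config$samples) {
    if (!file.exists(s$cgmap)) stop("missing cgmap for ", s$sample_id)
  }
  if (is.null(config$seed)) config$seed <- 1L
  class(config) <- c("run_config", "list")
  config
}

#' Build a run configuration from a generated synthetic dataset
#'
#' @param truth Ground-truth list returned by [generate_dataset()].
#' @param outdir Output directory for the pipeline run.
#' @return A validated `run_config`.
#' @export
config_from_truth <- function(truth, outdir) {
  f <- truth$files
  samples <- lapply(seq_len(nrow(truth$samples)), function(i) {
    sid <- truth$samples$sample_id[i]
    list(sample_id = sid, pair = truth$samples$pair[i],
         tolerance = truth$samples$tolerance[i],
         cgmap = f[[paste0("cgmap_", sid)]],
         peaks = list(H3K4me3 = f[[sprintf("peaks_%s_H3K4me3", sid)]],
                      H3K27me3 = f[[sprintf("peaks_%s_H3K27me3", sid)]]))
  })
  read_run_config(list(
    genome = f$genome, genes = f$genes, expression = f$expression,
    motifs = f$motifs, motif_map = f$motif_map,
    tf_families = f$tf_families, vcf = f$vcf,
    chrom_sizes = f$chrom_sizes, outdir = outdir,
    seed = truth$config$seed, samples = samples))
}

get_param <- function(config, stage, name, default) {
  v <- config$params[[stage]][[name]]
  if (is.null(v)) default else v
}

#' Run the full regulatory-landscape pipeline
#'
#' Executes, in order: per-sample LMR segmentation (and conversion-rate
#' estimation when a `lambda` spike-in contig is present), per-pair DMR
#' calling, genomic annotation of the pooled LMRs, histone-mark overlap
#' reports, SNP density, consensus-enhancer linking to target genes,
#' motif scanning of enhancers and enrichment in the focal pair's
#' tolerant-specific LMRs, and TF-network assembly. Per-stage outputs are
#' written under `config$outdir` together with `summary.json`; stages
#' whose optional inputs (VCF, peaks) are missing are skipped with an
#' explicit notice in the summary.
#'
#' @param config A `run_config` (see [read_run_config()]), or a path to
#'   one.
#' @param focal_pair Tolerant/susceptible pair used for the
#'   condition-specific motif analysis (default 1).
#' @return The summary list, invisibly; also written as JSON.
#' @export
run_all <- function(config, focal_pair = 1L) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("regland run; seed=%d", config$seed)
  summary <- list(seed = config$seed, skipped = character())

  ids <- vapply(config$samples, `[[`, character(1), "sample_id")
  spike <- get_param(config, "lmr", "spike_contig", "lambda")

  ## stage 1: LMRs per sample ------------------------------------------------
  lmr_thr <- get_param(config, "lmr", "threshold", 0.20)
  calls_by_sample <- list()
  lmrs_by_sample <- list()
  conv <- list()
  for (s in config$samples) {
    calls <- read_cgmap(s$cgmap)
    lam <- calls[calls$chrom == spike, , drop = FALSE]
    if (nrow(lam) > 0) conv[[s$sample_id]] <- conversion_rate(lam)
    calls <- calls[calls$chrom != spike, , drop = FALSE]
    calls_by_sample[[s$sample_id]] <- calls
    lmrs <- call_lmrs(calls, lmr_threshold = lmr_thr,
                      smooth_k = get_param(config, "lmr", "smooth_k", 3L),
                      min_cpg = get_param(config, "lmr", "min_cpg", 4L),
                      umr_cpg_cutoff = get_param(config, "lmr",
                                                 "umr_cpg_cutoff", 30L),
                      sample = s$sample_id)
    lmrs_by_sample[[s$sample_id]] <- lmrs
    write_bed(lmrs, file.path(config$outdir,
                              sprintf("lmrs_%s.bed", s$sample_id)),
              extra = c("n_cpg", "mean_meth"))
    logf("lmr %s: %d calls in, %d LMRs out", s$sample_id, nrow(calls),
         nrow(lmrs))
  }
  summary$lmr_counts <- vapply(lmrs_by_sample, nrow, integer(1))
  summary$conversion_rate <- conv

  ## stage 2: DMRs per pair ---------------------------------------------------
  tol <- vapply(config$samples, `[[`, character(1), "tolerance")
  pair <- vapply(config$samples, function(s) as.integer(s$pair), integer(1))
  dmrs_by_pair <- list()
  for (p in unique(pair)) {
    it <- which(pair == p & tol == "tolerant")
    is_ <- which(pair == p & tol == "susceptible")
    if (length(it) != 1 || length(is_) != 1) next
    dm <- call_dmrs(calls_by_sample[[ids[it]]], calls_by_sample[[ids[is_]]],
                    window = get_param(config, "dmr", "window", 200L),
                    alpha_q = get_param(config, "dmr", "qvalue", 0.05))
    dmrs_by_pair[[as.character(p)]] <- dm
    write_bed(dm, file.path(config$outdir, sprintf("dmrs_pair%d.bed", p)),
              extra = c("direction", "q"))
    logf("dmr pair %d (%s vs %s): %d tested, %d DMRs (%d hypo)", p,
         ids[it], ids[is_], attr(dm, "n_tested"), nrow(dm),
         sum(dm$direction == "hypo"))
  }
  summary$dmr_counts <- vapply(dmrs_by_pair, nrow, integer(1))

  ## stage 3: annotation, overlap, SNP density -------------------------------
  genes <- read_genes(config$genes)
  pooled <- do.call(rbind, lapply(lmrs_by_sample, function(x)
    x[c("chrom", "start", "end")]))
  union_lmrs <- merge_regions(pooled)
  ann <- classify_regions(union_lmrs, genes,
                          promoter_up = get_param(config, "annotate",
                                                  "promoter_up", 2000L))
  summary$category_fractions <- as.list(attr(ann, "fractions"))
  logf("annotate: %d union LMRs", nrow(union_lmrs))

  have_peaks <- all(vapply(config$samples, function(s)
    !is.null(s$peaks) && all(vapply(s$peaks, file.exists, logical(1))),
    logical(1)))
  if (have_peaks) {
    reports <- lapply(config$samples, function(s) {
      mark_overlap_report(lmrs_by_sample[[s$sample_id]],
                          read_bed(s$peaks$H3K4me3),
                          read_bed(s$peaks$H3K27me3))
    })
    names(reports) <- ids
    summary$mark_overlap <- list(
      frac_k27_mean = mean(vapply(reports, `[[`, numeric(1), "frac_k27")),
      ratio_mean = mean(vapply(reports, `[[`, numeric(1), "ratio")),
      per_sample = reports)
  } else {
    summary$skipped <- c(summary$skipped, "mark_overlap")
    logf("mark_overlap skipped: missing peak files")
  }

  chrom_sizes <- read.table(config$chrom_sizes, sep = "\t",
                            col.names = c("chrom", "size"))
  if (!is.null(config$vcf) && file.exists(config$vcf)) {
    snps <- read_vcf_sites(config$vcf)
    dens <- snp_density(snps, union_lmrs, chrom_sizes)
    summary$snp_density <- dens[c("n_inside", "density_inside",
                                  "density_outside", "ratio")]
    logf("snp_density: %d SNPs, ratio %.2f", nrow(snps), dens$ratio)
  } else {
    summary$skipped <- c(summary$skipped, "snp_density")
    logf("snp_density skipped: no VCF")
  }

  ## stage 4: enhancer-gene linking ------------------------------------------
  enhancers <- consensus_enhancers(lmrs_by_sample)
  meth <- enhancer_methylation(enhancers, calls_by_sample)
  expr_dt <- data.table::fread(config$expression)
  expr <- as.matrix(expr_dt[, -1])
  rownames(expr) <- expr_dt[[1]]
  pairs_df <- link_enhancers(
    meth, enhancers, expr, genes,
    alpha = get_param(config, "link", "alpha", 0.05),
    correction = get_param(config, "link", "correction", "none"),
    n_each_side = get_param(config, "link", "n_each_side", 10L))
  data.table::fwrite(pairs_df, file.path(config$outdir, "pairs.tsv"),
                     sep = "\t")
  st <- pair_stats(pairs_df)
  summary$pair_stats <- st[c("n_pairs", "n_enhancers", "n_genes",
                             "genes_per_enhancer", "enhancers_per_gene",
                             "median_distance", "frac_single_target")]
  logf("link: %d enhancers, %d tested, %d pairs", nrow(enhancers),
       attr(pairs_df, "n_tested"), nrow(pairs_df))

  ## stage 5: motif scan and enrichment --------------------------------------
  motifs <- read_motifs(config$motifs)
  enh_seqs <- region_sequences(config$genome, enhancers)
  scan_thr <- get_param(config, "scan", "p_threshold", 1e-4)
  hits <- scan_regions(enh_seqs, motifs, p_threshold = scan_thr)
  data.table::fwrite(hits, file.path(config$outdir, "hits.tsv"), sep = "\t")
  summary$n_motif_hits <- nrow(hits)
  logf("scan: %d hits over %d enhancers", nrow(hits), nrow(enhancers))

  fp <- as.character(focal_pair)
  it <- which(pair == focal_pair & tol == "tolerant")
  is_ <- which(pair == focal_pair & tol == "susceptible")
  if (length(it) == 1 && length(is_) == 1) {
    lmrs_tol <- lmrs_by_sample[[ids[it]]]
    lmrs_sus <- lmrs_by_sample[[ids[is_]]]
    spec <- tolerant_specific_lmrs(lmrs_tol, lmrs_sus,
                                   hypo_dmrs = dmrs_by_pair[[fp]])
    # background: the tolerant sample's LMRs shared with the susceptible one
    bg_set <- lmrs_tol[overlap_count(lmrs_tol, lmrs_sus)$flags, , drop = FALSE]
    if (nrow(spec) > 0 && nrow(bg_set) > 0) {
      spec$lmr_id <- sprintf("fg_%03d", seq_len(nrow(spec)))
      bg_set$lmr_id <- sprintf("bg_%03d", seq_len(nrow(bg_set)))
      enr <- enrich_motifs(region_sequences(config$genome, spec),
                           region_sequences(config$genome, bg_set),
                           motifs, p_threshold = scan_thr)
      data.table::fwrite(enr, file.path(config$outdir, "enrichment.tsv"),
                         sep = "\t")
      summary$enrichment_head <- head(enr[c("motif_id", "odds_ratio", "q")], 5)
      logf("enrich: %d fg vs %d bg regions", nrow(spec), nrow(bg_set))
    } else {
      summary$skipped <- c(summary$skipped, "enrichment")
      logf("enrichment skipped: no condition-specific LMRs")
    }
  }

  ## stage 6: network ---------------------------------------------------------
  motif_map <- read.table(config$motif_map, header = TRUE, sep = "\t")
  tf_fams <- read.table(config$tf_families, header = TRUE, sep = "\t")
  edges <- build_network(pairs_df, hits, motif_map, tf_fams)
  write_network(edges, file.path(config$outdir, "network.tsv"))
  subnet <- tf_subnetwork(edges, tf_fams$tf_gene_id, tf_fams)
  summary$network <- list(n_edges = nrow(edges),
                          n_tf_tf_edges = nrow(subnet$edges),
                          n_tfs = length(unique(edges$source_tf)))
  logf("network: %d edges (%d TF-TF)", nrow(edges), nrow(subnet$edges))

  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}
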