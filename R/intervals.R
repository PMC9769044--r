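#' Count overlaps between two region sets
#'
#' Counts how many regions of `a` overlap at least `min_overlap` bp with
#' any region of `b`. Intervals are 0-based half-open, so touching
#' intervals ([0,10) vs [10,20)) do not overlap.
#'
#' @param a,b Region data.frames (`chrom`, `start`, `end`).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return List with `n` (count of `a` regions hit) and `flags` (logical
#'   per row of `a`).
#' @export
overlap_count <- function(a, b, min_overlap = 1L) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(n = 0L, flags = logical(nrow(a))))
  }
  # suppressed warning: disjoint seqlevels between a and b are a legitimate
  # no-overlap case here, not a coordinate-system mismatch
  hits <- suppressWarnings(GenomicRanges::countOverlaps(
    regions_to_gr(a), regions_to_gr(b), minoverlap = min_overlap
  ))
  flags <- hits > 0
  list(n = sum(flags), flags = flags)
}

#' Merge overlapping regions into a disjoint set
#'
#' @param regions Region data.frame.
#' @return Merged data.frame (`chrom`, `start`, `end`), sorted; idempotent.
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0) return(empty_regions())
  gr_to_regions(GenomicRanges::reduce(regions_to_gr(regions)))
}

#' Total bases covered by a region set (after merging)
#' @param regions Region data.frame.
#' @return Number of covered bases.
#' @export
covered_bases <- function(regions) {
  m <- merge_regions(regions)
  sum(as.numeric(m$end - m$start))
}

#' Classify regions against gene annotation
#'
#' Assigns each region to exactly one genomic category by the position of
#' its midpoint, with precedence promoter > exonic > intronic > intergenic.
#' The promoter is the `promoter_up` bp immediately upstream of the TSS on
#' the coding strand (half-open, excluding the TSS itself). Genes without
#' exon structure are treated as single-exon.
#'
#' @param regions Region data.frame (e.g. LMRs).
#' @param genes Gene data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (TSS derived as `start` for `+`, `end - 1` for `-`).
#' @param exons Optional exon data.frame (`gene_id`, `chrom`, `start`,
#'   `end`); defaults to the gene bodies.
#' @param promoter_up Promoter window upstream of the TSS, bp.
#' @param by `"midpoint"` (default) classifies by region midpoint;
#'   `"any"` classifies by any-overlap with the same precedence.
#' @return Input regions with a `category` factor column; category
#'   fractions in `attr(, "fractions")`; strand-less genes are dropped and
#'   counted in `attr(, "n_rejected_genes")`.
#' @export
classify_regions <- function(regions, genes, exons = NULL,
                             promoter_up = 2000L,
                             by = c("midpoint", "any")) {
  by <- match.arg(by)
  bad <- !(genes$strand %in% c("+", "-"))
  n_rejected <- sum(bad)
  genes <- genes[!bad, , drop = FALSE]
  if (is.null(exons)) exons <- genes[c("gene_id", "chrom", "start", "end")]
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  prom <- data.frame(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", pmax(tss - promoter_up, 0L), tss + 1L),
    end = ifelse(genes$strand == "+", tss, tss + 1L + promoter_up),
    stringsAsFactors = FALSE
  )
  query <- if (by == "midpoint") {
    mid <- (regions$start + regions$end) %/% 2L
    data.frame(chrom = regions$chrom, start = mid, end = mid + 1L,
               stringsAsFactors = FALSE)
  } else {
    regions[c("chrom", "start", "end")]
  }
  in_prom <- overlap_count(query, prom)$flags
  in_exon <- overlap_count(query, exons)$flags
  in_gene <- overlap_count(query, genes)$flags
  category <- rep("intergenic", nrow(regions))
  category[in_gene] <- "intronic"
  category[in_exon] <- "exonic"
  category[in_prom] <- "promoter"
  out <- regions
  out$category <- factor(category,
                         levels = c("promoter", "exonic", "intronic",
                                    "intergenic"))
  fr <- table(out$category) / max(nrow(out), 1L)
  attr(out, "fractions") <- as.numeric(fr) |> setNames(names(fr))
  attr(out, "n_rejected_genes") <- n_rejected
  out
}

#' Overlap report of LMRs against histone marks
#'
#' H3K4me3 marks active transcription start sites and H3K27me3
#' repressed/poised chromatin; candidate enhancers (LMRs) intersect the
#' latter far more often. Reports per-mark overlap counts, the fraction of
#' LMRs overlapping H3K27me3 peaks, and the H3K27me3:H3K4me3 count ratio.
#'
#' @param lmrs LMR data.frame.
#' @param peaks_k4,peaks_k27 Peak region data.frames for H3K4me3 and
#'   H3K27me3.
#' @return List `count_k4`, `count_k27`, `frac_k27`, `ratio` (ratio is
#'   `Inf` when no LMR overlaps H3K4me3 but some overlap H3K27me3).
#' @export
mark_overlap_report <- function(lmrs, peaks_k4, peaks_k27) {
  n4 <- overlap_count(lmrs, peaks_k4)$n
  n27 <- overlap_count(lmrs, peaks_k27)$n
  frac <- if (nrow(lmrs) > 0) n27 / nrow(lmrs) else 0
  ratio <- if (n4 > 0) n27 / n4 else if (n27 > 0) Inf else NA_real_
  list(count_k4 = n4, count_k27 = n27, frac_k27 = frac, ratio = ratio)
}

#' SNP density inside and outside a region set
#'
#' Computes SNPs per kb inside the merged regions and in the genomic
#' complement, plus their ratio. SNPs on chromosomes absent from
#' `chrom_sizes` are rejected and counted.
#'
#' @param snps data.frame with `chrom` and `pos` (1-based site positions).
#' @param regions Region data.frame (merged internally so overlapping bp
#'   are not double-counted).
#' @param chrom_sizes data.frame with `chrom`, `size` (bp).
#' @return List of class `density_result`: `n_inside`, `bp_inside`,
#'   `n_outside`, `bp_outside`, `density_inside`, `density_outside` (per
#'   kb), `ratio` (`NA` when the outside density is zero), and
#'   `n_rejected`.
#' @export
snp_density <- function(snps, regions, chrom_sizes) {
  keep <- snps$chrom %in% chrom_sizes$chrom
  n_rejected <- sum(!keep)
  snps <- snps[keep, , drop = FALSE]
  regions <- merge_regions(regions[regions$chrom %in% chrom_sizes$chrom, ,
                                   drop = FALSE])
  bp_inside <- sum(as.numeric(regions$end - regions$start))
  bp_total <- sum(as.numeric(chrom_sizes$size))
  bp_outside <- bp_total - bp_inside
  if (nrow(snps) > 0 && nrow(regions) > 0) {
    sites <- data.frame(chrom = snps$chrom, start = snps$pos - 1L,
                        end = snps$pos, stringsAsFactors = FALSE)
    n_inside <- overlap_count(sites, regions)$n
  } else {
    n_inside <- 0L
  }
  n_outside <- nrow(snps) - n_inside
  d_in <- if (bp_inside > 0) 1000 * n_inside / bp_inside else 0
  d_out <- if (bp_outside > 0) 1000 * n_outside / bp_outside else 0
  ratio <- if (d_out > 0) d_in / d_out else NA_real_
  structure(
    list(n_inside = n_inside, bp_inside = bp_inside,
         n_outside = n_outside, bp_outside = bp_outside,
         density_inside = d_in, density_outside = d_out,
         ratio = ratio, n_rejected = n_rejected),
    class = "density_result"
  )
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf(
    "SNP density: %d SNPs in %.1f Mb of regions (%.1f/kb) vs %d in %.1f Mb outside (%.1f/kb); ratio %.2f\n",
    x$n_inside, x$bp_inside / 1e6, x$density_inside,
    x$n_outside, x$bp_outside / 1e6, x$density_outside, x$ratio))
  invisible(x)
}

#' Read a BED or narrowPeak file as a region data.frame
#'
#' @param path BED3+/narrowPeak path (plain text).
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`, `signal`, `p`, `q`, `peak_offset`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  nm <- c("chrom", "start", "end", "name", "score", "strand",
          "signal", "p", "q", "peak_offset")
  names(dt) <- nm[seq_len(min(ncol(dt), length(nm)))]
  as.data.frame(dt)
}

#' Write regions as BED (optionally with extra columns)
#' @param regions Region data.frame.
#' @param path Output path.
#' @param extra Names of extra columns to append after the BED6 fields.
#' @export
write_bed <- function(regions, path, extra = character()) {
  bed <- data.frame(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = if ("name" %in% names(regions)) regions$name else
      sprintf("region_%d", seq_len(nrow(regions))),
    score = if ("score" %in% names(regions)) regions$score else 0L,
    strand = if ("strand" %in% names(regions)) regions$strand else "."
  )
  for (e in extra) bed[[e]] <- regions[[e]]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a sites-only VCF as a SNP data.frame
#'
#' Keeps biallelic single-nucleotide variants; multiallelic or indel
#' records are counted and excluded.
#'
#' @param path VCF path (plain text, v4.x).
#' @return data.frame `chrom`, `pos`, `ref`, `alt` with attribute
#'   `n_excluded`.
#' @export
read_vcf_sites <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character())
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  f <- data.table::fread(text = body, header = FALSE, sep = "\t")
  out <- data.frame(chrom = as.character(f[[1]]), pos = as.integer(f[[2]]),
                    ref = as.character(f[[4]]), alt = as.character(f[[5]]),
                    stringsAsFactors = FALSE)
  ok <- nchar(out$ref) == 1 & nchar(out$alt) == 1 & !grepl(",", out$alt)
  res <- out[ok, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_excluded") <- sum(!ok)
  res
}

#' Precision and recall of called regions against a truth set
#'
#' A called region matches a truth region when their reciprocal overlap is
#' at least `min_reciprocal` of each interval's length (50 % by default).
#'
#' @param called,truth Region data.frames.
#' @param min_reciprocal Reciprocal overlap fraction required for a match.
#' @return List: `precision` (called regions matching some truth region),
#'   `recall` (truth regions matched), `n_called`, `n_truth`.
#' @export
region_recovery <- function(called, truth, min_reciprocal = 0.5) {
  if (nrow(called) == 0 || nrow(truth) == 0) {
    return(list(precision = ifelse(nrow(called) == 0, NA_real_, 0),
                recall = ifelse(nrow(truth) == 0, NA_real_, 0),
                n_called = nrow(called), n_truth = nrow(truth)))
  }
  ov <- suppressWarnings(GenomicRanges::findOverlaps(regions_to_gr(called),
                                                     regions_to_gr(truth)))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  w <- pmin(called$end[qh], truth$end[sh]) -
    pmax(called$start[qh], truth$start[sh])
  good <- w >= min_reciprocal * (called$end[qh] - called$start[qh]) &
    w >= min_reciprocal * (truth$end[sh] - truth$start[sh])
  list(precision = length(unique(qh[good])) / nrow(called),
       recall = length(unique(sh[good])) / nrow(truth),
       n_called = nrow(called), n_truth = nrow(truth))
}
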