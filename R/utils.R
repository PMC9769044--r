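#' @importFrom stats cor.test fisher.test p.adjust median rbinom rpois runif
#'   rnorm setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

# All region data.frames in this package use 0-based half-open coordinates
# (chrom, start, end). GRanges is 1-based closed; conversion happens only in
# these two helpers.

#' Convert a region data.frame to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open). All other columns are carried as metadata.
#' @return A `GRanges` object.
#' @keywords internal
regions_to_gr <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  meta <- df[, setdiff(names(df), c("chrom", "start", "end")), drop = FALSE]
  if (ncol(meta) > 0) S4Vectors::mcols(gr) <- meta
  gr
}

#' Convert a GRanges back to a 0-based half-open region data.frame
#' @param gr A `GRanges`.
#' @return data.frame with `chrom`, `start`, `end` and any metadata columns.
#' @keywords internal
gr_to_regions <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  meta <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(meta) > 0) df <- cbind(df, meta)
  rownames(df) <- NULL
  df
}

# empty region frame with the standard columns
empty_regions <- function(extra = character()) {
  base <- data.frame(chrom = character(), start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
  for (nm in extra) base[[nm]] <- numeric()
  base
}

#' Benjamini-Hochberg adjustment shorthand used across modules
#' @keywords internal
bh <- function(p) stats::p.adjust(p, method = "BH")
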