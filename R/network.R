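#' Assemble the TF regulatory network from motif hits and enhancer-gene
#' pairs
#'
#' A directed edge TF -> gene exists when some enhancer is linked to the
#' gene in the pairs table and contains at least one binding-site hit of a
#' motif mapped to that TF. Edges are deduplicated with site counts
#' aggregated; self-loops are permitted (TFs may target themselves). Hits
#' of motifs absent from the motif-to-TF map are dropped and counted.
#'
#' @param pairs Enhancer-gene pair data.frame (`lmr_id`, `gene_id`).
#' @param hits Motif hit data.frame (`motif_id`, `region_id` matching
#'   `lmr_id`).
#' @param motif_to_tf data.frame mapping `motif_id` to `tf_gene_id`.
#' @param tf_families Optional data.frame (`tf_gene_id`, `family`)
#'   labelling targets that are themselves TFs.
#' @param restrict_enhancers Optional region data.frame (e.g.
#'   condition-specific LMRs): only pairs whose enhancer id appears in its
#'   `lmr_id` column are used.
#' @param target_filter Optional character vector of gene ids (e.g.
#'   up-regulated genes): only edges onto these targets are kept.
#' @return data.frame of edges: `source_tf`, `target_gene`, `n_sites`,
#'   `via_enhancers` (comma-separated), `target_is_tf`, `target_family`;
#'   attribute `n_unmapped_hits`.
#' @export
build_network <- function(pairs, hits, motif_to_tf, tf_families = NULL,
                          restrict_enhancers = NULL, target_filter = NULL) {
  empty <- data.frame(source_tf = character(), target_gene = character(),
                      n_sites = integer(), via_enhancers = character(),
                      target_is_tf = logical(), target_family = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(restrict_enhancers)) {
    pairs <- pairs[pairs$lmr_id %in% restrict_enhancers$lmr_id, ,
                   drop = FALSE]
  }
  if (!is.null(target_filter)) {
    pairs <- pairs[pairs$gene_id %in% target_filter, , drop = FALSE]
  }
  if (nrow(pairs) == 0 || nrow(hits) == 0) {
    attr(empty, "n_unmapped_hits") <- if (is.null(hits)) 0L else nrow(hits)
    attr(empty, "empty_input") <- TRUE
    return(empty)
  }
  tf_of <- setNames(motif_to_tf$tf_gene_id, motif_to_tf$motif_id)
  mapped <- hits$motif_id %in% names(tf_of)
  n_unmapped <- sum(!mapped)
  hits <- hits[mapped, , drop = FALSE]
  hits$source_tf <- tf_of[hits$motif_id]
  # join: hit in enhancer e of TF u, pair (e, g) -> edge u -> g
  joined <- merge(hits[c("region_id", "source_tf")],
                  pairs[c("lmr_id", "gene_id")],
                  by.x = "region_id", by.y = "lmr_id")
  if (nrow(joined) == 0) {
    attr(empty, "n_unmapped_hits") <- n_unmapped
    return(empty)
  }
  agg <- stats::aggregate(
    list(n_sites = rep(1L, nrow(joined))),
    by = list(source_tf = joined$source_tf, target_gene = joined$gene_id),
    FUN = sum)
  via <- stats::aggregate(
    list(via_enhancers = joined$region_id),
    by = list(source_tf = joined$source_tf, target_gene = joined$gene_id),
    FUN = function(x) paste(sort(unique(x)), collapse = ","))
  edges <- merge(agg, via, by = c("source_tf", "target_gene"))
  if (!is.null(tf_families)) {
    fam <- setNames(tf_families$family, tf_families$tf_gene_id)
    edges$target_is_tf <- edges$target_gene %in% tf_families$tf_gene_id
    edges$target_family <- ifelse(edges$target_is_tf,
                                  fam[edges$target_gene], NA_character_)
  } else {
    edges$target_is_tf <- NA
    edges$target_family <- NA_character_
  }
  edges <- edges[order(edges$source_tf, edges$target_gene), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "n_unmapped_hits") <- n_unmapped
  edges
}

#' TF-to-TF subnetwork with degrees and family adjacency
#'
#' @param edges Edge data.frame from [build_network()].
#' @param tf_set Character vector of TF gene ids.
#' @param tf_families Optional data.frame (`tf_gene_id`, `family`) for the
#'   family-level adjacency.
#' @return List: `edges` (both endpoints in `tf_set`), `degrees`
#'   (data.frame `gene_id`, `out_degree`, `in_degree`),
#'   `family_adjacency` (family x family edge-count matrix, or `NULL`).
#' @export
tf_subnetwork <- function(edges, tf_set, tf_families = NULL) {
  stopifnot(length(tf_set) > 0)
  sub <- edges[edges$source_tf %in% tf_set &
                 edges$target_gene %in% tf_set, , drop = FALSE]
  nodes <- sort(unique(c(sub$source_tf, sub$target_gene)))
  degrees <- data.frame(
    gene_id = nodes,
    out_degree = vapply(nodes, function(n) sum(sub$source_tf == n),
                        integer(1)),
    in_degree = vapply(nodes, function(n) sum(sub$target_gene == n),
                       integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(degrees) <- NULL
  fam_adj <- NULL
  if (!is.null(tf_families) && nrow(sub) > 0) {
    fam <- setNames(tf_families$family, tf_families$tf_gene_id)
    sf <- fam[sub$source_tf]
    tf_ <- fam[sub$target_gene]
    fams <- sort(unique(stats::na.omit(c(sf, tf_))))
    fam_adj <- matrix(0L, length(fams), length(fams),
                      dimnames = list(from = fams, to = fams))
    for (i in seq_len(nrow(sub))) {
      if (!is.na(sf[i]) && !is.na(tf_[i])) {
        fam_adj[sf[i], tf_[i]] <- fam_adj[sf[i], tf_[i]] + 1L
      }
    }
  }
  list(edges = sub, degrees = degrees, family_adjacency = fam_adj)
}

#' Write a network as edge TSV, SIF, or GraphML
#' @param edges Edge data.frame.
#' @param path Output path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @export
write_network <- function(edges, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    data.table::fwrite(edges, path, sep = "\t")
  } else if (format == "sif") {
    writeLines(sprintf("%s regulates %s", edges$source_tf,
                       edges$target_gene), path)
  } else {
    nodes <- unique(c(edges$source_tf, edges$target_gene))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <graph id="regnet" edgedefault="directed">'), con)
    writeLines(sprintf('    <node id="%s"/>', nodes), con)
    writeLines(sprintf('    <edge source="%s" target="%s"/>',
                       edges$source_tf, edges$target_gene), con)
    writeLines(c("  </graph>", "</graphml>"), con)
  }
  invisible(path)
}
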