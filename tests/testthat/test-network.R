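mk_map <- function(...) {
  m <- c(...)
  data.frame(motif_id = names(m), tf_gene_id = unname(m),
             stringsAsFactors = FALSE)
}

test_that("minimal network: one pair plus one hit gives one edge", {
  pairs <- data.frame(lmr_id = "e1", gene_id = "g1")
  hits <- data.frame(motif_id = "M1", region_id = "e1")
  edges <- build_network(pairs, hits, mk_map(M1 = "tfA"))
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$source_tf, "tfA")
  expect_equal(edges$target_gene, "g1")
  expect_equal(edges$n_sites, 1L)
  # a hit in an enhancer linked to no gene contributes nothing
  lone <- data.frame(motif_id = "M1", region_id = "e_unlinked")
  expect_equal(nrow(build_network(pairs, lone, mk_map(M1 = "tfA"))), 0L)
  # unmapped motifs are dropped and counted
  e2 <- build_network(pairs, rbind(hits,
                                   data.frame(motif_id = "MX",
                                              region_id = "e1")),
                      mk_map(M1 = "tfA"))
  expect_equal(attr(e2, "n_unmapped_hits"), 1L)
  expect_equal(nrow(e2), 1L)
})

test_that("site counts aggregate and self-loops are permitted", {
  pairs <- data.frame(lmr_id = c("e1", "e2"), gene_id = c("tfA", "tfA"))
  hits <- data.frame(motif_id = "M1", region_id = c("e1", "e1", "e2"))
  edges <- build_network(pairs, hits, mk_map(M1 = "tfA"))
  expect_equal(nrow(edges), 1L)  # self-loop tfA -> tfA
  expect_equal(edges$n_sites, 3L)
  expect_equal(edges$via_enhancers, "e1,e2")
})

test_that("rebuilt network equals the planted edge set exactly", {
  gt <- sim_fixture()
  motif_map <- read.table(gt$files$motif_map, header = TRUE, sep = "\t")
  tf_fams <- read.table(gt$files$tf_families, header = TRUE, sep = "\t")
  edges <- build_network(gt$planted_pairs, gt$planted_motif_instances,
                         motif_map, tf_fams)
  expect_identical(edges[c("source_tf", "target_gene")], gt$planted_edges)
  # deterministic rebuild
  again <- build_network(gt$planted_pairs, gt$planted_motif_instances,
                         motif_map, tf_fams)
  expect_identical(edges, again)
  # removing a pair never adds an edge
  fewer <- build_network(gt$planted_pairs[-1, ], gt$planted_motif_instances,
                         motif_map, tf_fams)
  key <- function(e) paste(e$source_tf, e$target_gene)
  expect_true(all(key(fewer) %in% key(edges)))
  expect_lte(nrow(fewer), nrow(edges))
  # site-count self-consistency
  linked <- gt$planted_motif_instances$region_id %in% gt$planted_pairs$lmr_id
  expect_lte(sum(edges$n_sites), sum(linked) * nrow(gt$planted_pairs))
})

test_that("TF subnetwork filters endpoints and tallies degrees by family", {
  edges <- data.frame(
    source_tf = c("a", "a", "b", "c"),
    target_gene = c("b", "x", "a", "c"),
    n_sites = 1L, via_enhancers = "e", target_is_tf = NA,
    target_family = NA_character_, stringsAsFactors = FALSE)
  # all-TF->non-TF edge list gives an empty subnetwork
  expect_equal(nrow(tf_subnetwork(
    data.frame(source_tf = "a", target_gene = "x", n_sites = 1L),
    c("a", "b"))$edges), 0L)
  sub <- tf_subnetwork(edges, c("a", "b", "c"))
  expect_equal(nrow(sub$edges), 3L)  # a->b, b->a, c->c
  deg <- sub$degrees
  expect_equal(deg$out_degree[deg$gene_id == "a"], 1L)
  expect_equal(deg$in_degree[deg$gene_id == "a"], 1L)
  # family adjacency row sums equal per-family out-degrees (brute force)
  fams <- data.frame(tf_gene_id = c("a", "b", "c"),
                     family = c("NAC", "bZIP", "NAC"))
  sub2 <- tf_subnetwork(edges, c("a", "b", "c"), fams)
  adj <- sub2$family_adjacency
  fam_of <- setNames(fams$family, fams$tf_gene_id)
  for (f in rownames(adj)) {
    expect_equal(sum(adj[f, ]),
                 sum(fam_of[sub2$edges$source_tf] == f))
  }
})

test_that("restriction and target filters only ever shrink the network", {
  gt <- sim_fixture()
  motif_map <- read.table(gt$files$motif_map, header = TRUE, sep = "\t")
  full <- build_network(gt$planted_pairs, gt$planted_motif_instances,
                        motif_map)
  spec <- gt$planted_lmrs[gt$planted_lmrs$type == "specific", ]
  restricted <- build_network(gt$planted_pairs, gt$planted_motif_instances,
                              motif_map, restrict_enhancers = spec)
  expect_lte(nrow(restricted), nrow(full))
  some_targets <- unique(gt$planted_pairs$gene_id)[1:5]
  filtered <- build_network(gt$planted_pairs, gt$planted_motif_instances,
                            motif_map, target_filter = some_targets)
  expect_true(all(filtered$target_gene %in% some_targets))
})

test_that("network writers emit TSV, SIF and GraphML", {
  edges <- data.frame(source_tf = "a", target_gene = "b", n_sites = 1L,
                      via_enhancers = "e1", target_is_tf = TRUE,
                      target_family = "NAC")
  for (fmt in c("tsv", "sif", "graphml")) {
    f <- withr::local_tempfile()
    write_network(edges, f, fmt)
    expect_gt(file.size(f), 0)
  }
  g <- withr::local_tempfile()
  write_network(edges, g, "graphml")
  expect_silent(xml2::read_xml(g))
})
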