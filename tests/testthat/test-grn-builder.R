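test_that("regulatory scope applies a strict FDR cut", {
  degs <- deg_table(c("g1", "g2"), c(-1.0, 0.5), c(0.049, 0.05))
  expect_equal(regulatory_scope(degs), "g1")
  expect_equal(regulatory_scope(deg_table(character(0), numeric(0),
                                          numeric(0))), character(0))
  expect_equal(regulatory_scope(degs, fdr_threshold = 0.1),
               c("g1", "g2"))
  expect_error(deg_table("g1", 1, 1.2), "FDR")
  expect_error(deg_table("g1", Inf, 0.5), "finite")
})

test_that("the direct layer is root -> (bound intersect scope), no self-loops", {
  g <- build_direct_layer("root", c("g1", "g2", "g3"),
                          c("g2", "g3", "g4"))
  el <- grn_edges(g)
  expect_setequal(paste(el$source, el$target),
                  c("root g2", "root g3"))
  expect_true(all(el$provenance == "direct"))

  # disjoint bound and scope -> root-only graph
  empty <- build_direct_layer("root", "g1", "g9")
  expect_equal(grn_nodes(empty), "root")

  # the root's own gene never gets a self-loop
  self <- build_direct_layer("root", c("root", "g1"), c("root", "g1"))
  expect_setequal(grn_nodes(self), c("root", "g1"))
  expect_equal(nrow(grn_edges(self)), 1L)
})

test_that("catalog expansion keeps exactly the root-reachable subgraph", {
  direct <- build_direct_layer("root", c("g2", "g3"),
                               c("g2", "g3", "g4", "g6"))
  catalog <- tf_catalog(c("g2", "g5"), c("g4", "g6"))
  grn <- expand_and_prune(direct, catalog,
                          c("g2", "g3", "g4", "g5", "g6"))
  expect_setequal(grn_nodes(grn), c("root", "g2", "g3", "g4"))
  el <- grn_edges(grn)
  expect_setequal(paste(el$source, el$target),
                  c("root g2", "root g3", "g2 g4"))
  expect_equal(el$provenance[el$source == "g2"], "catalog")

  # empty catalog leaves the direct layer unchanged
  same <- expand_and_prune(direct, tf_catalog(character(0), character(0)),
                           c("g2", "g3"))
  expect_setequal(grn_nodes(same), grn_nodes(direct))

  # a reachable catalog cycle is retained in full
  cyc <- expand_and_prune(direct, tf_catalog(c("g2", "g4"), c("g4", "g2")),
                          c("g2", "g3", "g4"))
  el2 <- grn_edges(cyc)
  expect_true(all(c("g2 g4", "g4 g2") %in% paste(el2$source, el2$target)))
})

test_that("direct evidence dominates when a catalog edge duplicates it", {
  direct <- build_direct_layer("root", "g2", "g2")
  # a catalog edge into the root is never admitted; root->g2 stays direct
  grn <- expand_and_prune(direct, tf_catalog("root", "g2"), c("g2"))
  expect_equal(grn_edges(grn)$provenance, "direct")
})

test_that("built networks are root-reachable and scope-monotone", {
  set.seed(31)
  for (rep in 1:10) {
    genes <- paste0("g", 1:30)
    bound <- sample(genes, 12)
    scope_small <- sample(genes, 15)
    scope_big <- union(scope_small, sample(genes, 8))
    cat_df <- random_digraph(30, 0.06)$edges
    cat_df$source <- sub("n", "g", cat_df$source)
    cat_df$target <- sub("n", "g", cat_df$target)
    catalog <- tf_catalog(cat_df$source, cat_df$target)

    build <- function(scope) {
      expand_and_prune(build_direct_layer("root", bound, scope),
                       catalog, scope)
    }
    small <- build(scope_small)
    big <- build(scope_big)

    # every node reachable from the root (independent BFS via distances)
    d <- igraph::distances(small, v = "root", mode = "out")
    expect_true(all(is.finite(d)))
    # non-root nodes within scope; direct targets within the bound set
    expect_true(all(setdiff(grn_nodes(small), "root") %in% scope_small))
    els <- grn_edges(small)
    expect_true(all(els$target[els$provenance == "direct"] %in% bound))
    # enlarging the scope only ever adds nodes and edges
    expect_true(all(grn_nodes(small) %in% grn_nodes(big)))
    elb <- grn_edges(big)
    expect_true(all(paste(els$source, els$target) %in%
                      paste(elb$source, elb$target)))
  }
})

test_that("edge signs follow the knockdown-response convention", {
  expect_equal(infer_edge_sign(-1.2), "+")
  expect_equal(infer_edge_sign(0.8), "-")
  expect_error(infer_edge_sign(0), "malformed")

  grn <- toy_grn(data.frame(source = c("root", "root", "g1"),
                            target = c("g1", "g2", "g3")), "root")
  kd <- deg_table(c("g1", "g2"), c(-2, 1.5), c(0.01, 0.01))
  signed <- sign_edges(grn, list(root = kd))
  el <- grn_edges(signed)
  expect_equal(el$sign[el$target == "g1"], "+")
  expect_equal(el$sign[el$target == "g2"], "-")
  expect_equal(el$sign[el$source == "g1"], "unsigned")
})

test_that("essentiality categories follow the cell-line precedence rule", {
  calls <- essentiality_calls(data.frame(
    gene_id = c("gA", "gA", "gB", "gC", "gD"),
    cell_line = c("HT-29", "MOLM-13", "MOLM-13", "MV4-11", "HT-1080"),
    essential = c(TRUE, TRUE, TRUE, FALSE, FALSE)
  ))
  # essential in a non-leukemia line wins even if also essential in leukemia
  expect_equal(classify_essentiality(calls, "gA"), "nonspecific_essential")
  expect_equal(classify_essentiality(calls, "gB"), "leukemia_specific")
  expect_equal(classify_essentiality(calls, c("gC", "gD")),
               rep("nonessential", 2))
  expect_warning(out <- classify_essentiality(calls, "gZ"), "absent")
  expect_equal(out, "nonessential")
  expect_error(essentiality_calls(data.frame(gene_id = "g", cell_line = "x",
                                             essential = TRUE)),
               "partition")
})

test_that("node annotation enforces the scope invariant", {
  grn <- toy_grn(data.frame(source = "root", target = c("g1", "g2")),
                 "root")
  degs <- deg_table(c("g1", "g2"), c(-1, 2), c(0.01, 0.02))
  ann <- annotate_nodes(grn, degs)
  expect_equal(length(grn_nodes(ann)), 3L)
  expect_equal(igraph::V(ann)$logfc[match("g1", grn_nodes(ann))], -1)
  expect_true(igraph::V(ann)$is_root[match("root", grn_nodes(ann))])
  # a node missing from the DEG table violates the build invariant
  expect_error(annotate_nodes(grn, deg_table("g1", -1, 0.01)), "missing")
})

test_that("DEG, catalog and essentiality TSVs round-trip; catalog is cleaned", {
  dir <- withr::local_tempdir()
  degs <- deg_table(c("g1", "g2"), c(-1.5, 0.7), c(0.001, 0.2))
  write_deg_table(degs, file.path(dir, "deg.tsv"))
  expect_equal(read_deg_table(file.path(dir, "deg.tsv")), degs)

  expect_warning(cat1 <- tf_catalog(c("a", "a", "b"), c("b", "a", "c")),
                 "self-edge")
  expect_equal(nrow(cat1), 2L)
  expect_equal(nrow(tf_catalog(c("a", "a"), c("b", "b"))), 1L)

  utils::write.table(data.frame(source = "a", target = "b"),
                     file.path(dir, "cat.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_equal(read_tf_catalog(file.path(dir, "cat.tsv"))$target, "b")
})
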