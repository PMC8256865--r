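#' Read a knockdown DEG table from TSV
#'
#' Expects a header with columns \code{gene_id}, \code{logFC}, \code{FDR}.
#' The table reports, per gene, the log2 fold change of expression after
#' knockdown of a regulator versus control, and the multiple-testing
#' adjusted p-value.
#'
#' @param path file path.
#' @return a validated \code{data.frame} with class \code{"deg_table"}.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "logFC", "FDR")
  if (!all(need %in% names(df)))
    stop("DEG TSV must have columns: ", paste(need, collapse = ", "))
  deg_table(df$gene_id, df$logFC, df$FDR)
}

#' Construct a DEG table
#'
#' @param gene_id unique gene ids.
#' @param logFC finite log2 fold changes (knockdown vs control).
#' @param FDR adjusted p-values in \code{[0, 1]}.
#' @return a \code{data.frame} with class \code{"deg_table"}.
#' @export
deg_table <- function(gene_id, logFC, FDR) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene ids in a DEG table must be unique")
  logFC <- as.numeric(logFC)
  FDR <- as.numeric(FDR)
  if (length(logFC) && any(!is.finite(logFC))) stop("logFC must be finite")
  if (length(FDR) && (any(!is.finite(FDR)) || any(FDR < 0 | FDR > 1)))
    stop("FDR must lie in [0, 1]")
  out <- data.frame(gene_id = gene_id, logFC = logFC, FDR = FDR,
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Write a DEG table to TSV
#' @param degs a \code{deg_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_deg_table <- function(degs, path) {
  utils::write.table(as.data.frame(degs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TF interaction catalog from TSV
#'
#' Expects columns \code{source} and \code{target} (optionally
#' \code{evidence}). Self-edges are dropped with a warning; duplicate
#' (source, target) pairs are collapsed.
#'
#' @param path file path.
#' @return a \code{data.frame} with class \code{"tf_catalog"}.
#' @export
read_tf_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(df)))
    stop("catalog TSV must have columns: source, target")
  tf_catalog(df$source, df$target,
             evidence = if ("evidence" %in% names(df)) df$evidence else NULL)
}

#' Construct a TF interaction catalog
#'
#' @param source,target character vectors of regulator and target gene ids.
#' @param evidence optional evidence tag per edge.
#' @return a \code{data.frame} with class \code{"tf_catalog"} and no
#'   self-edges or duplicate pairs.
#' @export
tf_catalog <- function(source, target, evidence = NULL) {
  out <- data.frame(source = as.character(source),
                    target = as.character(target),
                    stringsAsFactors = FALSE)
  if (!is.null(evidence)) out$evidence <- as.character(evidence)
  self <- out$source == out$target
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped from TF catalog")
    out <- out[!self, , drop = FALSE]
  }
  out <- out[!duplicated(out[c("source", "target")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tf_catalog", "data.frame")
  out
}

#' Regulatory scope: DEGs at an FDR threshold
#'
#' The regulatory scope is the set of genes allowed to enter a GRN built
#' around a regulator: the genes differentially expressed when that
#' regulator is knocked down. The cut is strict: \code{FDR < fdr_threshold}.
#'
#' @param degs a \code{deg_table}.
#' @param fdr_threshold significance threshold (default 0.05).
#' @return sorted character vector of gene ids.
#' @export
regulatory_scope <- function(degs, fdr_threshold = 0.05) {
  stopifnot(inherits(degs, "deg_table"))
  sort(degs$gene_id[degs$FDR < fdr_threshold])
}

#' Build the direct layer of a root-centred GRN
#'
#' Direct interactions are root-to-gene edges supported by binding of the
#' root regulator (ChIP peaks annotated to promoters), restricted to the
#' regulatory scope. The root never receives a self-loop even if its own
#' gene is bound.
#'
#' @param root node id of the central regulator.
#' @param bound character vector of genes bound by the root (from
#'   [annotate_nearest_promoter()] / [bound_genes()]; pre-filter peaks with
#'   [define_enhancers()] for an enhancer-restricted build).
#' @param scope regulatory scope from [regulatory_scope()].
#' @return an \pkg{igraph} graph with graph attribute \code{root}, vertex
#'   attribute \code{bound_by_root}, and edge attribute
#'   \code{provenance = "direct"}.
#' @export
build_direct_layer <- function(root, bound, scope) {
  targets <- sort(setdiff(intersect(bound, scope), root))
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, 1 + length(targets),
                            name = c(root, targets))
  if (length(targets))
    g <- igraph::add_edges(g, rbind(rep(root, length(targets)), targets),
                           provenance = "direct")
  g <- igraph::set_graph_attr(g, "root", root)
  igraph::V(g)$bound_by_root <- igraph::V(g)$name %in% bound
  g
}

#' Expand a direct layer with catalog edges and prune to reachability
#'
#' Candidate edges are the direct edges plus every catalog edge whose
#' source and target both lie in the regulatory scope. Catalog edges that
#' do not explain connectivity between the root and downstream targets are
#' excluded: the final GRN is the subgraph induced by the nodes reachable
#' from the root over the candidate edges. Where a catalog edge duplicates
#' a direct edge, the direct provenance is kept.
#'
#' @param direct graph from [build_direct_layer()].
#' @param catalog a \code{tf_catalog}.
#' @param scope the same regulatory scope the direct layer was built with.
#' @return pruned \pkg{igraph} GRN; every node is reachable from the root.
#' @export
expand_and_prune <- function(direct, catalog, scope) {
  root <- igraph::graph_attr(direct, "root")
  keep <- catalog$source %in% scope & catalog$target %in% scope &
    catalog$source != root & catalog$target != root
  cat_edges <- catalog[keep, c("source", "target"), drop = FALSE]

  dir_edges <- igraph::as_edgelist(direct)
  nodes <- sort(unique(c(root, dir_edges, cat_edges$source,
                         cat_edges$target)))
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  el <- rbind(
    if (nrow(dir_edges) || is.matrix(dir_edges)) dir_edges else NULL,
    as.matrix(cat_edges)
  )
  prov <- c(rep("direct", nrow(dir_edges)), rep("catalog", nrow(cat_edges)))
  if (!is.null(el) && nrow(el)) {
    dup <- duplicated(paste(el[, 1], el[, 2]))  # direct rows first: dominate
    g <- igraph::add_edges(g, t(el[!dup, , drop = FALSE]),
                           provenance = prov[!dup])
  }
  reach <- igraph::subcomponent(g, root, mode = "out")
  g <- igraph::induced_subgraph(g, reach)
  g <- igraph::set_graph_attr(g, "root", root)
  bnd <- igraph::V(direct)$name[igraph::V(direct)$bound_by_root]
  igraph::V(g)$bound_by_root <- igraph::V(g)$name %in% bnd
  g
}

#' Infer the sign of a regulatory edge from the knockdown response
#'
#' If depleting the regulator lowers the target (negative knockdown logFC),
#' the regulator activates the target (\code{"+"}); if the target rises,
#' the regulator represses it (\code{"-"}). A logFC of exactly zero cannot
#' occur for a differentially expressed gene and signals malformed input.
#'
#' @param logfc the target's log2 fold change in the regulator's knockdown.
#' @return \code{"+"} or \code{"-"} (vectorized).
#' @export
infer_edge_sign <- function(logfc) {
  if (any(logfc == 0)) stop("logFC of 0 for a DEG: malformed input")
  ifelse(logfc < 0, "+", "-")
}

#' Sign GRN edges using regulator knockdown tables
#'
#' Each edge whose source regulator has a knockdown DEG table, and whose
#' target appears in it, receives a sign via [infer_edge_sign()]; other
#' edges remain \code{"unsigned"}.
#'
#' @param grn a GRN graph.
#' @param kd_tables named list of \code{deg_table}s, names = regulator node
#'   ids (the root's own table under the root's name).
#' @return the GRN with edge attribute \code{sign}.
#' @export
sign_edges <- function(grn, kd_tables) {
  el <- igraph::as_edgelist(grn)
  sign <- rep("unsigned", nrow(el))
  for (reg in names(kd_tables)) {
    tab <- kd_tables[[reg]]
    idx <- which(el[, 1] == reg)
    if (!length(idx)) next
    m <- match(el[idx, 2], tab$gene_id)
    has <- !is.na(m)
    if (any(has)) sign[idx[has]] <- infer_edge_sign(tab$logFC[m[has]])
  }
  igraph::E(grn)$sign <- sign
  grn
}

#' Read CRISPR essentiality calls from TSV
#'
#' Expects columns \code{gene_id}, \code{cell_line}, \code{essential}
#' (logical or 0/1).
#'
#' @param path file path.
#' @param leukemia_lines,other_lines cell-line names forming the leukemia
#'   and non-leukemia partitions; both must be non-empty.
#' @return a list with class \code{"essentiality_calls"}.
#' @export
read_essentiality_calls <- function(path,
                                    leukemia_lines = c("MOLM-13", "MV4-11"),
                                    other_lines = c("HT-29", "HT-1080")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "cell_line", "essential")
  if (!all(need %in% names(df)))
    stop("essentiality TSV must have columns: ", paste(need, collapse = ", "))
  essentiality_calls(df, leukemia_lines, other_lines)
}

#' Construct essentiality calls
#'
#' @param calls data.frame with columns \code{gene_id}, \code{cell_line},
#'   \code{essential}.
#' @param leukemia_lines,other_lines the two cell-line partitions.
#' @return a list with class \code{"essentiality_calls"}.
#' @export
essentiality_calls <- function(calls,
                               leukemia_lines = c("MOLM-13", "MV4-11"),
                               other_lines = c("HT-29", "HT-1080")) {
  if (!length(leukemia_lines) || !length(other_lines))
    stop("both cell-line partitions must be non-empty")
  calls$essential <- as.logical(calls$essential)
  calls$gene_id <- as.character(calls$gene_id)
  calls$cell_line <- as.character(calls$cell_line)
  unknown <- setdiff(unique(calls$cell_line),
                     c(leukemia_lines, other_lines))
  if (length(unknown))
    stop("cell line(s) not in either partition: ",
         paste(unknown, collapse = ", "))
  structure(list(calls = calls, leukemia_lines = leukemia_lines,
                 other_lines = other_lines),
            class = "essentiality_calls")
}

#' Classify a gene's essentiality category
#'
#' A gene essential in any non-leukemia line is \code{nonspecific_essential}
#' (that call takes precedence); otherwise a gene essential in any leukemia
#' line is \code{leukemia_specific}; otherwise \code{nonessential}. Genes
#' absent from the screen are \code{nonessential} with a warning.
#'
#' @param calls an \code{essentiality_calls} object.
#' @param gene gene id(s).
#' @return character vector of categories.
#' @export
classify_essentiality <- function(calls, gene) {
  stopifnot(inherits(calls, "essentiality_calls"))
  df <- calls$calls
  ess <- df[df$essential, , drop = FALSE]
  in_other <- unique(ess$gene_id[ess$cell_line %in% calls$other_lines])
  in_leuk <- unique(ess$gene_id[ess$cell_line %in% calls$leukemia_lines])
  absent <- !(gene %in% df$gene_id)
  if (any(absent))
    warning(sum(absent), " gene(s) absent from essentiality calls; ",
            "classified nonessential")
  ifelse(gene %in% in_other, "nonspecific_essential",
         ifelse(gene %in% in_leuk, "leukemia_specific", "nonessential"))
}

#' Annotate GRN nodes with knockdown response and essentiality
#'
#' Every node receives its logFC and FDR from the root's knockdown table
#' (every non-root node is in the regulatory scope, so a missing entry
#' violates the build invariant and raises an error) and its essentiality
#' category.
#'
#' @param grn a built GRN.
#' @param degs the root knockdown \code{deg_table}.
#' @param calls optional \code{essentiality_calls}; if \code{NULL}, all
#'   categories are \code{NA}.
#' @return the GRN with vertex attributes \code{logfc}, \code{fdr},
#'   \code{essentiality}, \code{is_root}.
#' @export
annotate_nodes <- function(grn, degs, calls = NULL) {
  root <- igraph::graph_attr(grn, "root")
  nm <- igraph::V(grn)$name
  m <- match(nm, degs$gene_id)
  missing <- is.na(m) & nm != root
  if (any(missing))
    stop("node(s) missing from DEG table: ",
         paste(nm[missing], collapse = ", "))
  igraph::V(grn)$logfc <- degs$logFC[m]
  igraph::V(grn)$fdr <- degs$FDR[m]
  igraph::V(grn)$is_root <- nm == root
  ess <- rep(NA_character_, length(nm))
  if (!is.null(calls)) {
    # the root (a fusion protein, not a gene) is never screened
    gene_nodes <- nm != root
    ess[gene_nodes] <- classify_essentiality(calls, nm[gene_nodes])
  }
  igraph::V(grn)$essentiality <- ess
  grn
}

#' Build a root-centred GRN end to end
#'
#' Runs the four construction steps: (1) regulatory scope from knockdown
#' DEGs, (2) direct layer from root binding (optionally restricted to
#' enhancer-overlapping peaks), (3) catalog expansion with reachability
#' pruning, (4) node annotation and edge signing.
#'
#' @param root central node id.
#' @param degs root knockdown \code{deg_table}.
#' @param peaks root ChIP peak set.
#' @param promoters \code{promoter_map}.
#' @param catalog \code{tf_catalog}.
#' @param enhancers optional enhancer peak set (from [define_enhancers()]);
#'   when given, only root peaks overlapping an enhancer are used for the
#'   direct layer (the build mode used for an intermediate TF such as
#'   RUNX1; the fusion-root build uses all peaks).
#' @param calls optional \code{essentiality_calls}.
#' @param kd_tables optional named list of knockdown tables for edge
#'   signing; defaults to the root's own table.
#' @param fdr_threshold scope threshold (default 0.05).
#' @return an annotated, signed \pkg{igraph} GRN.
#' @export
build_grn <- function(root, degs, peaks, promoters, catalog,
                      enhancers = NULL, calls = NULL, kd_tables = NULL,
                      fdr_threshold = 0.05) {
  if (!is.null(enhancers)) peaks <- intersect_peaks(peaks, enhancers)
  ann <- annotate_nearest_promoter(peaks, promoters)
  scope <- regulatory_scope(degs, fdr_threshold)
  direct <- build_direct_layer(root, bound_genes(ann), scope)
  grn <- expand_and_prune(direct, catalog, scope)
  grn <- annotate_nodes(grn, degs, calls)
  if (is.null(kd_tables)) kd_tables <- stats::setNames(list(degs), root)
  sign_edges(grn, kd_tables)
}

#' Root of a GRN
#' @param grn a GRN graph.
#' @return the root node id.
#' @export
grn_root <- function(grn) igraph::graph_attr(grn, "root")

#' Node ids of a GRN
#' @param grn a GRN graph.
#' @return character vector of node names.
#' @export
grn_nodes <- function(grn) igraph::V(grn)$name

#' Edge list of a GRN with provenance and sign
#' @param grn a GRN graph.
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{provenance}, \code{sign}.
#' @export
grn_edges <- function(grn) {
  el <- igraph::as_edgelist(grn)
  data.frame(
    source = el[, 1], target = el[, 2],
    provenance = if (is.null(igraph::E(grn)$provenance)) NA_character_
                 else igraph::E(grn)$provenance,
    sign = if (is.null(igraph::E(grn)$sign)) "unsigned"
           else igraph::E(grn)$sign,
    stringsAsFactors = FALSE
  )
}

#' Export a GRN
#'
#' Writes the edge list as TSV and, optionally, the full graph as GraphML.
#'
#' @param grn a GRN graph.
#' @param edges_path TSV path for the edge list.
#' @param graphml_path optional GraphML path.
#' @param nodes_path optional TSV path for the annotated node table.
#' @return \code{edges_path}, invisibly.
#' @export
write_grn <- function(grn, edges_path, graphml_path = NULL,
                      nodes_path = NULL) {
  utils::write.table(grn_edges(grn), edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(grn, graphml_path, format = "graphml")
  if (!is.null(nodes_path)) {
    nt <- data.frame(gene_id = igraph::V(grn)$name,
                     logfc = igraph::V(grn)$logfc,
                     fdr = igraph::V(grn)$fdr,
                     bound_by_root = igraph::V(grn)$bound_by_root,
                     essentiality = igraph::V(grn)$essentiality,
                     stringsAsFactors = FALSE)
    utils::write.table(nt, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(edges_path)
}
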