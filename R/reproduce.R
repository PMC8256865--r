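#' Recompute headline network metrics from exported GRN and KD tables
#'
#' Given the edge lists of two root-centred GRNs (TSV with columns
#' \code{source}, \code{target}, as written by [write_grn()] or as
#' distributed with a study) and the two knockdown DEG tables, this
#' recomputes the summary numbers of a fusion-root / intermediate-TF
#' analysis: total node count of the A-rooted GRN, the number of nodes
#' above a degree-centrality cutoff, and the FFL / cascade coherence
#' percentages of the integrated network.
#'
#' @param edges_a_path,edges_b_path TSV edge lists of the A- and B-rooted
#'   GRNs.
#' @param kd_a_path,kd_b_path knockdown DEG TSVs (gene_id, logFC, FDR).
#' @param root_a,root_b the two root node ids as they appear in the edge
#'   lists.
#' @param degree_cutoff degree-centrality threshold for the high-degree
#'   node count (default 500).
#' @return a list: \code{node_count}, \code{high_degree_count},
#'   \code{ffl_coherent_pct}, \code{cascade_coherent_pct},
#'   \code{cascade_incoherent_pct}.
#' @export
reproduce_headline_metrics <- function(edges_a_path, edges_b_path,
                                       kd_a_path, kd_b_path,
                                       root_a, root_b,
                                       degree_cutoff = 500) {
  read_edges <- function(path, root) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("source", "target") %in% names(df)))
      stop("edge TSV must have columns: source, target")
    nodes <- sort(unique(c(root, df$source, df$target)))
    g <- igraph::make_empty_graph(directed = TRUE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    g <- igraph::add_edges(g, t(as.matrix(df[c("source", "target")])))
    igraph::set_graph_attr(g, "root", root)
  }
  grn_a <- read_edges(edges_a_path, root_a)
  grn_b <- read_edges(edges_b_path, root_b)
  kd_a <- read_deg_table(kd_a_path)
  kd_b <- read_deg_table(kd_b_path)
  deg <- degree_centrality(grn_a)
  ig <- integrate_grns(grn_a, grn_b)
  records <- classify_motifs(enumerate_motifs(ig), kd_a, kd_b)
  s <- summarize_coherence(records)
  list(node_count = igraph::vcount(grn_a),
       high_degree_count = sum(deg > degree_cutoff),
       ffl_coherent_pct = s$ffl_coherent_pct,
       cascade_coherent_pct = s$cascade_coherent_pct,
       cascade_incoherent_pct = s$cascade_incoherent_pct)
}
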