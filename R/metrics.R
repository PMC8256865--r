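#' Degree centrality (total degree)
#'
#' The number of connections to and from a node: in-degree plus out-degree
#' on the simple directed graph.
#'
#' @param grn a GRN graph.
#' @return named integer vector, node -> degree.
#' @export
degree_centrality <- function(grn) {
  igraph::degree(grn, mode = "all", loops = FALSE)
}

#' Stress centrality (shortest-path counts through a node)
#'
#' For each node v, the number of shortest directed paths between ordered
#' pairs (s, t), with s, t and v all distinct, whose interior passes
#' through v. All co-optimal shortest paths count with weight 1 each
#' (integer path multiplicities, not the fractional weights of
#' betweenness). Paths are unweighted and directed.
#'
#' Computed with a breadth-first search from every source followed by a
#' dependency accumulation in reverse BFS order: with sigma(s, v) shortest
#' s-to-v path counts, the contribution of source s to node v is
#' sigma(s, v) * sum over shortest-path successors w of
#' (1 + delta_s(w) / sigma(s, w)), which totals the s-rooted shortest
#' paths running through v.
#'
#' @param grn a GRN graph (or any igraph directed graph).
#' @return named numeric vector, node -> stress count.
#' @export
stress_centrality <- function(grn) {
  n <- igraph::vcount(grn)
  out <- stats::setNames(numeric(n), igraph::V(grn)$name)
  if (n < 3L) return(out)
  adj <- igraph::as_adj_list(grn, mode = "out")
  adj <- lapply(adj, as.integer)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    order_v <- integer(0)
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- s
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      order_v <- c(order_v, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # delta[v] = sum over reachable targets t of (per-path count of
    # s->t shortest paths continuing from v); scaling by sigma[v] gives
    # the number of s-rooted shortest paths whose interior passes v
    delta <- numeric(n)
    for (w in rev(order_v)) {
      contrib <- 1 + delta[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + contrib
    }
    int <- setdiff(order_v, s)
    out[int] <- out[int] + sigma[int] * delta[int]
  }
  out
}

#' Centrality report for a GRN
#'
#' @param grn a GRN graph.
#' @return data.frame with columns \code{gene_id}, \code{degree},
#'   \code{stress}, sorted by decreasing stress then degree.
#' @export
centrality_report <- function(grn) {
  deg <- degree_centrality(grn)
  str <- stress_centrality(grn)
  out <- data.frame(gene_id = names(deg), degree = as.integer(deg),
                    stress = str[names(deg)], stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$stress, -out$degree, out$gene_id), , drop = FALSE]
}

#' Delete a node in silico
#'
#' Removes the node and all incident edges. The remaining graph is NOT
#' re-pruned for reachability: nodes disconnected by the deletion are
#' retained so that their loss of stress centrality is measurable. Deleting
#' the root is allowed.
#'
#' @param grn a GRN graph.
#' @param node node id to delete; must exist.
#' @return the graph without \code{node}.
#' @export
in_silico_delete <- function(grn, node) {
  if (!(node %in% igraph::V(grn)$name))
    stop("node not present in GRN: ", node)
  igraph::delete_vertices(grn, node)
}

#' Stress response to an in-silico deletion
#'
#' Stress centrality is computed before and after deleting one node, and a
#' per-gene stress fold change is reported for every remaining node g:
#' \deqn{FC(g) = \log_2((stress_{after}(g) + c) / (stress_{before}(g) + c))}
#' with pseudocount c (default 1) guarding zero-stress nodes. The summary
#' statistic is the mean of |FC| over all remaining nodes. Signed per-gene
#' FCs are additionally classified as positive (FC > 0.1), negative
#' (FC < -0.1) or neutral.
#'
#' @param grn a GRN graph.
#' @param node node id to delete.
#' @param pseudocount additive constant in the ratio (default 1).
#' @param log_base base of the logarithm (default 2).
#' @param fc_threshold classification threshold on |FC| (default 0.1).
#' @return a list with class \code{"deletion_impact"}: \code{deleted},
#'   \code{per_gene_fc} (named vector over remaining nodes),
#'   \code{fc_class}, and \code{mean_abs_fc}.
#' @export
deletion_impact <- function(grn, node, pseudocount = 1, log_base = 2,
                            fc_threshold = 0.1) {
  before <- stress_centrality(grn)
  after_g <- in_silico_delete(grn, node)
  after <- stress_centrality(after_g)
  keep <- setdiff(names(before), node)
  fc <- log((after[keep] + pseudocount) / (before[keep] + pseudocount),
            base = log_base)
  cls <- ifelse(fc > fc_threshold, "positive",
                ifelse(fc < -fc_threshold, "negative", "neutral"))
  structure(list(deleted = node, per_gene_fc = fc, fc_class = cls,
                 mean_abs_fc = if (length(fc)) mean(abs(fc)) else 0),
            class = "deletion_impact")
}

#' Rank all nodes by deletion impact
#'
#' Deletes each node in turn and ranks by the mean absolute stress fold
#' change of the remaining network.
#'
#' @param grn a GRN graph.
#' @param nodes nodes to perturb (default: all).
#' @inheritParams deletion_impact
#' @return data.frame with columns \code{gene_id}, \code{mean_abs_fc},
#'   sorted decreasing.
#' @export
deletion_impact_ranking <- function(grn, nodes = igraph::V(grn)$name,
                                    pseudocount = 1, log_base = 2) {
  fc <- vapply(nodes, function(v)
    deletion_impact(grn, v, pseudocount, log_base)$mean_abs_fc, numeric(1))
  out <- data.frame(gene_id = nodes, mean_abs_fc = fc,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$mean_abs_fc, out$gene_id), , drop = FALSE]
}
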