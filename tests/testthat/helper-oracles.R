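# Independent brute-force oracles used to check the implementation.
# These deliberately avoid the package's own algorithms (and igraph):
# stress is obtained by exhaustively enumerating shortest paths over the
# BFS-distance DAG, overlaps by pairwise interval arithmetic, nearest
# promoters by a full distance scan.

# exhaustive stress: count, for every ordered pair (s, t), the shortest
# s->t paths through each interior node, by recursive path enumeration
oracle_stress <- function(edges, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    edges$target[edges$source == v])
  stress <- stats::setNames(numeric(length(nodes)), nodes)
  for (s in nodes) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]
      q <- q[-1]
      for (w in adj[[v]]) if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        q <- c(q, w)
      }
    }
    for (t in nodes) {
      if (t == s || is.infinite(dist[t])) next
      enum <- function(v) {
        if (v == t) return(list(v))
        out <- list()
        for (w in adj[[v]])
          if (dist[w] == dist[v] + 1 && dist[w] <= dist[t])
            for (p in enum(w)) out[[length(out) + 1L]] <- c(v, p)
        out
      }
      for (p in enum(s)) {
        interior <- p[-c(1L, length(p))]
        stress[interior] <- stress[interior] + 1
      }
    }
  }
  stress
}

oracle_degree <- function(edges, nodes) {
  vapply(nodes, function(v)
    sum(edges$source == v) + sum(edges$target == v), numeric(1))
}

# random simple directed graph as an edge data frame
random_digraph <- function(n, p = 0.25) {
  nodes <- paste0("n", seq_len(n))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  edges <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

graph_from_edges <- function(edges, nodes) {
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(as.matrix(edges[c("source", "target")])))
  g
}

# brute-force half-open interval overlap: which rows of a overlap any of b
oracle_overlap <- function(a, b) {
  hits <- logical(nrow(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        max(a$start[i], b$start[j]) < min(a$end[i], b$end[j])) {
      hits[i] <- TRUE
      break
    }
  }
  hits
}

# brute-force nearest promoter: full scan with lexicographic tie-break
oracle_nearest <- function(centers, chroms, promoters) {
  vapply(seq_along(centers), function(i) {
    pr <- promoters[promoters$chrom == chroms[i], , drop = FALSE]
    if (nrow(pr) == 0L) return(NA_character_)
    d <- abs(pr$tss - centers[i])
    min(pr$gene_id[d == min(d)])
  }, character(1))
}

# a minimal GRN graph for builder tests, bypassing peak annotation
toy_grn <- function(edges, root, nodes = NULL) {
  nodes <- sort(unique(c(root, nodes, edges$source, edges$target)))
  g <- graph_from_edges(edges, nodes)
  igraph::set_graph_attr(g, "root", root)
}
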