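#' Integrate two root-centred GRNs into one motif frame
#'
#' The frame has a designated root regulator A (e.g. the fusion protein)
#' and an intermediate TF B (the root of the second GRN), with B a direct
#' target of A. The result is the edge-union graph; each edge is tagged
#' with the GRN(s) supporting it.
#'
#' @param grn_a GRN rooted at A.
#' @param grn_b GRN rooted at B; B must be a node of \code{grn_a} with an
#'   A-to-B edge, otherwise the motif frame is undefined and an error is
#'   raised.
#' @return an \pkg{igraph} graph with graph attributes \code{root_a},
#'   \code{root_b} and edge attribute \code{support} in
#'   \code{\{"A", "B", "A+B"\}}.
#' @export
integrate_grns <- function(grn_a, grn_b) {
  a <- grn_root(grn_a)
  b <- grn_root(grn_b)
  if (!(b %in% grn_nodes(grn_a)))
    stop("root of grn_b ('", b, "') is not a node of grn_a")
  el_a <- igraph::as_edgelist(grn_a)
  el_b <- igraph::as_edgelist(grn_b)
  if (!any(el_a[, 1] == a & el_a[, 2] == b))
    stop("grn_a has no edge from its root to '", b, "'")
  key_a <- paste(el_a[, 1], el_a[, 2])
  key_b <- paste(el_b[, 1], el_b[, 2])
  el <- rbind(el_a, el_b[!(key_b %in% key_a), , drop = FALSE])
  support <- c(ifelse(key_a %in% key_b, "A+B", "A"),
               rep("B", sum(!(key_b %in% key_a))))
  nodes <- sort(unique(c(grn_nodes(grn_a), grn_nodes(grn_b))))
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  g <- igraph::add_edges(g, t(el), support = support)
  g <- igraph::set_graph_attr(g, "root_a", a)
  igraph::set_graph_attr(g, "root_b", b)
}

#' Enumerate feed-forward loop and cascade motifs
#'
#' With A the root regulator and B the intermediate TF (A regulates B),
#' every other target T falls into exactly one of three buckets:
#' \itemize{
#'   \item both A-to-T and B-to-T edges present: a feed-forward loop (FFL);
#'   \item B-to-T only: a cascade (A reaches T only through B);
#'   \item A-to-T only: excluded (no three-node motif involving B).
#' }
#'
#' @param g integrated graph from [integrate_grns()].
#' @return data.frame of unclassified motif records, sorted by target:
#'   columns \code{target}, \code{kind} (\code{"FFL"} or \code{"cascade"}).
#' @export
enumerate_motifs <- function(g) {
  a <- igraph::graph_attr(g, "root_a")
  b <- igraph::graph_attr(g, "root_b")
  el <- igraph::as_edgelist(g)
  a_targets <- el[el[, 1] == a, 2]
  b_targets <- el[el[, 1] == b, 2]
  cand <- setdiff(sort(unique(c(a_targets, b_targets))), c(a, b))
  kind <- ifelse(cand %in% a_targets & cand %in% b_targets, "FFL",
                 ifelse(cand %in% b_targets, "cascade", NA_character_))
  keep <- !is.na(kind)
  data.frame(target = cand[keep], kind = kind[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a feed-forward loop by knockdown response signs
#'
#' The A-to-B edge is fixed as activating (the frame requires A to bind and
#' activate B), which reduces the eight signed FFL types to four. Signs are
#' read from the target's logFC in each regulator's knockdown: a negative
#' logFC means the regulator activates the target. With quadrant notation
#' (sign in A-KD, sign in B-KD):
#' \itemize{
#'   \item (-, -): both activate, coherent type 1 (C1);
#'   \item (+, +): both repress, coherent type 3 (C3);
#'   \item (-, +): A activates, B represses, incoherent type 1 (I1);
#'   \item (+, -): A represses, B activates, incoherent type 3 (I3).
#' }
#'
#' @param logfc_a_kd target logFC after knockdown of A (nonzero).
#' @param logfc_b_kd target logFC after knockdown of B (nonzero).
#' @return \code{"C1"}, \code{"C3"}, \code{"I1"} or \code{"I3"}
#'   (vectorized).
#' @export
classify_ffl <- function(logfc_a_kd, logfc_b_kd) {
  if (any(logfc_a_kd == 0) || any(logfc_b_kd == 0))
    stop("logFC of 0 for a DEG: malformed input")
  ifelse(logfc_a_kd < 0,
         ifelse(logfc_b_kd < 0, "C1", "I1"),
         ifelse(logfc_b_kd < 0, "I3", "C3"))
}

#' Classify a cascade by agreement of knockdown responses
#'
#' A cascade target responds to the A knockdown only through B. When the
#' two knockdown responses have the same sign the cascade is coherent;
#' opposing signs make it incoherent.
#'
#' @inheritParams classify_ffl
#' @return \code{"coherent"} or \code{"incoherent"} (vectorized).
#' @export
classify_cascade <- function(logfc_a_kd, logfc_b_kd) {
  if (any(logfc_a_kd == 0) || any(logfc_b_kd == 0))
    stop("logFC of 0 for a DEG: malformed input")
  ifelse(sign(logfc_a_kd) == sign(logfc_b_kd), "coherent", "incoherent")
}

#' Classify enumerated motifs using the two knockdown tables
#'
#' Each motif target is looked up in both knockdown DEG tables; targets
#' that are a DEG in only one knockdown cannot be sign-classified and are
#' kept with subtype \code{NA} in a diagnostics bucket (column
#' \code{classified} = FALSE).
#'
#' @param motifs data.frame from [enumerate_motifs()].
#' @param kd_a,kd_b \code{deg_table}s for the A and B knockdowns.
#' @return data.frame of motif records: \code{target}, \code{kind},
#'   \code{subtype}, \code{logfc_a_kd}, \code{logfc_b_kd},
#'   \code{classified}.
#' @export
classify_motifs <- function(motifs, kd_a, kd_b) {
  ma <- match(motifs$target, kd_a$gene_id)
  mb <- match(motifs$target, kd_b$gene_id)
  lfa <- kd_a$logFC[ma]
  lfb <- kd_b$logFC[mb]
  ok <- !is.na(lfa) & !is.na(lfb)
  subtype <- rep(NA_character_, nrow(motifs))
  ffl <- ok & motifs$kind == "FFL"
  casc <- ok & motifs$kind == "cascade"
  if (any(ffl)) subtype[ffl] <- classify_ffl(lfa[ffl], lfb[ffl])
  if (any(casc)) subtype[casc] <- classify_cascade(lfa[casc], lfb[casc])
  data.frame(target = motifs$target, kind = motifs$kind, subtype = subtype,
             logfc_a_kd = lfa, logfc_b_kd = lfb, classified = ok,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize motif coherence
#'
#' Coherent FFLs are C1 and C3 (the same-sign half-plane, matching the
#' coherent-cascade rule). Percentages are reported to one decimal; when a
#' motif kind has no classified records its percentage is undefined
#' (\code{NA}), not zero.
#'
#' @param records classified motif records from [classify_motifs()].
#' @return a list: \code{ffl_coherent_pct}, \code{cascade_coherent_pct},
#'   \code{cascade_incoherent_pct}, \code{counts} (named subtype counts),
#'   \code{n_ffl}, \code{n_cascade}, \code{n_unclassified}.
#' @export
summarize_coherence <- function(records) {
  cls <- records[records$classified %in% TRUE, , drop = FALSE]
  ffl <- cls$subtype[cls$kind == "FFL"]
  casc <- cls$subtype[cls$kind == "cascade"]
  counts <- c(
    C1 = sum(ffl == "C1"), C3 = sum(ffl == "C3"),
    I1 = sum(ffl == "I1"), I3 = sum(ffl == "I3"),
    coherent = sum(casc == "coherent"),
    incoherent = sum(casc == "incoherent")
  )
  pct <- function(x, n) if (n == 0) NA_real_ else round(100 * x / n, 1)
  list(
    ffl_coherent_pct = pct(sum(ffl %in% c("C1", "C3")), length(ffl)),
    cascade_coherent_pct = pct(sum(casc == "coherent"), length(casc)),
    cascade_incoherent_pct = pct(sum(casc == "incoherent"), length(casc)),
    counts = counts,
    n_ffl = length(ffl),
    n_cascade = length(casc),
    n_unclassified = sum(!records$classified)
  )
}

#' Write a motif report to TSV
#' @param records classified motif records.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_motif_report <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
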