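#' Construct a cohort expression matrix
#'
#' TPM values for genes (rows) by samples (columns), with each sample
#' assigned to one dataset (e.g. an ALL cohort, an AML cohort, and normal
#' fetal bone marrow).
#'
#' @param tpm numeric matrix, genes x samples, TPM (non-negative), with
#'   row and column names.
#' @param datasets character vector (or factor) of dataset labels, one per
#'   sample.
#' @return a list with class \code{"expression_cohort"}.
#' @export
expression_cohort <- function(tpm, datasets) {
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop("tpm must have gene row names and sample column names")
  if (anyDuplicated(rownames(tpm))) stop("gene ids must be unique")
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  datasets <- as.character(datasets)
  if (length(datasets) != ncol(tpm))
    stop("one dataset label per sample required")
  structure(list(tpm = tpm,
                 datasets = stats::setNames(datasets, colnames(tpm))),
            class = "expression_cohort")
}

#' Read a cohort from expression + metadata TSVs
#'
#' The expression TSV has gene rows and sample columns (first column
#' \code{gene_id}); the metadata TSV has columns \code{sample},
#' \code{dataset}.
#'
#' @param expr_path,meta_path file paths.
#' @return an \code{expression_cohort}.
#' @export
read_expression_cohort <- function(expr_path, meta_path) {
  df <- utils::read.delim(expr_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1] != "gene_id")
    stop("first column of expression TSV must be gene_id")
  tpm <- as.matrix(df[, -1, drop = FALSE])
  rownames(tpm) <- df$gene_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "dataset") %in% names(meta)))
    stop("metadata TSV must have columns: sample, dataset")
  m <- match(colnames(tpm), meta$sample)
  if (any(is.na(m))) stop("metadata missing for some samples")
  expression_cohort(tpm, meta$dataset[m])
}

#' Per-sample expressed gene sets
#'
#' A gene is expressed in a sample when its log2(TPM + 1) exceeds
#' (strictly) the mean log2(TPM + 1) of the sample's dataset, the mean
#' being taken over all gene-by-sample entries of that dataset. Thresholds
#' are computed independently per dataset, so cohorts on different scales
#' are comparable.
#'
#' @param cohort an \code{expression_cohort}.
#' @return named list, sample -> character vector of expressed genes; the
#'   per-dataset thresholds are attached as attribute
#'   \code{"thresholds"}.
#' @export
expressed_gene_sets <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  lg <- log2(cohort$tpm + 1)
  out <- vector("list", ncol(lg))
  names(out) <- colnames(lg)
  thr <- vapply(split(colnames(lg), cohort$datasets), function(smp) {
    mean(lg[, smp, drop = FALSE])
  }, numeric(1))
  for (s in colnames(lg)) {
    t <- thr[[cohort$datasets[[s]]]]
    out[[s]] <- rownames(lg)[lg[, s] > t]
  }
  attr(out, "thresholds") <- thr
  out
}

#' Derive per-sample subnetworks of a root-centred GRN
#'
#' For each sample the GRN construction workflow is re-run with the
#' regulatory scope restricted to the genes expressed in that sample
#' (scope intersected with the expressed set); catalog expansion and
#' reachability pruning are reapplied, so dropping one bridge TF removes
#' everything reachable only through it. The root is always present.
#'
#' @param root central node id.
#' @param degs root knockdown \code{deg_table}.
#' @param bound character vector of root-bound genes.
#' @param catalog \code{tf_catalog}.
#' @param expressed named list, sample -> expressed gene set (from
#'   [expressed_gene_sets()]).
#' @param fdr_threshold scope threshold (default 0.05).
#' @return named list, sample -> GRN graph.
#' @export
derive_subnetworks <- function(root, degs, bound, catalog, expressed,
                               fdr_threshold = 0.05) {
  scope_full <- regulatory_scope(degs, fdr_threshold)
  lapply(expressed, function(genes) {
    scope <- intersect(scope_full, genes)
    direct <- build_direct_layer(root, bound, scope)
    expand_and_prune(direct, catalog, scope)
  })
}

#' Binary node-activity matrix and per-dataset conservation
#'
#' Activity is 1 when a node of the full GRN appears in a sample's
#' subnetwork. Conservation of a node in a dataset is the percentage of
#' that dataset's samples whose subnetwork contains it.
#'
#' @param subnets named list, sample -> subnetwork GRN.
#' @param full the full GRN (defines the node universe).
#' @param datasets named character vector, sample -> dataset label.
#' @return a list: \code{activity} (binary nodes x samples matrix) and
#'   \code{conservation} (nodes x datasets matrix of percentages).
#' @export
activity_and_conservation <- function(subnets, full, datasets) {
  nodes <- grn_nodes(full)
  samples <- names(subnets)
  act <- matrix(0L, length(nodes), length(samples),
                dimnames = list(nodes, samples))
  for (s in samples) {
    sub_nodes <- grn_nodes(subnets[[s]])
    bad <- setdiff(sub_nodes, nodes)
    if (length(bad))
      stop("subnetwork node(s) outside the full GRN: ",
           paste(bad, collapse = ", "))
    act[sub_nodes, s] <- 1L
  }
  ds <- unique(datasets[samples])
  cons <- vapply(ds, function(d) {
    smp <- samples[datasets[samples] == d]
    100 * rowMeans(act[, smp, drop = FALSE])
  }, numeric(length(nodes)))
  cons <- matrix(cons, nrow = length(nodes),
                 dimnames = list(nodes, ds))
  list(activity = act, conservation = cons)
}

#' Cluster node-activity patterns with k-means
#'
#' Runs k-means (Euclidean, multiple restarts) directly on the binary
#' activity rows, deterministic for a fixed seed. Nodes active in no
#' sample are clustered with the rest and naturally form an "inactive"
#' cluster. A 2-D UMAP embedding can be added for visualization with
#' [activity_umap()]; it is never used for clustering.
#'
#' @param activity binary nodes x samples matrix.
#' @param k number of clusters (default 5).
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 25).
#' @return a list with class \code{"cluster_assignment"}: \code{cluster}
#'   (named integer vector), \code{k}, \code{seed}, \code{kmeans} (the
#'   fitted object).
#' @export
cluster_activity <- function(activity, k = 5, seed = 1, nstart = 25) {
  distinct <- nrow(unique(activity))
  if (k > distinct)
    stop("k = ", k, " exceeds the ", distinct,
         " distinct activity patterns available")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  set.seed(seed)
  km <- stats::kmeans(activity, centers = k, nstart = nstart,
                      iter.max = 100)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  structure(list(cluster = km$cluster, k = k, seed = seed, kmeans = km),
            class = "cluster_assignment")
}

#' UMAP embedding of activity patterns (visualization only)
#'
#' @param activity binary nodes x samples matrix.
#' @param seed RNG seed.
#' @param n_neighbors UMAP neighborhood size.
#' @return nodes x 2 embedding matrix.
#' @export
activity_umap <- function(activity, seed = 1, n_neighbors = 15) {
  if (!requireNamespace("uwot", quietly = TRUE))
    stop("the 'uwot' package is required for UMAP embedding")
  set.seed(seed)
  emb <- uwot::umap(activity,
                    n_neighbors = min(n_neighbors, nrow(activity) - 1))
  rownames(emb) <- rownames(activity)
  emb
}
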