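#' Parameters for the synthetic study generator
#'
#' The generator emulates every input of the pipeline with planted,
#' recoverable ground truth: a promoter map on synthetic chromosomes, ChIP
#' peak sets for the fusion root (A) and the intermediate TF (B) plus
#' histone marks defining enhancers, a TF-interaction catalog carrying the
#' planted feed-forward loops and cascades alongside decoy edges, two
#' knockdown DEG tables consistent with the planted signs, a three-dataset
#' patient expression cohort with planted activity clusters, and
#' per-cell-line essentiality calls.
#'
#' The default preset plants 50 FFLs (30 C1, 6 C3, 10 I1, 4 I3; the
#' C1-dominant, ~72\% coherent composition observed in fusion-driven
#' leukemia GRNs) and 100 cascades (73 coherent, 27 incoherent) among a
#' universe of 1000 genes, with knockdown effect size 1.5 log2 units,
#' sign-flip noise 0.05 and expression dropout 0.05.
#'
#' @param preset \code{"default"}, \code{"small"} or \code{"large"}.
#' @param ... named overrides of individual parameters (e.g.
#'   \code{n_ffl}, \code{n_cascade}, \code{sign_flip_rate},
#'   \code{n_samples}).
#' @return a named list of generator parameters.
#' @export
synth_params <- function(preset = c("default", "small", "large"), ...) {
  preset <- match.arg(preset)
  p <- list(
    n_genes = 1000L,
    n_chrom = 4L,
    tss_spacing = 10000L,
    peak_halfwidth = 100L,
    root_a = "ROOT_A",
    root_b = "g0001",
    n_ffl = c(C1 = 30L, C3 = 6L, I1 = 10L, I3 = 4L),
    n_cascade = c(coherent = 73L, incoherent = 27L),
    n_direct_only = 40L,
    n_orphan = 50L,
    decoy_peak_rate = 0.1,
    n_decoy_catalog = 30L,
    effect_size = 1.5,
    sign_flip_rate = 0.05,
    dropout = 0.05,
    n_samples = c(ALL = 12L, AML = 12L, FBM = 3L),
    k_clusters = 5L,
    essentiality_props = c(nonessential = 0.7,
                           nonspecific_essential = 0.2,
                           leukemia_specific = 0.1),
    leukemia_lines = c("MOLM-13", "MV4-11"),
    other_lines = c("HT-29", "HT-1080"),
    active_meanlog = log(100), active_sdlog = 0.5,
    inactive_meanlog = log(0.5), inactive_sdlog = 0.5
  )
  if (preset == "small") {
    p$n_genes <- 300L
    p$n_ffl <- c(C1 = 6L, C3 = 2L, I1 = 2L, I3 = 2L)
    p$n_cascade <- c(coherent = 8L, incoherent = 4L)
    p$n_direct_only <- 10L
    p$n_orphan <- 10L
    p$n_decoy_catalog <- 10L
    p$n_samples <- c(ALL = 6L, AML = 6L, FBM = 3L)
  } else if (preset == "large") {
    p$n_genes <- 4000L
    p$n_ffl <- c(C1 = 120L, C3 = 24L, I1 = 40L, I3 = 16L)
    p$n_cascade <- c(coherent = 292L, incoherent = 108L)
    p$n_direct_only <- 160L
    p$n_orphan <- 200L
    p$n_decoy_catalog <- 120L
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  n_planted <- 1L + sum(p$n_ffl) + sum(p$n_cascade) + p$n_direct_only +
    p$n_orphan
  if (p$n_genes < n_planted + p$n_decoy_catalog)
    stop("n_genes too small for the planted network (need >= ",
         n_planted + p$n_decoy_catalog, ")")
  p
}

#' Generate the synthetic regulome
#'
#' Places one promoter per gene on synthetic chromosomes, plants ChIP peaks
#' for the fusion root near the promoters of its direct targets (the
#' intermediate TF B, the FFL targets and a set of A-only targets) plus
#' decoy peaks near non-network promoters, plants TF-B peaks at FFL and
#' cascade targets with supporting H3K27ac/H3K4me1 enhancer marks, and
#' builds a TF catalog containing the planted B-to-target edges plus decoy
#' edges that fail the scope filter (between non-network genes) or the
#' reachability pruning (among orphan DEGs unconnected to the root).
#'
#' @param params from [synth_params()].
#' @param seed RNG seed.
#' @return a list: \code{promoters}, \code{peaks} (list with elements
#'   \code{root_a}, \code{root_b}, \code{h3k27ac}, \code{h3k4me1}),
#'   \code{catalog}, \code{truth}.
#' @export
generate_regulome <- function(params = synth_params(), seed = 1) {
  p <- params
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(p$n_genes))
  if (!(p$root_b %in% genes)) stop("root_b must be one of the gene ids")
  if (p$root_a %in% genes) stop("root_a must not collide with a gene id")

  # role assignment: B first, then planted targets from a shuffled pool
  pool <- sample(setdiff(genes, p$root_b))
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  ffl_subtype <- rep(names(p$n_ffl), p$n_ffl)
  ffl_targets <- take(length(ffl_subtype))
  casc_subtype <- rep(names(p$n_cascade), p$n_cascade)
  casc_targets <- take(length(casc_subtype))
  direct_only <- take(p$n_direct_only)
  orphans <- take(p$n_orphan)
  nonnet <- pool

  # cascade targets get a planted B-KD sign; coherence fixes the A-KD sign
  casc_sign_b <- sample(c(-1, 1), length(casc_targets), replace = TRUE)
  direct_sign <- sample(c(-1, 1), length(direct_only), replace = TRUE)
  orphan_sign <- sample(c(-1, 1), length(orphans), replace = TRUE)

  chrom <- paste0("chrS", ((seq_len(p$n_genes) - 1L) %% p$n_chrom) + 1L)
  tss <- ((seq_len(p$n_genes) - 1L) %/% p$n_chrom) * p$tss_spacing + 2000L
  promoters <- promoter_map(genes, chrom, tss,
                            sample(c("+", "-"), p$n_genes, replace = TRUE))
  loc <- function(g) {
    i <- match(g, genes)
    list(chrom = chrom[i], tss = tss[i])
  }
  peak_at <- function(g, halfwidth = p$peak_halfwidth, jitter = 30L) {
    l <- loc(g)
    centre <- l$tss + sample(seq(-jitter, jitter), length(g),
                             replace = TRUE)
    data.frame(chrom = l$chrom, start = pmax(0L, centre - halfwidth),
               end = centre + halfwidth, stringsAsFactors = FALSE)
  }

  a_bound <- c(p$root_b, ffl_targets, direct_only)
  n_decoy_a <- ceiling(p$decoy_peak_rate * length(a_bound))
  decoy_a <- sample(nonnet, n_decoy_a)
  a_df <- peak_at(c(a_bound, decoy_a))
  peaks_a <- peak_set(a_df$chrom, a_df$start, a_df$end,
                      label = paste0(p$root_a, "_ChIP"))

  b_bound <- c(ffl_targets, casc_targets)
  n_decoy_b <- ceiling(p$decoy_peak_rate * length(b_bound))
  decoy_b <- sample(setdiff(nonnet, decoy_a), n_decoy_b)
  b_df <- peak_at(c(b_bound, decoy_b))
  peaks_b <- peak_set(b_df$chrom, b_df$start, b_df$end,
                      label = paste0(p$root_b, "_ChIP"))

  # enhancer marks over every planted B peak and over half the B decoys;
  # plus unsupported acetylation elsewhere so the enhancer filter has work
  enh_genes <- c(b_bound, decoy_b[seq_len(n_decoy_b %/% 2)])
  k27_df <- peak_at(enh_genes, halfwidth = 150L)
  k4_df <- peak_at(enh_genes, halfwidth = 180L)
  lone_k27 <- sample(setdiff(nonnet, c(decoy_a, decoy_b)), 20)
  k27_df <- rbind(k27_df, peak_at(lone_k27, halfwidth = 150L))
  h3k27ac <- peak_set(k27_df$chrom, k27_df$start, k27_df$end,
                      label = "H3K27ac")
  h3k4me1 <- peak_set(k4_df$chrom, k4_df$start, k4_df$end,
                      label = "H3K4me1")

  # catalog: planted B->target edges plus two kinds of decoys
  planted_cat <- data.frame(source = p$root_b,
                            target = c(ffl_targets, casc_targets),
                            stringsAsFactors = FALSE)
  n_half <- p$n_decoy_catalog %/% 2
  decoy_nn <- data.frame(
    source = sample(nonnet, p$n_decoy_catalog - n_half),
    target = sample(nonnet, p$n_decoy_catalog - n_half),
    stringsAsFactors = FALSE
  )
  decoy_orph <- data.frame(
    source = sample(orphans, n_half, replace = TRUE),
    target = sample(c(orphans, casc_targets), n_half, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cat_df <- rbind(planted_cat, decoy_nn, decoy_orph)
  cat_df <- cat_df[cat_df$source != cat_df$target, , drop = FALSE]
  catalog <- tf_catalog(cat_df$source, cat_df$target)

  edges_a <- rbind(
    data.frame(source = p$root_a, target = a_bound,
               provenance = "direct", stringsAsFactors = FALSE),
    data.frame(source = p$root_b, target = c(ffl_targets, casc_targets),
               provenance = "catalog", stringsAsFactors = FALSE)
  )
  edges_b <- data.frame(source = p$root_b,
                        target = c(ffl_targets, casc_targets),
                        provenance = "direct", stringsAsFactors = FALSE)
  motifs <- data.frame(
    target = c(ffl_targets, casc_targets),
    kind = c(rep("FFL", length(ffl_targets)),
             rep("cascade", length(casc_targets))),
    subtype = c(ffl_subtype, casc_subtype),
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    root_a = p$root_a, root_b = p$root_b,
    genes = genes,
    ffl_targets = ffl_targets, ffl_subtype = ffl_subtype,
    cascade_targets = casc_targets, cascade_subtype = casc_subtype,
    cascade_sign_b = casc_sign_b,
    direct_only = direct_only, direct_sign = direct_sign,
    orphans = orphans, orphan_sign = orphan_sign,
    nonnetwork = setdiff(nonnet, character(0)),
    bound_a = sort(a_bound), bound_b = sort(b_bound),
    planted_edges_a = edges_a, planted_edges_b = edges_b,
    planted_motifs = motifs,
    params = p, seed = seed
  ), class = "synthetic_truth")

  list(promoters = promoters,
       peaks = list(root_a = peaks_a, root_b = peaks_b,
                    h3k27ac = h3k27ac, h3k4me1 = h3k4me1),
       catalog = catalog,
       truth = truth)
}

# planted knockdown sign of each FFL subtype in the (A-KD, B-KD) tables;
# negative logFC = activation by the depleted regulator
.ffl_sign_map <- list(
  C1 = c(a = -1, b = -1), C3 = c(a = 1, b = 1),
  I1 = c(a = -1, b = 1), I3 = c(a = 1, b = -1)
)

#' Generate the two knockdown DEG tables
#'
#' Every planted network gene is a DEG (FDR drawn below 0.05) in the
#' appropriate knockdown, with logFC sign dictated by its planted motif
#' subtype and magnitude |Normal(mu, mu/3)|; each planted sign is flipped
#' independently with probability \code{sign_flip_rate}. Genes outside the
#' network receive null logFC and FDR >= 0.05.
#'
#' @param truth a \code{synthetic_truth}.
#' @param sign_flip_rate probability in [0, 0.5) of flipping a planted
#'   sign (default: the value in the truth's parameters).
#' @param effect_size mean |logFC| mu (default from parameters).
#' @param seed RNG seed.
#' @return list of two \code{deg_table}s: \code{kd_a}, \code{kd_b}.
#' @export
generate_kd_tables <- function(truth,
                               sign_flip_rate = truth$params$sign_flip_rate,
                               effect_size = truth$params$effect_size,
                               seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (sign_flip_rate < 0 || sign_flip_rate >= 0.5)
    stop("sign_flip_rate must lie in [0, 0.5)")
  set.seed(seed)
  mu <- effect_size
  mag <- function(n) pmax(abs(stats::rnorm(n, mu, mu / 3)), 1e-6)
  flip <- function(s) s * ifelse(stats::runif(length(s)) < sign_flip_rate,
                                 -1, 1)
  sig_fdr <- function(n) stats::runif(n, 0, 0.049)

  ffl_a <- vapply(truth$ffl_subtype, function(s) .ffl_sign_map[[s]]["a"],
                  numeric(1))
  ffl_b <- vapply(truth$ffl_subtype, function(s) .ffl_sign_map[[s]]["b"],
                  numeric(1))
  casc_b <- truth$cascade_sign_b
  casc_a <- ifelse(truth$cascade_subtype == "coherent", casc_b, -casc_b)

  # A knockdown: B, FFL and cascade targets, A-only targets and orphan
  # DEGs are significant; everything else is null
  a_genes <- c(truth$root_b, truth$ffl_targets, truth$cascade_targets,
               truth$direct_only, truth$orphans)
  a_sign <- flip(c(-1, ffl_a, casc_a, truth$direct_sign,
                   truth$orphan_sign))
  rest_a <- setdiff(truth$genes, a_genes)
  kd_a <- deg_table(
    c(a_genes, rest_a),
    c(a_sign * mag(length(a_genes)),
      stats::rnorm(length(rest_a), 0, 0.3)),
    c(sig_fdr(length(a_genes)),
      stats::runif(length(rest_a), 0.05, 1))
  )

  # B knockdown: FFL and cascade targets significant (and B itself, the
  # depleted gene); everything else null
  b_genes <- c(truth$root_b, truth$ffl_targets, truth$cascade_targets)
  b_sign <- c(-1, flip(c(ffl_b, casc_b)))
  rest_b <- setdiff(truth$genes, b_genes)
  kd_b <- deg_table(
    c(b_genes, rest_b),
    c(b_sign * mag(length(b_genes)),
      stats::rnorm(length(rest_b), 0, 0.3)),
    c(sig_fdr(length(b_genes)),
      stats::runif(length(rest_b), 0.05, 1))
  )
  list(kd_a = kd_a, kd_b = kd_b)
}

# activity of each planted cluster across the three cohorts
.cluster_patterns <- matrix(
  c(1, 1, 1,   # 1: constitutive core
    1, 1, 0,   # 2: leukemia-specific (silent in normal marrow)
    1, 0, 0,   # 3: ALL-restricted
    0, 1, 0,   # 4: AML-restricted
    0, 0, 0),  # 5: inactive
  nrow = 5, byrow = TRUE,
  dimnames = list(NULL, c("ALL", "AML", "FBM"))
)

#' Generate the patient expression cohort
#'
#' Each GRN gene is assigned one of five planted activity programs across
#' the ALL, AML and FBM datasets (constitutive, leukemia-only, ALL-only,
#' AML-only, inactive); the intermediate TF B is always constitutive so
#' that cascade targets stay wired in every subnetwork where they are
#' expressed. Active gene-by-sample entries are drawn from a high-TPM
#' log-normal and inactive entries from a low-TPM log-normal; an active
#' entry drops to the inactive distribution with probability
#' \code{dropout}. Non-network genes receive random programs so that the
#' per-dataset expression thresholds sit between the two modes.
#'
#' @param truth a \code{synthetic_truth}.
#' @param n_samples named integer vector of samples per dataset (default
#'   from parameters).
#' @param dropout per-entry dropout probability (default from parameters).
#' @param seed RNG seed.
#' @return a list: \code{cohort} (an \code{expression_cohort}) and
#'   \code{cluster} (named planted cluster label per GRN gene).
#' @export
generate_expression_cohort <- function(truth,
                                       n_samples = truth$params$n_samples,
                                       dropout = truth$params$dropout,
                                       seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  p <- truth$params
  grn_genes <- c(truth$root_b, truth$ffl_targets, truth$cascade_targets,
                 truth$direct_only)
  others <- setdiff(truth$genes, grn_genes)
  k <- nrow(.cluster_patterns)
  cl <- c(1L, sample(seq_len(k), length(grn_genes) - 1L, replace = TRUE))
  names(cl) <- grn_genes
  cl_other <- sample(seq_len(k), length(others), replace = TRUE)
  names(cl_other) <- others

  datasets <- rep(names(n_samples), n_samples)
  samples <- paste0(datasets, "_", unlist(lapply(n_samples, seq_len)))
  all_cl <- c(cl, cl_other)[truth$genes]
  active <- .cluster_patterns[all_cl, datasets, drop = FALSE] == 1
  dimnames(active) <- list(truth$genes, samples)
  active[active & matrix(stats::runif(length(active)) < dropout,
                         nrow(active))] <- FALSE
  tpm <- matrix(0, nrow(active), ncol(active),
                dimnames = dimnames(active))
  n_act <- sum(active)
  tpm[active] <- stats::rlnorm(n_act, p$active_meanlog, p$active_sdlog)
  tpm[!active] <- stats::rlnorm(length(active) - n_act,
                                p$inactive_meanlog, p$inactive_sdlog)
  list(cohort = expression_cohort(tpm, datasets), cluster = cl)
}

#' Generate CRISPR essentiality calls
#'
#' Each GRN gene is assigned a planted category (proportions from the
#' parameters) and per-cell-line essential flags consistent with it: a
#' nonspecific-essential gene is essential in at least one non-leukemia
#' line, a leukemia-specific gene only in leukemia lines, a nonessential
#' gene nowhere.
#'
#' @param truth a \code{synthetic_truth}.
#' @param seed RNG seed.
#' @return a list: \code{calls} (an \code{essentiality_calls}) and
#'   \code{category} (named planted category per GRN gene).
#' @export
generate_essentiality <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  p <- truth$params
  grn_genes <- c(truth$root_b, truth$ffl_targets, truth$cascade_targets,
                 truth$direct_only)
  category <- sample(names(p$essentiality_props), length(grn_genes),
                     replace = TRUE, prob = p$essentiality_props)
  names(category) <- grn_genes
  lines <- c(p$leukemia_lines, p$other_lines)
  grid <- expand.grid(gene_id = grn_genes, cell_line = lines,
                      stringsAsFactors = FALSE)
  ess <- logical(nrow(grid))
  for (g in grn_genes) {
    idx <- which(grid$gene_id == g)
    ln <- grid$cell_line[idx]
    flag <- logical(length(idx))
    if (category[[g]] == "nonspecific_essential") {
      other_idx <- which(ln %in% p$other_lines)
      flag[sample(other_idx, sample(length(other_idx), 1))] <- TRUE
      leuk_idx <- which(ln %in% p$leukemia_lines)
      flag[leuk_idx] <- stats::runif(length(leuk_idx)) < 0.5
    } else if (category[[g]] == "leukemia_specific") {
      leuk_idx <- which(ln %in% p$leukemia_lines)
      flag[sample(leuk_idx, sample(length(leuk_idx), 1))] <- TRUE
    }
    ess[idx] <- flag
  }
  grid$essential <- ess
  list(calls = essentiality_calls(grid, p$leukemia_lines, p$other_lines),
       category = category)
}

#' Simulate a complete synthetic study
#'
#' Runs all generators with sub-seeds derived from one master seed and
#' returns every pipeline input together with the planted truth.
#'
#' @param params from [synth_params()].
#' @param seed master RNG seed (sub-seeds are \code{seed}, \code{seed+1},
#'   \code{seed+2}, \code{seed+3}).
#' @return a list: \code{promoters}, \code{peaks}, \code{catalog},
#'   \code{kd_a}, \code{kd_b}, \code{cohort}, \code{planted_cluster},
#'   \code{essentiality}, \code{planted_category}, \code{truth}.
#' @export
simulate_study <- function(params = synth_params(), seed = 1) {
  reg <- generate_regulome(params, seed = seed)
  kd <- generate_kd_tables(reg$truth, seed = seed + 1)
  expr <- generate_expression_cohort(reg$truth, seed = seed + 2)
  ess <- generate_essentiality(reg$truth, seed = seed + 3)
  list(promoters = reg$promoters, peaks = reg$peaks,
       catalog = reg$catalog,
       kd_a = kd$kd_a, kd_b = kd$kd_b,
       cohort = expr$cohort, planted_cluster = expr$cluster,
       essentiality = ess$calls, planted_category = ess$category,
       truth = reg$truth)
}

#' Write the planted truth as JSON
#'
#' @param truth a \code{synthetic_truth}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the 'jsonlite' package is required to write truth JSON")
  out <- truth
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
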