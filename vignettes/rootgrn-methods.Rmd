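---
title: "Methods: root-centred GRN construction, perturbation and motif analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: root-centred GRN construction, perturbation and motif analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootgrn)
```

# The model

`rootgrn` analyses transcriptional regulation organised around a single
central regulator (the *root*) — typically an oncogenic fusion protein
whose depletion deregulates far more genes than it binds. The working
model is that unbound differentially expressed genes (DEGs) are reached
indirectly, through intermediate transcription factors (TFs) that the
root binds and regulates. A GRN in this package is therefore a directed
graph anchored at the root, in which every node is a knockdown DEG and
every node is reachable from the root: a gene enters the network only if
there is a regulatory explanation — a chain of binding and catalog
interactions — connecting it back to the root.

## Construction

Four steps, mirrored by `build_grn()`:

1. **Regulatory scope** (`regulatory_scope()`): genes with knockdown FDR
   strictly below the threshold (default 0.05). The strictness matters
   only at the boundary but is applied literally so that scope sets are
   reproducible.
2. **Direct layer** (`build_direct_layer()`): root → gene edges for
   scope genes whose promoter is the nearest promoter of a root ChIP
   peak. *Nearest* means smallest unsigned distance from the peak
   midpoint (`floor((start + end)/2)` in 0-based half-open coordinates)
   to a TSS on the same chromosome; strand is ignored. Equidistant ties
   go to the lexicographically smallest gene id — an arbitrary but
   deterministic rule, so that re-running the build never reshuffles the
   network. Peaks on chromosomes carrying no promoter are reported
   unannotated rather than failing the run. For an intermediate-TF build
   the peaks are first restricted to enhancer-supported ones, an
   enhancer being an H3K27ac peak overlapping an H3K4me1 peak by at
   least 1 bp (`define_enhancers()`); the 1-bp rule deliberately errs
   against discarding genuine regulatory binding.
3. **Catalog expansion and pruning** (`expand_and_prune()`): TF-catalog
   edges are admitted only when both endpoints are in the scope, then
   the graph is cut down to the subgraph reachable from the root.
   Reachability is the whole content of the pruning rule: an interaction
   that cannot lie on any root-to-target path explains nothing in a
   root-centred model. The root itself participates only through its
   ChIP-derived direct edges — catalog edges into or out of the root are
   never admitted, so indirect structure cannot be conjured for a
   regulator (such as a fusion protein) that the catalog does not model.
   When a catalog edge duplicates a direct edge, the direct provenance
   is kept: binding evidence dominates curated inference.
4. **Annotation** (`annotate_nodes()`, `sign_edges()`): each node
   carries its knockdown logFC/FDR and a CRISPR essentiality category;
   each edge whose source regulator has a knockdown table is signed by
   the target's response — logFC < 0 under knockdown means the regulator
   activates the target. A logFC of exactly 0 for a DEG is treated as
   malformed input, not silently assigned a sign. Essentiality follows a
   fixed precedence: essential in any non-leukemia line ⇒ *nonspecific
   essential*, otherwise essential in any leukemia line ⇒
   *leukemia-specific*, otherwise *nonessential*. The precedence encodes
   the screening logic that a gene required by unrelated cancer lines is
   not a leukemia-selective dependency, whatever the leukemia lines say.

Two useful invariants follow from this construction and are enforced by
tests: every node of every built network is reachable from the root, and
enlarging the scope can only add nodes and edges, never remove any.

## Peak-level operations

Coordinates are BED-style 0-based half-open throughout the user-facing
interface; internally intervals live in `GRanges`, whose 1-based closed
convention represents the same sets, so an overlap of ≥ 1 bp in one
convention is ≥ 1 bp in the other. `intersect_peaks(a, b)` returns the
peaks of `a` (coordinates intact) supported by any overlap in `b` — it
identifies peaks, not overlap fragments, and is therefore intentionally
asymmetric; the same operation defines fusion-protein peaks from two
antibody tracks and enhancer-supported peaks from histone marks.

Two ChIP normalizations are provided. Tags-per-ten-million rescales a
tag count by `1e7 / library_total`. For spike-in (reference chromatin)
normalization the package uses
\[
\alpha = \frac{\text{spike}_{\text{input}} / \text{hg}_{\text{input}}}
             {\text{spike}_{\text{IP}} / \text{hg}_{\text{IP}}},
\]
with adjusted signal = raw IP signal × α. The defining property, chosen
where several ratio conventions would fit the verbal description, is
that identical spike:target ratios in input and IP imply α = 1 (no
adjustment), and that α is invariant to rescaling all four counts. A
zero anywhere signals an unusable spike-in and raises an error.

# Centrality and in-silico deletion

Degree centrality is total degree (in + out). Stress centrality is the
Shimbel variant: for node *v*, the number of shortest directed paths
between ordered pairs (s, t), all three distinct, whose interior passes
through *v*; co-optimal paths each count 1 (integer multiplicities, not
the fractional weights of betweenness). It is computed per source by
breadth-first search followed by a dependency accumulation in reverse
BFS order (O(nm) overall); the test suite checks it against an
exhaustive shortest-path enumeration oracle on random graphs and against
the closed form (k−1)(n−k) on directed paths.

`in_silico_delete()` removes a node and its incident edges and
deliberately does **not** re-prune reachability: nodes stranded by the
deletion are kept precisely so their loss of centrality is measurable.
`deletion_impact()` reports, for every remaining gene,
\[
\mathrm{FC}(g) = \log_2\!\frac{\text{stress}_{\text{after}}(g) + c}
                              {\text{stress}_{\text{before}}(g) + c},
\qquad c = 1,
\]
and the mean of |FC|. The log-ratio form with pseudocount 1 is a design
choice — it yields signed, symmetric values and handles the many
zero-stress nodes of sparse networks — and both the pseudocount and the
log base are exposed as arguments rather than hard-coded. Per-gene FCs
are classified positive/negative at |FC| > 0.1, a threshold matched to
the signed fold-change scale on which such deletion responses are
usually read. Only the deleted node is excluded from the mean; its
immediate neighbours are retained, since excluding them would require an
additional, unstated modelling decision.

# Motif analysis

`integrate_grns()` unions the networks of a root regulator A and an
intermediate TF B, requiring B to be a direct, activated target of A
(the A→B edge is asserted, and fixed as activating throughout). Every
other target T then falls into exactly one bucket: both A→T and B→T
edges make a feed-forward loop; B→T alone makes a cascade; A→T alone is
excluded. With A→B fixed as activating, the eight signed FFL types
collapse to four, read off the quadrant of the two knockdown responses
(A-KD logFC, B-KD logFC):

| quadrant | meaning | subtype |
|----------|---------|---------|
| (−, −) | A and B both activate T | C1 |
| (+, +) | A and B both repress T | C3 |
| (−, +) | A activates, B represses | I1 |
| (+, −) | A represses, B activates | I3 |

The quadrant→label map follows standard FFL nomenclature with the
direct X→Z arm read from the A knockdown; since the labels are
convention, the mapping is centralized in `classify_ffl()` where it can
be re-mapped if a different diagram convention is preferred. Cascades
are *coherent* when the two responses agree in sign — by construction
the coherent-FFL half (C1 ∪ C3) is exactly the same-sign half-plane, the
identical rule. Targets that are a DEG in only one knockdown cannot be
sign-classified; they are retained in a diagnostics bucket
(`classified = FALSE`) and excluded from percentages rather than being
guessed. Coherence percentages are reported to one decimal; a motif kind
with no classified records yields an undefined (`NA`) percentage, never
a misleading 0.

# Patient subnetworks

A gene is *expressed* in a sample when its log2(TPM + 1) strictly
exceeds the grand mean of log2(TPM + 1) over all gene × sample entries
of that sample's dataset. Reading "mean log2 TPM per dataset" as the
grand mean (rather than per-gene or per-sample means) keeps one
threshold per dataset and makes cohorts on different scales comparable;
the +1 pseudocount handles zero TPM. Per-sample subnetworks re-run the
entire construction with the scope intersected with the expressed set,
so the reachability invariant holds sample by sample, and losing one
bridge TF from a sample's expressed genes removes everything that only
it explained. Node presence across subnetworks forms the binary activity
matrix; conservation of a node in a dataset is the percentage of that
dataset's samples containing it.

Activity patterns are clustered with k-means (Euclidean) directly on
the binary rows — k = 5 by default, 25 restarts, fixed seed, so results
are reproducible — and *not* on a UMAP embedding: the embedding
(`activity_umap()`) distorts distances and is provided for plotting
only. Nodes active in no sample are clustered with the rest and form the
inactive cluster naturally.

# The synthetic study

The generator (`simulate_study()`) emulates every input with planted
ground truth: promoters laid out on four synthetic chromosomes (10 kb
TSS spacing); root ChIP peaks (±100 bp around target TSSs, ±30 bp
jitter) at the intermediate TF, the FFL targets and a set of root-only
targets, plus decoy peaks near non-network promoters at rate 0.1;
TF-B peaks at FFL and cascade targets, all enhancer-supported, with
extra unsupported acetylation so the enhancer filter has real work; a
TF catalog containing the planted B→target edges plus decoys that fail
either the scope filter (edges between non-network genes) or the
reachability pruning (edges among *orphan DEGs* — significant genes
with no explanation from the root, mirroring the unbound-DEG phenomenon
that motivates the whole model); knockdown tables in which every planted
target is a DEG (FDR ~ U(0, 0.049)) with |logFC| ~ |N(μ, μ/3)| and sign
dictated by its motif subtype; an expression cohort; and essentiality
calls over two leukemia and two non-leukemia cell lines.

Defaults define the study conditions and are not tuned per run: 1000
genes; 50 FFLs split 30/6/10/4 across C1/C3/I1/I3 and 100 cascades split
73/27 coherent/incoherent — a C1-dominant, ~72%-coherent composition of
the kind reported for fusion-driven leukemia GRNs; effect size μ = 1.5
log2 units; sign-flip noise ε = 0.05; expression dropout 5%. Sub-seeds
are derived from one master seed, and identical seeds give byte-identical
outputs.

Five activity programs are planted across the three cohorts:
constitutive, leukemia-shared (silent in normal fetal bone marrow),
ALL-restricted, AML-restricted, and inactive; the intermediate TF is
always constitutive so that cascade targets stay wired wherever they are
expressed. Active entries draw TPM from a log-normal centred at 100,
inactive from one centred at 0.5, which puts every dataset's grand-mean
threshold cleanly between the modes.

**Cohort sizing is a power consideration.** The FBM cohort has 3 samples
(the realistic size for such normal-tissue references), so the
constitutive and leukemia-shared programs differ in only 3 of the
activity columns. For the planted partition to be the k-means optimum,
that 3-column signal (squared centroid separation ≈ 3·(1−dropout)²) must
exceed the expected within-cluster dropout scatter, which grows with the
number of leukemia columns (≈ dropout·(1−dropout)·n_active). The default
therefore uses 12 ALL and 12 AML samples; with much larger leukemia
cohorts at 5% dropout the two programs become statistically
inseparable — not an algorithmic failure but an identifiability limit of
binary activity clustering, which is why the cluster-recovery check
evaluates the adjusted Rand index as an average over seeds: individual
dropout draws can sit on the wrong side of the k-means objective.

## What the generator does and does not emulate

It emulates the *logical* structure of the inputs — binding near
promoters, scope membership, signed responses, decoy interactions,
dataset-specific expression programs — at desk scale (hundreds of
network genes, tens of samples; the test suite and acceptance script run
on these sizes throughout). It does not emulate read-level data, peak
shapes, correlated noise between the two knockdowns, graded expression
within the active state, partially conserved activity programs, or
catalog incompleteness. Passing the recovery tests therefore shows the
pipeline is correct and well-calibrated under its own model; it does not
certify performance on real cohorts, where signal-to-noise and catalog
coverage are worse in ways the generator deliberately does not model.

# Degenerate inputs and numerical conventions

* Interval invariants (`start < end`, `start ≥ 0`, non-empty chromosome
  names) and table invariants (unique gene ids, FDR ∈ [0,1], finite
  logFC) are checked at construction, not at use.
* Catalog self-edges are dropped with a warning; duplicate edges are
  collapsed.
* Genes absent from an essentiality screen classify as nonessential,
  with a warning; the root, a fusion protein that no screen contains, is
  annotated `NA` silently.
* k-means refuses k larger than the number of distinct activity
  patterns rather than returning degenerate clusters.
* An empty motif set yields undefined percentages; an empty peak set or
  catalog flows through every operation as the corresponding empty
  result.
* Stress on graphs with fewer than three nodes is identically zero;
  isolated nodes have degree 0 and never appear in any path interior.

# Known limitations

* Gene identifiers are plain case-sensitive symbols; alias resolution is
  the caller's job.
* Edge signs come from marginal knockdown responses; confounding between
  the direct and indirect arms of an FFL is not modelled.
* Stress is unweighted and directed; no eigenvector-style centralities
  are provided.
* The deletion analysis recomputes exact stress twice per deleted node;
  ranking all nodes of very large networks is quadratic-ish in practice
  and should be restricted to candidate nodes via the `nodes` argument
  of `deletion_impact_ranking()`.
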