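# rootgrn

Root-centred gene regulatory network (GRN) analysis for regulators that
drive broad transcriptional programs — the motivating case being a
leukemic fusion protein whose knockdown deregulates thousands of genes,
most of them not directly bound by the fusion complex. `rootgrn` asks how
such indirect regulation is wired: which intermediate transcription
factors (TFs) relay the signal, through which signed circuit motifs, and
which nodes the network depends on.

The package implements, end to end:

1. **GRN construction** around a central regulator ("root") in four
   steps: (i) the *regulatory scope* is the set of genes differentially
   expressed after knocking down the root (FDR < 0.05, strict); (ii) the
   *direct layer* connects the root to scope genes whose promoters are
   the nearest promoter to a root ChIP-seq peak (optionally restricted to
   enhancer-supported peaks, an enhancer being an H3K27ac peak
   overlapping H3K4me1 by ≥ 1 bp); (iii) *indirect edges* are drawn from
   a TF-interaction catalog, admitted only between scope genes, and
   pruned to the subgraph reachable from the root — catalog edges that do
   not explain connectivity between the root and its downstream targets
   are excluded; (iv) nodes are *annotated* with their knockdown
   response, per-edge activation/repression signs (logFC < 0 under
   knockdown ⇒ activation), and CRISPR-screen essentiality categories
   (nonspecific essential ≻ leukemia-specific ≻ nonessential).
2. **Network centrality and perturbation**: total degree; Shimbel stress
   centrality (the number of shortest directed paths passing through a
   node's interior, co-optimal paths each counted once); in-silico node
   deletion with a per-gene stress fold change
   `FC(g) = log2((stress_after + 1) / (stress_before + 1))`, classified
   at |FC| > 0.1, and ranking of nodes by mean |FC|.
3. **Motif analysis** over two integrated GRNs (fusion root A,
   intermediate TF B, with A→B activating): every shared target forms a
   feed-forward loop (FFL), classified C1/C3/I1/I3 from the sign
   quadrant of its two knockdown responses; every B-only target forms a
   cascade, coherent when the two responses agree in sign. Coherence
   percentages summarize how cooperatively the two regulators act.
4. **Patient subnetworks**: per-sample rebuilds of the GRN restricted to
   genes expressed in that sample (log2(TPM+1) above the dataset's grand
   mean), a binary node-activity matrix, per-dataset node conservation,
   and k-means clustering of activity patterns (UMAP available for
   visualization only).
5. **A synthetic-data generator** that emulates every input — promoters,
   peak sets, TF catalog, knockdown DEG tables, a three-cohort
   expression matrix, essentiality screens — with planted, recoverable
   ground truth (motif subtypes, signs, activity clusters, essentiality
   categories), so the whole pipeline is testable without any external
   download.

## Worked example

```r
library(rootgrn)

sim <- simulate_study(synth_params("small"), seed = 7)
tr  <- sim$truth

grn_a <- build_grn(tr$root_a, sim$kd_a, sim$peaks$root_a, sim$promoters,
                   sim$catalog, calls = sim$essentiality)
enh   <- define_enhancers(sim$peaks$h3k27ac, sim$peaks$h3k4me1)
grn_b <- build_grn(tr$root_b, sim$kd_b, sim$peaks$root_b, sim$promoters,
                   sim$catalog, enhancers = enh)

head(centrality_report(grn_a), 3)
#>    gene_id degree stress
#> 1    g0001     25     12
#> 36  ROOT_A     23      0
#> 4    g0023      2      0
```

The intermediate TF `g0001` tops the ranking: it is bound by the root
and relays the cascade layer, so all root-to-cascade shortest paths run
through it (stress 12 = one per cascade target). Motif classification of
the integrated network:

```r
records <- classify_motifs(enumerate_motifs(integrate_grns(grn_a, grn_b)),
                           sim$kd_a, sim$kd_b)
summarize_coherence(records)[c("ffl_coherent_pct", "cascade_coherent_pct")]
#> $ffl_coherent_pct
#> [1] 66.7
#> $cascade_coherent_pct
#> [1] 58.3
```

With the small preset's 12 FFLs and 12 cascades and 5% sign-flip noise,
two-thirds of FFLs are coherent (the planted fraction is 8/12). Deleting
the root in silico shows where the network's shortest-path load sat:

```r
imp <- deletion_impact(grn_a, tr$root_a)
round(imp$mean_abs_fc, 3)
#> [1] 0.106
sort(imp$per_gene_fc)[1]
#>    g0001
#> -3.70044
```

The only negative stress fold change belongs to `g0001`, whose
through-traffic existed solely because the root fed it — the signature
of a relay TF.

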