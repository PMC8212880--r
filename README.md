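# graftnet

Network-based target discovery for vein-graft disease proteomics.

Vein grafts exposed to arterial flow ("arterialization") develop maladaptive
wall lesions, and the proteome of the remodeling graft is a natural place to
look for therapeutic targets. `graftnet` implements a complete, testable
version of that discovery platform for label-free tissue proteomics:

1. **Static filtering** — per-sample median normalization of protein
   abundances, per-protein one-way ANOVA across tissue conditions (e.g.
   control vein IVC vs neointimal/adventitial graft layers), Benjamini–
   Hochberg FDR filtering at q ≤ 0.05, and a Ward-linkage bipartition of the
   filtered proteins into control-predominant and lesion-predominant
   clusters.
2. **Kinetic coabundance clustering** — graft and control-vein time-course
   profiles (D1, D3, W2, W4) are replicate-averaged, fractionally normalized
   (xₜ / Σxₜ), pooled, and clustered with a diagonal-covariance Gaussian
   mixture fitted by EM (k-means++ restarts). Clusters are labelled
   *early*, *late*, or *flat* by centroid shape, and the disease-condition
   proteins of the non-flat phases are carried forward.
3. **Pathway networks** — hypergeometric overrepresentation
   P(X ≥ k | N, K, n) of each protein set against a GMT pathway collection,
   a pathway–pathway network whose edges are shared dataset proteins, and
   normalized betweenness / closeness / degree centralities identifying the
   top-ranked "conduit" pathways.
4. **Target prioritization** — within each top pathway, the induced
   interactome subgraph on its dataset proteins is scored by the same three
   centralities and the consensus most-central protein is called by Borda
   rank aggregation (sum of the three dense ranks; unanimity = 3).
5. **Disease-module proximity** — closest network distance
   d(A,B) = mean over a∈A of minimum hops to B (symmetrized; the separation
   score s = ⟨d_AB⟩ − (⟨d_AA⟩+⟨d_BB⟩)/2 is available as an alternative),
   judged against a degree-preserving null: both modules are replaced by
   degree-bin-matched random node sets, 1000 times by default, yielding
   z-scores, pseudocounted empirical p-values (r+1)/(n+1), and a
   BH-corrected N×N association matrix.

Because raw vascular proteomes of this kind are rarely shareable, the
package ships seeded synthetic-data generators with planted ground truth —
trend templates, differential proteins, a scale-free interactome with a
planted hub target, hub-anchored pathways, and disease modules at controlled
proximity — so every stage (and the pipeline end to end) is validated
against what was planted.

## Worked example

```r
library(graftnet)

## generate the synthetic study bundle (planted hub target, 400 proteins)
bundle <- synth_bundle(dir = "vg_inputs", n_nodes = 400, seed = 1)
bundle$hub_target
#> [1] "P0003"

## run the full pipeline (n_rand = 1000 randomizations by default)
config <- read_config(bundle$config_path)
config$out_dir <- "vg_results"
res <- run_pipeline(config)

res$primary_target
#> [1] "P0003"
length(res$differential$retained)
#> [1] 88
lengths(res$clusters)
#> cluster1 cluster2
#>       49       39
head(res$targets[res$targets$network == "lesion", 1:6], 3)
#>   pathway_id protein_id borda_score betweenness closeness degree
#> 1       PW01      P0003           3   0.9444444         1      1
#> 2       PW02      P0003           3   0.9818841         1      1
#> 3       PW03      P0003           3   0.9777778         1      1
subset(res$proximity, significant,
       select = c(module_a, module_b, d_obs, z, p_emp, q))
#>   module_a  module_b     d_obs         z       p_emp          q
#> 8 cluster2 AVF_SYNTH 0.5967949 -6.889246 0.000999001 0.01498501
```

Reading the output: the ANOVA filter retains 88 of 400 proteins and splits
them into a 49-protein control-predominant and a 39-protein
lesion-predominant cluster; the three top-ranked central pathways of the
lesion network all call protein `P0003` — the planted hub — with a unanimous
Borda score of 3, so it becomes the pipeline's primary target. In the
proximity matrix, the only significant association links the
lesion-predominant cluster to the synthetic disease module grown around the
hub (observed closest distance 0.60 hops vs a degree-preserving null,
z = −6.9, empirical p = 1/1001, BH q = 0.015); all other pairs are blank
(p > 0.05), exactly as planted.

Every run writes deterministic TSVs (differential records, cluster
memberships, centroids, enrichment and centrality tables, target calls, the
proximity matrix) plus a `manifest.json` recording the configuration,
package version, per-file checksums and all warnings; a rerun with the same
seed reproduces every file byte for byte.

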