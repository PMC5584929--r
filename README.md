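# phagestate

Infection-state inference for temperate cyanophage from metatranscriptomes.

During *Microcystis* blooms, the phage infecting the bloom can run either a
**lytic** program (replication, packaging, host lysis) or sit as a
**lysogen** (integrated prophage, marked by mobile-element genes).
`phagestate` implements, as tested and reusable R functions, the molecular
inference of that state from community RNA-seq data:

1. **Filtered competitive quantification** — paired-end alignments against
   the phage and host genomes are filtered at a 0.9 aligned-length fraction
   and a 0.9 identity fraction, each mate is resolved to its single best
   genome, pairs whose mates map to different genomes are discarded, and
   read pairs are counted within ORFs (gene × sample count matrix).
2. **Marker-ratio state classification** — per sample, the log2 ratio of
   the lytic marker (tail sheath, *gp091*) to the lysogeny marker (IS607
   transposase, *gp135*; serine recombinase *gp136* reported alongside) on
   normalised expression:
   `r_s = log2( e_s(gp091) / e_s(gp135) )`, with `r_s > 0` called lytic and
   `r_s < 0` lysogenic. Samples with negligible phage and host expression
   are excluded first.
3. **Co-expression structure** — gene–gene Pearson association (p from the
   t reference distribution, edges at p ≤ 0.1), average-linkage clustering
   on `d = 1 − ρ`, and a SIMPROF-style permutation test that collapses
   branches whose members' expression patterns are statistically
   indistinguishable.
4. **Ordination and environmental drivers** — Bray-Curtis dissimilarity
   `d(i,j) = Σ|x_i − x_j| / Σ(x_i + x_j)` over library-size-normalised,
   square-root-transformed phage expression; Kruskal non-metric MDS
   (stress-1 minimisation with isotonic regression and restarts);
   least-squares environmental vectors with permutation p-values; and
   exhaustive **BIOENV/BEST** selection of the environmental subset whose
   Euclidean distances maximally Spearman-correlate with the expression
   resemblance, with a global permutation test.

A first-class **synthetic-data module** generates phage/host gene models,
correlated limnological covariates, latent infection states tied to the
environment through a logistic link, negative-binomial counts with planted
co-expression blocks, and paired-end SAM fixtures (including labelled decoy
reads), so the entire pipeline is testable against known ground truth with
no sequencing download.

## Worked example

```r
library(phagestate)

cfg <- pipeline_config(
  seed = 42,
  sim = list(n_samples = 33, state_fold_change = 10),
  coexpr = list(alpha = 0.05, edge_p = 0.1, n_perm = 199, k = 3,
                linkage = "average"),
  ordination = list(n_restarts = 20, max_iter = 300, tol = 1e-7),
  best = list(max_subset_size = 3, n_perm = 49))
rep <- run_pipeline(cfg, "demo_run")
rep
#> phagestate run report
#>   samples retained: 33
#> lysogenic     lytic
#>        15        18
#>   nMDS stress-1: 7.09e-07
#>   BEST subset: { pH, TDP } rho = 0.0317

rep$marker_correlations
#>   gene1 gene2        rho      p_value  n undefined
#> 1 gp091 gp135 -0.5074916 2.573332e-03 33     FALSE
#> 2 gp091 gp136 -0.5366701 1.282891e-03 33     FALSE
#> 3 gp135 gp136  0.8822821 1.145911e-11 33     FALSE

rep$cluster_report$summary
#>   cluster n_genes     markers n_coexpressed
#> 1       1     164       gp091           164
#> 2       2       8                         8
#> 3       3      12 gp135,gp136            12

head(rep$env_fit[order(rep$env_fit$p_value), ], 2)
#>   variable         dx dy         R p_value
#> 3      TDS -0.3701254  0 0.3701254    0.06
#> 5       pH  0.3136422  0 0.3136422    0.10
```

Reading: of 33 samples, 18 are called lytic-dominated and 15
lysogen-dominated; the lytic marker is negatively correlated with both
lysogeny markers (ρ ≈ −0.51 and −0.54) while transposase and recombinase are
tightly co-expressed (ρ ≈ 0.88); the lysogeny markers fall in a small
cluster separate from the large replication/structural cluster containing
the tail sheath; and on the ordination the total-dissolved-solids vector
points toward the lytic side while pH points toward the lysogenic side —
the structure the generator planted. The near-zero stress reflects the
strong two-cluster geometry of high-fold-change synthetic data. Every
intermediate (counts, expression matrices, state calls, dendrogram as
Newick, ordination coordinates, BEST table) is written as TSV under
`demo_run/`.

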