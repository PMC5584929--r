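---
title: "Methods: inferring lytic vs lysogenic phage states from metatranscriptomes"
author: "phagestate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring lytic vs lysogenic phage states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

*Microcystis aeruginosa* blooms carry a temperate myovirus (Ma-LMM01-like)
whose genome encodes both a lytic program and lysogeny machinery — an IS607
mobile element made of a transposase (*gp135*) and a serine recombinase
(*gp136*). In community RNA-seq from bloom water, the relative transcription
of the viral tail sheath (*gp091*, a structural, lytic-cycle gene) versus
the IS607 genes is a molecular readout of which program dominates each
sample. `phagestate` turns that readout, and the supporting whole-genome
expression analyses, into a tested pipeline. Because the real libraries are
large external deposits, the package ships a synthetic-data generator that
emulates the study design with known ground truth; every claim the test
suite makes is a claim about recovering planted truth.

# Quantification model

Input alignments (SAM) are assumed to be *competitive*: each read was mapped
against host and phage references jointly. Per record we compute the aligned
length (query bases aligned, soft clips excluded), the read length, and the
mismatch count from the `NM` tag (from `MD` when `NM` is missing; records
with neither, or with hard clips covering more than half the read, are
rejected as malformed). A record passes if

* aligned_length / read_length ≥ 0.9, and
* (aligned_length − mismatches) / aligned_length ≥ 0.9.

Identity is computed over the aligned segment, not the full read — the two
cutoffs are stated and applied separately. Each mate is then resolved to its
single best candidate by score `aligned_length − mismatches`; equal-best
ties are broken uniformly at random with a seeded generator
(`random_best`, mirroring a mapper's default), or the whole read is dropped
(`discard_ties`, the conservative alternative). A pair is retained only if
both mates resolved, both pass, and both map to the same genome; exclusions
are tallied by reason (`orphan`, `filtered`, `cross_genome`).

Counting is pair-in-ORF. The default containment rule, `both_within`,
requires both mate intervals inside one ORF — the literal reading of
"pairs mapped within open reading frames". Because the edge case is not
well defined, `fragment_within` and `any_overlap` are configuration
options; under `any_overlap` a fragment touching two adjacent ORFs goes to
the larger overlap, ties to the lexicographically smaller gene id. Pairs
matching no ORF land in an intergenic tally, so genes + intergenic always
equals retained pairs (a conservation law the tests assert). Gene models
are kept 0-based half-open internally; GFF3 is converted on read.

# Normalisation and the state call

Three transforms are provided, each returning a provenance-tagged matrix
whose transform chain can be replayed bit-identically from the source
counts:

* **library-size**: counts / retained pairs × 10⁶. The per-million scale is
  for readability only; it cancels in every downstream ratio and
  resemblance (asserted by test).
* **rpoB**: counts divided by the host RNA-polymerase-B count in the same
  sample, a proxy for host cell density. Samples with zero rpoB cannot be
  normalised and are excluded with a logged reason rather than
  pseudocounted — consistent with the negligible-expression rule below.
* **log2(x + 10)** and **square root**, used ahead of correlation and
  Bray-Curtis respectively.

Samples are first screened for negligible expression: excluded iff the
phage-gene pair total is strictly below `min_total_pairs` (default 10 — the
smallest total at which a marker ratio has any resolution) or rpoB is zero.
The threshold is a declared stand-in: the qualitative criterion it encodes
("negligible expression of phage and host genes") has no published numeric
form.

The state call is the sign of
`log2((e(gp091) + ε) / (e(gp135) + ε))` on normalised expression, with an
optional indeterminate band around zero (default width 0). The pseudocount
ε is half the smallest nonzero value in the matrix, so zero-vs-zero gives
ratio 0 and the sign is otherwise untouched; the *gp136* ratio is reported
alongside as the secondary lysogeny marker. Swapping marker roles negates
every ratio and swaps the calls (an antisymmetry the tests assert).
Marker–marker correlations are Pearson on log2(x + 10) absolute abundances,
with two-sided p from the t distribution on n − 2 df; a seeded permutation
p (B = 9999) is available for small n. Constant rows are flagged undefined
rather than given a coefficient.

# Co-expression and branch collapse

Whole-genome co-expression uses the Pearson coefficient as the index of
association, significance edges at p ≤ 0.1, and agglomerative clustering on
`d = 1 − ρ`. Average linkage (UPGMA) is the default — the common default of
the ordination software family this analysis mirrors — with complete
linkage available; genes are sorted lexicographically first so the merge
structure is deterministic and order-invariant. Zero-variance genes are
removed (logged) before association since their correlation is undefined.

"Statistically indistinguishable" branches are collapsed by a SIMPROF-style
permutation test applied top-down. At a node with member expression
profiles, the statistic is

π = mean | ρ_ij − mean(ρ) | over within-node pairs,

i.e. the dispersion of the within-node pairwise correlations, and the null
is built by permuting each member gene's sample values independently
(B ≥ 99, seeded; p = (1 + #{π_b ≥ π_obs}) / (B + 1)). Homogeneity is the
null: a node collapses when no internal heterogeneity is detected
(p > α, default α = 0.05, kept separate from the 0.1 edge cutoff), and
descendants of collapsed nodes are not tested, so collapse is hierarchical
by construction. This construction was a genuinely open design point — the
source workflow names only a clustering function and a p cutoff. A
dispersion statistic was chosen over a mean-association statistic
deliberately: a node of near-copies of one pattern has *strong* association
but *low* dispersion, and must collapse; a node mixing anti-correlated
blocks has high dispersion and must split; and independent-noise members
(no structure at all) collapse with probability ≈ 1 − α, which is the
correct behaviour when "indistinguishable" is the null hypothesis. A
mean-association statistic would reject exactly the nodes that ought to
collapse. One consequence: at α = 0 nothing is ever rejected, so the root
collapses into a single group; at α = 1 every node is rejected and only
leaves remain.

# Ordination and environmental drivers

Bray-Curtis dissimilarity is computed on library-size-normalised,
square-root-transformed phage expression (samples as columns). A pair of
all-zero samples is defined as distance 0 with a warning.

The nMDS is Kruskal's: minimise stress-1,
`sqrt( Σ (d*_ij − d̂_ij)² / Σ d*_ij² )`, where d* are configuration
distances and d̂ the isotonic regression of d* on the dissimilarity order
(primary treatment of ties: tied dissimilarities ordered by current
distance). Updates are Guttman transforms with step-halving backtracking,
so the recorded stress trace is non-increasing — if no step improves,
the restart stops. The first restart starts from classical metric scaling
(a good basin for near-metric data), the remainder from seeded random
configurations; the best restart is reported with its trace and the full
per-restart stress vector. The final configuration is centred, scaled to
unit RMS (stress-1 is scale-free, so the scale is a display convention),
rotated to principal axes and sign-fixed, which pins down the
rotation/reflection indeterminacy for reproducible tests. Strongly
clustered data (e.g. high fold-change synthetic data) can reach near-zero
stress with a nearly collapsed second axis; environmental vector fitting
therefore drops axes whose spread is below 10⁻⁴ of the leading axis before
regression, so directions are not driven by numerical dust. Vectors are
least-squares fits of each standardised variable on the remaining axes
(length = multiple correlation R, permutation p by shuffling the variable,
seeded).

BEST is implemented as exhaustive BIOENV, not stepwise: with at most ~18
candidate variables and subsets capped at `max_subset_size`, full
enumeration is affordable and is its own oracle (the suite checks it
against an independently coded brute-force enumerator). Environmental
variables are z-scored; subset distance is Euclidean; agreement is Spearman
with average ranks. The global p permutes sample labels of the
environmental table and re-runs the *entire search* per permutation,
comparing maximal correlations — this accounts for selection over subsets,
which a naive per-subset permutation would not. Missing environmental
values are refused, never silently pairwise-deleted.

The similarity contours drawn on published ordination figures are reduced
to their tabular content: group membership from average-linkage clustering
of the same resemblance matrix cut at 40/60/80% similarity.

# The synthetic-data generator

The generator defines the study conditions the tests run under:

* **Design**: 33 usable samples (7 stations × 5 bloom months), paired-end
  125 bp libraries of 10⁵–10⁶ read pairs; a 184-gene phage genome plus a
  host genome containing *rpoB*.
* **Blocks**: each phage gene belongs to one of three co-expression blocks
  — lysogeny (12 genes incl. *gp135*, *gp136*, *gp031*, *gp032*, *gp171*,
  *gp067*), packaging/lysis (60), replication/structural (112 incl.
  *gp091* and its tail/head partners) — the 12/60/112 split mirroring the
  three major clusters of the genome-wide dendrogram the pipeline targets.
* **States and environment**: 17 limnological variables from a multivariate
  normal with exchangeable correlation 0.3 (real sonde/nutrient tables are
  collinear; BEST must discriminate correlated candidates), rescaled to
  realistic units; P(lysogenic) = logistic(intercept + β·z(env)) with
  default β = (+1.5 on pH, −1.5 on TDS), the two directions the analysis is
  designed to detect.
* **Counts**: NB(mean = libsize × baseline × fold, dispersion 0.3), the
  lysogeny block up-regulated `state_fold_change`-fold in lysogenic
  samples, the other two phage blocks in lytic samples, host genes flat.
  Fold effects are only ever *up* in one state, matching how marker
  dominance flips. Baselines are log-normal (σ_log = 1) for dynamic range;
  the three marker genes use a reduced spread (σ_log = 0.25) because the
  observed lytic ratio range in the field (≈1.2- to 79-fold) is centred
  near the pure state effect, implying near-balanced marker baselines;
  *rpoB* gets a 10× boost so host normalisation is stable. No published
  count-noise model exists for these libraries; fixed-dispersion NB is a
  declared stand-in.
* **Reads**: every counted pair becomes a proper SAM pair fully inside its
  source ORF (fragment 250–500 bp, `NM` from binomial substitutions), so
  error-free, decoy-free fixtures re-quantify *exactly*. Decoy pairs
  (cross-genome, identity 0.85, or 80%-length alignments) carry their truth
  label in the `ZD` tag, enabling exact filter accounting without side
  files.

What the generator does *not* emulate: rRNA contamination, per-cycle
quality profiles, mapper-specific alignment artefacts, genuinely continuous
(mixed-infection) states, and spatial/temporal autocorrelation between
samples. Passing tests therefore demonstrate correctness of the inference
machinery under the declared model, not robustness to every artefact of
real libraries.

# Numerical choices and problem sizes

Tolerances: filter fractions are compared with ≥ (a record at exactly 0.9
passes); the negligible threshold is strict <; stress convergence stops
when the per-iteration improvement falls below 10⁻⁷; collapse requires
B ≥ 99 permutations for usable null resolution. Test problem sizes were
chosen as the smallest that exercise each property cleanly: round trips on
4 samples × 44 genes; state recovery at the full 33-sample design over 20
seeds; correlation calibration on 2000 null pairs; block recovery on 150
genes; BIOENV oracle equivalence on 5 variables × 12 samples × 50
instances; the end-to-end ordination/BEST link over 25 seeded runs.

# Known limitations

* The classifier is transcriptional only; it cannot distinguish true
  lysogeny from free IS607 activity, and no DNA-level integration evidence
  is modelled.
* Pipeline defaults feed library-size-normalised log2 expression to the
  clustering stage; whether the original workflow clustered raw,
  library-size- or rpoB-normalised counts is not documented, so the choice
  is config-overridable.
* The permutation collapse test treats samples as exchangeable; temporal
  autocorrelation would make it anti-conservative on real time series.
* BIOENV reports rank correlation, not variance explained; no
  PERMANOVA-style partitioning is attempted.
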