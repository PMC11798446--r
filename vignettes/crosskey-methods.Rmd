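---
title: "Methods: platform-independent key-gene identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: platform-independent key-gene identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosskey)
```

## The problem and the pipeline

Case/control expression studies of the same disease are routinely spread
over several measurement platforms whose gene universes overlap but do not
coincide. The common practice of intersecting per-dataset differentially
expressed gene (DEG) lists silently discards any gene that a single platform
fails to measure, or fails to call, anywhere — which is exactly the kind of
gene a cross-platform study is supposed to rescue. crosskey implements the
opposite construction: per-dataset DEG calling, then **unions** within each
platform (icDEGs) and across platforms (gcDEGs), followed by filters that
restore specificity:

1. **Differential expression, per dataset.** Log2 scale (auto-detected),
   quantile normalization, an empirical-Bayes moderated two-group t-test,
   Benjamini–Hochberg adjustment, probe-to-gene collapsing, and the
   thresholds |log2FC| ≥ 1.2 and adjusted p < 0.01.
2. **Set algebra.** icDEGs = union over a platform's datasets; gcDEGs =
   union over platforms. A gene called anywhere survives to the next stage
   (the "necessity" guarantee: unions never lose a candidate).
3. **Discriminative filter.** Each gcDEG is scored by a single-feature SVM
   (RBF kernel): best 5-fold cross-validated accuracy on a stratified 80%
   training split, grid-searched over cost and gamma, averaged across the
   datasets that measure the gene, selected when the mean strictly exceeds
   0.95.
4. **Network evidence.** A protein–protein interaction graph over the
   selected genes (edge confidence ≥ 0.70), hub ranking by maximal clique
   centrality (MCC), and dense-module detection with MCODE
   (degree cutoff 2, node score cutoff 0.2, k-core 2, max depth 100);
   modules with score ≥ 6 and ≥ 6 nodes contribute their genes.
5. **Literature evidence.** The union of hub genes reported by prior
   studies (meta-hub genes), from a curated table with an explicit alias
   map for typographical variants.
6. **Key genes.** The intersection of the three evidence streams: MCC
   hubs ∩ module genes ∩ meta-hubs. Although the three streams are
   *combined*, key genes are by definition *common* to all three, so the
   final operation is an intersection — the union reading would return the
   whole evidence pool and make the final filter vacuous.
7. **Validation.** Per key gene: rank AUC (equivalent to the univariate
   logistic model's ROC AUC), median-split Kaplan–Meier curves with a
   log-rank test, and a univariate Cox proportional-hazards fit.

## Statistical details

**Moderated t.** For probe $g$ with pooled residual variance $s_g^2$ on
$d_g = n_1 + n_2 - 2$ df, the posterior variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and
$t_g = \overline{x}_{case} - \overline{x}_{ctrl}$ divided by
$\tilde s_g \sqrt{1/n_1 + 1/n_2}$, referred to a Student t with
$d_0 + d_g$ df. The hyperparameters $(d_0, s_0^2)$ are the closed-form
moment estimates obtained by matching $\log s_g^2$ to a scaled F
distribution (computed with `limma::fitFDist`, which implements exactly
that estimator, including the $d_0 = \infty$ branch when the moment
equation has no finite solution). The whole path is cross-checked against
`limma::lmFit`/`eBayes` in the test suite. Fold-change direction is fixed
as case minus control.

**Quantile normalization** uses the tie-averaging variant: tied values
receive the mean of the quantile means they span
(`limma::normalizeQuantiles(ties = TRUE)`). Normalization happens per
dataset, before probe filtering; scale auto-detection treats a matrix
whose maximum exceeds 100 as linear intensities (`log2(x + 1)`), with an
override for pre-logged data.

**Probe collapsing** keeps, per gene symbol, the probe with the smallest
adjusted p-value; exact ties go to the lexicographically smallest probe
id. Blank-symbol probes are dropped. Collapsing happens *after* testing
because the selection criterion is the probe's adjusted p.

**SVM scoring.** Features are standardized on each training fold (RBF
kernels are scale-sensitive). The default grids are
C ∈ {0.1, 1, 10, 100} and γ ∈ {0.001, 0.01, 0.1, 1}. The reported score
is the best cross-validated accuracy on the 80% split; the 20% hold-out
accuracy is computed and attached as an attribute but plays no role in
selection, since the selection rule is defined on the CV accuracy. Fold
assignments derive from a hash of (seed, dataset, gene symbol) and from
sample *ids*, so results are identical under any evaluation order or
column permutation. Note that a best-over-grid CV accuracy is an
optimistically biased estimate of generalization accuracy; it is used
here as a ranking score, not as an error estimate.

**MCC** of a vertex $v$ is $\sum_{C \ni v} (|C| - 1)!$ over maximal
cliques $C$ of size ≥ 2 (vertices in none score 0); on triangle-free
graphs this equals the degree. Enumeration uses the pivoted
Bron–Kerbosch algorithm (via igraph) behind a configurable clique budget
(default $10^6$) that errors rather than truncating. The implementation
is tested against a brute-force subset-enumeration oracle on random
graphs with up to 12 vertices.

**MCODE.** Vertex weight = (highest k-core level of the closed
neighborhood) × (density of that core), zero when the degree is below 2
or the core level below the k-core floor of 2. Seeds are taken in
decreasing weight; breadth-first expansion admits unvisited neighbors
with weight ≥ 0.8 × seed weight (node score cutoff 0.2) up to depth 100;
haircut removes degree-1 members; fluff is off. A module's score is its
density times its node count, with density computed over **ordered**
vertex pairs ($2e/(n(n-1))$), so a complete module on $n$ nodes has
$2\binom{n}{2} = n(n-1)$ edges by that convention and scores exactly
$n$ — a complete 7-node module reports 42 edges and score 7.0. Modules
need score ≥ 6 and ≥ 6 nodes to contribute genes.

**Survival.** Kaplan–Meier, log-rank, and Cox fits are delegated to the
survival package (Breslow tie handling for Cox). The median split sends
values strictly above the cohort median to "high", ties to "low". Risk
groups derive purely from expression, never from outcome. The rank AUC
is computed by pair counting via the rank-sum identity; for one
covariate this is identical to the logistic-model ROC AUC, which removes
an optimizer from a deterministic quantity (the equivalence is asserted
against pROC in the tests).

**Over-representation.** Hypergeometric upper tail per term against a
user-supplied collection, BH across the collection's terms;
significance is flagged on the raw p < 0.05 with adjusted values
reported alongside. The default universe is the union of genes measured
across the analyzed datasets, not the genome.

## The literature table and its counts

The packaged snapshot (`hcc_literature_hubs()`) transcribes 48 prior
hub-gene studies verbatim, including typographical variants; a separate,
human-reviewed alias map resolves the evident ones (e.g. DK1 → CDK1,
RACGAP → RACGAP1, BBCL2 → BCL2, and one fused token expanded to two
symbols). Because a published total may count raw tokens or corrected
symbols, `meta_hub_union()` reports three numbers: unique raw tokens
(148 here), unique normalized symbols (137), and distinct normalized
tokens including unresolved fragments (138). One token — a stray "C"
split off a neighboring symbol — cannot be resolved and is flagged
rather than dropped.

## The synthetic generator

`synth_config()` describes a study with three platforms sharing a
150-gene core out of 200 genes each, two datasets per platform with 30
samples per group, twelve planted genes at log2 effect ±3 against
Gaussian noise of SD 0.5 (a 6σ separation, so planted genes should
saturate every filter), one to three probes per gene with 10% of
annotations blanked, a planted 7-gene near-clique (edge probability 1,
confidence ≥ 0.9) in a sparse background network (edge probability
0.005, confidence Uniform(0.2, 0.95)), a 300-subject survival cohort
whose exponential hazard has log-slope 0.7 per unit expression of a
designated planted gene with ~30% uniform censoring (the censoring
horizon is solved numerically to hit that rate approximately), and a
ten-study literature table covering all planted genes plus decoys
absent from every universe.

Choices worth noting:

- Per-gene baselines are drawn once per platform from Uniform(4, 10) on
  the log2 scale, so platforms differ in absolute level without an
  explicit batch model.
- Every artifact draws from its own RNG stream derived from the master
  seed by a documented string hash (`stream_seed()`), so artifacts are
  independent and byte-identical across reruns regardless of generation
  order.
- Blank annotations are assigned only among zero-effect genes; blanking
  a planted gene's only probe would silently change the ground truth.
- Quantile normalization interacts with planted effects: when a large
  fraction of a small universe is shifted, the forced common
  distribution compresses the observed fold changes below the planted
  ±3. At the default 12/400 probes the attenuation is mild; in the
  deliberately small test universes a planted gene occasionally drops
  below the fold-change cutoff in one dataset — which is precisely the
  loss mode the union construction rescues, and the tests assert the
  rescue rather than pretending the loss cannot happen.

What the generator does **not** emulate: probe-level microarray physics
(intensity distributions, background correction), batch effects,
correlated co-expression structure, or realistic PPI topology beyond
"dense planted module in sparse background". Passing the end-to-end
test therefore shows the pipeline's logic is correct under its own
assumptions, not that the thresholds are well calibrated for any real
platform.

## Problem sizes and tolerances in the test suite

Unit tests run on hand-sized fixtures with closed-form expectations
(quantile normalization on a 2×2 matrix; moderated t with fixed
$d_0 = 4$, $s_0^2 = 1$; log-rank on four subjects; hypergeometric
5/210). Property tests use reduced synthetic universes (60 genes, 10-20
samples per group) so the SVM stage stays fast; the end-to-end recovery
check runs the full default configuration. Simulation-level guarantees
use 1000 null replicates for the log-rank type-I error (accepted band
0.03-0.07), 100 replicates at n = 500 for Cox CI coverage (≥ 90%), and
20 seeds for the planted-vs-null separation of the SVM filter (all
planted selected, ≥ 95% of nulls rejected). The null accuracy band for
label-independent genes ([0.30, 0.80], mean in [0.45, 0.65]) was frozen
from a 50-seed simulation of the same estimator; it sits above 0.5 on
average because a maximum over a 16-point hyperparameter grid is
optimistically biased.

## Known limitations

- The pipeline is two-group only: no covariates, no multi-factor
  designs, no array-quality weights.
- Set algebra carries no effect sizes across datasets — there is no
  pooled log2FC or random-effects meta-analysis; a gene up in one
  dataset and down in another is retained with direction "discordant".
- MCC is computed on the full network (not per component), and clique
  enumeration is exponential in the worst case; the budget makes the
  failure explicit.
- The meta-hub stream depends entirely on the curated table; no
  literature mining is attempted.
- Single-covariate, in-sample AUC is reported; no train/test protocol
  is applied at the validation stage.
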