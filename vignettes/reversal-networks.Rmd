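---
title: "Reversal screening and network module integration for three-group multi-omics studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reversal screening and network module integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revnet)
```

## The study design this package analyses

revnet targets a common pharmacology design: a *control* group, a
*disease model* group, and a *treated* group (disease model receiving a
candidate drug), each profiled on several omics layers — transcripts,
proteins, metabolites. The scientific question is not merely "what is
dysregulated in disease?" but "which disease-associated changes does the
treatment undo?". The analysis therefore proceeds in two contrasts per
layer: model vs control (the disease signature) and treated vs model
(the treatment response), and the features of interest are those
significant in both with opposite fold-change signs — the *reverted*
features. Their interactome neighborhoods, detected as dense modules and
compared across layers with a network-separation score, nominate the
mechanism.

## Differential screening

Each layer is screened feature-by-feature on the log2 scale. The fold
change is the difference of group means of log2 values (not the log of
the ratio of arithmetic means — the data are modeled as log-normal, and
all downstream statistics operate on the log scale). The test is Welch's
unequal-variance *t* by default; with five samples per group no
dispersion sharing across features is attempted, and Student's pooled
test is available as an option. A feature is *called* when |log2FC| >
1 and raw p < 0.05 — the raw p, not the Benjamini–Hochberg q, is the
criterion; q-values are reported for transparency. Features constant in
both groups get p = 1 when the means agree (and the smallest
representable p when they disagree, a case that cannot arise under the
generator's continuous noise).

Raw counts are never transformed silently: `log2_transform()` applies
log2(x + 1) and must be called explicitly.

## OPLS-DA and the VIP criterion for metabolomics

The metabolite layer uses orthogonal projections to latent structures
discriminant analysis. After per-feature mean-centering and
unit-variance scaling, class-orthogonal variation is removed by the
classical deflation scheme — per orthogonal component, the weight
vector is the loading minus its projection onto the predictive weight,
and the data are deflated by the resulting score/loading pair — before
a single predictive PLS component is extracted. With one predictive
component the VIP of feature *j* reduces to √p·|w_j| (p features,
normalized weights), which makes mean(VIP²) = 1 an exact identity and
"VIP > 1" the natural above-average-influence cut.

Fit quality is summarized by R²Y and by Q² from 7-fold cross-validation.
Folds are assigned deterministically: samples are shuffled within class
under the model seed, interleaved by class, and dealt round-robin, so
folds stay class-balanced and every fit is reproducible. Permutation
validation refits the model under label shuffles and reports
(1 + #{Q²_perm ≥ Q²_obs}) / (n_perm + 1). With only five samples per
class, roughly one random permutation in 126 reproduces the true
labeling or its complement, so occasional high permuted Q² values are
expected and the empirical p has a resolution floor of 1/(n_perm + 1).

The metabolite selection criterion is VIP > 1 together with raw p <
0.05 from the univariate Welch screen of the same contrast
(`vip_criterion()` re-flags a differential table accordingly); the
reversal step below then treats the layer exactly like the others.

## The reversal screen

`find_reverted()` intersects the two contrasts: significant in both,
with opposite fold-change signs. This is deliberately the weaker of the
plausible operationalizations — it does not require the treated group
to land back at control levels, only a significant opposite movement.
A stricter mode (`min_restore`) additionally requires the restoring
change to reach a chosen fraction of the disease change; it is off by
default because the magnitude-of-restoration requirement is an
assumption the default analysis should not impose.

## MCODE-style module detection

Reverted features are projected onto a user-supplied interactome (TSV
edge list; STRING exports work directly, and an optional confidence
cut-off is applied at load time). Modules are detected with the
three-stage MCODE scheme: vertex weighting by the highest k-core of the
closed neighborhood times that core's density; greedy seeded expansion
admitting neighbors whose weight reaches (1 − node_score_cutoff) of the
seed weight; then a 2-core filter and the haircut.

One behavior deserves emphasis. Under the canonical weighting, the two
endpoints of a bridge between two equally dense complexes carry the same
weight as complex-interior vertices, so a purely weight-gated expansion
walks across the bridge and merges the complexes no matter how the
cutoff is set. This package therefore applies the haircut rule *during*
expansion as well: once a complex has at least two members, a candidate
connected to it by a single edge is refused. Such a candidate would be
shaved off by the post-hoc haircut anyway; refusing it up front also
prevents the complex from leaking through bridge edges, so two dense
blocks joined by one edge are reported as two modules. With `haircut =
FALSE` the classical merging behavior is recovered. All ties — seed
order, candidate order, module order — are broken lexicographically, so
detection is invariant to vertex-insertion order.

Hubs within a module are ranked by degree in the module-induced
subgraph (ties lexicographic). Degree is a documented stand-in for
fancier centrality scores; with modules of a few dozen nodes the top
ranks rarely differ.

## The separation score S_AB

For modules A and B on one shared graph,

S_AB = ⟨d_AB⟩ − (⟨d_AA⟩ + ⟨d_BB⟩) / 2,

with hop-count shortest paths (edge confidences are treated as
confidences, not lengths). ⟨d_AA⟩ averages, over members of A, the
distance to the nearest *other* member; a singleton's within-distance is
0 by convention — conservative, since it never inflates apparent
synergy. ⟨d_AB⟩ averages, over all members of A and B, the distance to
the nearest member of the other set, *excluding self-pairs* for nodes
the two sets share. The self-exclusion makes S_AA = 0 an exact
algebraic identity.

A consequence worth knowing when reading results: for two disjoint
connected modules every member has an in-module neighbor, so ⟨d_AA⟩ =
⟨d_BB⟩ = 1 and S_AB = ⟨d_AB⟩ − 1 ≥ 0. The score therefore floors at 0,
attained exactly when every member of either module sits adjacent to
(or inside) the other — the "same neighborhood" situation. Under the
self-inclusive convention used elsewhere in the network-medicine
literature, overlapping sets push the score negative but a module is
then not at separation zero from itself; the two properties are
mutually exclusive, and this package chooses the self-consistent S_AA =
0. Interpretation is unchanged: the most synergistic pair is the matrix
argmin, and values at or near the floor mean interleaved neighborhoods.

Distances are undefined across connected components, so
`separation_matrix()` restricts to the largest component, reports
dropped nodes, and flags any module losing more than half its members
as unevaluable (NA row/column) rather than imputing an arbitrary large
distance.

## Over-representation analysis

Enrichment of any feature set against user-supplied GMT collections is
a one-sided hypergeometric test: with N universe features, K in the
set, n in the query and k overlapping, p = P(X ≥ k). The universe
defaults to the union of all collection members; query and sets are
intersected with it first, so out-of-universe identifiers can never
influence a record. BH correction is applied across the tested sets.
Database content is always an input — nothing is bundled or fetched.

## The synthetic-data generator

Because the emulated study deposits no raw data, every stage is
exercised on synthetic data with planted truth. The generator draws
per-feature baselines uniformly on log2(8–12), perturbs a fraction of
features in the model group by ±effect_log2, returns a sub-fraction to
the control mean in the treated group (reversed) while the rest keep
the model mean (persistent), and adds Gaussian log2-scale noise —
i.e., log-normal abundances. Defaults are five samples per group (the
emulated design), effect 3 log2 units and noise SD 0.3; the source
study reports no per-layer dispersions or effect distributions, so
these are stated choices of a clearly detectable planted signal at
n = 5, not fitted values. Interactomes come from a stochastic block
model — planted dense blocks over a sparse background — because
planted blocks give MCODE a ground truth; cross-block and background
pairs use the mean of the endpoints' between-block probabilities.

`simulate_study()` assembles a full on-disk study: three layers, a
shared interactome whose planted blocks include one *mixed* block of
reverted genes and reverted proteins interleaved in a single dense
neighborhood (the planted synergistic pair), a small GMT collection
with the planted sets, and a ready `config.yaml`. The pipeline's
problem sizes — 300/300/120 features, 5 samples per group, blocks of
16/32/16 nodes — keep a full run in the low seconds while leaving the
planted structure unambiguous.

What passing these tests shows — and does not show. The generator
emulates group structure, planted effects and modular topology; it does
not emulate count overdispersion, missing values, batch effects,
correlated features within pathways, or the identifier-mapping mess of
real STRING exports. Recovery rates on synthetic data are a correctness
check of the machinery, not a performance claim about real studies.

## Numerical and degenerate-input choices

* Zero-variance features: rejected by OPLS-DA with the offending ids
  named; given p = 1 (equal means) in the Welch screen.
* PCA: SVD of the column-centered matrix; all-constant input is an
  error, not a silent zero.
* BH q-values: `stats::p.adjust`; tests verify them against a
  brute-force step-up oracle.
* Empty reverted sets summarize to zero counts without division errors;
  an edgeless graph yields an empty module set; an empty module set is
  an error for the separation matrix (there is nothing to compare).
* All RNG use is seeded and restores the caller's RNG state; identical
  seeds give bit-identical datasets, graphs and pipeline summaries.

## Pipeline and configuration

`run_pipeline()` executes screen → OPLS/VIP → reversal → induced
subnetworks → MCODE per layer (labels A1…, B1…) → S_AB matrix → best
pair → hubs → ORA, writing TSVs, a JSON summary, a stage log and a
MANIFEST with MD5 content hashes. Configuration is YAML;
`validate_config()` collects *all* problems before failing and
suggests near-miss key names. Stage order is fixed; only enrichment is
skippable (it is the only stage requiring an external collection).

## Known limitations

* Significance of S_AB values is not assessed against degree-preserving
  randomizations; only the sign/minimum is used.
* No count-model screening (negative binomial, dispersion shrinkage) —
  the Welch test on log2(x+1) is deliberate for the 5-per-group design,
  but underpowered relative to count models on real RNA-seq.
* Identifier matching between layers and the interactome is exact
  string matching; no orthology or id-conversion service is consulted.
* Multi-class OPLS-DA and ranked (GSEA-style) enrichment are out of
  scope.
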