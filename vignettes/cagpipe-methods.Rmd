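---
title: "cagpipe: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cagpipe: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagpipe)
```

`cagpipe` implements the downstream half of a longitudinal
gut-microbiome succession analysis over a shotgun gene catalog: the
study design it models follows a litter of giant-panda cubs through
three age windows (C0: 0–1.5 months, C1: 1.5–6, C2: 6–9) together
with the father (F) and mother (M), 33 fecal samples in all
(5/9/8/5/6 per group). This vignette explains each stage's model and
assumptions, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was open.

## Taxonomic profiles and diversity

Gene-to-taxon aggregation is a pure group-by sum: a taxon's abundance
in a sample is the sum of its assigned genes' abundances, with genes
unclassified at the requested rank pooled into an `Unclassified` row
so that column mass is conserved exactly. Filtering removes a taxon
only when its relative abundance is *strictly below* 1e-8
(`abundance_floor`) in *every* sample; a taxon at the floor in one
sample is kept everywhere, so filtering never creates ragged profiles.

Shannon diversity uses the natural logarithm, and Pielou evenness is
defined consistently as `J = H / ln S` (undefined, `NA`, for
single-taxon samples) — the internal consistency of the pair is the
reason for fixing the base. Chao1 is the bias-corrected estimator
`S_obs + F1(F1-1)/(2(F2+1))`, which is finite when no doubletons
exist and reduces to observed richness without singletons.
Rarefaction resamples reads *without replacement* (hypergeometric),
10 resamples per depth by default; its mean richness is testable
against the closed form `E[S_d] = Σᵢ (1 − C(N−nᵢ, d)/C(N, d))`.

The Whittaker index `β_w − 1 = S_union/ᾱ − 1` is a presence/absence
measure; "presence" means relative abundance at or above the same
1e-8 floor. Because a weighted ordination of such a matrix is often
wanted, `whittaker_distance(weighted = TRUE)` switches to the
proportional-difference form `Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`; the default stays
presence/absence, honouring the index's standard definition, and the
switch is recorded in the run configuration. PCoA is classical
scaling of `−D²/2`; negative eigenvalues (expected, since β_w is not
Euclidean) are reported untouched — no Lingoes/Cailliez correction —
and excluded from the variance-explained denominator. PERMANOVA uses
Anderson's pseudo-F with `p = (1 + #{F* ≥ F}) / (1 + n_perm)`;
999 permutations by default, so the attainable floor is p = 0.001. A
degenerate all-zero distance matrix returns `R² = 0, p = 1` with a
warning rather than an error, so synthetic edge cases cannot crash a
pipeline run.

## Canopy clustering, CAGs and MGS

The co-abundance model assumes genes residing on one genome scale
together across samples, so the Pearson correlation of abundance
profiles (PCC) is the natural similarity and `1 − PCC` the clustering
distance. Canopy clustering iterates genes in a seeded-random order;
each unassigned gene seeds a canopy that captures all unassigned
genes at PCC ≥ 0.90 (`canopy_capture_pcc`), then refines its profile
as the per-sample median over members and re-gathers membership until
a fixed point, at most 5 iterations (a bound that in practice is
never hit on synthetic data but keeps the runtime predictable).
Canopies whose median profiles correlate above 0.97 merge into one
CAG by single linkage — the simplest rule consistent with "merge
correlated canopies", and the threshold is read as *correlation*
above 0.97 (distance below 0.03), since merging at correlation
*below* −0.9 would join anti-correlated canopies and contradict
co-abundance. CAGs with strictly more than 20 genes are flagged MGS;
a CAG is labelled with its modal species only when that species
covers at least half of the member genes, otherwise `group`; ties at
exactly one half resolve lexicographically with a warning. Genes with
zero variance, or zero in more than 90% of samples, are excluded from
clustering (PCC on near-constant vectors is unstable) and listed in
the run report.

Significance screening contrasts two pooled classes (e.g. C0+C1 vs
C2): per member gene a two-sided Wilcoxon rank-sum test, Holm
adjustment across all tested genes, retention of genes with adjusted
p < 0.05; each CAG is collapsed to the per-sample median of its
retained genes, scored with the LDA effect size, and reported at
|score| ≥ 2.0 with a CAG-level Holm-adjusted q-value. At these group
sizes (pooled n of 11–22) the Wilcoxon p-value is computed by exact
enumeration — the convention `stats::wilcox.test` applies below n =
50 — because the exact tail (minimum p ≈ 2/C(22,8) ≈ 6e-6) is what
allows any single gene to clear a Holm family of thousands; the
normal approximation's floor (~1e-4) cannot, and would silence the
stage entirely. The standalone `wilcoxon_rank_sum()` operation
defaults to exact enumeration up to a pooled size of 12 and the
tie/continuity-corrected normal approximation beyond, with the
threshold exposed.

## LDA effect size

The biomarker score is a reimplementation of the LDA-effect-size idea
for a flat design: the study's groups have no subclass structure, so
the within-class subcondition stage is omitted. Features first pass a
Kruskal–Wallis filter at α = 0.05. Surviving features are placed on
the `[1, 1e6]` relative scale — fractional abundances are multiplied
by 1e6 (the per-million convention); matrices already on an absolute
scale are scored as-is. Over 30 stratified bootstrap resamples a
one-dimensional discriminant between the two classes is evaluated per
feature (for a single feature the discriminant axis is the feature
itself, so the class difference of the projection is the scaled mean
difference), and the reported score is the bootstrap median of
`log10(1 + |difference|)`, signed by enrichment direction. Doubling a
feature's values can raise its score by at most `log10 2`, which
anchors the scale's interpretation.

## Keystone discovery

Two independent lines of evidence are intersected. First, "stable"
genera — present in strictly more than 70% of samples — form a
Spearman correlation network; edge significance uses the t statistic
`t = ρ√((n−2)/(1−ρ²))` on n−2 degrees of freedom, two-sided, pruning
edges with p > 0.05 (a perfectly monotone pair gets the enumeration
bound `2/n!`, flagged exact); hub genera have strictly more than 30
connections in the pruned network. Second, a 500-tree random forest
classifies samples into the five age groups from genus abundances;
the out-of-bag error rate summarises accuracy and the mean decrease
in Gini ranks genera, of which the top 20 are kept. The shared set —
hubs that are also top-20 — is the keystone call, in forest rank
order. Spearman ties take average ranks (abundance data contain
zeros); class imbalance is left unweighted. The forest size of 500
follows the convention for stabilising Gini rankings at small n.

## The synthetic-data generator

`simulate_catalog()` plants `n_species` species (default 60), each a
contiguous block of genes (15–40) sharing one lineage, plus 20%
background genes with unclassified lineage, and annotations drawn
from small fixed vocabularies (60% of genes annotated; each species
favours a 3-pathway repertoire so host attribution has signal).
`simulate_abundance()` renders a gene's abundance as

    latent(species, sample) x size(gene) x lognormal noise(cv)

where the latent trajectory is
`base(species) x fold(species, group) x lognormal(trajectory_cv)`.
With `gene_noise_cv = 0` the genes of one species are exactly
proportional — the noiseless limit canopy clustering assumes; the
default cv of 0.1 leaves within-cluster PCC far above the capture
threshold, and recovery degrades gracefully as cv grows.

Group effects encode a cub-to-adult succession gradient with group
scores (C0 −1, C1 −0.4, C2 +1, F/M 0): a "block" of 70% of species
loads on it with strength 0.3–0.5 and random sign, which makes block
members mutually rank-correlated across 33 samples — the
connectivity that hub detection needs. The planted keystone genera
(default 5) are block members with the strongest loading (0.8, i.e. a
C0→C2 fold change of ~5, comfortably above the 4-fold truth
invariant) and are drawn as abundant core members (upper half of the
base-abundance distribution, shifted up 0.3 log units) — in real cub
communities the structurally important genera are dominant ones, and
a planted keystone must be distinguishable from the background block
for recovery to be a meaningful test.

Structural zeros follow a detection-limit model: a species is absent
from a sample when its latent log abundance falls below a global
detection threshold calibrated so that community-wide presence equals
`occupancy` (default 0.95). One draw per taxon and sample; rare taxa
blink out, dominant taxa never do, and group fold changes move taxa
across the limit — which is exactly why the presence/absence
Whittaker ordination sees the group structure. With
`base_abundance_sdlog = 0` (a homogeneous community) the model
reduces to an exact per-taxon Bernoulli(occupancy), the setting the
occurrence-filter calibration tests use. With `occupancy = 1` no
zeros are generated, the setting the cluster-recovery tests use.

What the generator does **not** emulate: sequencing-depth (sampling)
zeros as distinct from structural absence, phylogenetically realistic
lineages (labels are rank-consistent but arbitrary), strain-level
mosaicism within species blocks, compositional interactions beyond
closure, and read-level artefacts. Passing recovery tests therefore
demonstrates correctness of the algorithms under the stated model,
not performance on real sequencing data.

## Problem sizes and runtime

The default design — 33 samples, 60 species, ~2,000 genes — runs the
complete pipeline in a few seconds on one CPU; recovery and
calibration studies in the test suite use 20–50 seeds at the same
scale, and the PERMANOVA type-I study uses 400 null datasets at 199
permutations. These sizes were chosen so the whole suite documents
the statistical behaviour (calibration, power, recovery) at the
study's own n while remaining quick to re-run.

## Known limitations

* The canopy partition depends on the seeded iteration order; two
  orders can split borderline genes differently. Determinism is
  guaranteed for a fixed seed, and agreement with a brute-force
  reference is exact on small inputs, but there is no canonical
  partition for overlapping clusters.
* Holm control across thousands of genes is conservative; at n = 33
  only near-perfectly separated genes survive, so the significant-CAG
  list is short at desk scale. This mirrors the method, not a bug.
* The LDA effect size is a per-feature discriminant, not a joint
  multivariate LDA; features are scored independently.
* PERMANOVA assumes exchangeability under the null; repeated samples
  from the same individual (P3/P4 cubs) are treated as exchangeable,
  as the modelled study did.
* With fewer than ~32 stable genera the over-30-connections hub rule
  is unattainable by construction; the keystone stage then reports an
  empty hub set rather than relaxing the threshold.
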