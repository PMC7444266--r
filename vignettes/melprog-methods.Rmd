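---
title: "Methods: co-expression modules, survival signatures and histone PTM dynamics in a melanoma progression panel"
author: "melprog authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules, survival signatures and histone PTM dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melprog)
```

# The study system

`melprog` analyses stepwise tumour-progression cell-line panels of the kind
used to model melanoma development in the mouse: four states derived from one
melanocyte lineage — non-malignant melanocytes (melan-a), pre-malignant
mesenchymal-like melanocytes (4C), non-metastatic melanoma cells (4C11-) and
metastasis-prone melanoma cells (4C11+) — each profiled in biological
triplicate. Two omic layers are supported: a log-scale normalised expression
matrix (genes x 12 samples) and a histone post-translational-modification
(PTM) peptide-area table from derivatisation mass spectrometry. A third,
independent input is a patient survival cohort used to ask whether genes
highlighted by the panel carry prognostic information.

The four-line design is hard-wired (the phenotype encodings and the
classification rules are defined on exactly these states); the replicate
count is configurable.

# Co-expression network model

The network core follows the unsigned weighted co-expression paradigm.

*Adjacency.* For genes $i, j$ with expression over samples,
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$. The soft threshold $\beta$
(default 10, a positive integer in practice) suppresses weak correlations
while keeping a weighted graph. `pick_soft_threshold()` reports, per
candidate $\beta$, the scale-free model fit — the $R^2$ of the regression of
$\log_{10} p(k)$ on $\log_{10} k$ over ~10 connectivity bins, sign-flipped
when the slope is positive so that maximising it prefers decaying degree
distributions — and the mean connectivity, which decreases monotonically in
$\beta$. The recommended $\beta$ is the smallest one whose signed $R^2$
reaches 0.8 (configurable).

*Topological overlap.* Gene similarity combines direct adjacency and shared
neighbourhoods:
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$
with $\ell_{ij} = \sum_u a_{iu} a_{uj}$. Modules are detected on
$1 - \mathrm{TOM}$ by average-linkage hierarchical clustering.

*Tree cut.* The cut is a dynamic-hybrid-style procedure built from four
stages, each a deliberate design choice:

1. scan ~80 candidate cut heights and keep the height yielding the most
   clusters of at least `min_module_size` (default 50) genes; `deep_split`
   (0-4, default 2) resolves ties towards coarser or finer cuts;
2. accept a cluster only if it is *cohesive*: its mean within-cluster TOM
   similarity must exceed 3x both its mean similarity to the rest of the
   network and the network-wide median similarity (guards against carving
   chance-correlated noise into pseudo-modules);
3. re-cluster the unassigned genes recursively (up to 3 rounds), so modules
   hidden under a coarse first cut are still extracted;
4. PAM-like reattachment: an unassigned gene joins its most similar module
   when its mean similarity there reaches `pam_frac` (default 0.5) of that
   module's internal cohesion.

A plain fixed-height cut (`method = "fixed"`) is available as the simple
fallback. Exact module counts will differ from other implementations of the
same paradigm; the partition-level properties (recovery of planted modules,
size-ordered colour labels, grey for unassigned genes) are what the package
guarantees and tests.

*Eigengenes, merging, membership QC.* A module eigengene is the first right
singular vector of the module's gene-standardised submatrix, oriented so it
correlates non-negatively with the module's mean profile. Modules whose
eigengenes are closer than `merge_cut_height` (default 0.25 on
$1-\mathrm{cor}$) are merged iteratively, recomputing eigengenes after every
merge. Finally `coexpress()` applies a module-membership quality cut: genes
whose absolute correlation with their own eigengene (kME) falls below
`kme_min` (default 0.7) return to grey. The default is strict on purpose: at
$n = 12$ samples, absolute chance correlations around 0.6 are routine, so a
laxer cut (0.3 is common for large cohorts) lets noise genes ride along.
Labels are re-assigned by descending size from the canonical colour sequence
(turquoise, blue, brown, yellow, ...) after every step that changes the
partition.

*Connectivity and hubs.* `intramodular_connectivity()` sums each gene's
adjacency weights inside its own module (kWithin); the 10 top-ranked genes
per module are its hubs, with exact ties broken by gene id. Trait-level hub
subnetworks pool the hubs of the modules associated with a trait, weight
pairs by $|\mathrm{cor}|^\beta$, keep edges above 0.2 and return the largest
connected component.

# Phenotype encodings and module-trait association

Sample phenotypes are encoded numerically: tumour state (4C11-, 4C11+ = 1),
EMT (mesenchymal-like 4C, 4C11- = 1), metastasis (4C11+ = 1) and progression
(1-4 in line order). Eigengene-trait association uses Pearson correlation
with two-sided p-values from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of
freedom; a module is flagged when $|r| > 0.3$ and $p < 0.1$ (defaults), with
a strict preset at $|r| \ge 0.5$. Both cutoff pairs are in circulation for
this kind of analysis, which is why both are exposed. A documented
limitation: replicates are treated as independent samples in the correlation
test, so p-values are optimistic relative to a mixed-model treatment; the
permutation check in the test suite quantifies the remaining approximation
error of the $t$ transform itself.

# Gene-set enrichment and survival screening

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ for a module of $n$ genes overlapping a set with $K$ members in
an $N$-gene universe. The universe defaults to every analysed gene (grey
included) because the filtered gene list is the population actually eligible
for module membership; it is configurable since reasonable alternatives
exist. Raw p-values decide significance at 0.05 (the convention this
analysis style follows); Benjamini-Hochberg adjusted values are reported
alongside. Ortholog maps (two-column tables) are applied before
intersection, dropping unmapped genes with a count message.

The survival layer is classical: median splits (low group takes values at or
below the median — a deterministic tie rule), two-group log-rank tests
(asymptotic $\chi^2_1$, or exact permutation over all relabellings for small
cohorts), and Cox proportional-hazards fits with Efron tie handling. Two
covariate presets mirror common primary-melanoma analyses: MA1 adjusts for
age, sex and tumour site; MA2 additionally for AJCC stage and mitotic rate.
Multi-gene signatures are scored as the mean expression of their genes. The
gene-wise screen records per-gene failures and continues, and its primary
p-value (log-rank for median-split mode) feeds `rank_prognostic_genes()`.

# Histone PTM quantification

PTM tables carry one row per (histone, backbone peptide, modification
string) with one raw area column per sample. The modification grammar is
`<residue letter><position><mark>` tokens concatenated in position order
(`K9me2K14ac`), with marks in {ac, me1, me2, me3, ph} and `unmod` as the
sentinel for the unmodified form; the parser validates tokens against the
backbone range and round-trips to the canonical string. Other layouts can be
adapted via `column_map`.

Relative abundance divides each form's area by the total area of its
backbone in the same sample, so abundances sum to 1 per (histone, backbone,
sample) — asserted to $10^{-9}$ on every run — and are invariant to
per-sample rescaling. Global mark levels sum the relative abundances of all
forms carrying at least one token of a class (union semantics: a form with
two acetyl tokens counts once). Single-mark levels sum over all forms
carrying a specific (histone, residue, mark) token, with a row-wise z-score
variant. Differential testing is one-way ANOVA across the four lines
followed by Tukey HSD (studentised range; Tukey-Kramer when unbalanced) at
multiplicity-adjusted $p < 0.05$.

# Fuzzy clustering of PTM profiles

Combinatorial PTM dynamics are clustered with fuzzy c-means on row-z-scored
profiles: memberships $u_{ik} \propto d_{ik}^{-2/(m-1)}$, centroids as
$u^m$-weighted means, k-means++ seeding with 10 restarts keeping the best
objective. The two auto-estimation rules are this package's own design (the
analysis style they reimplement does not publish its internals):

* fuzzifier $m$ from the dataset dimensions via the minimum-distance
  heuristic for clustering standardised omics profiles,
  $m = 1 + (1418/N + 22.05)D^{-2} + (12.33/N + 0.243) D^{-0.0406\ln N - 0.1134}$;
* cluster number $c$ by scanning 2-12 and keeping the largest $c$ that is
  *admissible*: minimum pairwise centroid separation above `min_sep`
  (default 0.8 on the z-profile scale) and every cluster supported by at
  least 3 confident members (membership > 0.5). The support condition
  matters because an over-split solution often parks a centroid on outliers
  rather than duplicating an existing centroid.

Sample-level structure uses correlation-distance hierarchical clustering
(complete linkage by default), under which epithelial (melan-a, 4C11+) and
mesenchymal (4C, 4C11-) samples separate whenever EMT-patterned forms
dominate.

# Phenotype rules

Each form's significance pattern holds the three consecutive Tukey contrasts
(melan-a vs 4C, 4C vs 4C11-, 4C11- vs 4C11+), the end-to-end anchor
(melan-a vs 4C11+) and an epithelial-group vs mesenchymal-group Welch test.
The rules:

* **EMT** — group contrast significant while both within-group contrasts
  (melan-a vs 4C11+, 4C vs 4C11-) are not. The call is exclusive by design:
  an EMT V-profile necessarily also trips the step-wise comparisons, and
  treating those as independent evidence would double-label every EMT mark.
  The "similar expression in mesenchymal versus epithelial cells" idea is
  ambiguous between a within-pair similarity and a between-group difference;
  this operationalisation (between-group difference + within-group
  similarity) reproduces the canonical V-shaped EMT profiles.
* **progression** — the melan-a vs 4C contrast is significant, or at least
  two of the three consecutive contrasts are.
* **metastasis** — the 4C11- vs 4C11+ contrast is significant.

Progression and metastasis may co-occur (the consecutive-change clause
overlaps the metastasis clause by construction); the empty label set means
unclassified. Because the EMT clause *requires* non-significance of two
contrasts, raising the significance threshold is monotone only for the
progression and metastasis label sets — the EMT set can grow under a
stricter threshold; the tests assert monotonicity for the two monotone
labels only. Clusters inherit the majority label of their confident members;
ties and empty clusters fall back to a centroid-level rule that replaces
significance with an effect-size threshold (0.5 z-units) and logs the
decision.

# The synthetic-data generators

The generators plant known structure so every stage has a recoverable ground
truth; their defaults are the package's standard study conditions, chosen
once and documented here as assumptions (no within/between-line variance
magnitudes are published for the real panels).

*Expression.* Six planted modules (300, 250, 200, 150, 100, 50 genes) plus
450 background genes over 4 lines x 3 replicates. Each module has an
eigen-profile: a line-level pattern (progression 1-4, EMT 0/1/1/0,
metastasis 0/0/0/1, tumour 0/0/1/1, or an independent normal profile for
"null" modules), standardised, expanded to samples, plus per-sample jitter
(SD 0.6). The jitter stands in for the replicate-level biological
variability that keeps correlated programs distinguishable in real panels.
Member genes are `loading x profile + N(0, 0.5)` with lognormal loadings
(sdlog 0.5) so intramodular hubs exist. Default planted patterns are
progression, EMT and metastasis plus three nulls: the tumour encoding
correlates at $r = 0.895$ with progression across the four lines, so
planting both makes the ground truth unidentifiable at $n = 12$. The
progression module is planted with negative orientation (`sign = -1`):
progression and metastasis encodings correlate at $r = 0.77$, and two
positively oriented modules would merge at the 0.25 eigengene cut in a
sizeable fraction of runs — anti-correlated planting reflects the equally
common biology of programs shut down along progression and keeps the truth
recoverable. What passing recovery tests show is therefore recovery of
*identifiable* planted structure; they do not certify behaviour on real data
with collinear programs, batch effects or missingness (all out of scope).

*Cohort.* Event times follow a proportional-hazards model (exponential by
default, Weibull optional) with linear predictor
$\sum_g \beta_g x_g + \text{covariate effects}$, standard-normal expression,
planted log-HR 0.4 on the prognostic genes and small fixed effects for age,
sex, site, stage and mitotic rate. Censoring is independent exponential with
its rate solved numerically so the expected censored fraction matches
`censoring_rate` (default 0.3) despite hazard heterogeneity.

*PTM table.* 60 backbones expanding to 245 forms (one unmodified form per
backbone). Each modified form follows one of eight archetype profiles over
the lines — three progression shapes (early loss, early gain, dip with
partial recovery), two EMT V-shapes, three metastasis shapes (flat-then-up,
drift-then-drop, drift-then-surge) — scaled by a per-form weight, with the
unmodified form absorbing the remainder so ratios sum to 1 by construction.
The shapes were chosen by a constrained search maximising mutual z-profile
separation subject to the phenotype rules: metastasis shapes may change
significantly only at the final step, so their mutual separation comes from
sub-significant drifts. Acetyl-carrying forms draw from the archetypes that
dip at 4C and methyl-only forms from the remainder, planting the global
acetylation drop (and methylation gain) in the pre-malignant line. Replicate
noise is lognormal with sdlog 0.10 (CV ~10 %, typical of DIA histone-MS
biological triplicates). Areas are strictly positive.

All draws flow from the single config seed (distinct derived streams per
generator); identical configs give byte-identical outputs.

# Numerical choices and degenerate inputs

* Zero-variance genes are rejected with a named-gene error (correlation is
  undefined), never silently dropped.
* Variance-filter ties and kWithin ties break lexicographically by gene id;
  module-size ties in colour assignment break by first gene index.
* The scale-free fit needs at least 3 non-empty connectivity bins, else
  $R^2$ is reported missing for that $\beta$.
* Fuzzy c-means adds $10^{-12}$ to squared distances before the membership
  power and gives a point sitting exactly on a centroid full membership
  there; non-convergence at `max_iter` returns the best iterate flagged
  `converged = FALSE`.
* A median split of constant values, a zero backbone area, or a constant row
  under correlation distance are errors naming the offending unit; a
  log-rank group with zero events is a warning, not an error.
* Pipeline outputs serialise numbers at 15 significant digits; ground-truth
  serialisation uses 17 digits so doubles round-trip exactly.

# Problem sizes used by the tests

The test-suite and the acceptance script exercise the package at desk scale,
the package's standard verification set-up: module recovery over 20
simulation seeds (1,500 genes, 12 samples each) plus a 10-seed hub/trait
arm; 500 null simulations per calibration check; 200 cohort replicates of
n = 500 for Cox coverage plus 100 null cohorts; three full PTM fixtures (245
forms) for the clustering and classification checks. On one CPU the whole
suite completes in a few minutes.

# Known limitations

* Module counts and exact memberships are cut-procedure-specific; only
  partition-level properties are stable across implementations.
* The correlation p-values ignore the replicate structure (see above).
* The EMT rule's reliance on accepting null within-group contrasts makes its
  label set non-monotone in the significance threshold and inflates EMT
  misses when replicate noise is high.
* The generators emulate neither batch effects nor missing data, and the
  survival generator's covariate effects are fixed small constants, not
  estimates of any real cohort.
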