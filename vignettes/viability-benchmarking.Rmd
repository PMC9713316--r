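---
title: "Benchmarking viability discrimination with simulated spike-in studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking viability discrimination with simulated spike-in studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viabench)
```

## The problem

Sequencing-based community profiling reads nucleic acids, not viability: DNA
from heat-killed or otherwise membrane-compromised cells persists and is
counted alongside DNA from live cells. In food microbiology this matters
directly — a pasteurized product full of dead-cell DNA can look contaminated.
Several assay designs try to restore the live/dead distinction:

* **PMA-shotgun**: propidium monoazide enters membrane-compromised cells,
  cross-links their DNA under light, and blocks its amplification, making a
  DNA shotgun library viability-selective.
* **RNA-based methods** (rRNA amplicon sequencing, metatranscriptomics): RNA
  decays quickly after death and its abundance tracks metabolic activity, so
  RNA libraries under-represent dead cells — strongly for mRNA, less so for
  the more stable rRNA.

`viabench` evaluates such methods the way mock-community benchmarking studies
do: a defined 5-strain community (*Bacillus*, *Escherichia*, *Lactococcus*,
*Pseudomonas*, *Staphylococcus*) is spiked, live or heat-killed, into a
low-background milk matrix in triplicate; each sample is profiled by four
library types on two platforms; and the resulting genus-level count tables
are scored against sequenced control communities. Because the package ships a
full generative model of that design, every stage runs end to end without any
external sequencing data.

## Scoring: abundance-mass confusion

For one sample we compare the observed genus profile $o$ (relative
abundances) with a reference profile $e$. Mass is apportioned over
mock-community genera $M$ and all other taxa:

* $TP = \sum_{i \in M} \min(o_i, e_i)$ — mock mass the method got right,
* $TN = \sum_{j \notin M} \min(o_j, e_j)$ — non-mock mass it got right,

and, under the default **excess-deficit** scheme,

* $FP = \sum_{i \in M} \max(o_i - e_i, 0)$ (mock excess),
* $FN = \sum_{i \in M} \max(e_i - o_i, 0)$ (mock deficit).

Then $A = \frac{TP + TN}{TP + TN + FP + FN}$, $P = \frac{TP}{TP + FP}$,
$S = \frac{TP}{TP + FN}$, $F = \frac{2PS}{P + S}$, with any $0/0$ defined as
0 and flagged degenerate. Under this scheme $TP + FP$ is exactly the observed
mock mass and $TP + FN$ the reference mock mass, which is what precision and
sensitivity denominators should be under standard precision/recall
semantics.

The verbal description of these quantities also admits a second reading in
which FN collects *non-mock* disagreement; we expose it as the
**split-mass** scheme ($FP = \sum_{i \in M} |o_i - e_i|$,
$FN = \sum_{j \notin M} |o_j - e_j|$). It has a pleasant closed form: its
accuracy is a monotone transform of Bray-Curtis dissimilarity,
$A = (1 - BC)/(1 + BC)$, which the test suite verifies to $10^{-12}$ over
random profile pairs. Both schemes agree on the worked example below only in
TP; the four metrics differ, so the scheme is an explicit flag, defaulting to
excess-deficit.

```{r toy}
obs <- c(Bacillus = 0.1, Escherichia = 0.3, Lactococcus = 0.2,
         Pseudomonas = 0.2, Staphylococcus = 0.1, Acinetobacter = 0.1)
expected <- c(Bacillus = 0.2, Escherichia = 0.2, Lactococcus = 0.2,
              Pseudomonas = 0.2, Staphylococcus = 0.2)
performance_metrics(confusion_mass(obs, expected, names(expected)))
performance_metrics(confusion_mass(obs, expected, names(expected),
                                   scheme = "split-mass"))
```

### Choice of reference

By default each live spiked sample is scored against the *sequenced* live
community control of the same method and platform, and each dead sample
against the dead control (`reference = "matched_control"`). This measures
what the benchmarking design measures: whether the method reproduces its own
view of the known community, net of method-specific observation bias. A
`"theoretical"` reference (intended proportions, 0.2 each) is available for
scoring against simulator truth.

For dead samples an alternative question is "did the method correctly report
*nothing viable*?" — `expect_absent = TRUE` scores dead spikes against the
matched unspiked-matrix control, so any detected mock mass counts as
false-positive mass. We default to the matched dead control because the
benchmark design sequences exactly those controls for comparison; both
options are tested.

## Absolute quantification

Relative abundances are anchored to each sample's total-bacteria qPCR value:
`cells_i = qpcr_total * abundance_i`, reported per genus with
`log10(cells/mL)` and a below-detection flag at zero abundance (excluded
from log-scale summaries rather than imputed, since there is no principled
imputation floor at the count-table level). Pairing shotgun with PMA-shotgun
samples by (platform, condition, replicate) yields the PMA depletion
summary; in dead-spiked pairs the log10 difference directly reflects the
dead-DNA residual, and the ratio estimator
$\hat\varepsilon = \overline{\text{mock mass}}_{\text{PMA}} /
\overline{\text{mock mass}}_{\text{shotgun}}$ over dead pairs recovers the
simulator's PMA residual (default 0.05) — the suite checks recovery within
±0.02 from 30 pairs.

## The generative model

Latent layer, per spiked sample (cells/mL):

* live condition: $L_i = 10^7 \cdot 0.2 \cdot g_i$, $D_i = 0$, with
  per-strain overnight growth factors
  $g_i \sim \mathrm{LogNormal}(\log \mu_g, \sigma_g)$ — the matrix
  incubation grows the community beyond its intended equal concentrations;
* dead condition: $L_i = 0$, $D_i = 10^7 \cdot 0.2$ — heat-killed cells do
  not grow;
* untreated community controls: $g_i = 1$, no matrix background;
* unspiked matrix: background flora only (default three genera at
  $10^3$ cells/mL, a near-sterile UHT matrix).

The latent loads of a given (condition, replicate) are shared by every
method and platform, mirroring the split-aliquot design in which all assays
measure the same physical sample.

Observation layer:

* **method**: $\text{signal}_i = L_i a_i^{[\text{RNA}]} w_{\text{live}} +
  D_i w_{\text{dead}}$; defaults $w_{\text{dead}} = 1$ (shotgun),
  $\varepsilon_{\text{PMA}} = 0.05$ (PMA-shotgun), $\rho_{\text{rRNA}} =
  0.10$ (16S), $\rho_{\text{mRNA}} = 0.01$ (metatranscriptomics). RNA
  methods scale live signal by activity $a_i$ (default: *Pseudomonas* 5,
  others 1 — an illustrative encoding of "most active strain", not an
  estimate).
* **platform**: total reads $\sim$ Poisson(depth), counts multinomial in the
  signal proportions, then a binomial fraction `misclass_rate` of every
  taxon's counts is reassigned uniformly across background genera. Defaults:
  depth $10^6$ / rate 0.002 (high-depth, low-error) and $10^5$ / 0.02
  (low-depth, high-error). No taxon-specific error profile is modelled —
  platform differences in real data mix depth, chemistry and pipeline
  effects that the benchmark does not quantify separately.
* **qPCR**: $(\sum_i L_i + w^{\text{qPCR}}_{\text{dead}} \sum_i D_i +
  \sum_j B_j) \cdot \mathrm{LogNormal}(0, \sigma_q)$, with
  $w^{\text{qPCR}}_{\text{dead}} = \varepsilon_{\text{PMA}}$ for PMA-treated
  aliquots and 1 otherwise (qPCR reads DNA, so RNA methods' samples still
  count dead cells in full).

Raw taxon labels mimic classifier output — GTDB-style species names
("Pseudomonas_E proteolytica"), a staphylococcal sibling-species switch
between platforms, Silva's "Escherichia-Shigella" for the 16S method — so
the taxonomy-harmonization step is exercised by every simulated study.

### Free parameters and why these defaults

| parameter | default | units | rationale |
|---|---|---|---|
| spike density | 1e7 | cells/mL/strain | stated design density |
| replicates | 3 | — | stated design |
| growth mean $\mu_g$ | 10 | fold | one decade of overnight growth at room temperature |
| growth spread $\sigma_g$ | 0.5 | log-scale | strains differ visibly but stay within ~one order |
| background | 3 genera × 1e3 | cells/mL | near-sterile UHT matrix |
| $\varepsilon_{\text{PMA}}$ | 0.05 | — | strong but imperfect dead-DNA exclusion |
| $\rho_{\text{rRNA}}, \rho_{\text{mRNA}}$ | 0.10, 0.01 | — | rRNA outlives mRNA after death |
| $\sigma_q$ | 0.1 | log-scale | ~±25% qPCR assay spread |

The growth and activity parameters are not estimated from data — the
benchmark reports no per-strain growth or activity numbers — so they are
documented free parameters chosen once as plausible for an overnight milk
incubation, and all study-level conclusions the tests assert (PMA precision
pattern, RNA suppression of dead signal, clustering by library type before
platform) are robust across seeds at these values.

What the simulator deliberately omits: read-level error (no FASTQ), chimeras,
amplification bias, 16S copy-number variation, taxon-specific
misclassification, death or regrowth of background flora. Passing tests
therefore demonstrate correctness of the scoring and diversity machinery and
qualitative faithfulness of the study design, not quantitative agreement with
any real sequencing run.

### Seed policy

One master seed; every random draw uses a private stream seeded by hashing
`(key components) -> [0, 2^31 - 1)` ([stream_seed]). Latent loads hash
(condition, replicate); counts and qPCR draws hash (method, platform,
condition, replicate, purpose). Consequences: two runs with the same config
are byte-identical, removing a method leaves all other draws untouched, and
paired live samples have identical totals when $\sigma_q = 0$.

## Beta diversity

The diversity stage is self-contained (and cross-checked in the test suite
against vegan, ape and stats):

* **Bray-Curtis** $\sum|x_i - y_i| / \sum(x_i + y_i)$, equal to half the L1
  distance on normalized profiles.
* **PCoA**: double-centre $-\tfrac12 D^2$, eigendecompose, scale
  eigenvectors by $\sqrt\lambda$. Eigenvalues below $10^{-9}\lambda_{max}$
  are treated as null; negative eigenvalues are reported and their axes
  dropped; each axis is oriented so its largest-magnitude coordinate is
  positive (a deterministic sign convention — eigenvectors are otherwise
  sign-ambiguous). On Euclidean input the embedding reproduces the input
  distances to $10^{-8}$.
* **PERMANOVA** (one-way): $SS_{\text{total}} = \sum_{i<j} d_{ij}^2 / N$,
  within-group analogues per group, pseudo-$F = \frac{SS_B/(a-1)}{SS_W/(N-a)}$,
  $R^2 = SS_B / SS_{\text{total}}$. Squared dissimilarities are used
  throughout (the standard formulation). The permutation p-value uses the +1
  rule; when the number of distinct label arrangements is at most the
  requested permutation count the exact p-value is computed by exhaustive
  enumeration instead. Default 999 permutations.
* **Clustering**: agglomerative with complete (default), average or single
  linkage. Complete linkage is the conventional default in this ecosystem's
  dendrogram tooling; the flag exists because the choice is not forced by
  the analysis. Ties in the merge distance (within $10^{-12}$) are broken by
  the lexicographically smallest member id, making dendrograms fully
  deterministic. Trees export as ultrametric Newick (leaf depth = root merge
  height).

Study-level groupings tested: library type (DNA = shotgun, PMA-shotgun; RNA
= metatranscriptomics, 16S) and platform. By default only spiked samples
enter the analysis; controls can be included by flag.

## Numerical and degenerate-input choices

* Profile closure is validated at $10^{-6}$ on inputs; normalization itself
  is exact to $10^{-12}$.
* All-zero profiles, all-zero signal vectors, empty mock sets, missing
  controls and missing qPCR values are errors with named culprits — never
  silent zeros.
* Genus collapse conserves per-sample totals exactly and is idempotent;
  "unclassified"/"unassigned" rows are dropped before normalization with the
  dropped mass reported.
* A zero denominator in any metric returns 0 with a degenerate flag rather
  than NaN, so aggregation never propagates missingness.
* When $SS_W = 0$ the pseudo-F is infinite; the permutation comparison
  handles this without NaN and $R^2 = 1$.

## Problem sizes

Default studies are deliberately compact: 8 count tables × 9 samples
(72 samples, ≤ 8 taxa) at depths $10^6$/$10^5$. The qualitative-pattern
checks run 100 independent studies; PERMANOVA oracle checks enumerate label
arrangements only for fixtures of ≤ 8 samples. A full simulate → evaluate →
diversity → report run takes seconds.

## Known limitations

* Genus level is the only supported scoring rank; species-level scoring
  founders on exactly the classifier-naming inconsistencies the
  harmonization map exists to absorb.
* PERMANOVA is one-way; no strata or multi-factor partitioning.
* The misclassification model reassigns uniformly into background genera
  only; cross-mock misassignment is not modelled.
* $\hat\varepsilon$ recovery assumes the background is negligible relative
  to the dead spike, as in the default conditions.
* No "other-taxa" abundance filter is applied before scoring; the benchmark
  design leaves such filtering unstated, and at these background levels it
  would be a no-op.
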