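---
title: "Methods: from ex vivo drug response to per-patient gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ex vivo drug response to per-patient gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respcard)
```

# Overview

`respcard` models a tumor-board style analysis for solid tumors such as head
and neck squamous cell carcinoma: patient-derived tumor cell cultures are
screened against a panel of targeted inhibitors, the same tumors are
characterized genomically (somatic variants, allele-specific copy number,
expression, protein arrays), and the two views are joined per patient. The
package's chain of inference is:

1. plate viability signals → harmonized, QC-flagged AUC values;
2. AUC values → per-drug Z-scores → per-gene drug-sensitivity scores with a
   permutation null;
3. significant genes → network propagation → degree-corrected prioritization
   of the patient's altered genes;
4. everything → a per-patient Response Card.

This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data generators do
and do not emulate.

# Dose-response processing

Viability is defined per plate as `(signal − blank mean) / (control mean −
blank mean)`, where controls contain cells without drug and blanks contain
no viable cells. A plate whose control mean does not exceed its blank mean
is a hard error rather than a silent negative scale. Viability is clamped
to [0, 1]; values below 0 before clamping set a `negative_clamped` flag so
that aggressive baseline drift remains visible downstream.

Each run (one sample, drug, panel, replicate) is fitted against log10
concentration in one of two ways:

* **OLS** — a straight line in log10 concentration. Simple, robust to the
  7-point design, and linear in the parameters.
* **Probit** — least squares on the probit-transformed viability, with
  values squeezed into `[1e-3, 1 − 1e-3]` first. The squeeze bounds the
  transform at ±3.09 so saturated wells (0 or 1 exactly) cannot produce
  infinite working responses; the fitted curve `pnorm(a + b·x)` is the
  classical sigmoid shape.

The AUC is the trapezoid integral of the fitted curve, clipped to [0, 1],
over a 100-point grid spanning the observed log10 range. The paper-style
*rescaled* AUC divides by the width of that range, so 1 means full viability
everywhere and 0 means complete kill everywhere. Integrating the *fitted*
curve (rather than the raw points) treats both fit kinds uniformly and makes
the two agree within 0.05 on noiseless linear curves, which the tests check.

Runs whose fitted viability *increases* with concentration are flagged
`increasing_removed` and excluded from replicate averaging. "Increases" is
operationalized as fitted slope > 0.05 per log10 unit (on the fit's own
scale); a tolerance is necessary because noise around a flat curve produces
small positive slopes that carry no evidence of a paradoxical response. The
value is a package parameter (`increasing_slope_tol`).

Replicate harmonization works on the raw-area scale: within a panel, a
maximum AUC difference above 1 sets `within_panel_divergent`; across
panels, panel means differing by more than 0.75 set
`across_panel_divergent`. Both thresholds are exposed as arguments because
the area scale depends on the dilution design (a 7-point 3-fold series
spans `6·log10(3) ≈ 2.86` log10 units). The final AUC per (sample, drug) is
the clamped mean of per-panel means; divergence flags never drop data by
themselves, they mark it.

# Drug-target matrix

Target evidence rows (drug, gene, binding-assay value in nM, publication
count) are filtered to assay values strictly below 100 nM — a conventional
potency bound for calling a protein a real target rather than an off-target
trace. Per drug, interactions are then binned by publication support into
the categories ≥ 3, = 2 and = 1, and only the genes of the highest
non-empty category are kept: a drug with two well-studied targets and one
singleton keeps only the two. The binning is configurable (`pub_breaks`)
since other resources may justify different support levels. A per-row
exclusion list handles interactions with known-discrepant evidence. Drugs
left with no targets are dropped from the matrix with a warning naming
them; they still contribute AUC data, just no gene attribution.

# Gene scores and the permutation test

With the binary target matrix `T` (genes × drugs) and the per-drug Z-score
matrix `Z` (drugs × samples; sample SD, n − 1 denominator, recorded in the
matrix attributes), the gene score is the matrix product `G = T Z`: the sum
of standardized responses to the drugs that target the gene. The score is
deliberately *not* an average — a gene covered by eight potent inhibitors
that all come back sensitive should outrank a gene covered by one.

Missing AUCs are handled by contribution, not imputation: a missing
`z_jk` contributes nothing to any gene score in sample *k*, and a (gene,
sample) cell all of whose targeted drugs are missing is `NA`. Genes with no
drugs surviving the intersection of `T` and `Z` are reported absent rather
than scored 0, since 0 would masquerade as "observed and average".

The null distribution permutes the *drug labels* of `Z`: whole rows are
relabeled jointly for all samples, so the cross-sample correlation
structure of each drug's response survives under the null and only the
target annotation is broken. A row's missingness pattern travels with it.
The empirical p-value uses add-one smoothing and counts ties:

```
p_ik = (1 + #[ g_perm ≤ g_obs ]) / (n_perm + 1)
```

Counting ties is what makes the p-value valid: a score that is invariant
under permutation (a gene targeting every drug) ties with every permutation
and gets p = 1, as it should; a strict `<` count would hand that same gene
the *minimum* attainable p-value. Equality is tested up to 1e-12 to absorb
floating-point reordering. With 1,000 permutations the smallest attainable
p is 1/1001 ≈ 0.000999, which is what makes the tier-1 cutoff (p < 0.001)
reachable at all — it requires that no permutation beats or ties the
observed score. Tiers 2 and 3 sit at 0.01 and 0.05. No multiple-testing
correction is applied; the tiers are screening strata, not confirmatory
claims.

# Network propagation and the RDPN null

The interaction network keeps edges with confidence strictly above 0.95,
discards direction, collapses duplicates and self-loops, and restricts to
the largest connected component (ties broken by node count, then total
edge score, then lexicographically smallest node id — an arbitrary but
deterministic rule). Propagation iterates

```
P_k = (1 − c) W P_{k−1} + c P_0,   W = D^{−1/2} A D^{−1/2},   c = 0.7
```

from the restart vector `P_0` — the genes of the patient's highest
non-empty significance tier, uniformly weighted, summing to 1. Using only
the highest non-empty tier keeps the seed set sharp: mixing tier-1 genes
with dozens of tier-3 genes dilutes the restart mass exactly where the
signal is strongest. The restart weight c = 0.7 keeps most mass near the
seeds while still reaching 2-3 hops out.

Convergence is declared when the L1 change between iterates falls below
1e-6 (cap 10,000 iterations; with c = 0.7 the iteration contracts by a
factor 0.3 per step, so convergence takes ~15 iterations and the cap is
never near). The tests verify the iterate against the closed-form solve
`P = c (I − (1 − c) W)^{-1} P_0` to 1e-5 in L∞.

One caution about the normalization: `W` is symmetric but not stochastic,
so the L1 mass of the converged vector is *not* bounded by 1 — seeding the
hub of a star graph gives mass ≈ 1.17. The invariants the package
guarantees are nonnegativity, the fixed-point identity, and the geometric
bound `‖P‖₁ ≤ c / (1 − (1 − c)·s)` with `s` the maximum column sum of `W`.
Scores are comparisons, not probabilities.

High-degree genes accumulate propagation mass no matter where the seeds
are. The RDPN null corrects for this: 1,000 networks are generated by
degree-preserving double-edge swaps (two edges (a,b), (c,d) →
(a,d), (c,b); proposals creating self-loops or multi-edges are rejected, so
every node keeps its exact degree), each null network targets 10 accepted
swaps per edge with a capped number of proposals, and propagation is rerun
with the *same* restart vector. The per-gene empirical p counts how often
the null score reaches the observed one, again with add-one smoothing. A
hub's observed score is reproduced by almost every rewiring (p near 1); a
low-degree gene that scores high only because it genuinely sits next to the
seeds loses that adjacency under rewiring and earns a small p. Graphs that
admit no swap at all (complete graphs, stars) return all p = 1 with a
warning — the honest answer, since the null cannot distinguish anything.
The restart vector is kept fixed across nulls; the alternative of
re-deriving seeds per null would conflate seed selection with topology.

Altered genes (filtered mutation or non-neutral copy-number call) with
RDPN p strictly below 0.05 are prioritized, ranked by propagation score.
The connecting subnetwork uses the classical shortest-path Steiner
approximation — grow a tree from one terminal, repeatedly attach the
closest remaining terminal — which is within a factor 2 of the optimal
Steiner tree; the tests verify that bound against exhaustive enumeration on
small graphs.

# Genomic integration

Variant filtering keeps calls that pass the caller filter, have a
non-synonymous or indel consequence, have population allele frequency
strictly below 0.01 (missing frequency = novel = kept, flagged), and are
either damaging by both protein predictors (not SIFT-tolerated *and* not
PolyPhen-benign) or rescued by a pathogenic ClinVar assertion. Requiring
both predictors to fail is the conservative reading of a conjunction that
could be parsed either way; `require_both = FALSE` gives the looser one. A
user-supplied blocklist removes recurrent artifact genes.

Gene-level copy number sums major and minor alleles per segment, centers by
the per-sample median over segments (unweighted by segment length — a
simple, assembly-agnostic baseline), assigns each gene the overlapping
value of largest absolute magnitude, and calls amp/del at strictly > 1 /
< −1. Segment tables are 1-based closed; gene intervals are BED-like
0-based half-open and converted on read. Concordance against expression and
protein Z-scores is conservative: an amplification is concordant (`cA`)
only when every available modality is positive; mixed or zero signs are
discordant, and deletions mirror with flipped signs.

Patients are matched to cell lines by Jaccard distance between binary
alteration profiles over a declared gene subset; entities with empty
profiles are excluded (Jaccard distance is undefined on empty sets), and
ties report all minimum-distance lines. Matched pairs can then be compared
by Pearson correlation of AUC over common drugs (≥ 3 required).

# Subtype calling

Expression is median-centered per gene *on the cohort being called* — the
calling cohort is the distribution the sample must stand out of — and each
sample is assigned the centroid with the highest Pearson correlation over
common genes. A call is indeterminate when the best correlation is
negative, when the runner-up is within 0.1, or when the best correlation is
exactly tied. Accuracy is always evaluated on determinate calls, with the
indeterminate count reported separately. An optional reference-median mode
(centering against stored medians) is a natural extension for calling
single new samples against a fixed cohort; the default centers on the data
at hand.

# Combination testing

For each combination, the per-sample reference is the minimum log AUC over
its component drugs, and the combination's log AUC is compared to that
reference by a paired t-test. The mean difference is the log combination
ratio: negative means the combination beats its best single agent. The log
base is natural by default (log2 optional, in which case −1 means
"half the AUC"). AUCs are floored at 1e-4 before the log and flagged, since
a 0 AUC is a measurement floor, not evidence of infinite potency.
Difference vectors with (numerically) zero variance report the ratio with
p = NA — a t-test on constants answers no question — rather than p = 1.

# The synthetic cohort

The generators produce every input the pipeline consumes, with the planted
truth recorded for assertions:

* **Plates** — 7-point 3-fold dilution series (top 10 µM), two replicates,
  negative-control and blank wells per plate, Gaussian signal noise
  (SD 0.05 of the control level). The generative curve is a
  four-parameter logistic in log10 concentration; planted sensitive
  (sample, gene) pairs pull viability down by `effect` at saturation in
  every drug targeting the gene, with the midpoint at the geometric middle
  of the dilution range.
* **Target evidence** — 1-3 targets per background drug, a 20% fraction of
  assay values placed at or above 100 nM, varied publication counts; each
  planted gene is guaranteed eight sub-100 nM, top-support drugs — the
  multi-inhibitor coverage of a heavily drugged kinase in an oncology
  panel.
* **Network** — preferential attachment (m = 2), which produces the skewed
  degree distribution the RDPN null exists to correct. Gene ids are mapped
  onto nodes so that planted drivers take low-degree nodes and planted
  targets take median-degree nodes: neither should be a hub whose score is
  explained by degree alone. Drivers are guaranteed an edge (score 0.99)
  to a planted target gene. About 10% of background edges score below
  0.95 to exercise the confidence filter.
* **Alterations** — one toy chromosome of 10 kb gene intervals; background
  variants land per (sample, gene) at a configurable rate with randomized
  annotations (so only a subset survives filtering), planted drivers are
  always PASS / missense / AF 1e-4 / deleterious / probably_damaging /
  pathogenic; segments are diploid with optional focal amplifications.
* **Expression** — four block-structured centroids (each subtype
  up-regulates its own quarter of the genes); samples are centroid + noise,
  with an optional fraction placed midway between cyclically adjacent
  centroids. The cyclic pairing keeps the cohort balanced so per-gene
  median centering preserves the planted ambiguity.
* **Combinations** — the per-sample minimum of the component AUCs times a
  potency ratio with log-normal noise.

What the generators do **not** emulate: realistic mutational spectra or
allele frequencies, linkage between expression subtype and drug response,
plate spatial effects, batch structure, or heavy-tailed assay noise.
Passing tests therefore demonstrate that the statistical machinery recovers
what it is designed to recover under its own assumptions — not that those
assumptions hold in any particular clinical dataset.

# Problem sizes and study conditions

The demo pipeline uses a 12-sample, 40-drug, 120-gene cohort with 1,000
permutations and 1,000 rewired networks — small enough to run in about a
minute, large enough that the planted driver is recovered through the full
chain. The permutation-calibration study uses a 200-gene null cohort
(40 drugs × 12 samples, 1,000 permutations). The planted-signal power study
is run at the screening design the package targets — an 89-inhibitor panel
and a 20-sample cohort, with the planted gene covered by eight drugs and
its carrier shifted down 2 within-drug SDs. Panel size matters here for a
structural reason: the permutation null draws from the carrier's own
Z-scores, so with a small panel the planted rows contaminate a substantial
fraction of permutations and cap the attainable significance; with an
89-drug panel the planted 8 rows are rarely drawn and tier-1 recovery is
reliable. The same logic is why a gene covered by a single drug can never
reach tier 1: its null *is* the carrier's Z-score distribution.

# Known limitations

* The probit fit is least squares on the transformed response, not a
  binomial GLM; with 7 points per curve and viability (not count) data this
  is the standard pragmatic choice, but standard errors of the fit are not
  propagated into the AUC.
* RDPN p-values inherit permutation granularity: with 1,000 rewirings the
  smallest p is 1/1001, so alpha levels below 0.001 are unreachable.
* The Steiner subnetwork is a 2-approximation with unit edge costs; edge
  confidence scores are not used as distances.
* Cards z-score expression and protein data against the analyzed cohort;
  with very small cohorts those Z-scores are noisy, and no shrinkage is
  applied.
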