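# respcard

Integration of ex vivo drug response with tumor genomics for per-patient
**Response Cards**.

Functional screens of patient-derived tumor cell cultures — panels of small-
molecule inhibitors assayed as dose-response curves — measure what actually
kills a patient's tumor cells, but on their own they do not say *why*. This
package implements a complete analysis stack that ties drug sensitivity back
to genes: it converts raw plate viability signals into harmonized AUC
values, scores genes by the standardized response to the drugs that target
them, tests those scores with a drug-label permutation null, propagates the
significant genes over a protein-interaction network to reach the somatic
alterations that sit near them, and assembles everything into a per-patient
Response Card. A synthetic-data module generates every input with known
planted structure, so the whole pipeline is testable end to end without
access to patient data.

## The statistics at the core

**Drug-response AUC.** Plate signals are normalized per plate against
negative-control and blank wells, clamped to [0, 1] (negative values
flagged), fitted against log10 concentration by OLS or probit regression,
and integrated over the observed log10 range; the AUC is rescaled by the
width of that range so it lies in [0, 1] (lower = more sensitive).
Within-panel replicates whose raw-area AUCs differ by more than 1 and
across-panel replicates differing by more than 0.75 are flagged; curves
whose fitted viability increases with concentration are removed.

**Gene score.** With a binary drug-target matrix `T = [t_ij]` (gene *i*
targeted by drug *j*; evidence restricted to binding assays < 100 nM and,
per drug, the highest publication-support category) and per-drug Z-scores
`z_jk = (x_jk - mean(x_j)) / sd(x_j)` of the AUC matrix, the score of gene
*i* in sample *k* is

```
g_ik = sum_j t_ij * z_jk
```

Strongly negative scores mark genes whose inhibitors the sample is unusually
sensitive to. Significance comes from permuting the drug labels of `Z`
(1,000 times) and recomputing `G`; tiers are assigned at p < 0.001, < 0.01
and < 0.05.

**Network propagation.** The interaction network (edges with confidence
> 0.95, largest connected component, symmetrically normalized adjacency
`W = D^{-1/2} A D^{-1/2}`) diffuses the top-tier genes by random walk with
restarts,

```
P_k = (1 - c) W P_{k-1} + c P_0,      c = 0.7,
```

iterated to convergence. Because node degree inflates propagation scores,
empirical p-values are computed against 1,000 degree-preserving rewired
networks (RDPN); genes carrying a mutation or copy-number alteration with
RDPN p < 0.05 are prioritized, and a Steiner-tree-style subnetwork connects
them to the top-scoring genes.

Around this core the package also implements somatic variant filtering
(caller PASS, non-synonymous/indel, population AF < 0.01, damaging by both
protein predictors or ClinVar-pathogenic), gene-level copy-number calling
from allele-specific segments (total = major + minor, sample-median
centered, max-|value| per gene, amp/del at ±1), concordance labels against
expression/protein Z-scores (cA/dA/cD/dD), nearest-centroid expression
subtype calling with a 0.1-margin indeterminacy rule, Jaccard-distance
matching of patients to cell lines, and paired t-tests of drug combinations
against their best single agent on the log AUC scale.

## Worked example

```r
library(respcard)

truth <- synthetic_truth(
  sensitive_pairs = data.frame(sample_id = "S01", gene_id = "G0001"),
  driver_genes    = data.frame(sample_id = "S01", gene_id = "G0020"))

ev     <- generate_target_db(40, 60, truth = truth, seed = 11)
tm     <- build_target_matrix(filter_and_select(ev))
plates <- generate_viability_plates(12, 40, effect = 0.6, truth = truth,
                                    target_matrix = tm, seed = 12)
auc    <- compute_auc_matrix(plates, fit_kind = "ols")
Z      <- zscore_by_drug(auc$auc)
scores <- permutation_pvalues(tm, Z, n_perm = 1000, seed = 13)
scores
#> Gene score result: 32 genes x 12 samples, 1000 permutations
#>   tier-1 (p < 0.001) cells: 2
scores$scores["G0001", "S01"]   # -28.28: S01 is highly sensitive to
scores$p["G0001", "S01"]        #  0.000999: the inhibitors of G0001
```

The planted pair (S01, G0001) is recovered: its gene score sums eight
strongly negative drug Z-scores, and no drug-label permutation reaches a
lower score, giving the smallest attainable p-value (1/1001) and tier 1.
Propagating S01's tier-1 genes over a generated network then recovers the
planted altered driver sitting next to G0001:

```r
edges <- generate_network(60, attach_m = 2, truth = truth, seed = 14)
net   <- build_network(edges, score_threshold = 0.95)
p0    <- build_seed_vector(scores, "S01", net$nodes)
rd    <- rdpn_pvalues(net, p0, n_rewired = 1000, seed = 15)
prioritize_altered_genes(rd, c("G0020", "G0035"))
#>   gene_id      score           p
#> 1   G0020 0.07941143 0.000999001
```

G0020 is altered, adjacent to the seed, and essentially never scores as
high on degree-preserving rewired networks — so it is prioritized; the
altered but network-distant G0035 is not.

The full pipeline, from plate signals to exported Response Cards, runs off
one YAML configuration:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "respcard"),
             out_dir = "demo_out")
```

which writes the AUC matrix, gene scores and p-values, subtype calls,
combination tests, filtered variants, copy-number calls, one
`card_<sample>.json` per scored patient, and a manifest with file checksums
and the seed. `inst/scripts/run_pipeline.R` wraps this for the shell.

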