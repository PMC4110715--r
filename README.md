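# phasenet

Phase-specific active network modules and candidate disease-associated
genes from multi-platform expression profiles on a protein–protein
interaction scaffold.

## The problem

Diseases that progress through ordered phases — the motivating case is
prostate cancer, staged early (clinical stages I+II), middle (III) and
late (IV) — reorganize molecular interactions differently at each
transition. Individual differential-expression lists from single
platforms are noisy and poorly reproducible; interaction networks are
static. phasenet implements the integrative middle ground for analysts
who have (a) an undirected PPI edge list, (b) two or more gene-expression
matrices from different platforms with per-sample phase labels, and
(c) optional known-gene lists for validation:

1. Per platform and per phase contrast (early–middle, middle–late,
   early–late), genes are tested with an **empirical-Bayes moderated
   t-test** — the pooled variance s²_g is shrunk toward a prior,
   s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g) — with Benjamini–Hochberg
   adjustment, and adjusted p-values become z-scores through the inverse
   normal CDF, z = Φ⁻¹(1 − p).
2. A **greedy active-module search** on the network finds connected
   subnetworks maximizing the calibrated aggregate score
   z_A = Σz_i/√k; the top ten ranked modules merge into a **core
   subnetwork** per platform and contrast.
3. Per contrast, genes shared by all platforms' core subnetworks
   (platform coverage respected) form a **consensus module**; pairwise
   Jaccard overlap percentages, 100·G/(|CS¹|+|CS²|−G), are reported as a
   diagnostic.
4. Genes unique to one contrast's module are **phase-specific
   signatures**; genes common to all three are the **candidate
   disease-associated genes** (the module biomarker).
5. Candidates are validated by the exact hypergeometric tail
   P(X ≥ x) = 1 − Σ_{k<x} C(M,k)C(N−M,n−k)/C(N,n), by 10⁶-draw random
   sampling from the network universe, and by stratified 5-fold
   cross-validated SVM classification of case vs control samples
   (ROC/AUC).

A synthetic-data module generates networks, planted connected modules
with a shared core, multi-platform profiles and known-gene lists under a
single master seed, so the whole pipeline is testable end to end without
any external download.

## Worked example

```r
library(phasenet)

bundle <- synthetic_bundle(n_nodes = 300, seed = 1)   # network + planted truth
fit <- phasenet(bundle$network, bundle$profiles,
                known_lists = bundle$known_lists,
                case_control = case_control_data(bundle$profiles[[1]]),
                enrich_reps = 1e5, seed = 1)
summary(fit)
#> Phase-specific network module analysis
#>   profiles: profile1, profile2, profile3
#>   consensus module [early-middle]: 39 genes, 59 interactions
#>   consensus module [middle-late]: 55 genes, 99 interactions
#>   consensus module [early-late]: 39 genes, 64 interactions
#>   candidate disease-associated genes: 13
#>   unique signatures [early-middle]: 8 genes
#>   unique signatures [middle-late]: 5 genes
#>   unique signatures [early-late]: 1 genes
#>   enrichment vs 'known': x = 11/13, p_hyper = 4.03e-09, p_mc = 1e-05
#>   candidate-panel cross-validated AUC: 1.0000

round(recovery_metrics(bundle$truth, fit$candidates), 3)
#> precision    recall        f1
#>     0.846     0.917     0.880
```

Reading the output: each consensus module collects the genes (and their
induced interactions) that every platform's module search recovered for
one phase transition; the 13 candidates sit in all three, 11 of them are
on the 40-gene known list (hypergeometric tail 4×10⁻⁹, sampling p-value
10⁻⁵ at 10⁵ draws), and as a classifier panel they separate late-phase
from control samples with AUC 1.0. Against the 12-gene planted core the
candidate set has F1 = 0.88.

The same analysis runs from files via a YAML configuration
(`run_pipeline("config.yaml")`) or from a shell via the wrapper in
`inst/cli/phasenet.R` (subcommands `simulate`, `de`, `modules`,
`consensus`, `validate-enrichment`, `validate-classifier`, `run-all`).

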