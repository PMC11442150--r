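---
title: "DrugReSC: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DrugReSC: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DrugReSC)
```

DrugReSC ranks drug instances by their contribution to separating
disease-associated cells from other cells in a single-cell expression
matrix. This vignette explains the model stage by stage, the parameters
that matter, the synthetic generator used for validation, and the design
choices made where more than one reasonable option existed.

## Inputs and their assumptions

Three inputs are required. The **expression matrix** is log-scale
(log2 of a TPM-like quantity plus a pseudocount), genes × cells, with
unique gene symbols and cell identifiers and finite values. Only the
*rank order of absolute expression within each cell* enters the scoring,
so any monotone within-cell normalisation gives identical results; this
is deliberate robustness, not an accident. The **cell labels** are
binary — 1 for disease-associated cells as called by any upstream
phenotype-association method, 0 otherwise; both classes must be present.
Label/matrix cell sets must match exactly: a mismatch is an error, never
a silent intersection, because silently dropped cells usually indicate a
misaligned upstream labelling. The **drug DE profiles** give, per drug
instance, a log-fold-change and p-value per gene against vehicle
control; these vectors are consumed as given (whether they came from
moderated or plain statistics is upstream's choice).

## Signature construction

Per instance, the up-signature is {g : c~g~ > 0, p~g~ < 0.01} and the
down-signature {g : c~g~ < 0, p~g~ < 0.01}. Both inequalities are
strict; genes at c~g~ = 0 or p~g~ = 0.01 are excluded. No
multiple-testing correction is applied to the drug p-values — the
threshold acts as a signature-size control, not an inference. Instances
are filtered to one treatment dose (default 10 µM, the most common assay
concentration in large perturbation screens; micro-sign and "u" spellings
are treated as equal). Instances whose two sides are both empty are
excluded with a warning rather than scored 0, since an all-zero
drug-by-cell row would distort the importance null.

## The enrichment walk and D2C scores

Within a cell, genes are sorted by |expression| descending; the top gene
receives rank N, the bottom rank 1. Ties in |expression| are broken by
lexicographic gene symbol. The walk needs a total order, and a
deterministic symbol tie-break keeps every run bit-reproducible; average
ranks inside a weighted walk would buy little and cost exactness (the
implementation must match a brute-force oracle to 1e-12, which it does —
see the test suite). Because ranks here are positive integers, the
absolute value in the |r~j~|^α^ weight is a formal no-op, kept for
fidelity to the weighted-walk definition.

For signature G the hit curve accumulates rank weights |r~j~|^α^
(α = 0.25 by default; larger α emphasises extreme ranks) normalised by
the signature total, while the miss curve rises by 1/(N − N~G~) per
non-signature gene. The enrichment score is the *signed* value of
P~hit~ − P~miss~ at the position of maximal |P~hit~ − P~miss~|, ties
resolving to the earliest position. The signed reading preserves the
directionality that the D2C difference needs. Two degenerate cases are
errors rather than conventions: a signature with no gene in the matrix
(nothing to walk) and a signature covering all N genes (the miss
denominator N − N~G~ vanishes).

D2C = ES~up~ − ES~down~ ∈ [−2, 2]. A positive score means the cell's
profile is concordant with the drug's induced changes; in the reversal
reading, drugs whose *down*-signature is enriched in a cell's
highly-expressed genes (and vice versa) score negatively there. If
exactly one side of a signature is absent from the matrix, the other
side alone is used (with a warning); if both are absent the instance is
dropped and logged. The matrix transform processes one cell at a time —
a single sort per cell shared across all signatures — so memory stays at
O(genes + instances × cells).

## Random-forest permutation importance

The forest (100 trees by default; Gini impurity, unlimited depth,
minimum node size 1 — standard classification-forest defaults) treats
cells as observations and instances as features. mtry is selected by
minimum out-of-bag error over the grid {⌊√D/2⌋, ⌊√D⌋, ⌊2√D⌋, ⌊D/3⌋}
clipped to [1, D], ties to the smallest value.

Importance is computed on raw correct-vote *counts*: for tree t,
C~td~ counts correct out-of-bag predictions; then instance d's values
are permuted within the out-of-bag set (one fresh permutation per
(d, t) pair from a seeded stream; `n_permutations` allows inner
averaging for variance reduction), the out-of-bag cells are re-predicted
through tree t, and the raw score is the mean over trees of
C~td~ − CP~td~. The conventional mean-decrease-accuracy variant — each
difference divided by the tree's out-of-bag size — is available behind
`scale = "rate"`; the count form is the default because it is the
definition this package commits to, and the two orderings agree up to
the mild variation in out-of-bag sizes. A constant column scores exactly
zero, as permuting it changes nothing.

Raw scores are standardised by min–max to [0, 1]. When all raw scores
are equal the standardised score is defined as 0.5 everywhere (with a
warning): no instance is distinguished, and 0.5 avoids fabricating a
best or worst. Ranks break ties by (−score, instance id).

## Alternative backends

*Wilcoxon*: two-sided rank-sum p per instance, importance −log10 p.
The continuity correction is disabled so that identical group multisets
give p = 1 exactly; with no ties and small n the exact distribution is
used. *ANOVA*: Bartlett's test at level 0.05 (a conventional gate;
nothing in the method is sensitive to this choice) routes each instance
to the classic one-way F or the Welch F, importance = F. *L1 logistic*:
glmnet with 5-fold CV; the CV-optimal penalty is used (the natural
reading of "minimum regularisation strength" selected by CV), and
importance is |coefficient| × feature sd, i.e. on the standardised
scale. *SVM sensitivity* and *boosting gain* are optional adapters over
e1071 and xgboost and are comparators, not part of the core surface.
*Vote*: a method votes for an instance that lands in the top half of its
ranking; instances with ≥ 3 votes are ensemble candidates. Top-half
membership makes votes comparable across methods whose score scales
differ by orders of magnitude.

## Evaluation protocol

Ground truths are balanced: all known positives plus an equal number of
negatives drawn uniformly without replacement from the candidate pool,
replicated (default 10 samplings with derived seeds master+1..master+n),
metrics averaged with sample sd. AUROC uses the Mann–Whitney pair
convention (0.5 per tied pair). AUPR integrates step-wise down the
ranked list with tied scores grouped, so an all-tied ranking scores the
prevalence. F1 is the standard harmonic mean 2TP/(2TP + FP + FN);
accuracy is (TP + TN)/total. Both need hard labels: the default
binarisation predicts positive for the top m = |positives| instances
(on balanced truths this is a median split), ties broken by instance
id; a fixed threshold is available. A single replicate reports sd = 0
with an explicit flag.

## The synthetic generator

`simulate_cohort()` emulates the statistical structure the method
assumes, at desk scale. Baseline log2 expression is Gaussian
(per-gene means Uniform(1, 8), sd = `noise_sd` = 1, clipped at 0) — a
count layer would add nothing testable, because only within-cell rank
order enters the scoring. Defaults: 2000 genes, 300 cells, 10% disease
cells, a 100-gene program split into an up- and a down-half shifted by
±`effect_size` (default 2 log2 units) in disease cells. Positive drugs
*reverse* the program: their down-signature covers a
`reversal_strength` fraction (default 1) of the program's up-half,
their up-signature the matching fraction of the down-half. Signature
genes get |logfc| ~ |N(effect, 0.2)| with p ~ Uniform(1e-6, 0.009) —
strictly below the 0.01 cutoff, so signature recovery from the DE table
is exact and the signature-construction tests stay sharp; background
genes get p ≥ 0.2.

Negative drugs receive signatures of matched sizes over random
non-program genes, organised in blocks of `n_positive_drugs` instances
that share a random "decoy program" each member partially reverses. The
block structure matters: positive drugs for one indication necessarily
overlap in the program genes they reverse, which correlates their D2C
columns, and permutation importance is known to favour groups of
correlated features offered to the forest more often. If negatives were
drawn independently, that bias alone would separate the groups even with
no planted effect. With matched blocks the positive and negative groups
are exchangeable at `effect_size = 0`, so the null benchmark is
calibrated at chance, while decoy programs carry no phenotype signal at
any effect size.

What the generator does **not** emulate: landmark-gene panel structure
and expression-inference tiers of real perturbation assays, dropout and
library-size variation of real scRNA-seq, correlated gene modules beyond
the planted program, and dose–response structure (every instance sits at
10 µM). Passing tests therefore show the pipeline recovers planted
reversal structure under clean Gaussian noise — not that it matches any
particular real-data benchmark.

## Determinism and numerical choices

Every stochastic step (bootstrap draws, permutation streams, CV folds,
negative samplings, simulation) derives from an integer seed, and a full
scoring run is bit-reproducible under a fixed master seed. The optimised
cumulative-sum enrichment walk is required to agree with the
brute-force walk to 1e-12 (property-tested over random rankings,
signatures and α). Validation problem sizes — 2000 × 300 cohorts, 10
seeds per condition, 10 negative samplings — were chosen so the full
suite completes in a few minutes on one CPU while keeping the planted
signal and the null calibration unambiguous.

## Known limitations

Labels are an input: the quality of the upstream disease-cell calls
bounds everything downstream. Permutation importance shares credit among
strongly correlated instances (e.g. replicates of the same compound), so
per-drug aggregation across instances should be done at reporting time.
The method ranks contribution to the phenotype classification and does
not by itself distinguish phenotype-reversing from phenotype-promoting
drugs; the sign information lives in the D2C matrix (compare group means
per instance) rather than in the importance score. Length-aware TPM is
not computed internally — the normalisation helper uses total-count
scaling to 1e6, and users with gene lengths should normalise upstream.
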