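---
title: "Predicting skin sensitization with QSAR, similarity and structural alerts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting skin sensitization with QSAR, similarity and structural alerts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinqsar)
library(dplyr)
```

## The problem and the model

Skin sensitization — a heightened immune response on topical exposure — is a
primary toxicological endpoint for cosmetic and dermatology products, and the
one that regulatory pressure most urgently demands animal-free methods for.
The mechanistic chain is well understood through the adverse outcome pathway:
an electrophilic molecule (or its metabolite) covalently modifies skin
proteins, and that haptenation event initiates the immune cascade. skinqsar
implements an integrated in-silico predictor built on three complementary
lines of evidence:

1. **Potency-stratified QSAR models.** Binary classifiers trained to separate
   sensitizers from non-sensitizers, stratified by potency class (extreme
   `X`, strong `St`, unknown-potency `S`, moderate `M`, weak `W` versus
   non-sensitizer `N`): model-2 is trained on {X, St, S} vs N, model-3 on M
   vs N, model-4 on W vs N. (A model-1 for {X, St} alone can be assembled,
   but the generalized model-2 covers its strata, so the shipped workflows
   use models 2–4.) Each model is a *variant grid*: five descriptor-set
   recipes x three train/test split strategies x five classifier families,
   addressed by codes like `2C4RF` (model-2, cross-validation split,
   descriptor set-4, random forest).
2. **Structural similarity.** A test molecule is screened against the
   labeled reference pool with 1024-bit hashed linear-path fingerprints and
   the Tanimoto coefficient `|A∩B|/|A∪B|`. If the best coefficient reaches
   0.6 the molecule votes with the class of its most similar neighbor(s).
3. **Structural alerts.** A SMARTS library of skin-protein reactive groups —
   Michael acceptors, Schiff-base-forming carbonyls, acyl-transfer agents,
   SN2 alkylating agents, SNAr-activated haloaromatics and related
   electrophiles. Any match votes sensitizer; no match votes
   *non*-sensitizer (score −1, not 0), because the absence of a reactive
   group is itself evidence against protein haptenation.

The five component votes are merged by a weighted consensus

```
score = m2·w_m2 + m3·w_m3 + m4·w_m4 + s_similarity·w_similarity + s_substr·w_substr
```

with *direction-specific* weights: the weight applied depends on which way
the component votes (a sensitizer call by model-2 may carry weight 1 while a
non-sensitizer call carries 0.8). A positive score means sensitizer, negative
means non-sensitizer, and exactly zero is *indeterminate* — the workflow
abstains rather than guessing. Four built-in weight schemes (`KB-a`..`KB-d`)
encode knowledge-based weightings; `KB-b` is the default. Alternatively,
`meta_integrate()` trains a perceptron or linear max-margin combiner on the
raw vote vectors; a trained combiner never abstains.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| Tanimoto cutoff | 0.6 | minimum coefficient for a similarity vote; exactly 0.6 passes |
| t-test alpha | 0.05 | Welch two-sided significance level for descriptor screening |
| best-first patience | 5 | consecutive non-improving expansions before the CFS search stops |
| trees | 100 | tree-ensemble size; all other classifier families use their defaults |
| train fraction | 0.8 | the D and S split strategies hold out 20% |
| folds | 10 | cross-validation folds for the C strategy and meta-integration |
| weight scheme | KB-b | consensus weights; substructure pair is (1, 0.5) because presence is stronger evidence than absence |
| seed | 20160607 | every stochastic operation takes an explicit seed |

## Design choices

**Weights are direction reads, not signs.** The weight tables list separate
columns for sensitizer-direction and non-sensitizer-direction calls. We read
them as the magnitude multiplied by the signed vote (contribution =
value x weight(component, direction)). This is the only reading consistent
with a weighted sum of ±1 votes and with the zero entries for the
no-match/tie similarity directions.

**Score-zero comparison.** The consensus sum is rounded to 10 decimals
before the sign test. All built-in weights are tenths, so every reachable
score is an exact multiple of 0.1 and the indeterminate test is exact, not
an epsilon comparison.

**CFS merit.** The correlation-based subset evaluator is concretized as
`M_S = k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)` with Pearson feature–feature
correlation and point-biserial feature–class correlation. The search is
forward best-first with an open list ordered by merit, deterministic
lexicographic tie-breaking, and a patience of 5 non-improving expansions —
on every random instance with ≤ 10 features we have tested it attains the
exhaustive-search optimum. Note that an exact duplicate of a selected
feature leaves the merit unchanged (2r/√4 = r), so redundant copies are
never added: improvement must be strict.

**"Least average similarity".** Model-1's diverse non-sensitizer pick and
the diversity selections are defined as the k molecules with the smallest
mean pairwise Tanimoto coefficient to the rest of the candidate pool (self
excluded). The stratified representative pick is a per-class greedy max–min
selection seeded at the least-average-similarity member. Both are
deterministic and order-invariant (ties break by molecule id).

**Meta-learner inputs.** The meta-classifiers see the raw component votes in
{−1, 0, +1}, not the weighted contributions: feeding weighted contributions
would entangle the learned combiner with a particular hand-set scheme, and
the linear combiner can recover any weighting itself.

**Identity checking.** Two molecules are "the same" only on full
27-character InChIKey equality. Prefix matching would conflate
stereoisomers, and the point of the check is to confirm that a
100%-Tanimoto neighbor really is the same structure (hashed path
fingerprints can collide).

**Structure handling.** Parsing, canonicalization, InChIKeys, FP2
fingerprints and SMARTS matching all run through OpenBabel (via ChemmineR /
ChemmineOB). No 3D structures are generated: all features here are 2D, and
molecules that fail parsing or sanitization are excluded with a logged
count, mirroring the standard practice of dropping structures that fail
conversion. Salts and mixtures are not desalted. One toolkit limit worth
knowing: the SMARTS interface reports unique-match *counts* per pattern, not
matched atom indices, so alert verdicts carry per-alert match counts rather
than atom lists.

**Descriptors are pluggable.** The built-in provider computes a compact 2D
set (OpenBabel physicochemical properties plus constitutional counts from
the canonical SMILES). Any table with an `id` column and numeric features
can replace it — the selection, reduction and training machinery is
indifferent to the provider. We deliberately do not re-implement any large
published descriptor engine; the per-model descriptor lists of such engines
are data, not code.

## The synthetic benchmark: what it does and does not emulate

`generate_benchmark()` builds labeled molecule sets with the statistical
structure the workflow assumes: sensitizers are scaffolds (a fixed pool of
~30 simple drug-like ring systems and chains) with a *planted* electrophilic
fragment grafted on by SMILES suffix concatenation, optionally through an
inert linker; non-sensitizers are the same scaffolds with only inert
decoration. Every structure is validated, verified against the alert
library (sensitizers must match their planted alert; non-sensitizers must
match nothing), and deduplicated by InChIKey. Class prevalence and the
potency mix default to the labeled-pool proportions (X 17 : St 32 : S 180 :
M 90 : W 74 over 393 sensitizers, prevalence 393/543).

This emulates: class structure, the coupling between sensitizer status and
reactive sub-structures, fingerprint diversity, and descriptor separation.
It does **not** emulate real chemical space: real sensitizers include
pro-haptens that require metabolic activation, alert-free sensitizers, and
non-sensitizers that *do* carry nominal alerts. Passing the end-to-end
check on this benchmark therefore demonstrates that the machinery is wired
correctly and can recover a signal that is genuinely present — it does not
certify real-world predictive performance, which depends on the training
data and alert library supplied.

## Worked example

```{r example, eval = FALSE}
library(skinqsar)

# a desk-scale benchmark: 120 molecules, parent-pool class structure
bm <- generate_benchmark(benchmark_spec(n = 120, seed = 11))
class_counts(bm)

# hold out 20% with the class-proportional separation split
sp <- split_dataset(bm, "S", seed = 42)
train <- dplyr::filter(bm, id %in% sp$id[sp$subset == "train"])
test  <- dplyr::filter(bm, id %in% sp$id[sp$subset == "test"])

# train the shipped workflow (variants 2C4RF, 3C2RF, 4C2RF; scheme KB-b)
bundle <- train_workflow(train, workflow = "PW-2", seed = 99)

res <- run_workflow(test, bundle)
evaluate_workflow(res, test)
autoplot(res)
```

## Numerical conventions and degenerate inputs

* Welch t-test screening excludes zero-variance-in-both-classes features up
  front (they carry no signal and an undefined t statistic) and reports
  them; a class with fewer than two members is an error, not a silent NaN.
* Correlations against constant features are treated as 0 in the CFS merit.
* Tanimoto of two empty fingerprints is defined as 1 (two featureless
  structures are maximally similar); the similarity tie rule applies at the
  maximal coefficient only, since the vote is by *highest* similarity.
* Performance measures exclude indeterminate predictions from every
  denominator and report them separately; this is the only convention
  consistent with published leave-one-out tables where 8 abstentions among
  74 predictions with 49 correct yield 74.24% (49/66), not 66.2% (49/74).
  Display rounding is two decimals, half-up.
* An all-constant vote matrix for meta-integration degrades to a
  majority-class predictor with a warning rather than an opaque fit error.

## Problem sizes used in the shipped checks

The test-suite and the reproduction script run at desk scale, chosen as the
smallest sizes at which each property is cleanly observable: the end-to-end
workflow check trains on 80% of a 400-molecule benchmark; the Y-randomization
check uses a 120-molecule benchmark with 10 permutation runs; the CFS oracle
comparison runs 100 random instances of up to 10 features against exhaustive
enumeration; the type-I-error simulation screens 20 replicates of 1000 null
features at n = 20 per class.

## Known limitations

* Classifier families are the standard R analogs (randomForest, linear-kernel
  SVM, rpart, nnet, binomial GLM), not bit-exact replicas of any other
  toolkit's implementations; per-variant accuracies on real data will differ
  in the decimals even under identical protocols.
* The shipped alert library encodes the canonical electrophilic reaction
  domains as curated SMARTS; it is a starting point, and any
  literature-derived library with columns `id`, `smarts`, `mechanism` can be
  dropped in.
* No applicability-domain index beyond the component provenance is computed,
  and no pro-hapten (metabolic activation) prediction is attempted.
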