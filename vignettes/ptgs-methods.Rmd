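---
title: "Building and scoring a predictive toxicogenomics space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and scoring a predictive toxicogenomics space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most omics-based toxicity signatures are derived at a single dose, yet
toxicity is a dose phenomenon: the same compound is inert below its
potency threshold and cytotoxic above it. `ptgspace` implements a
pipeline that learns dose-relevant structure from a large
chemical-perturbation transcriptomics corpus even when each compound
was profiled at essentially one concentration. The trick is to borrow
dose information *across* compounds: each screening measurement sits at
a known distance from that compound's independently measured potency
(its GI50, the concentration giving 50% growth inhibition), so the
corpus as a whole spans a wide effective dose range. The selected
"predictive toxicogenomics space" (PTGS) — a small ordered subset of
latent components and their associated genes — then scores new
expression experiments for cytotoxicity, rat liver pathology, and human
drug-induced liver injury (DILI) risk.

## The model, stage by stage

**Preprocessing** (`preprocess_corpus()`). Input is a normalized log2
expression matrix plus an instance table (compound, system, dose,
batch, control flags). The 5% of genes with the highest control
variance are removed corpus-wide; within each batch a robust control
reference is formed by dropping the control array with the largest
summed Euclidean distance to the others (none is dropped when only two
exist — dropping one of two would be arbitrary) and averaging the rest;
differential profiles are treatment minus reference (both already
log2); and only the strongest instance (largest Euclidean norm) is kept
per compound/system pair. All ties break lexicographically so the
pipeline is bit-deterministic.

**Activation counts** (`activation_counts()`). Each profile is reduced
to gene-set space by preranked gene-set enrichment: the weighted
Kolmogorov–Smirnov running-sum score (weight exponent 1, the classic
weighted statistic) against a permutation null of random same-size
sets. The permutation p-value is computed against the same-sign side of
the null — the convention that makes p uniform within each enrichment
direction — and FDR q-values are Benjamini–Hochberg adjusted within
direction. A q of exactly zero is floored at `1/(n_perm + 1)`. Counts
are `max(round(-log2(q)) - 1, 0)` (round-half-to-even), applied
separately to the positive and negative directions, so every gene set
contributes two signed features (`SET+`, `SET-`). A set whose members
all carry zero log-ratio receives an enrichment score of zero: it shows
no directional signal, and scoring it by the unweighted walk would
flag mid-ranked clusters as spuriously depleted.

**Component model** (`fit_components()`). The integer count matrix is
the corpus of a latent Dirichlet allocation model: instances are
"documents", signed gene-set activations are "words", and K components
capture co-occurring activation patterns. Inference is collapsed Gibbs
sampling (Rcpp), with the symmetric Dirichlet concentrations `alpha`
and `beta` updated each sweep by a log-normal random-walk Metropolis
step (step 0.1) against Gamma(1, 1) hyperpriors. Posterior means of
theta and phi are accumulated after burn-in with thinning; the
collapsed log joint is recorded per sweep so convergence is
inspectable. Instances without any activation keep the uniform prior
mixture. Component labels are arbitrary: every downstream consumer is
permutation-safe, and recovery tests match components by exact
assignment (bitmask dynamic programming) on cosine similarity.
`choose_component_count()` picks K by how well compound–compound
cosine similarity in component space retrieves annotation-sharing
pairs.

**Fusing with potency** (`cumulative_auc_selection()`). For the
instances with potency data, the concentration-dependent cytotoxicity
is `i_TOX = log10(concentration) − log10(GI50)`; an instance is
labelled cytotoxic when `i_TOX > 0` (strictly above the GI50 level).
Components are ranked by their probability-weighted mean i_TOX, with
`p(i|z)` obtained from theta by Bayes inversion under a uniform
instance prior (a token-count prior is available via
`instance_prior = "tokens"`). Components are then added in rank order,
the cumulative theta mass serving as a classifier score, and the space
is cut at the smallest prefix whose Mann–Whitney AUC reaches 95% of
the curve's maximum — trading a little AUC for a much smaller, more
interpretable space. Selected components are labelled A, B, C, … in
rank order. `calibrate_score_threshold()` reports both the
prevalence-targeted threshold (smallest score above which the
cytotoxic fraction reaches 50%) and the Youden point.

**Gene space** (`derive_gene_space()`). Each selected component is
characterized by its top instances and top gene sets (smallest prefix
of cumulative probability 0.2; boundary ties break by id). Every gene
in the top sets is tested with a two-sided one-sample t-test of its
log2 ratios against zero across the top instances — the one-sample
form is the coherent reading because the profiles are already
differential. Genes at p < 0.01 form the component list, ranked by
ascending p with the sign of the mean as direction; a gene may appear
in several components with opposite directions. Pooling all tests, the
genes surviving Bonferroni correction (pooled denominator; a
per-component denominator is available by flag) form the core set.

**Gene-based scoring** (`rotation_set_test()`,
`virtual_gi50_call()`). New experiments are scored against the gene
lists with the ROAST rotation gene-set test (limma) using the
floormean summary and non-directional (mixed) p-values,
`p = (b + 1)/(n_rot + 1)`; the proportion of list genes with moderated
|z| > √2 is the `%active` statistic. Moderated z-scores come from the
limma empirical-Bayes pipeline via the augmented-df t-to-normal map.
With fewer than 3 residual degrees of freedom the rotation null is
unreliable and the implementation substitutes a sign-flip null over
the effect-plus-residual coordinates (the same decomposition limma
rotates), with a warning; the exhaustive version of that sign-flip
scheme also serves as the independent oracle in the tests. An
experiment is called active at the virtual GI50 level when its
PTGS_ALL q (BH across the experiment batch) is below 0.05 and more
than 25% of the list is active.

**Liver pathology** (`select_predictive_components()`). Ordinal
findings (present < minimal < slight < moderate < severe) are
cumulated from the lowest grade up, weighted scores use weights 1–5 on
the raw grade counts, and endpoints are dichotomized at the published
cutoffs (3 for present/minimal and weighted scores, 2 otherwise) with
a minimum-positives filter (10 for AUC analyses, more than 15 for
regression — both exposed as parameters since the source analyses used
both). Per endpoint, an elastic-net logistic model (mixing 0.5,
penalty chosen by repeated 3-fold cross-validated deviance) links the
component probabilities to the label. Per-component p-values are a
penalized score test: the leave-one-component-out elastic net chooses
the adjustment set at the cross-validated penalty, the adjustment set
is refitted without penalty so the score equations hold exactly, and
the classical GLM score statistic of adding the component is computed.
The refit step matters: testing against shrunken fitted values leaks
unexplained signal into correlated null components. Multiplicity is
handled by a nested procedure — endpoint groups screened by BH on
per-endpoint Simes p-values, then an adaptive two-step BH within
surviving groups at the group-adjusted level — and a component is
selected only where its q and the endpoint model's q (BH-adjusted
Wilcoxon p of the fitted score) both pass 0.05. The sum of the
selected components' probabilities is the component-based DILI score;
its decision threshold is the smallest score above which at least half
the treatments show pathology.

**Safety margins** (`dili_margin_analysis()`). For hepatocyte dose
series, the LOEL is the lowest concentration whose score is active
(non-monotone patterns keep the lowest active dose, logged); the
safety margin is `log10(LOEL) − log10(Cmax)`. The decision threshold
sits an epsilon (1e-9) below the smallest defined negative-control
margin, which makes specificity on the calibration negatives 100% by
construction; when every negative is inactive the threshold falls back
to a ceiling of 2 log10 units, the upper edge of the conventional
10–100-fold acceptable-margin band. Compounds below threshold are
DILI-positive; inactive compounds are negative (a screening read-out,
not an exclusion). `combine_predictions()` ORs calls across assays.

## The synthetic world

The generators state one fixed world and the tests live in it; none of
their parameters is tuned per test.

`simulate_corpus()` defaults: 200 compounds × 3 cell systems profiled
at 10 µM (log10 M = −5), 2000 genes in 50 partitioned sets (5 genes of
overlap each), K = 8 planted components of which 3 are toxic, GI50
drawn uniformly on [−8, −3] log10 M (the usual potency-screen range,
giving i_TOX spread of ±3), component gene effects of 2 log2 units on
their driver sets (a strong but realistic perturbation response),
Gaussian noise SD 0.3, batches of 20 with 3 controls. The toxic
components' mixture mass grows logistically in i_TOX; GI50/TGI/LC50
are spaced +0.5/+1.0 log10 units. What this world does *not* contain:
probe-level artifacts, batch waves beyond mean shifts, correlated
noise, or compounds with split mechanisms — so a green recovery test
establishes that the chain of estimators is consistent in a clean
regime, not that it survives every pathology of real arrays.

`simulate_pathology_study()` uses the in vivo design of 1:3:10 dose
ratios, 6 animals per treatment (3 nominally profiled), and
proportional-odds ordinal grades driven by a latent toxic activity.
The reported component probabilities are deliberately a *subset* of a
larger mixture: the planted predictive components' mass tracks the
toxic activity while the remaining components' values are drawn
independently of it. Without this decoupling the closure constraint
(rows summing to one) makes every component carry dose information
through the shared denominator, and "exact recovery of the planted
components" is not even statistically well-posed.

`simulate_dili_panel()` uses 1:5:25 hepatocyte dose ratios, Cmax on
[−7.5, −5.5] log10 M, and a planted margin gap of 2 log10 units:
negative controls activate (if at all) only at least 100-fold above
Cmax; positives activate below that band with probability 0.9 — a
detection rate, not a certainty, so the planted panel's expected
sensitivity is 90% at forced 100% specificity.

## Numerical choices and edge cases

- All concentrations are log10 molar internally; readers convert from
  µM on request. Margins are invariant to common unit shifts.
- AUC is the Mann–Whitney statistic with midrank tie correction
  everywhere, and is checked against a quadratic pair-counting oracle.
- `round` is R's round-half-to-even, including in the count
  quantization.
- The quantization formula is printed ambiguously in its source; the
  implementation uses the only reading that yields non-negative counts
  increasing with significance.
- Degenerate inputs: all-tied profiles enrich nothing (q = 1
  everywhere); empty count rows keep uniform mixtures; two-control
  batches skip outlier removal; single-class endpoints are skipped;
  degenerate cross-validation folds are reshuffled with a logged
  warning.
- Gibbs sampling uses R's RNG, so `set.seed()` makes fits
  bit-reproducible; enrichment permutations likewise.
- Test-suite runs scale the sampler to 500 sweeps / 250 burn-in and
  enrichment to 200 permutations; interactive defaults are 2000/1000
  and 1000. The recovery margins at the reduced scale are wide (matched
  cosines ≈ 0.95 against a 0.8 requirement).

## Known limitations

- The grouped multiple-testing procedure is a reconstruction of a
  two-step adaptive group BH; the exact internals of the published
  implementation it stands in for are not reproducible from its
  description.
- The floormean rotation statistic follows the limma implementation;
  the sign-flip fallback is a conservative stand-in below 3 residual
  df, not an exact equivalent.
- Retrieval-based selection of K assumes annotation-sharing compounds
  share components; with sparse or noisy annotations the retrieval AUC
  curve can be flat and K weakly identified.
- The safety-margin classifier treats Cmax as given (total blood
  concentration); no protein binding or pharmacokinetic adjustment is
  attempted.
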