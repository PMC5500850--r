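# ptgspace

Builds a **predictive toxicogenomics space (PTGS)** from
chemical-perturbation transcriptomics and uses it to score expression
experiments for cytotoxicity, rat liver pathology, and human
drug-induced liver injury (DILI) risk.

## Who this is for

Computational toxicologists and bioinformaticians who have (a) a corpus
of perturbation expression profiles (compound × cell system, log2
intensities with controls), (b) gene-set collections (GMT), and
(c) potency anchors (GI50/TGI/LC50 in log10 molar) — and who want a
dose-aware toxicity score that transfers to new experiments, including
in vivo and hepatocyte dose series.

## The method in brief

Single-concentration screens cannot show dose response per compound,
but across compounds every profile sits at a known distance from its
potency threshold:

`i_TOX = log10(concentration) − log10(GI50)`,

with `i_TOX > 0` marking measurement above the 50%-growth-inhibition
level. The pipeline:

1. **Preprocess**: control-variance gene filter, robust per-batch
   control references, log2-ratio profiles, strongest instance per
   compound/system.
2. **Activation counts**: preranked gene-set enrichment per profile;
   direction-specific FDR q quantized to integer counts
   `max(round(−log2 q) − 1, 0)` over signed features `SET+` / `SET−`.
3. **Component model**: latent Dirichlet allocation by collapsed Gibbs
   sampling (Rcpp) with Metropolis-sampled hyperparameters, giving
   instance mixtures θ and component emissions φ.
4. **PTGS selection**: components ranked by probability-weighted mean
   i_TOX, `tox(z) = Σᵢ p(i|z)·i_TOX(i)`; the space is the smallest
   rank prefix whose cumulative-score ROC-AUC reaches 95% of the
   curve's maximum; the score of an instance is its θ mass on the
   selected components.
5. **Gene space**: per-component gene lists by one-sample t-tests in
   the most active instances; Bonferroni core set; union list
   (`PTGS_ALL`).
6. **Gene-based scoring**: limma/ROAST rotation tests (floormean,
   mixed p), `%active = % genes with |z| > √2`; virtual GI50 calls at
   q < 0.05 and %active > 25.
7. **Liver pathology**: cumulative ordinal endpoints, weighted
   pathology scores (1·present + … + 5·severe), elastic-net +
   penalized-score-test selection of DILI-predictive components with
   nested grouped FDR control.
8. **Safety margins**: LOEL from hepatocyte dose series,
   `margin = log10 LOEL − log10 Cmax`, threshold calibrated for 100%
   specificity on negative controls.

Everything is testable offline: `simulate_corpus()`,
`simulate_pathology_study()` and `simulate_dili_panel()` generate all
five input kinds with planted ground truth.

## Worked example

```r
library(ptgspace)

sim <- simulate_corpus(n_compounds = 60, n_systems = 2, n_genes = 1000,
                       n_sets = 24, K_true = 6, n_toxic = 2, seed = 42)
pp <- preprocess_corpus(sim$expr, sim$instances)
set.seed(42)
counts <- activation_counts(pp$profiles, sim$sets, n_perm = 200)
fit <- fit_components(counts, K = 6, n_sweeps = 500, burn_in = 250,
                      thin = 5, seed = 42)
fit
#> PTGS component model: K = 6 over 48 signed features, 120 instances
#>   alpha = 0.153  beta = 0.04712

itox <- sim$truth$itox[rownames(fit$theta)]
probs <- component_instance_probabilities(fit, rownames(fit$theta))
ranking <- weighted_component_cytotoxicity(probs$p_i_given_z, itox)
round(ranking$tox, 3)
#>     C4     C2     C3     C1     C5     C6
#>  1.566  1.559  0.071 -0.286 -0.465 -0.466

ptgs <- cumulative_auc_selection(ranking, fit$theta, itox > 0)
round(ptgs$auc_curve, 3)
#> [1] 0.909 0.993 0.929 0.877 0.784 0.307

score <- ptgs_component_score(fit$theta, ptgs)
cor(score, itox, method = "spearman")
#> [1] 0.915
```

The two components with the highest probability-weighted cytotoxicity
(1.57 and 1.56 log10 units above GI50 on average) are selected as the
PTGS — the cumulative AUC peaks at two components (0.993) and adding
more only dilutes it. The resulting score correlates strongly
(Spearman 0.92) with the planted concentration-dependent cytotoxicity:
high-scoring instances are the ones measured above their GI50.

DILI classification from a hepatocyte dose-series panel:

```r
panel <- simulate_dili_panel(seed = 42)
res <- dili_margin_analysis(panel$doses, panel$annotations)
sprintf("margin threshold %.2f; sensitivity %.0f%%; specificity %.0f%%",
        res$threshold, res$sensitivity, res$specificity)
#> [1] "margin threshold 2.62; sensitivity 88%; specificity 100%"
```

The threshold sits just below the smallest negative-control margin, so
specificity is 100% by construction; compounds whose PTGS activation
starts within ~2.6 log10 units of their therapeutic Cmax are flagged.

## Command line

A thin CLI wraps the same functions:

```sh
exec/ptgs simulate --what corpus --out-dir fixtures --seed 1
exec/ptgs preprocess --expr fixtures/expr.tsv --instances fixtures/instances.csv --out profiles.tsv
exec/ptgs enrich --profiles profiles.tsv --gmt fixtures/sets.gmt --n-perm 1000 --seed 1 --out counts.tsv
exec/ptgs fit --counts counts.tsv --k 100 --seed 1 --out model.json
exec/ptgs select --model model.json --potency fixtures/potency.csv --instances fixtures/instances.csv --out ptgs.json
exec/ptgs power --what auc --total 1689 --auc 0.75
```

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch —
simulate, preprocess, enrich, fit, select, score, pathology component
selection, and DILI margin classification — under a given seed, logs
the headline quantities of each stage, and writes the acceptance
report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
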