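# odorstrength

Ordinal odor-strength modeling from molecular structure, in R.

How strongly a molecule smells — odorless < low < medium < high — is an
ordinal perceptual attribute governed largely by mass transport: an odorant
must be volatile enough to reach the olfactory epithelium, yet have the
right balance of polarity and lipophilicity to cross the mucus layer and
reach the receptors. `odorstrength` provides the full workflow for building
and auditing ordinal odor-strength predictors in this setting, for
computational chemists and QSAR/QSOR practitioners:

* **Synthetic two-source data.** Real strength annotations are scattered
  across databases with incompatible licensing, so the package ships a
  generator that emulates their statistical structure: molecules from a
  fragment grammar; a latent mass-transport score
  `s = beta0 - beta_mw*|MW - mu_mw| - beta_logp*|logP - mu_logp| +
  beta_pol*(HBD + HBA) + noise` thresholded at `tau1 < tau2 < tau3`; two
  annotation sources with different class profiles, an overlap, and
  adjacent-category label noise calibrated so that the chance-corrected
  agreement on the overlap is about 0.8.
* **Curation.** Keyword mapping of free-text odor descriptions, SMILES
  canonicalization (OpenBabel), dot/invalid-SMILES filters, duplicate
  removal, "very high" reclassification, source merging, and agreement
  statistics: quadratically weighted Cohen's kappa and ordinal
  Krippendorff's alpha.
* **Featurization.** Physicochemical + topological descriptor vectors and
  six fingerprint families (Morgan bits/counts at radius 3 / 2048 bits,
  MACCS keys, path, topological torsion, atom pair), with Tanimoto
  similarity.
* **Leakage-aware splits.** Molecules with Tanimoto >= 0.8 are grouped into
  connected components that move atomically through stratified 80/20
  holdouts and repeated k-fold cross-validation.
* **Ordinal learners.** Direct four-class logistic, random forest, XGBoost,
  MLP, and a CORAL cumulative-logit model whose threshold biases are
  monotone by construction (rank-consistent `P(y > k | x)` for every
  input); a hierarchical odorous-then-strength pipeline; a descriptor
  ensemble averaging member codes; budgeted hyperparameter search with
  percentile pruning.
* **Evaluation.** The macro-averaged ordinal MSE
  `macroMSE = (1/N) * sum_i MSE_i` (N = number of categories, `MSE_i` the
  squared-code error within true category i), micro MSE, F1, one-vs-rest
  ROC AUC, normalized confusion matrices, the 5x2cv paired t-test, and
  ordinal-vs-continuous rating comparison.
* **Explanation.** Shapley-value attributions (exact tree-path
  contributions for XGBoost, permutation sampling otherwise) summed over
  feature groups from complete-linkage clustering of feature correlations,
  with a silhouette-selected threshold.

## Worked example

```r
library(odorstrength)

cfg <- experiment_config(
  generator = generator_config(n_molecules = 1200, seed = 1),
  seed = 2, smoke = TRUE)       # 3-fold / 2-repeat layout for a quick run
res <- run_experiment(cfg)

res$curation$agreement
#> <agreement_report> n_overlap = 360, weighted kappa = 0.829, ordinal alpha = 0.810

res$evaluation
#> <evaluation_report> n = 240 | macro MSE 0.538 | micro MSE 0.554 | F1 macro 0.557 | accuracy 0.571 | ROC AUC 0.808

head(res$explanation$importance$groups[, c("rank", "importance", "members")], 2)
```

Reading the output: the two synthetic annotation sources agree at kappa
0.83 / alpha 0.81 on their 360-molecule overlap (the generator's target
regime); the direct descriptor ensemble (random forest + MLP + XGBoost)
reaches macro MSE 0.54 on the 240-molecule holdout, far below the best
constant predictor (macro MSE 1.5), with most residual errors in adjacent
categories; and the top attribution groups collect the size/lipophilicity
descriptors that drive the latent mass-transport score.

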