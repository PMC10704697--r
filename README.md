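# hybridgcn

Continuous protein solubility prediction in R, for protein engineers and
method developers who have per-residue sequence features and predicted
contact maps and want a regression model — not a soluble/insoluble label —
plus the evaluation and ablation machinery around it.

Solubility here is the supernatant-to-total ratio from cell-free expression
assays, a value in [0,1]. The model is a hybrid graph convolutional network:

* six per-residue feature blocks — language-model output probabilities
  (ESM, 20 channels), BLOSUM62 rows (20), AAPHY7 physicochemical properties
  (7), PSSM (20) and HMM (30) evolutionary profiles, SPIDER3 structural
  predictions (14) — are stacked into a hybrid node-feature matrix
  `H ∈ R^{L×C}` (C = 111);
* an **adaptive feature re-weighting (AFR)** gate rescales channels:
  `G = colMeans(H)`, `O = V G + b`, `W = σ(max(0, O))`, `R = H ⊗ W` —
  a per-protein, per-channel attention over feature channels;
* graph convolutions `X_k = relu(Â X_{k-1} W_k + b_k)` propagate features
  over the contact map, with `Â = D^{-1/2}(A + I)D^{-1/2}`;
* a tanh/softmax self-attention readout pools residues into one vector, and
  a sigmoid head maps it to a solubility in (0,1).

Training (Adam on per-protein squared error with analytic backprop,
RMSE-monitored early stopping) runs in compiled code; every stage also has
a pure-R reference implementation that the test suite uses as an oracle.
The package ships the full metric suite (RMSE, R², accuracy / precision /
recall / F1 / rank-based AUC at the 0.5 threshold), the 5-fold × 5-seed
cross-validation and fold-model ensembling protocol, four feature/module
ablation grids, and a synthetic-data generator that plants label signal in
known feature channels so relevance recovery by the AFR gate is testable
end to end with no external feature extractors.

## Worked example

Simulate a dataset with planted channel relevance (signal in the leading
ESM and HMM channels), fit, and evaluate on held-out proteins:

```r
library(hybridgcn)

sim <- simulate_dataset(sim_config(n_proteins = 300,
                                   length_range = c(30, 80), seed = 42))
cfg <- hybridgcn_config(gcn_hidden = 64, attention_hidden = 32,
                        epochs = 100, patience = 15, seed = 42)
fit <- hybridgcn(sim$records[1:240], cfg)
print(fit)
#> Hybrid GCN solubility regressor
#>   features: ESM+BLOSUM+AAPHY7+PSSM+HMM+SPIDER3 (C = 111), AFR on
#>   trained on 216 proteins (24 held out for early stopping), best epoch 51
#>   training RMSE 0.1741, best validation RMSE 0.0985

pred <- predict(fit, sim$records[241:300])
round(head(pred, 4), 3)
#> SYN0241 SYN0242 SYN0243 SYN0244
#>   0.319   0.515   0.180   0.436

y <- vapply(sim$records[241:300], `[[`, numeric(1), "solubility")
evaluate_predictions(y, pred)
#>    rmse    r2 accuracy precision recall    f1   auc
#> 1 0.157 0.686    0.817     0.895  0.654 0.756 0.889
```

The model explains about 69% of the held-out label variance (the oracle
ceiling for this generator is roughly 0.77) and classifies solubility at
the 0.5 threshold with AUC 0.89. The AFR gate's diagnostics recover the
planted relevance — informative channels are gated above noise channels:

```r
rep <- relevance_recovery_report(fit, sim$records[1:240], sim$ground_truth)
sprintf("gate gap %.3f, rank separation %.3f", rep$gap, rep$rank_auc)
#> "gate gap 0.065, rank separation 0.567"

block_importance(colMeans(afr_weights(fit, sim$records[1:240])),
                 fit$block_spans)
#>     ESM  BLOSUM  AAPHY7    PSSM     HMM SPIDER3
#>   0.520   0.502   0.500   0.506   0.503   0.500
```

ESM — one of the two planted-informative blocks — carries the largest mean
gate. Cross-validation and ablations follow the same interface:

```r
cv <- run_cv(records, cfg, cv_plan(n_folds = 5, seeds = 1:5))   # mean± sd report
grid <- ablation_grid(records, cfg, mode = "leave_one_out")     # 6 runs
both <- train_full_and_ensemble(records, cfg)                   # single + ensemble
```

Real datasets are read with `load_dataset()` from a directory of
`<id>.<BLOCK>.tsv` feature matrices, `<id>.contact.tsv` contact maps, a
`labels.tsv` table and an optional FASTA and manifest; `simulate_dataset()`
writes the same dialect. A command-line front end with `simulate`, `train`,
`cv`, `ablate`, `predict` and `evaluate` subcommands is installed at
`inst/cli/hybridgcn.R`.

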