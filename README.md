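# intlognet

Integrative network-penalized logistic regression for biomarker selection
across multiple case/control cohorts.

## The problem

Gene signatures selected from a single expression cohort reproduce poorly:
cohorts are small relative to the number of genes, features are highly
collinear, and every platform or laboratory adds its own offset. Simply
pooling cohorts ignores that heterogeneity; analyzing them separately wastes
the shared signal. `intlognet` fits **one** logistic regression jointly
across M cohorts, with a shared coefficient vector and per-sample intercepts
that a graph penalty shrinks toward one constant per cohort — heterogeneity
is absorbed where it belongs, in the intercepts, not in the biomarkers.

## The model

For stacked samples with features X, outcomes Y and known cohort membership,
the fit minimizes

    (1/N) Σᵢ [ −Yᵢ(β₀ᵢ + xᵢᵀβ) + log(1 + exp(β₀ᵢ + xᵢᵀβ)) ]
      + λ P_α(β) + μ β₀ᵀ L̃ β₀

where L̃ is the Laplacian of the within-cohort complete graph over samples
(so β₀ᵀL̃β₀ is the sum of squared within-cohort intercept differences), and
P_α is one of four variable penalties: lasso ‖β‖₁, elastic net
½(1−α)‖β‖₂² + α‖β‖₁, network ½(1−α)βᵀLβ + α‖β‖₁ with L the normalized
Laplacian of a feature network (e.g. a PPI graph), or abs-network — the same
quadratic form on |β|, letting interacting genes carry opposite-signed
effects. The optimizer is a proximal Newton iteration whose quadratic
subproblems are solved exactly by blockwise intercept solves alternating
with cyclic coordinate descent (soft-thresholding updates, compiled core),
with step-halving so the objective never increases. Per-cohort prediction
intercepts are the within-cohort averages of the fitted β₀. Details and
design choices are in `vignettes/integrative-network-logistic.Rmd`.

## Worked example

Simulate a four-cohort study driven by transcription-factor modules (20 TFs
× 10 targets, p = 220; the first four modules carry the signal), select λ by
five-fold cross-validation, and compare the integrated fit with direct
merging:

```r
library(intlognet)

cfg <- simulation_config(n_tf = 20, seed = 42)   # 4 cohorts, 100 + 100 each
sim <- simulate_datasets(cfg)

cv  <- cv_lambda(sim$train, penalty_config("abs_network", alpha = 0.5, mu = 1),
                 network = sim$network, fit_kind = "integrated", seed = 42)
fit <- cv$fit
fit

test <- list(X  = do.call(rbind, lapply(sim$test, `[[`, "X")),
             y  = unlist(lapply(sim$test, `[[`, "y")),
             ds = rep(1:4, each = 100))
p_int   <- predict(fit, test$X, dataset = test$ds)
merged  <- fit_merged(sim$train, penalty_config("abs_network", lambda = cv$best_lambda),
                      network = sim$network)
p_merge <- predict(merged, test$X)

round(c(auc_integrated = auc_rank(test$y, p_int),
        auc_merged     = auc_rank(test$y, p_merge)), 3)
unlist(selection_metrics(fit$beta, sim$beta_true)[c("precision", "recall")])
length(selected_subnetworks(fit, sim$network))
```

Output:

```
Penalized logistic fit (abs_network, lambda = 0.01, alpha = 0.5, mu = 1)
  85 / 220 nonzero coefficients; 7 outer iteration(s); converged
  dataset intercepts: -1.161, -0.414, 0.764, 1.265
auc_integrated     auc_merged
         0.958          0.941
precision    recall
0.4705882 0.9090909
[1] 42
```

The integrated model recovers the cohort-specific intercept ordering (true
means −3, −1, 1, 3, attenuated to match the shrunken coefficient scale),
predicts the pooled test sets better than direct merging, and finds 40 of
the 44 true signal genes (recall 0.91); the 85 selected genes induce 42
connected subnetworks of the TF graph. The command-line interface
(`exec/intlognet`)
exposes the same pipeline as `simulate`, `fit`, `cv`, `predict`,
`evaluate`, `experiment` and `subnets` subcommands.

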