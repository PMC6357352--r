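# drtransfer

Transfer-learning prediction of multi-drug response from paired mutation
and expression profiles, with the downstream pharmacogenomic statistics
that make the predictions useful.

## Who this is for and what it does

Cell-line screens pair genomic profiles with measured drug response
(log10 IC50 in µM, lower = more sensitive); tumor cohorts have genomes but
no response labels. `drtransfer` implements the bridging strategy of
pre-training two omics autoencoders on a large unlabeled tumor corpus and
transplanting their encoder halves — mutation encoder M_enc and expression
encoder E_enc, each `input → 1024 → 256 → 64` at full scale — into a joint
feed-forward network whose prediction head P
(`64 + 64 → 128 → 128 → 128 → D`) outputs the log-IC50 of all D drugs for
a sample at once. Every neuron computes `y = F(Σ wᵢxᵢ + b)` with ReLU
activations (linear at P's output); training is mini-batch Adam on MSE
with He-uniform initialization, an 80/10/10 train/validation/test split
and early stopping at 3 non-improving validation epochs.

Around that core the package provides:

* **Preprocessing**: log2(TPM+1) transform, low-information gene filter
  (mean < 1 or sd < 0.5 removed), MAF → binary mutation matrix over the
  four nonsynonymous classes, cross-cohort gene-universe alignment
  (`R/data_io.R`).
* **Imputation**: missing log-IC50 entries filled by a weighted mean over
  the 5 nearest drugs (`knn_impute_responses()`).
* **Benchmark**: the transfer model vs random initialization, PCA
  encoders, single-omics variants, multivariate linear regression and
  per-drug SVM, over repeated random splits (`run_benchmark()`).
* **Association statistics**: per-stratum and pan-cohort mutation–drug
  scans (two-tailed Welch t-tests, Bonferroni-adjusted P < 1e-5, mutation
  rate > 10%, ≥ 10 carriers per stratum) and extreme-responder
  characterization (1% response tails; cancer-type composition,
  differential mutation rates, top differentially expressed genes)
  (`R/association.R`).
* **Synthetic cohorts** with shared latent factors, driver mutations and
  a corpus→cohort transfer structure, so the whole pipeline is testable
  without any data downloads (`generate_cohort()`).

A command-line front end (`inst/cli/drtransfer`) exposes the subcommands
`simulate`, `impute`, `pretrain`, `train`, `predict`, `benchmark`, `scan`
and `responders`.

## Worked example 1 — train the transfer model on synthetic cohorts

```r
library(drtransfer)

sim <- generate_cohort(synthetic_config(seed = 7))   # corpus + cohort
ic  <- knn_impute_responses(sim$cohort$response)     # fill 10% missing

grid <- search_grid(layer1 = 64, layer2 = 32, bottleneck = 16,
                    batch_size = 64, screen_epochs = 5, refit_epochs = 60)
menc <- grid_search_autoencoder(sim$corpus$mutation,   grid, seed = 1)$encoder
eenc <- grid_search_autoencoder(sim$corpus$expression, grid, seed = 2)$encoder

split <- split_samples(colnames(ic), seed = 3)       # 240/30/30 samples
model <- assemble_model(menc, eenc, n_drugs = nrow(ic), seed = 4,
                        drug_ids = rownames(ic))
fit <- train_response_model(model, sim$cohort$mutation,
                            sim$cohort$expression, ic, split,
                            train_config(patience = 3, seed = 5))
round(c(test_mse = fit$metrics$mse, epochs = fit$metrics$epochs,
        median_spearman = median(fit$metrics$spearman)), 3)
#>        test_mse          epochs median_spearman
#>           1.082          29.000           0.854
```

Test-set MSE of 1.08 against a response variance near 2.5, and a median
per-sample Spearman correlation of 0.85, mean the model reproduces most of
each held-out sample's drug ranking. (Running an identically-architected
model with randomly initialized encoders on the same split gives a higher
test MSE — `run_benchmark()` quantifies that gap over repeated splits.)

## Worked example 2 — mutation–drug association scan

On a 200-sample cohort with three planted driver mutations (each shifting
one drug's log-IC50 by +1.0) among 50 genes × 20 drugs:

```r
cfg <- synthetic_config(latent_dim = 2, n_expr_genes = 20, n_mut_genes = 50,
                        n_drugs = 20, n_corpus = 10, n_cohort = 200,
                        n_drivers = 3, driver_effect = 1.0,
                        p_background = 0.2, p_driver = 0.3,
                        response_loading_scale = 0, noise_sd_response = 0.3,
                        missing_fraction = 0, n_strata = 1, seed = 81)
sim <- generate_cohort(cfg)
rec <- mutation_drug_scan(sim$cohort$response, sim$cohort$mutation)
subset(rec, significant,
       select = c(gene, drug, delta_ic50, t, p_adj, n_mut, n_wt, direction))
#>       gene     drug delta_ic50    t    p_adj n_mut n_wt direction
#> 101 MG0006 drug_001      1.023 19.1 3.14e-27    53  147 resistant
#> 562 MG0029 drug_002      0.985 22.3 1.05e-41    63  137 resistant
#> 823 MG0042 drug_003      0.976 21.8 8.45e-42    62  138 resistant
```

Out of 1000 Bonferroni-corrected tests the scan flags exactly the three
planted pairs, with ΔIC50 estimates near the true +1.0 (positive delta =
resistance-associated). Extreme-responder analysis on the same cohort:

```r
gr <- extreme_responder_groups(sim$cohort$response["drug_001", ], fraction = 0.05)
gr$size                                                        # 10 per tail
mean_mutation_burden(gr$resistant, sim$cohort$mutation, sim$truth$driver_genes)
#> [1] 1.7
mean_mutation_burden(gr$sensitive, sim$cohort$mutation, sim$truth$driver_genes)
#> [1] 0.3
```

Resistant extremes carry 1.7 driver mutations on average vs 0.3 in the
sensitive tail — the planted resistance drivers concentrate where the
response says they should.

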