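# histexpr

Predicting gene-expression panels from stained histopathology images by
**slide-level feature aggregation**.

## The problem

Intrinsic molecular subtypes of breast cancer (Luminal A/B, HER2-enriched,
Basal) and the prognostic gene panels behind assays such as PAM50 are
clinically valuable but require RNA profiling that is slow, expensive and
tissue-destructive.  An H&E-stained slide, by contrast, exists for nearly
every patient.  `histexpr` implements a pipeline that regresses a
configurable panel of gene-expression values (default: 138 genes, with a
50-gene intrinsic-subtype subset) on features extracted from tumour-
annotated image patches — and does so *efficiently*, by collapsing each
patient's patches to a single vector before any training happens.

Given patch features `x_1 … x_N` (one length-`F` vector per 224 x 224
patch, from a pluggable pretrained backbone), the slide representation is

    z = (1/N) * sum_i x_i

and a small 1-D convolutional regression head (C1: 256 kernels of size 5;
C2, C3: 512 kernels of size 1; ReLU; global average pooling; linear output
layer) maps `z` to the `G` panel genes, trained with Adam (learning rate
0.001), MSE loss, minibatches of 12 and early stopping (patience 4, at
most 150 epochs, best weights restored).  Because an epoch touches one
record per *patient* instead of one per *patch*, training cost — and
energy — drops by roughly the patch count per slide relative to the
conventional patch-based strategy, which ships alongside as
`patch_based_reference_train()` for comparison.

The supporting stages are all included: QuPath-style GeoJSON annotation
ingest, saturation-based tissue masking, stride-224 patch tiling, Macenko
stain-vector normalization, `log2(1+x)` expression preprocessing and panel
selection, Spearman / Benjamini-Hochberg FDR / R-squared evaluation, a
four-member soft-voting subtype classifier, and Kaplan-Meier / log-rank /
concordance-index / Cox survival analysis, plus synthetic-fixture
generators with known ground truth so everything is testable offline.

## Worked example

Train and evaluate on a synthetic cohort whose expression is a known
linear map of the patient-mean features (plus noise), then check that a
generated survival effect is recovered:

```r
library(histexpr)

co  <- make_cohort(n_patients = 120, patches_per_patient = 20,
                   n_features = 32, n_genes = 20, noise_sd = 0.1, seed = 1)
agg <- aggregate_cohort(co)            # 120 x 32 matrix of slide vectors
train_ids <- co$patient_ids[1:80]
test_ids  <- co$patient_ids[81:120]

fit <- train_head(agg[train_ids, ],
                  expr_matrix(unclass(co$expression)[train_ids, ],
                              scale = "log2p1"),
                  train_config(seed = 1))
fit
#> <trained_head> F = 32 -> 20 genes; 19 epoch(s), best epoch 15
#>   (monitored loss 0.7937), 72 record(s)/epoch

report <- evaluate_predictions(predict(fit, agg[test_ids, ]),
                               unclass(co$expression)[test_ids, ])
report
#> <eval_report> median rho: 0.922 across 40 patients, 0.777 across
#>   20 genes; 20/20 genes significant at FDR 0.05

clin <- make_survival(co$subtype_labels, hazard_ratio_lumB = 2, seed = 1)
d    <- dichotomise(clin)
cox_fit(d[!is.na(d$luminal_group), ], "luminal_group")
#>       parameter              term  n     hr ci_lower ci_upper         p
#> 1 luminal_group luminal_groupLumB 62 3.0952   1.6283   5.8835 0.0005652
```

The per-patient median correlation (0.92) exceeds the per-gene median
(0.78): each patient's expression *profile* is dominated by per-gene
baseline levels shared across patients, while per-gene correlations must
capture between-patient variation — the generator reproduces exactly this
contrast.  The Cox fit recovers an elevated Luminal-B hazard (true ratio
2; the estimate 3.1 sits inside its wide 62-patient confidence interval).

The training-energy bookkeeping behind the efficiency claim:

```r
energy_report(4, 8.48, 300)   # patch-based: 4 GPUs x 8.48 h x 300 W
#> <energy_report> 4 device(s) x 8.48 h x 300 W = 10,176 Wh (10.176 kWh)
energy_report(1, 0.66, 300)   # aggregation: 1 GPU x 0.66 h
#> <energy_report> 1 device(s) x 0.66 h x 300 W = 198 Wh (0.19 kWh)
```

A command-line wrapper over the same functions is installed at
`inst/cli/histexpr.R` (subcommands `fixtures`, `tile`, `normalise`,
`extract`, `aggregate`, `train`, `evaluate`, `survival`, `energy`,
`run-all`).

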