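# diliwfp — Bayesian weighted fingerprints for DILI prediction

`diliwfp` predicts drug-induced liver injury (DILI) potential from 881-bit
PubChem structural fingerprints, for cheminformaticians screening drug
candidates or natural-product libraries for hepatotoxicity risk. Its core is
a naive-Bayes feature-weighting scheme: for every substructure bit the
package estimates, with Laplace smoothing (pseudo-count k), the posterior
probability that a compound carrying the substructure is hepatotoxic,

    P(S|P) = (c_SP + k) / (N_P + 2k)
    P(P|S) = P(S|P) π_P / (P(S|P) π_P + P(S|N) π_N)
    L      = log2( P(P|S) / P(N|S) )

and bits with log-odds `L >= θ` are amplified by the weight `w = n·L`
(all other bits keep weight 1) before training two classifiers: a random
forest on the weighted feature matrix and an SVM on a precomputed Tanimoto
kernel — `a·b / (‖a‖² + ‖b‖² − a·b)`, which reduces exactly to
intersection-over-union on binary input. Decision cutoffs are calibrated to
a target sensitivity of 0.8 (missing a hepatotoxicant costs more than a
false alarm), (θ, n) are selected by stratified 10-fold cross-validation
over a grid, and the selected high-`L` bits double as a structural-alert
table. Fingerprints are read from PaDEL-Descriptor CSV output
(`Name,PubchemFP0,…,PubchemFP880`); a synthetic generator with planted
discriminative bits makes the whole pipeline testable without external data.

## Worked example

```r
library(diliwfp)

spec <- synth_spec(seed = 42)            # 180 positives, 132 negatives, 881 bits,
ds   <- synth_generate(spec)             # 10 planted causal bits (0.6 vs 0.1)
ds
#> <fp_dataset> 312 compounds x 881 bits (180 positive, 132 negative, 0 unlabeled)

# substructure statistics and structural alerts at the usual threshold
stats <- smoothed_stats(count_substructures(ds), k = 1)
head(alert_table(stats, theta = 2.5), 3)
#>   bit_index        L c_SP c_SN      category                            description
#> 1         8 3.491180  111    9 element count Hierarchic element counts (bits 0-114)
#> 2         9 3.379212  113   10 element count Hierarchic element counts (bits 0-114)
#> 3         1 3.175679  116   12 element count Hierarchic element counts (bits 0-114)

# cross-validated performance of the weighted-kernel SVM
cfg <- model_config("svm", theta = 1.5, n_mult = 15, seed = 1)
crossvalidate(ds, cfg, n_folds = 10)
#> <evaluation_report> 10-fold CV (svm): pooled AUC=0.994 AUPR=0.996 acc=0.872 sens=0.783 spec=0.992

# train, then score new compounds
model <- dili_train(ds, cfg)
model
#> <dili_model> svm; 312 training compounds; 14 weighted bits (theta=1.5, n=15); cutoff=0.7228

newds <- synth_generate(synth_spec(n_pos = 3, n_neg = 2, seed = 99))
round(predict_scores(model, newds), 3)
#> pos_0001 pos_0002 pos_0003 neg_0001 neg_0002
#>    0.797    0.881    0.703    0.448    0.259
```

The alert table lists the bits most enriched in hepatotoxic compounds: bit 8
appears in 111 of 180 positives but only 9 of 132 negatives, giving posterior
odds of 2^3.49 ≈ 11:1 in favor of the positive class — exactly the ten
planted causal bits surface at the top. The CV report shows the weighted
kernel separating the classes (pooled AUC 0.994) with the sensitivity/
specificity balance set by the 0.8 calibration target; prediction scores are
in [0, 1], and `predict_labels()` thresholds them at the model's calibrated
cutoff (0.723 here, so the third positive at 0.703 is missed — the price of a
cutoff tuned on training calibration scores rather than test data).

A command-line front end covering the same pipeline
(`synth`, `weights`, `cv`, `train`, `predict`, `report`) ships as
`inst/cli/diliwfp.R`:

```sh
Rscript inst/cli/diliwfp.R synth --out-dir data --seed 7
Rscript inst/cli/diliwfp.R cv --fingerprints data/fingerprints.csv \
    --labels data/labels.csv --algorithm svm --out-dir cvout
```

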