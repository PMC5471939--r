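---
title: "Bayesian weighted fingerprints for DILI prediction: models and methods"
author: "diliwfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian weighted fingerprints for DILI prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diliwfp)
```

## The problem

Drug-induced liver injury (DILI) is a leading cause of drug withdrawal, and a
binary in-silico flag — "does this structure look like the hepatotoxic ones we
already know?" — is cheap enough to run over whole compound libraries.
`diliwfp` works on 881-bit PubChem structural fingerprints: each bit marks the
presence of a predefined substructure (element counts, ring systems, atom
pairs, neighbor patterns, SMARTS patterns). The package does not compute these
fingerprints; it ingests the CSV dialect written by PaDEL-Descriptor, the
standard tool for producing them, and everything downstream treats the 881-bit
vector as the compound.

## The weighting model

Let $P$ and $N$ be the positive (DILI-concern) and negative classes with
$N_P$ and $N_N$ training compounds, and let $S$ denote "substructure $S$
present". For each bit we count occurrences per class ($c_{SP}$, $c_{SN}$)
and estimate the class-conditional presence probabilities with Laplace
smoothing over the two outcomes (present/absent):

$$P(S \mid P) = \frac{c_{SP} + k}{N_P + 2k}, \qquad
  P(S \mid N) = \frac{c_{SN} + k}{N_N + 2k}.$$

Bayes' rule with empirical class priors $\pi_P = N_P/(N_P+N_N)$ gives the
posterior that a compound carrying $S$ is hepatotoxic,

$$P(P \mid S) = \frac{P(S \mid P)\,\pi_P}
  {P(S \mid P)\,\pi_P + P(S \mid N)\,\pi_N},$$

and each bit is scored by its log odds ratio
$L = \log_2 \left( P(P \mid S) / P(N \mid S) \right)$. Bits with $L \ge
\theta$ are the candidate structural alerts; they receive the multiplicative
weight $w = n \cdot L$ (amplification parameter $n$), all other bits keep
weight 1, and the weight vector is applied element-wise to the binary
fingerprints. Only positively-associated bits are weighted: the use case is
flagging hepatotoxicity, so substructures typical of *safe* compounds are
deliberately left alone.

Worked example, at the package's default class balance (180 positives, 132
negatives): a bit present in 90 positives and 11 negatives, with $k = 1$,
gives $P(S|P) = 91/182 = 0.5$, $P(S|N) = 12/134 \approx 0.0896$, posterior
$P(P|S) \approx 0.884$ and $L \approx 2.93$ — comfortably above the usual
alert threshold of 2.5.

```{r worked}
smoothed_stats(list(c_SP = 90, c_SN = 11, N_P = 180, N_N = 132), k = 1)[c("post_P", "L")]
```

### Parameter choices and ambiguities

* **Pseudo-count `k`** (default 1): classic add-one smoothing. It exists to
  keep never-observed bits finite; any small positive value behaves
  similarly, and `k = 0` is rejected whenever a bit is absent from (or fixed
  in) an entire class. As $k \to \infty$ every posterior shrinks to the class
  prior, which the tests assert.
* **Outcome cardinality 2** in the smoothing denominator: a bit is present or
  absent.
* **Priors** are unsmoothed empirical class frequencies by default
  (`smooth_priors = TRUE` applies the same pseudo-count to them; with
  hundreds of training compounds the difference is negligible).
* **The weight formula.** "Amplify the selected substructures by $n$" admits
  three readings: $w = n \cdot L$, $w = n \cdot$ (raw posterior odds), or a
  flat $w = n$. All three select the same bits and preserve their ordering
  within a model family; we use $w = n \cdot L$ because $L$ is the quantity
  the threshold is defined on, so selection and amplification act on one
  scale. The choice affects relative magnitudes only.
* **Selection is `>= theta`** (ties at the threshold are in), and `theta`
  must be positive so every applied weight is positive; `theta = Inf` is the
  documented "no weighting" sentinel.
* **$\log_2$** is used everywhere L appears.

## Classifiers

Two learners consume the weighted features:

* **Random forest** (`randomForest`, 500 trees, $\sqrt{p}$ feature
  subsampling) on the weighted matrix; the score is the fraction of trees
  voting positive. A caveat the package states rather than hides: rescaling a
  *binary* column by a positive constant does not change the partitions an
  axis-aligned split can induce, so tree models are in principle invariant to
  this weighting — a property test pins this down at stump level. Weighting
  can still move RF performance in practice through vote granularity and
  tie-breaking, so both weighted and unweighted results are worth recording.
* **SVM** (`kernlab`, C-classification, default cost 1) on a *precomputed
  Tanimoto kernel*. For binary vectors the Tanimoto coefficient is
  intersection over union; for weighted vectors the package uses the standard
  continuous generalization
  $T(a,b) = a \cdot b / (\lVert a\rVert^2 + \lVert b\rVert^2 - a \cdot b)$,
  the common extension that reduces exactly to the binary form on 0/1 input
  (asserted bit-for-bit in the tests). It is not invariant to uniform
  scaling of one vector set — that is intended, as the weights are meant to
  reshape similarity. Two all-zero vectors get similarity 0 with a warning.
  SVM scores are decision values mapped through a logistic link to $[0,1]$;
  the link is monotone, so ranking metrics and sensitivity-targeted cutoffs
  do not depend on it.

## Decision cutoff

Screening prefers false alarms over missed hepatotoxicants, so the decision
cutoff is calibrated to a **target sensitivity of 0.8**: the largest cutoff
$c$ such that at least 80% of positive calibration compounds score $\ge c$.
Calibration scores are held out from fitting — out-of-bag votes for RF, inner
5-fold decision values for SVM — to avoid the optimism of resubstitution
scores. The guarantee is exact on the calibration scores; on new data the
achieved sensitivity fluctuates around the target. One sharp edge documented
here because it is easy to trip over: when positive scores are distinct, the
"largest cutoff" rule *by construction* sheds the bottom 20% of calibration
positives, so even perfectly separable data need not yield accuracy 1 at the
calibrated cutoff (ranking metrics still hit 1). Ties — e.g. RF votes
saturating at 1 — let the cutoff sit in the class gap.

## Evaluation

* **Cross-validation** is stratified 10-fold with a seeded shuffle. Weights
  are re-estimated inside each fold by default; computing them once on the
  full data before splitting (`paper_style_leakage = TRUE`) leaks label
  information from the held-out folds into their own features and is provided
  only to measure that effect. Both fold-averaged and pooled metrics are
  reported, since conventions differ.
* **AUC** is the normalized midrank (Mann–Whitney) statistic: tied
  positive–negative pairs count one half. **AUPR** uses the step rule
  $\sum_i (R_i - R_{i-1}) P_i$ over descending distinct score thresholds
  (PR integration conventions differ; this is the non-interpolated one).
  Confusion metrics use "score $\ge$ cutoff is positive".
* **Grid search** runs every $(\theta, n)$ cell over the *same* fold split
  and selects by pooled AUC (default grids $\theta \in \{0.5, 1, 1.5, 2,
  2.5\}$, $n \in \{5, 10, 15, 20\}$; add `theta = Inf` to carry the
  unweighted baseline in the table).
* **Independent testing** requires structural disjointness:
  `merge_deduplicate()` drops any test compound whose canonical SMILES occurs
  in training, and drops *both* records of any test structure carrying
  contradictory labels — the conservative reading, since a contradiction
  cannot be adjudicated from the data. Canonicalization is delegated to Open
  Babel (via ChemmineOB) behind `canonicalize_smiles()`; raw string equality
  is the fallback and may miss true duplicates.

## The synthetic generator — what it does and does not show

All tests and the acceptance analysis run on synthetic data from
`synth_generate()`: independent Bernoulli bits with a planted signal — ten
"causal" bits firing at rate 0.6 in positives vs 0.1 in negatives, all other
bits at a background rate of 0.15 in both classes, class sizes 180:132 by
default. The background rate reflects a typical set-bit density for PubChem
fingerprints of drug-like molecules; the causal contrast is strong enough
that the theoretical log-odds ($\log_2 6 \approx 2.59$ at equal priors)
clears the usual alert thresholds while finite-sample noise does not.
`expected_log_odds()` returns the population value of $L$ per bit (optionally
with finite-sample Laplace shrinkage), which makes the generator a
quantitative oracle: estimated $L$ must converge to it, planted bits must
top the ranking, and label-permuted data must score at chance.

What passing these tests does *not* show: real fingerprints are strongly
correlated (bits are nested substructure patterns), classes are not
homogeneous Bernoulli mixtures, and real alert bits share compounds. The
synthetic results validate the *machinery* — formulas, selection, kernels,
calibration, CV plumbing — not field performance on curated drug datasets,
which depends on external data this package deliberately does not bundle.

## Problem sizes and numerical notes

The shipped test-and-acceptance analyses use 200+200 compounds × 881 bits for
recovery and model comparisons (20 replicates), 60+60 × 120 for permutation
nulls, and 5000 per class for the consistency check of $L$ against theory —
sizes at which binomial noise in a single bit's $L$ is ≈0.06, so agreement is
reported as mean absolute deviation across bits. Posterior identities
($P(P|S) + P(N|S) = 1$, $L = \log_2$ of their ratio) hold to $10^{-12}$;
kernels are symmetric to $10^{-12}$ with unit self-similarity for nonzero
rows. Degenerate inputs are defined, not improvised: all-zero fingerprints
get similarity 0 with a warning, empty prediction inputs return empty score
vectors, and single-class inputs are hard errors naming the metric or stage.

## Known limitations

* No fingerprint computation from structures; PaDEL-dialect CSV is the
  contract. Records whose fingerprints are missing upstream should be dropped
  before ingestion.
* Per-bit annotations ship as section ranges of the public PubChem
  fingerprint layout (element counts, rings, atom pairs, neighbors, SMARTS);
  exact per-bit SMARTS text can be supplied as a user annotation map.
* The SVM probability-like score is a logistic squash of the margin, not a
  calibrated probability; only its ordering and the calibrated cutoff are
  meaningful.
* Binary classification only (positive/negative DILI concern); no severity
  grades, no toxicophore naming.
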