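# csknn

Cost-sensitive k-nearest-neighbour classification with entropy features for
heavily imbalanced biomarker panels.

## What this is for

Serum-protein screening data comes as one row of marker concentrations per
person — e.g. 39 markers per sample — with brutal class imbalance
(reference shape: 799 normal, 44 liver cancer, 54 ovarian cancer).  On
such data, plain majority-vote KNN is accurate overall but blind to the
minority classes: the neighbourhoods of borderline cases are stuffed with
normals.  `csknn` implements two complementary remedies:

1. **Entropy features.**  Each sample's ordered marker vector is treated
   as a sequence u(1..n) and summarised by regularity statistics:
   approximate entropy (ApEn), sample entropy (SaEn), fuzzy entropy
   (FuzzyEn) and information entropy (InfoEn).  Serum panels of healthy
   subjects are measurably more "complex" than those of cancer patients,
   so these two numbers carry class signal of their own.

2. **Cost-sensitive decisions.**  Neighbour counts k_j are smoothed into
   class probabilities by m-estimation,
   p(j|x) = k/(k+m) · k_j/k + m/(k+m) · b_j (b_j = training prior), and
   the predicted class minimises the expected misclassification cost
   L(i|x) = Σ_j p(j|x) C(j, i), where C(j, i) — rows = true class — is
   derived from the training imbalance: mistaking a smaller class for a
   larger one costs their count ratio (799/44 ≈ 18.2 for a missed liver
   case), the reverse costs 1, correct calls cost 0.

With uniform costs and m = 0 the classifier reduces exactly to classical
majority-vote KNN, which makes the comparison between the two an
apples-to-apples experiment; `jackknife_evaluate()` (leave-one-out),
`kfold_evaluate()` and `feature_set_experiment()` run it leakage-safe
(standardiser, priors and costs refitted in every split).  A synthetic
panel generator with a per-class sequence-regularity knob makes the whole
pipeline testable without access to clinical data.

## Worked example

```r
library(csknn)

panel <- simulate_panel(sim_config(seed = 1))   # 897 x 39, classes 799/44/54
feats <- entropy_features(panel, which = c("ApEn", "SaEn"), undefined = "cap")
round(tapply(feats$ApEn, panel$label, mean), 3)
#>     0     1     2
#> 0.272 0.073 0.177
round(tapply(feats$SaEn, panel$label, mean), 3)
#>     0     1     2
#> 0.426 0.111 0.278
```

Mean entropies order normal (0) > ovarian (2) > liver (1): healthy
sequences are the most irregular, liver-cancer sequences the most regular.
The ratio-mode cost matrix derived from the class counts:

```r
build_cost_matrix(c(799, 44, 54))$costs
#>     predicted
#> true     0 1     2
#>    0  0.00 1 1.000
#>    1 18.16 0 1.227
#>    2 14.80 1 0.000
```

Leave-one-out comparison of plain KNN and the cost-sensitive classifier on
the raw markers:

```r
jackknife_evaluate(panel, k = 5, m_smooth = 1, cost = "ratio")
#> Confusion matrix (rows = true, cols = predicted):
#>     predicted
#> true   0   1   2
#>    0 506 131 162
#>    1   0  41   3
#>    2   6   4  44
#>
#> Acc (macro, mean per-class accuracy): 0.7933
#> accuracy (micro, fraction correct):   0.6589
#> macro precision 0.4773  macro recall 0.7933  macro F1 0.4931
#> AUC (cancer_vs_normal): 0.8601

knn <- jackknife_evaluate(panel, k = 5, m_smooth = 0, cost = "uniform")
#> plain KNN: macro recall 0.712, micro accuracy 0.936
```

The trade is exactly the cost-sensitive one: plain KNN keeps micro
accuracy high (0.936) but misses minority cases (macro recall 0.712); the
cost-sensitive rule recovers them (macro recall 0.793, only 3 of 98 cancer
cases called normal) at the price of majority false alarms.  Adding the
two entropy columns (`feature_set_experiment(panel, sets = "combined",
protocol = "jackknife")`) lifts macro recall further, to 0.814 on this
panel.

A thin command-line surface wraps the same functions
(`exec/csknn simulate | featurize | select-k | select-m | evaluate |
predict`); every run writes a `manifest.json` with the config echo, seed
and input hashes.

## Documentation

The methods vignette (`vignettes/cost-sensitive-knn.Rmd`) describes the
entropy definitions and their conventions (self-matches, template ranges,
the fuzzy exponent, the undefined-SaEn cap), the cost-matrix construction
and its published fixed-matrix counterpart, the k/m selection protocols,
and what the synthetic generator does and does not emulate.
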