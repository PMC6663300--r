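# mtenet

Greedy inference of directed effective networks from multivariate time
series with **multivariate transfer entropy** and **hierarchical
nonparametric statistical testing**.

`mtenet` is aimed at researchers who record many interacting processes over
time — neural recordings (EEG/MEG, calcium imaging, fMRI), ecological or
economic panels — and want a minimal directed network in which a link
X → Y means that the past of X reduces the uncertainty about the present of
Y beyond what Y's own past and the other selected sources already explain.

## The method in brief

For each target process Y the algorithm selects a *nonuniform embedding*: a
sparse set of lagged variables chosen greedily by conditional mutual
information (CMI), in four steps:

1. **Target past** — greedily add lagged variables of Y itself that
   maximise I(C; Y_t | Y_sel) (active information storage), so self-memory
   is never mistaken for transfer;
2. **Sources past** — greedily add lagged variables of the other processes
   by conditional transfer entropy I(C; Y_t | Y_sel, X_sel), which blocks
   common-driver and pathway redundancy and admits synergies;
3. **Pruning** — remove selected variables whose contribution
   I(C; Y_t | Y_sel, X_sel∖{C}) has become redundant;
4. **Omnibus test** — test the collective transfer entropy
   T\* = I(X_sel; Y_t | Y_sel) of the surviving set.

Every greedy decision is guarded by an extreme-statistic permutation test
(maximum statistic for selection, minimum statistic for pruning) that
controls the family-wise error rate across the n candidates of that
iteration — the implied per-variable rate is the Dunn–Šidák value
1 − (1 − α)^(1/n), and the per-target rate is ≈ α. Omnibus p values are
combined across targets by Benjamini–Hochberg FDR. Two CMI estimators are
provided: a covariance-based **Gaussian** estimator with an analytic χ²
null (fast, exact for linear dynamics, equivalent to Granger causality) and
the **Kraskov–Grassberger / Frenzel–Pompe** k-nearest-neighbour estimator
(model-free, for nonlinear dynamics), with surrogate-data nulls.

The package also ships the full synthetic validation suite: directed
Erdős–Rényi ground truths, stable vector-autoregressive (VAR) and chaotic
coupled-logistic-map (CLM) simulators, precision/recall/specificity and
coupling-lag scoring, and the empty-network false-positive-rate protocol.

## Worked example

```r
library(mtenet)

net <- random_var_network(10, p = 0.3, seed = 1)   # ground truth
dat <- simulate_var(net, T = 10000, seed = 2)      # 10000 x 10 x 1 array
res <- infer_network(dat, inference_settings(alpha = 0.001))

res
#> inferred network: 10 nodes, 25 directed links (q_fdr = 0.05)

head(res$links)
#>    source target lags lag         te omnibus_p
#> 10      1      4    1   1 0.06257544         0
#> 14      1      6    1   1 0.06902845         0
#> 2       2      1    2   2 0.06483660         0
#> 18      2      7    5   5 0.04322088         0
#> 25      2     10    1   1 0.10334151         0
#> 3       3      2    2   2 0.03504133         0

unlist(classification_scores(confusion_counts(res, net)))
#>   precision      recall specificity
#>           1           1           1

relative_lag_error(res, net)$relative_error
#> [1] 0
```

All 25 true links are recovered with no false positives, and every inferred
coupling lag matches the generative lag (`te` is the collective transfer
entropy into the link's target, in nats; `lag` is the representative lag of
the link, `lags` all selected lags). At shorter T the recall drops first
while precision stays near 1 — the statistical tests are conservative by
design.

A thin command-line front end wraps the same functions:

```sh
exec/mtenet simulate-var --nodes 10 --samples 1000 --seed 1 \
    --out data.csv --truth truth.json
exec/mtenet infer --data data.csv --out result.json --alpha 0.001
exec/mtenet evaluate --result result.json --truth truth.json
```

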