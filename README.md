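# pofm — proportional-odds finite mixtures for ordinal biclustering

`pofm` fits model-based one- and two-mode clusterings of ordinal data
matrices: `n` subjects by `p` items, every cell an ordered category in
`1..q` (Likert-type questionnaires, graded clinical scales, product
ratings).  It is aimed at analysts who want *likelihood-based* row and/or
column clusters that respect the ordinal scale — with information criteria
for choosing the number of clusters and fuzzy (posterior-probability)
allocations — rather than distance-based biclustering.

## The model

Each cell follows a proportional-odds (cumulative-logit) model,

    logit P(Y_ij <= k) = mu_k − alpha_r − beta_c − gamma_rc ,   1 <= k < q,

with strictly increasing cutpoints `mu` and effects attached to *latent
clusters*: rows come from a finite mixture with `R` components and mixing
proportions `pi` (columns: `C`, `kappa`).  Either mode may instead be
unclustered ("single") or carry a fixed effect per row/column
("saturated"); the interaction `gamma` is optional and doubly
sum-to-zero.  Cluster membership is treated as missing data and the model
is fitted by EM with multiple random restarts; the two-mode E-step uses a
mean-field variational approximation, and the marginal likelihood is
computed by exact column-partition enumeration whenever `C^p <= 2^20`
(the fit records which value it reports).  Ten model-selection criteria
(AIC, AICc, AICu, CAIC, BIC, AIC3, CLC, NEC, ICL-BIC, AWE) are available,
together with a simulator, Rand-index evaluation, and drivers that
run model-selection and cluster-recovery simulation studies.

## A worked example

```r
library(pofm)

cfg <- pofm_sim_config(n = 60, p = 30, q = 3,
                       alpha = c(0, 1, 2), beta = c(0, -1),
                       kappa = c(0.5, 0.5))
sim <- pofm_simulate(cfg, seed = 1)
fit <- pofm_fit(sim$data, pofm_spec("clustered", "clustered", R = 3, C = 2),
                n_starts = 5, seed = 1)
fit
#> pofm model spec: rows clustered (3 groups), cols clustered (2 groups), additive
#>   data: 60 x 30, q = 3;  nu = 8 parameters
#>   loglik = -1791.4208 (variational_bound), complete = -1808.5991, entropy = 17.1783
#>   EM: 76 iterations, converged = TRUE
#>   pi:     0.349 0.411 0.240
#>   kappa:  0.501 0.499

rand_index(hard_assignment(fit$posteriors$zhat), sim$row_groups)
#> [1] 0.7745763
round(align_labels(fit$params, cfg$params)$alpha, 4)
#> [1] 0.0000 0.8031 1.9910
```

The fit reports the maximised log-likelihood (here the variational bound,
since `2^30` column partitions rule out exact enumeration), the expected
complete-data log-likelihood, and their difference — the allocation
entropy that the classification-based criteria penalise.  The estimated
mixing proportions sit near the generating thirds/halves, the hard row
partition agrees with the truth on 77% of row pairs, and the
label-aligned cluster effects recover the generating `alpha = (0, 1, 2)`.

Choosing the number of clusters over a grid:

```r
sel <- pofm_select(sim$data, pofm_spec_grid(3, 2), criterion = "aic3",
                   n_starts = 5, seed = 2)
sel$table[, c("R", "C", "nu", "loglik", "aic3", "bic")]
#>   R C nu    loglik     aic3      bic
#> 1 1 1  2 -1913.437 3832.874 3841.865
#> 2 1 2  4 -1876.866 3765.733 3783.715
#> 3 2 1  4 -1842.322 3696.644 3714.626
#> 4 2 2  6 -1798.271 3614.542 3641.515
#> 5 3 1  6 -1837.662 3693.324 3720.298
#> 6 3 2  8 -1791.421 3606.842 3642.806
```

AIC3 (minimised) selects the generating `(R, C) = (3, 2)`; BIC's heavier
penalty prefers `(2, 2)` here — exactly the under-selection tendency the
bundled selection study quantifies.

A thin command-line wrapper ships in `inst/cli/pofm.R`
(`fit`, `select`, `simulate`, `study` subcommands; YAML configs, CSV/JSON
outputs, a manifest per run).

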