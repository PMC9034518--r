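# bnscore

Bayesian model selection for network-informed risk gene prioritization.

Disease risk-gene discovery typically leaves geneticists with a short list of
confidently implicated "seed" genes and a genome of unscored candidates.
`bnscore` ranks every gene in the genome by its posterior odds of being a
risk gene, integrating three kinds of evidence: proximity to the seed genes
in a weighted functional network, binary functional annotations (e.g.
membership in implicated biological processes), and continuous gene-level
metrics (e.g. loss-of-function intolerance). It is aimed at statistical
geneticists and systems biologists prioritizing candidates for complex
disorders such as autism spectrum disorder, and generalizes to any trait
with a seed set and annotation matrices.

## The model

For each gene, two models are compared: M1 ("risk gene") and M0 ("not a
risk gene"). With annotation data **D** = (D1, ..., Dp) assumed independent
across annotations under both models, the posterior odds factorize as

    P(M1 | D) / P(M0 | D) = [ P(M1) / P(M0) ] × ∏_l  P(D_l | M1) / P(D_l | M0)

* **Prior odds.** P(M1)/P(M0) = c · P(N_s), where c = n_risk / (n_total −
  n_risk) is the assumed genome-wide ratio of risk to non-risk genes
  (default 1000 / 17000) and P(N_s) is the gene's average
  random-walk-with-restart reaching probability to the seed genes in a
  weighted functional network (restart r = 0.5 by default).
* **Bayes factors.** Each binary annotation is modelled as Bernoulli with a
  Beta(α, β) prior on the rate; the marginal likelihood is
  B(α + k, n − k + β) / B(α, β). Each continuous annotation is modelled as
  normal with a Normal-Inverse-Gamma prior (μ0, κ, ν, σ²); the marginal is a
  non-standardized t, t_ν(μ0, σ²(1 + κ)/κ). Hyperparameters are fitted by
  empirical Bayes: under M1 from the seed genes, under M0 from a random
  background set (default 500 genes). Annotations are pre-screened by
  one-sided Fisher enrichment (binary) and Welch t-test (continuous).

The package also ships the benchmarking suite used to validate the scores
(ROC/PR AUC, paired one-sided DeLong test, sliding top-K Fisher enrichment
with Benjamini–Hochberg correction), the SI/pSI expression-specificity index
with a permutation null, and a synthetic-data generator that plants risk
genes so the whole pipeline can be validated end to end without external
data.

## Worked example

```r
library(bnscore)

sim <- simulate_universe(simulation_config(rng_seed = 7))
sim
#> synthetic universe: 2000 genes, 100 risk (50 observed seeds, 50 held out)
#>   5 binary + 5 continuous annotations; network with 41801 edges

fit <- bnscore(sim$universe, sim$seeds, binary = sim$binary,
               continuous = sim$continuous, network = sim$network,
               rng_seed = 7)
fit
#> Bayesian gene prioritization fit
#>   universe: 2000 genes (50 seeds, 500 background, 1450 candidates)
#>   annotations: 10 screened, 10 selected (5 binary, 5 continuous)
#>   prior: literal mode, constant 1000/17000, restart r = 0.50
#>   top candidates:
#>   gene log10_posterior_odds rank
#>  g0462           0.48464176    1
#>  g0576           0.01930597    2
#>  g0290          -0.17368655    3
#>  g0215          -0.62142005    4
#>  g0947          -0.65341048    5

ev <- evaluate_scores(fit$ranked, sim$held_out, topk = c(100L, 500L))
ev$auc
#>                  score   roc_auc    pr_auc
#> 1 log10_posterior_odds 0.9967193 0.9467556
ev$enrichment
#>                  score   k odds_ratio      p_value corrected bh_adjusted_p
#> 1 log10_posterior_odds 100   726.3846 1.324020e-42     FALSE  2.648040e-42
#> 2 log10_posterior_odds 500   149.3789 9.622384e-18      TRUE  9.622384e-18
```

The top-candidate scores are log10 posterior odds: `g0462`'s 0.48 means
odds of about 3:1 in favour of M1 given its network position and
annotations. The held-out evaluation — the 50 planted risk genes *not*
shown to the model as seeds, with all training genes depleted — gives a
ROC-AUC of 0.997, and the top 100 candidates are ~726-fold enriched for
held-out risk genes relative to the rest of the ranking.

A command-line front end mirroring the R functions lives in
`inst/cli/bnscore.R` (subcommands `simulate`, `prior`, `select`, `bf`,
`score`, `evaluate`, `psi`); all of its outputs are plain TSV and
byte-reproducible given a seed.

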