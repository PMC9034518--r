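---
title: "Methods: Bayesian network-and-annotation gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian network-and-annotation gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnscore)
```

## The model

`bnscore` treats risk-gene discovery as Bayesian model selection. For every
gene we compare M1 ("risk gene") against M0 ("not a risk gene") and report
the posterior odds

$$\frac{P(M_1 \mid \mathbf{D})}{P(M_0 \mid \mathbf{D})}
  = \frac{P(M_1)}{P(M_0)} \prod_{l=1}^{p}
    \frac{P(D_l \mid M_1)}{P(D_l \mid M_0)},$$

with the annotation vector $\mathbf{D}$ assumed independent across
annotations under both models. The assumption is strong — functional
annotations are correlated in practice — and makes the total Bayes factor a
product of per-annotation factors. Redundant annotations therefore
double-count evidence; the pre-screening step (below) is the only mitigation
applied, as in the framework this package implements.

### Prior odds from the network

The prior odds are $c \cdot P(N_s)$, where $c = n_\mathrm{risk} /
(n_\mathrm{total} - n_\mathrm{risk})$ is the assumed genome-wide ratio of
risk to non-risk genes and $P(N_s)$ is the gene's average reaching
probability to the seed genes under a random walk with restart (RWR) on a
weighted functional network. Defaults $n_\mathrm{risk} = 1000$,
$n_\mathrm{total} = 18000$ reflect the common estimate of about a thousand
risk genes for a polygenic neurodevelopmental disorder; both are plain
arguments so the tool applies to other traits.

The RWR fixed point solves $p = (1-r)\,W^\top p + r\,e_s$ for a
row-stochastic transition matrix $W$ and restart probability $r$.
Numerical choices:

* $W$ is the degree-normalized weight matrix; isolated nodes get a unit
  self-loop so $W$ stays stochastic. Because rows are normalized, $P(N_s)$
  is invariant to any global rescaling of edge weights (a tested property).
* $r = 0.5$ by default. The restart parameter is not identified by any
  external constraint here; 0.5 is the midpoint of common RWR practice, and
  results should be reported together with $r$.
* The per-source iteration stops when the L1 change drops below `tol`
  (default 1e-10, geometric convergence at rate $1-r$) and errors rather
  than returning an unconverged vector.
* Averaging the per-source fixed points over seeds is algebraically a single
  sparse linear solve $(I - (1-r)W)\,v = r\,\bar e_S$; `avg_reach_to_seeds()`
  uses that solve by default and the per-gene iteration as a cross-checked
  alternative. Equality of the two routes is asserted in the tests.
* Genes absent from the network get prior odds 0 by default (`missing_prior`
  exposes an alternative floor). A zero prior annihilates annotation
  evidence for that gene; the score table carries the reason rather than
  dropping the gene.

When the network is built from gene-to-term assignments
(`build_go_network()`), the edge weight is the summed information content of
shared terms, $w(i,j) = \sum_t -\log_2 f_t$ with $f_t$ the fraction of genes
carrying term $t$. This is one standard instantiation of "shared-annotation
strength"; a precomputed edge list is the primary ingestion path and any
weighting can be substituted.

### Bayes factors from annotations

Binary annotations use the conjugate Beta–Bernoulli marginal
$B(\alpha + k,\, n - k + \beta)/B(\alpha, \beta)$, continuous annotations
the Normal-Inverse-Gamma marginal, a non-standardized
$t_\nu(\mu_0,\, \sigma^2 (1+\kappa)/\kappa)$. Both are evaluated in log
space via `lbeta`/`dt`; both closed forms are verified against numerical
quadrature of the defining integrals in the test suite.

Hyperparameters are fitted by empirical Bayes, under M1 from the seed genes
and under M0 from the background genes:

* **Binary:** $\tilde\alpha = k + 1$, $\tilde\beta = n - k + 1$ — the
  conjugate update of a uniform prior. The implied single-gene carrier
  probability $(k+1)/(n+2)$ tracks the group frequency and is never exactly
  0 or 1, so annotations carried by all or none of a fitting group stay
  usable. This smoothed-frequency estimator is deliberately simple and is
  pluggable (any object with `alpha`/`beta` works).
* **Continuous:** $\tilde\mu_0 = \bar x$, $\tilde\kappa = n$,
  $\tilde\nu = n - 1$, and $\tilde\sigma^2$ set so the implied marginal t
  has variance exactly equal to the group sample variance (moment
  matching). This requires $n \ge 4$ and positive variance; other
  conventions (e.g. $\kappa$ as a prior pseudo-count decoupled from $n$)
  would change the tails but not the mean/variance match.

Annotations are screened before fitting: one-sided Fisher exact enrichment
for binary annotations (the direction of interest is enrichment in seeds),
two-sided Welch t-tests for continuous ones, both at `alpha_level = 0.05`
with no multiplicity correction — the screen is a coarse relevance filter,
not an inference, and downstream enrichment analyses are where
Benjamini–Hochberg correction is applied.

Missing annotation values contribute a Bayes factor of exactly 1
(evidence-neutral). This keeps the score defined genome-wide instead of
restricting it to fully annotated genes; it also means a gene with no
annotation data at all is ranked purely by its network prior.

### Scores and ranking

Posterior odds are accumulated in log10 space; the primary score column is
`log10_posterior_odds`, with raw odds alongside. Ranking ties are broken
lexicographically by gene identifier, making every ranking deterministic.
Seed and background (training) genes are scored but excluded from the
candidate ranking by default: the candidates are exactly the genes in
neither training set.

## Evaluation machinery

* `roc_auc()` is the Mann–Whitney probability with ties counted 1/2.
* `pr_auc()` uses step interpolation (average precision). PR conventions
  differ across software; linear interpolation between recall points
  overstates the area, so it is not used.
* `delong_one_sided()` implements the structural-components variance
  estimate for paired AUCs. When the paired variance is exactly zero the
  test statistic is undefined; the implementation returns p = 0.5 for a
  zero AUC difference and a maximally extreme p (0 or 1, with a warning)
  for a nonzero difference, which keeps both the self-comparison identity
  and the directional behaviour of perfectly separated scores.
* `topk_enrichment()` builds the (top-K vs rest) × (benchmark vs not) table
  over the evaluated genes after training-gene depletion — "the rest of the
  genome" always means the evaluated universe minus the top K. The odds
  ratio uses the Haldane–Anscombe 0.5 correction only when a zero cell
  occurs, and the result is flagged when it does. The Fisher p-value is
  two-sided by default.

## Expression specificity (SI / pSI)

For a target condition, each gene's fold change against every other
condition is ranked across genes (rank 1 = most target-enriched, ties
averaged), and SI is the mean rank over the $m - 1$ comparisons; SI = 1
means the gene tops every comparison. A pseudocount (default 1e-8) guards
the ratio against zero expression.

Raw SI is not comparable across conditions, so a permutation p-value is
attached: $\mathrm{pSI}(g) = (1 + \#\{SI^\mathrm{null}_g \le
SI^\mathrm{obs}_g\})/(n_\mathrm{perm} + 1)$, whose smallest attainable value
is $1/(n_\mathrm{perm}+1)$. Two permutation units are provided:

* `within_gene` (default): each gene's expression vector is shuffled across
  conditions. This preserves each gene's magnitude distribution, but note
  its power limit: a gene's own extreme value returns to the target
  condition with probability $1/m$ per round, so with few conditions the
  pSI of even a perfectly specific gene concentrates near $1/m$, not near
  the floor. With $m = 4$ conditions, 0.25 is the effective lower limit.
* `within_condition`: each condition's column is shuffled across genes.
  This asks "how specific is this gene relative to what any gene shows
  under these conditions" and can resolve specificity down to the
  permutation floor; it is the scheme to use when $m$ is small and
  condition-specific gene lists at pSI < 0.05 are the goal (the acceptance
  script uses it for exactly that reason).

Both schemes reproduce the estimator identity
$(1 + \mathrm{hits})/(n_\mathrm{perm}+1)$ against an independent
re-implementation in the tests, are bit-reproducible given `rng_seed`, and
give pSI = 1 on a constant matrix.

## The synthetic-data generator

`simulation_config()` plants a known truth so the whole pipeline can be
validated without external data: a universe of 2,000 genes with 100 risk
genes, of which 50 are observed as seeds (the remaining 50 form the
held-out benchmark, emulating a time-lapse design where later-discovered
risk genes evaluate a model trained on earlier ones); five binary
annotations at carrier rates 0.6 (risk) vs 0.1 (non-risk); five continuous
annotations shifted by one standard deviation; a two-block random graph
with within-risk edge probability 0.3 against 0.02 elsewhere and
exponential edge weights; and an expression matrix of gamma background
noise with 20 genes boosted 10-fold in one of four conditions. The 500
background genes are drawn uniformly from the non-seed genome, so roughly
2.5% of them are (unknown to the model) true risk genes — the same
conservative contamination the real design accepts.

These sizes keep a full 20-replicate recovery experiment to a few minutes
on one CPU while leaving enrichment tables non-degenerate. What the
generator does **not** emulate: correlated annotations, scale-free or
GO-like network topology, realistic expression marginals, or any
gene-identifier semantics. Passing recovery tests therefore demonstrate
that the machinery is correct and that integration behaves as designed
under the assumed generative model — not that the defaults are calibrated
for any particular real dataset.

One property of this configuration is worth knowing when reading the
recovery reports: the planted block structure makes the network prior alone
nearly ROC-perfect on held-out genes, so the ROC gap between the combined
score and the network-only ablation sits at the ceiling within Monte-Carlo
noise; the integration benefit is visible in the PR-AUC and in the combined
score's clear ROC advantage over the binary-only and continuous-only
ablations (the acceptance script reports all of these). The null configuration
(`null_simulation_config()`) removes all three signals and is used to check
calibration: held-out AUC near 0.5 and top-100 enrichment odds ratios near
1.

## Known limitations

* Annotation independence is assumed, not tested; heavily redundant
  annotation panels will overstate the total Bayes factor.
* The prior treats $P(N_s)$ as a probability scale factor, not a calibrated
  likelihood ratio of network evidence; posterior odds are a ranking score
  whose absolute scale depends on the network and on $r$.
* Candidate-gene marginals are computed per gene ($n = 1$ draws); blockwise
  alternatives would share information across candidates but are not
  implemented.
* The empirical-Bayes estimators are method-of-moments choices behind a
  pluggable interface; they are simple, robust at degenerate counts, and
  not claimed optimal.
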