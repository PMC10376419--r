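---
title: "Latent-variable risk estimation for MCI from gut-microbiota compositions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable risk estimation for MCI from gut-microbiota compositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcibiome)
```

## The problem and the model

Mild cognitive impairment (MCI) has been associated with shifts in the gut
microbiota, and those shifts differ between men and women. Given a
genus-level 16S count table and case/control labels, this package asks two
questions: *which genera shift*, and *how well does a low-dimensional
"dysbiosis" summary of those shifts predict case status* when the analysis
is blinded to the labels at scoring time.

The core model is a confirmatory factor model over centred log-ratio (CLR)
abundances. Genera more abundant in cases indicate a latent variable lv1,
genera less abundant indicate lv2, and both latents regress on the binary
disease flag, treated as an ordered indicator of a standard-normal latent
response with a probit threshold. All observed variables are standardized
and latent variances fixed to 1, so every free parameter is a correlation-
scale quantity: loadings $\lambda_j$, the latent correlation
$\psi_{12}$, disease paths $\beta_l$, and the threshold $\tau$.

Estimation is diagonally weighted least squares (DWLS): with $s$ the
vector of nonredundant sample moments (Pearson correlations among
indicators, polyserial correlations between indicators and the disease
latent response, and the threshold) and $\sigma(\theta)$ the model-implied
moments,

$$ F(\theta) \;=\; \sum_k w_k \,\big(s_k - \sigma_k(\theta)\big)^2,
   \qquad w_k = 1/\Gamma_{kk}, $$

where $\Gamma_{kk}$ is the asymptotic variance of $\sqrt{n}\,s_k$
(normal-theory $(1-r^2)^2$ for Pearson terms, inverse observed information
for polyserial terms with a documented $1$ fallback, delta-method
$p(1-p)/\varphi(\tau)^2$ for the threshold). Fit statistics follow the
conventional definitions: $\chi^2 = (n-1)F_{\min}$,
$\mathrm{GFI} = 1 - F_{\min}/F_{\mathrm{baseline}}$ with the baseline
setting every implied moment to zero,
$\mathrm{AGFI} = 1-(1-\mathrm{GFI})\,m/\mathrm{df}$, and
$\mathrm{RMSEA} = \sqrt{\max\{(\chi^2-\mathrm{df})/(\mathrm{df}\,(n-1)),
0\}}$, so RMSEA is exactly 0 whenever $\chi^2 \le \mathrm{df}$. The
unscaled $\chi^2$ is used throughout; no mean-and-variance adjustment is
applied.

## Polyserial correlations

The binary disease flag is linked to the continuous indicators through a
two-step maximum-likelihood polyserial correlation: the threshold is fixed
first from the margin, $\tau = \Phi^{-1}(\text{control proportion})$, then
each correlation maximizes the conditional likelihood
$\prod_i P(d_i \mid x_i; \rho)$ with
$P(d=1\mid x) = \Phi\!\big((\rho x - \tau)/\sqrt{1-\rho^2}\big)$ by
univariate optimization on $(-0.995, 0.995)$. Tests verify recovery of a
planted $\rho = 0.5$ at $n = 2000$ within 0.05.

## Indicator pruning and the one-latent fallback

Real starting specifications (every classified genus) rarely fit. The
pruning rule is a deterministic greedy loop: while the targets
(GFI $\ge 0.94$, AGFI $\ge 0.89$, RMSEA $\le 0.01$ — the weaker of the two
published final models, overridable) are unmet and an indicator can be
removed without any latent falling below 3 indicators, every candidate
drop is refit and the drop maximizing $\mathrm{GFI} + \mathrm{AGFI} -
\mathrm{RMSEA}$ is made permanent, ties broken by indicator order. The
published account does not specify its reduction rule; a drop-one-refit
greedy search is the simplest rule that is deterministic, replayable from
its log, and agnostic to the starting order.

When the fitted two-latent model shows $|\psi_{12}| \ge 0.85$ the two
latents are near-collinear: they multicolline the downstream logistic
model and either one explains the disease alone, so the analysis rebuilds
a one-latent (lv1-only) model — the male branch of the published analysis.
The 0.85 default is our choice; the source describes the correlation only
as "strong". Ties at the threshold collapse.

Two pipeline-level robustness choices depart from the strict per-function
contracts (each is recorded in the stratum log): when classification
yields fewer than 3 indicators for a required latent, the pipeline falls
back to the top-ranked genera by signed effect so that null or weak-signal
datasets still run end to end (`build_sem_spec()` itself refuses); and
when the strict fit targets are unreachable at cohort-scale $n$, the
default `on_prune_failure = "best"` keeps the best specification found
rather than halting.

## Factor scores and the risk model

Scoring is blinded: the measurement part (loadings and latent correlation,
no disease node) is refit on the Pearson correlations alone, and
empirical-Bayes (regression-method) scores are computed per standardized
sample row $x$ as $\hat\eta = \Psi \Lambda^\top (\Lambda \Psi
\Lambda^\top + \Theta)^{-1} x$. The first indicator of each latent is
forced to load non-negatively so that scores are comparable across refits.

The risk model is a maximum-likelihood logistic regression of case status
on the factor scores, evaluated by outcome-stratified 10-fold
cross-validation. Class imbalance is handled by SMOTE — each synthetic
minority point is $x + u\,(\mathrm{nn}_j(x) - x)$, $u \sim U(0,1)$, with
$\mathrm{nn}_j$ one of the $k = 5$ nearest minority neighbours — applied
*inside each training fold only*; no synthetic point ever derives from a
test-fold sample. Because the published account does not say whether its
AUCs are out-of-fold or apparent, both are computed and labelled; the
out-of-fold value is the honest one and is what `print()` reports first.

## What the synthetic generator emulates

`mci_sim_config()` plants exactly the structure the model assumes: a
per-sample latent score $z \sim N(1, \sigma_z)$ for cases and
$N(0, \sigma_z)$ for controls; baseline log-abundances drawn once per
dataset from $N(0,1)$ across genera (rank-abundance skew); log relative
abundance of lv1/lv2 genera shifted by $\pm\,\text{loading} \times z$;
compositions closed to 1; a Dirichlet layer
($p \sim \mathrm{Dirichlet}(\pi/\omega)$, $\omega = 0.01$, i.e. total
concentration 100) for biological overdispersion; and multinomial reads at
Poisson depth 20,000. Defaults mirror the published cohort: male 11/17 and
female 18/23 case/control cells, ~50 genera, 8 case-enriched and 3
case-depleted planted genera (the shape of the final female measurement
model).

The latent spread default $\sigma_z = 0.5$ is a calibration, chosen as
follows: the Bayes-optimal AUC attainable from the latent score is
$\Phi\!\big(1/(\sigma_z\sqrt2)\big)$, which is 0.76 at $\sigma_z = 1$ —
below the published discrimination — and $\approx 0.92$ at
$\sigma_z = 0.5$, which brackets the published sex-specific AUCs (0.75 and
0.87) once attenuated by measurement error and small-sample
cross-validation. The generator emulates a cohort in which the dysbiosis
factor carries the reported discriminative signal.

What the generator does **not** emulate: taxonomic misassignment, chimeras
and read-level artifacts; multiple independent dysbiosis axes; covariate
structure (age, BMI, antibiotics — the source cohort includes antibiotic
users without adjustment, and no covariate-adjustment stage is provided
here either); zero-inflation beyond what the Dirichlet-multinomial
produces; and between-genus phylogenetic correlation. Passing tests
therefore demonstrate internal statistical correctness and recovery of a
planted single-factor signal, not performance on real cohorts.

## Numerical choices and degenerate inputs

* CLR pseudo-count 0.5 and 128 Monte-Carlo instances by default (the
  conventional Dirichlet prior; the source states neither). The
  latent-variable stage consumes the ensemble *mean* (`clr_mode =
  "mc-mean"`), which is deterministic given the ensemble; `"point"` and
  `"single-instance"` are provided as deviation knobs.
* The exact expectation of the Dirichlet-CLR is
  $\psi(x_i + 0.5) - \frac1p\sum_j \psi(x_j + 0.5)$ (digamma), which sits
  a Jensen gap above the plug-in point estimate (0.077 for counts (8,2));
  tests check Monte-Carlo consistency against the digamma closed form.
* Effect-size dispersion is floored at machine epsilon; within-group
  pairings are drawn once per Monte-Carlo instance in global sample order,
  making effects exactly antisymmetric under label swap.
* DWLS optimization: `nlminb` with loadings and correlations bounded in
  $(-0.995, 0.995)$, a smooth penalty keeping the explained variance of
  the disease response below 1, five deterministically jittered restarts,
  tolerance $10^{-8}$ on $F$. Saturated models (df = 0) report GFI and
  `NA` for AGFI/RMSEA.
* Factor scoring adds a $10^{-8}$ ridge if the implied covariance is
  numerically singular, and errors with the condition number if that is
  insufficient.
* PERMANOVA uses squared Bray–Curtis distances in the sums of squares
  (the adonis convention), unrestricted label permutations, and
  `p = (1 + \#\{F^* \ge F\})/(1 + B)`; an exhaustive-enumeration option
  exists for two-group designs and is oracle-tested at $n = 3+3$.
* NMDS is Kruskal stress-1 via monotone regression (vegan's monoMDS),
  $k = 2$, 20 random restarts, max 300 iterations; non-convergence in all
  restarts returns the best configuration with a warning (captured into
  the stratum log by the pipeline).

## Problem sizes used by the test suite

The suite exercises the statistics at sizes a desk replication supports:
20-replicate calibration loops at $n = 20/20$ with 128-instance
ensembles; 200 null cohorts at $n = 10/10$ with 999 permutations for the
PERMANOVA type-I check; DWLS oracles at population scale and $n = 5000$;
and 20 end-to-end runs at the published cohort scale ($18/23$). These
sizes are the package's own reproducibility choices and are stated here so
they can be scaled up by readers with more patience.

## Known limitations

* The DWLS $\chi^2$ is unscaled; with strongly non-normal CLR data the
  RMSEA-based pruning targets act as relative, not absolute, criteria.
* Fit-index pruning cannot detect indicators that are merely
  *uninformative*: an independent noise genus is fit exactly with a zero
  loading and survives pruning. Only indicators that contradict the
  factor structure (e.g. a correlated nuisance block) are removed.
* The effect-size estimator inherits the $\sqrt{2/n}$ sampling noise of
  any standardized two-group statistic; at $n = 20$ per group, per-genus
  null effects have SD $\approx 0.3$, so the $\pm 0.2$ classification rule
  is liberal at small $n$. This is a property of the method, not of the
  implementation.
* Sex strata are analysed fully independently (separate seeds, separate
  models); no multi-group model or cross-sex shrinkage is attempted.
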