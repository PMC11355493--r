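---
title: "A Bayesian mixture model for ultra-rare variant gene association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian mixture model for ultra-rare variant gene association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvbmix)
```

## The problem

Burden tests collapse all rare variants of a gene into one score and so
implicitly assume that most collapsed variants are causal. For disorders
such as schizophrenia, where a gene's association may be driven by one or
two large-effect ultra-rare variants among many neutral ones, this
assumption costs power. `rvbmix` implements a gene-based association method
that needs only per-variant minor-allele counts in cases and controls
(no individual-level genotypes) and models the *uncertainty* of each
variant's risk status explicitly, so a sparse signal is not diluted by the
neutral majority.

The intended setting is a large case-control exome study: ultra-rare
variants (cohort minor-allele count at most 5), restricted to constraint
genes (pLI > 0.9), split into two functional classes — class I pools
protein-truncating variants with missense variants of MPC ≥ 3, class II
holds missense variants with MPC in [2, 3). The default cohort is 24,248
cases against 97,322 controls.

## Model

Write $p_0 = n_\text{case} / (n_\text{case} + n_\text{control})$ for the
cohort case fraction. Under no association, each of a variant's $T$ minor
alleles falls in a case independently with probability $p_0$. A risk
variant with relative risk $\gamma$ tilts this share to

$$q(\gamma) = \frac{\gamma p_0}{\gamma p_0 + 1 - p_0},$$

the standard retrospective-sampling tilt, which equals $p_0$ at
$\gamma = 1$ and increases to 1. The effect size of a risk variant in
class $c$ is drawn from a mean-parameterised Gamma prior,
$\gamma \sim \mathrm{Gamma}(\bar\gamma_c \sigma,\ \sigma)$, whose mean is
exactly the class hyperparameter $\bar\gamma_c$. The per-variant Bayes
factor contrasts the two accounts of the observed split $a$ of $T$ alleles:

$$\mathrm{BF} = \frac{\int \mathrm{Binom}(a \mid T, q(\gamma))\,
\mathrm{dGamma}(\gamma; \bar\gamma_c\sigma, \sigma)}
{\mathrm{Binom}(a \mid T, p_0)}.$$

Two latent layers connect variants to genes: gene $i$ is a risk gene with
probability $\delta$, and each variant of a risk gene is a risk variant
with the class probability $\eta_c$ (variants of null genes are never risk
variants). Marginalising the variant indicators gives the gene Bayes factor

$$\mathrm{BF}_i = \prod_j \left[(1 - \eta_{c(j)}) + \eta_{c(j)}
\mathrm{BF}_{ij}\right],$$

and the posterior risk probability of the gene is
$\delta \mathrm{BF}_i / ((1 - \delta) + \delta \mathrm{BF}_i)$.

### Estimation

$(\delta, \eta_1, \eta_2)$ are shared across the gene universe and
estimated by EM on the two-level latent structure. The E-step computes the
posterior gene indicator $T_i$ and, conditional on the gene being a risk
gene, the variant indicator $U_{ij}$; the M-step sets $\delta$ to the mean
of $T_i$ and $\eta_c$ to the $T$-weighted mean of $U_{ij}$ within the
class. Genes with no retained variants stay in the universe with a neutral
Bayes factor of 1, so $\delta$ keeps its interpretation as the risk-gene
fraction of the whole universe rather than of the variant-bearing subset.

$\eta_c = 0$ is an absorbing fixed point of these updates, so the fit runs
from five spread starting points in the unit cube and keeps the best final
log-likelihood. The starts are deterministic — the same coverage a jittered
multistart would give, without making fits depend on RNG state.

Significance of each $\eta_c$ comes from a likelihood-ratio test against
the constrained model with that class's $\eta$ pinned at 0 (all other
parameters re-optimised). Because the null value lies on the boundary of
$[0, 1]$, the statistic is referred to the 50:50 mixture of a point mass at
zero and $\chi^2_1$; a class whose variants carry no evidence yields
$\Lambda = 0$ and $p = 0.5$.

### Gene nomination

Genes are ranked by posterior risk probability and the running Bayesian FDR
of each prefix is the cumulative mean of $1 - \text{posterior}$. The
nominated set is the largest prefix with running FDR strictly below the
level (default 5%). Ties in posterior are broken lexicographically by gene
symbol so the ranking is reproducible byte for byte.

### Enrichment

Nominated lists are characterised two ways: overlap with reference gene
sets (counts, percentages of the reference set, one-sided Fisher exact
tests inside the constraint-gene universe — `stats::fisher.test` and
hypergeometric tails do the actual arithmetic) and a database-agnostic
fold-change term enrichment, $(k/n)/(K/N)$ with a hypergeometric upper-tail
p-value and Bonferroni correction, which reproduces the statistic of a GO
over-representation analysis for any gene-to-term map supplied as a table.
Fisher tests default to the one-sided enrichment direction; two-sided
p-values are available by argument.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `gamma_bar` (class I) | prior mean relative risk | 3 | damaging classes show severalfold risk in large exome studies; estimates are insensitive to 4 or 5 |
| `gamma_bar` (class II) | prior mean relative risk | 1 | moderate-MPC missense is not expected to carry substantial risk |
| `sigma` | Gamma prior rate (inverse dispersion) | 1 | prior variance $\bar\gamma/\sigma$; 1 keeps the prior weakly informative |
| `mac_max` | ultra-rare cap on cohort MAC | 5 | the ultra-rare regime of large exome meta-analyses |
| `mpc_high`, `mpc_low` | missense class boundaries | 3, 2 | class I is $[3, \infty)$, class II $[2, 3)$; a score of exactly 3 is class I, giving a clean partition |
| `fdr_level` | Bayesian FDR level | 0.05 | conventional nomination threshold |
| `tol`, `max_iter` | EM stopping rule | 1e-8, 5000 | relative log-likelihood change; see below |

The MAC filter uses the combined case + control count: external-control
designs publish cohort-wide counts, and a single cohort-wide cap matches
that practice.

## Numerical choices

* **Quadrature.** The marginal likelihood integral is evaluated with
  adaptive quadrature over the prior's effective support
  $[Q(10^{-14}), Q(1 - 10^{-14})]$ (Gamma quantiles). The binomial factor
  is bounded by 1, so truncation error is below $2 \times 10^{-14}$ while
  the finite interval keeps the adaptive subdivision centred on the prior
  mass even for near-degenerate priors. Tests hold the result to relative
  error $10^{-5}$ against a dense-grid trapezoid oracle (integrated in
  $\sqrt\gamma$, where half-integer Gamma shapes make the integrand
  polynomial-smooth) over every ultra-rare count configuration.
* **Collapsed EM.** Ultra-rare counts admit only ~40 distinct
  (class, case-count, total) configurations, each with one Bayes factor, so
  the EM iterates over a dense genes-by-configurations count matrix. One
  iteration is $O(G \times 40)$ and a 5-start fit on 3000 genes takes a
  couple of seconds in plain R.
* **Stability.** Gene Bayes factors are accumulated in log space;
  posteriors use the logistic form
  $1/(1 + \frac{1-\delta}{\delta} e^{-\log \mathrm{BF}_i})$, which is exact
  for extreme $\log \mathrm{BF}$. $\delta$ is clamped to
  $[10^{-12}, 1 - 10^{-12}]$ to keep the log-likelihood finite.
* **Degenerate inputs.** A variant with total count 0, a gene with no
  variants, and a class with no variants are all neutral (BF 1, unchanged
  $\eta$). A flat likelihood (all BFs equal to 1) leaves the starting
  values untouched and converges immediately — the likelihood is constant,
  so every point is an MLE and the fixed point is the natural
  representative.
* **LRT clamping.** The constrained refit occasionally beats the full fit
  by numerical slack; statistics below zero are clamped to 0 (p = 0.5),
  the conservative direction.

## The synthetic generator

`simulate_dataset()` realises exactly the generative model above, so
parameter recovery is well-posed: gene indicators
$Z_i \sim \mathrm{Bern}(\delta)$, per-class variant counts Poisson, variant
indicators $U_{ij} \sim \mathrm{Bern}(\eta_c Z_i)$, relative risks from the
class Gamma prior (1 for non-risk variants), totals drawn from a
distribution on $\{1, \dots, 5\}$ (uniform by default — ultra-rare MAC
spectra are not published at this granularity, and inference conditions on
the totals, so the choice affects power only), and case counts binomial
with the tilted share.

Defaults mirror the schizophrenia study conditions: $G = 3000$ constraint
genes, $\delta = 0.451$, $\eta = (0.6766, 0.081)$, $\bar\gamma = (3, 1)$,
$\sigma = 1$, 24,248 cases / 97,322 controls. Variants per gene are Poisson
with means 10 (class I) and 20 (class II): across ~120,000 exomes a
constraint gene harbours tens of distinct MAC ≤ 5 sites, with moderate-MPC
missense outnumbering truncating and high-MPC variants. This density
matters: at a few variants per gene the marginal likelihood becomes nearly
flat along a $\delta$–$\eta$ ridge and the risk-gene fraction is only
weakly identified, which is worth remembering when applying the model to
small or sparsely covered panels.

What the generator does *not* emulate: population structure and ancestry
mismatch between cases and external controls, calling artifacts, per-gene
variation in mutability or coverage, LD (irrelevant at these frequencies),
and any de novo mutation process. Passing recovery and calibration tests on
this generator therefore shows internal consistency of the method, not
robustness to the confounders a real meta-analysis must first harmonise
away.

## Problem sizes in the test suite

The suite exercises: the full enumerable grid of ultra-rare count
configurations against the quadrature oracle; exhaustive
$(\delta, \eta_1, \eta_2)$ grid searches (coarse 0.01 pass over the unit
cube, then an exhaustive $10^{-3}$ refinement around the coarse optimum) on
3–4 gene toys; parameter recovery over 20 replicates at $G = 2000$;
Bayesian-FDR calibration over 100 replicates at $G = 3000$; type-I error of
the boundary LRT over 200 replicates at $G = 500$; and Fisher exact
p-values against full hypergeometric enumeration on all 2×2 tables with
$N \le 30$. These sizes make the whole suite run in a few minutes while
leaving each check at the scale its claim refers to.

## Known limitations

* The two classes are fixed by annotation; there is no per-gene prior, no
  covariate adjustment, and no uncertainty interval on $\delta$ or
  $\eta_c$ (point estimates plus boundary LRTs, as in the analyses this
  package supports).
* De novo variants are out of scope; the likelihood is for inherited
  case-control counts only.
* $p_0$ is a single cohort-wide constant, which presumes well-matched
  cases and controls; stratified or covariate-adjusted nulls are not
  implemented.
* The Bayesian FDR is calibrated only insofar as posteriors are; model
  misspecification (wrong prior means, heterogeneous $\eta$ across genes)
  propagates directly into the realized false discovery proportion.
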