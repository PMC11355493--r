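# rvbmix

Bayesian mixture-model gene association for ultra-rare variants from
case–control minor-allele counts.

## The problem

In large exome case–control studies of disorders such as schizophrenia,
a gene's association signal is often carried by a handful of large-effect
ultra-rare variants (cohort minor-allele count ≤ 5) hidden among many
neutral ones. Burden tests, which collapse all of a gene's rare variants
into one score, assume most collapsed variants are causal and lose power
exactly in this sparse-signal regime. `rvbmix` is for analysts who have
only per-variant allele counts in cases and controls — the situation with
count-only external controls, where individual genotypes are unavailable —
and want gene-level evidence that models each variant's uncertain risk
status explicitly.

## The model

With case fraction $p_0 = n_\text{case}/(n_\text{case}+n_\text{control})$,
a variant's $T$ minor alleles split binomially between cases and controls:
with share $p_0$ under the null, or with the tilted share
$q(\gamma) = \gamma p_0 / (\gamma p_0 + 1 - p_0)$ for a risk variant of
relative risk $\gamma \sim \mathrm{Gamma}(\bar\gamma_c\sigma, \sigma)$,
where $\bar\gamma_c$ is the prior mean relative risk of variant class $c$
(class I: protein-truncating and MPC ≥ 3 missense, default
$\bar\gamma = 3$; class II: MPC 2–3 missense, default $\bar\gamma = 1$).
The per-variant Bayes factor integrates the binomial likelihood over this
prior. A two-level mixture ties variants to genes: a gene is a risk gene
with probability $\delta$, and each variant of a risk gene is a risk
variant with class probability $\eta_c$, giving the gene Bayes factor

$$\mathrm{BF}_i = \prod_j\left[(1-\eta_{c(j)}) + \eta_{c(j)}\,\mathrm{BF}_{ij}\right].$$

$(\delta, \eta_1, \eta_2)$ are estimated by EM across the constraint-gene
universe, each $\eta_c$ is tested by a boundary-corrected likelihood-ratio
test, and genes are nominated by Bayesian FDR (cumulative mean of
$1-\text{posterior}$ over the posterior-ranked list, threshold 5%).
Overlap and fold-change enrichment statistics characterise the nominated
list against reference gene sets. A synthetic-data generator realising
exactly this generative model provides ground truth for calibration.

See `vignettes/rare-variant-mixture.Rmd` for the full account.

## Worked example

Simulate a 1000-gene cohort at the default study conditions (24,248 cases,
97,322 controls, 45.1% risk genes), fit the mixture, and nominate genes:

```r
library(rvbmix)
sim <- simulate_dataset(sim_config(n_genes = 1000, seed = 11))
p0 <- null_case_share(24248, 97322)
priors <- list(I = group_prior(3), II = group_prior(1))
bf <- variant_bf_table(sim$variants, p0, priors)
fit <- fit_mixture(bf, genes = sim$genes$gene)
print(fit)
#> Two-level rare-variant mixture fit
#>   delta (risk-gene proportion): 0.4204
#>   eta[I] (risk-variant proportion): 0.7067  (LRT p = 2.2e-212)
#>   eta[II] (risk-variant proportion): 0.1190  (LRT p = 0.0134)
#>   log-likelihood (rel.): 484.518735 after 906 iteration(s)

sel <- bayesian_fdr_select(fit$gene_results, level = 0.05)
sum(sel$selected)
#> [1] 173
head(sel, 3)
#>     gene    bf posterior rank  cum_fdr selected
#> 1 G00260 47817         1    1 2.88e-05     TRUE
#> 2 G00299  7014         1    2 1.13e-04     TRUE
#> 3 G00006  3001         1    3 2.28e-04     TRUE
truth_fdp(sel$gene[sel$selected], sim$genes)
#> [1] 0.05202312
```

The fitted proportions recover the generating values (δ = 0.451,
η₁ = 0.6766, η₂ = 0.081): the class-I risk-variant proportion is estimated
near 0.7 with overwhelming significance while class II hovers near 0.1
with marginal evidence, and the realized false discovery proportion of the
nominated set sits at the nominal 5% level. With real data, replace the
simulation by `read_variant_table()`, `filter_ultra_rare()`,
`assign_variant_class()` and `restrict_to_gene_set()` on your count table
and constraint-gene list, or drive the whole chain from a YAML config with
`run_pipeline()`.

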