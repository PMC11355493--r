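# Independent oracles used across the suite. Each reimplements the target
# quantity by a different route (dense-grid integration, Monte Carlo,
# exhaustive enumeration, grid search) and must stay free of the package's
# own code paths.

# Dense-grid trapezoid oracle for the per-variant Bayes factor. Integrates
# in t = sqrt(gamma): for Gamma shapes that are multiples of 1/2 the
# transformed integrand is polynomial x smooth, so the plain trapezoid rule
# converges cleanly even where the Gamma density is unbounded at 0.
bf_trapezoid_oracle <- function(a, total, p0, gamma_bar, sigma,
                                h = 2e-4, upper = 200) {
  shape <- gamma_bar * sigma
  t <- seq(0, sqrt(upper), by = h)
  g <- t^2
  q <- g * p0 / (g * p0 + 1 - p0)
  dens <- ifelse(t == 0,
                 if (abs(shape - 0.5) < 1e-12) 2 * sigma^shape / gamma(shape) else 0,
                 stats::dgamma(g, shape, rate = sigma) * 2 * t)
  integ <- stats::dbinom(a, total, q) * dens
  tr <- (sum(integ) - (integ[1] + integ[length(integ)]) / 2) * h
  tr / stats::dbinom(a, total, p0)
}

# Monte Carlo oracle: average binomial likelihood ratio over prior draws.
bf_mc_oracle <- function(a, total, p0, gamma_bar, sigma, n = 1e7) {
  g <- stats::rgamma(n, shape = gamma_bar * sigma, rate = sigma)
  q <- g * p0 / (g * p0 + 1 - p0)
  ratio <- stats::dbinom(a, total, q) / stats::dbinom(a, total, p0)
  list(bf = mean(ratio), se = stats::sd(ratio) / sqrt(n))
}

# Exhaustive hypergeometric enumeration for a 2x2 table with fixed margins.
# Two-sided: sum of table probabilities <= observed, with the conventional
# (1 + 1e-7) relative slack for floating-point ties.
fisher_enum_oracle <- function(a, b, c, d,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - r2):min(k, r1)
  p <- exp(lchoose(r1, xs) + lchoose(r2, k - xs) - lchoose(N, k))
  pobs <- p[xs == a]
  if (alternative == "greater") sum(p[xs >= a])
  else sum(p[p <= pobs * (1 + 1e-7)])
}

# Grid-search oracle for the mixture MLE on tiny instances: full coarse
# grid over (delta, eta1, eta2), then an exhaustive 1e-3-step refinement in
# a window around the coarse optimum.
grid_search_mixture <- function(bf_tab, genes,
                                step_coarse = 0.01, step_fine = 1e-3,
                                window = 0.02) {
  stopifnot(length(genes) <= 6)
  bfs1 <- lapply(genes, function(g)
    bf_tab$bf[bf_tab$gene == g & bf_tab$var_class == "I"])
  bfs2 <- lapply(genes, function(g)
    bf_tab$bf[bf_tab$gene == g & bf_tab$var_class == "II"])
  eval_grid <- function(dg, e1g, e2g) {
    LL <- array(0, c(length(dg), length(e1g), length(e2g)))
    for (i in seq_along(genes)) {
      A <- vapply(e1g, function(e) prod((1 - e) + e * bfs1[[i]]), numeric(1))
      B <- vapply(e2g, function(e) prod((1 - e) + e * bfs2[[i]]), numeric(1))
      lr <- outer(A, B)
      for (k in seq_along(dg)) {
        LL[k, , ] <- LL[k, , ] + log((1 - dg[k]) + dg[k] * lr)
      }
    }
    idx <- which(LL == max(LL), arr.ind = TRUE)[1, ]
    c(delta = dg[idx[1]], eta1 = e1g[idx[2]], eta2 = e2g[idx[3]],
      ll = max(LL))
  }
  full <- seq(0, 1, by = step_coarse)
  co <- eval_grid(full, full, full)
  ref <- function(center) {
    seq(max(0, center - window), min(1, center + window), by = step_fine)
  }
  eval_grid(ref(co["delta"]), ref(co["eta1"]), ref(co["eta2"]))
}

# Small classified variant table used by several unit tests.
toy_bf_tab <- function() {
  data.frame(
    gene = c("A", "A", "B", "C"),
    var_class = c("I", "I", "I", "II"),
    bf = c(8, 1.2, 0.5, 1.1),
    stringsAsFactors = FALSE
  )
}

study_p0 <- function() null_case_share(24248, 97322)

study_priors <- function() list(I = group_prior(3, 1), II = group_prior(1, 1))
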