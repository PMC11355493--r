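#' Null case share of a variant's carriers
#'
#' Under no association, each of a variant's minor alleles falls in a case
#' with probability equal to the case fraction of the cohort.
#'
#' @param n_case Number of cases (>= 1).
#' @param n_control Number of controls (>= 1).
#' @return `n_case / (n_case + n_control)`, in (0, 1).
#' @export
null_case_share <- function(n_case, n_control) {
  if (length(n_case) != 1 || length(n_control) != 1 ||
      is.na(n_case) || is.na(n_control) || n_case < 1 || n_control < 1) {
    stop("n_case and n_control must both be >= 1")
  }
  n_case / (n_case + n_control)
}

#' Case share under a relative risk
#'
#' Tilts the binomial case/control split by a relative risk: a carrier
#' allele lands in a case with probability
#' `gamma * p0 / (gamma * p0 + (1 - p0))`. Strictly increasing in `gamma`
#' and equal to `p0` at `gamma = 1`.
#'
#' @param gamma Relative risk (> 0); vectorised.
#' @param p0 Null case share in (0, 1).
#' @return Case-share probabilities.
#' @export
risk_case_share <- function(gamma, p0) {
  stopifnot(p0 > 0, p0 < 1)
  gamma * p0 / (gamma * p0 + (1 - p0))
}

#' Relative-risk prior for a variant class
#'
#' The relative risk of a risk variant in a class is modelled as
#' `gamma ~ Gamma(shape = gamma_bar * sigma, rate = sigma)`, so the prior
#' mean is exactly `gamma_bar` and `sigma` controls dispersion
#' (variance `gamma_bar / sigma`).
#'
#' @param gamma_bar Prior mean relative risk (> 0).
#' @param sigma Prior rate / inverse-dispersion (> 0, default 1).
#' @return A `group_prior` object.
#' @export
group_prior <- function(gamma_bar, sigma = 1) {
  stopifnot(is.numeric(gamma_bar), gamma_bar > 0,
            is.numeric(sigma), sigma > 0)
  structure(list(gamma_bar = gamma_bar, sigma = sigma), class = "group_prior")
}

#' @export
print.group_prior <- function(x, ...) {
  cat(sprintf("group_prior: gamma ~ Gamma(shape = %.4g, rate = %.4g), mean %.4g\n",
              x$gamma_bar * x$sigma, x$sigma, x$gamma_bar))
  invisible(x)
}

#' Per-variant Bayes factor
#'
#' Contrasts the risk model, in which the variant's relative risk is drawn
#' from the class Gamma prior, against the null binomial split of its
#' carriers between cases and controls:
#' \deqn{BF = \frac{\int \mathrm{Binom}(a \mid T, q(\gamma))\,
#'   d\Gamma(\gamma;\ \bar\gamma\sigma,\ \sigma)}
#'   {\mathrm{Binom}(a \mid T, p_0)},}
#' with \eqn{q(\gamma) = \gamma p_0 / (\gamma p_0 + 1 - p_0)}. The marginal
#' likelihood is evaluated by adaptive quadrature on \eqn{(0, \infty)}.
#' A variant with total count 0 carries no information and has BF 1.
#'
#' @param ac_case Minor-allele count in cases (vectorised).
#' @param ac_total Total minor-allele count (vectorised with `ac_case`).
#' @param p0 Null case share, see [null_case_share()].
#' @param prior A [group_prior()].
#' @param rel_tol Quadrature relative tolerance (default 1e-10).
#' @return Bayes factor(s), non-negative.
#' @export
variant_bayes_factor <- function(ac_case, ac_total, p0, prior,
                                 rel_tol = 1e-10) {
  stopifnot(inherits(prior, "group_prior"))
  if (any(ac_case < 0) || any(ac_case > ac_total)) {
    stop("need 0 <= ac_case <= ac_total")
  }
  n <- max(length(ac_case), length(ac_total))
  ac_case <- rep_len(ac_case, n)
  ac_total <- rep_len(ac_total, n)
  vapply(seq_len(n), function(i) {
    .variant_bf_one(ac_case[i], ac_total[i], p0,
                    prior$gamma_bar, prior$sigma, rel_tol)
  }, numeric(1))
}

.variant_bf_one <- function(a, total, p0, gamma_bar, sigma, rel_tol) {
  if (total == 0) return(1)
  shape <- gamma_bar * sigma
  integrand <- function(g) {
    q <- risk_case_share(g, p0)
    stats::dbinom(a, total, q) * stats::dgamma(g, shape = shape, rate = sigma)
  }
  # integrate over the prior's effective support; the binomial factor is
  # bounded by 1 so the mass outside (< 2e-14) cannot matter at rel_tol
  lo <- stats::qgamma(1e-14, shape = shape, rate = sigma)
  hi <- stats::qgamma(1e-14, shape = shape, rate = sigma, lower.tail = FALSE)
  marg <- stats::integrate(integrand, lower = lo, upper = hi,
                           rel.tol = rel_tol, abs.tol = 0,
                           subdivisions = 500L, stop.on.error = FALSE)
  if (!marg$message %in% c("OK", "roundoff error was detected")) {
    stop("quadrature failed for counts (", a, ", ", total, "): ",
         marg$message)
  }
  marg$value / stats::dbinom(a, total, p0)
}

#' Bayes factors for a classified variant table
#'
#' Computes the per-variant Bayes factor for every row of a classified
#' variant table, using the prior of each row's class. Results are memoised
#' over the small set of distinct (class, ac_case, total) configurations, so
#' large ultra-rare tables cost only a handful of quadratures.
#'
#' @param variants Classified variant data.frame (needs `gene`, `variant`,
#'   `var_class`, `ac_case`, `ac_control`).
#' @param p0 Null case share.
#' @param priors Named list of [group_prior()]s keyed by class label,
#'   e.g. `list(I = group_prior(3), II = group_prior(1))`.
#' @param rel_tol Quadrature relative tolerance.
#' @return The input with an added `bf` column.
#' @export
variant_bf_table <- function(variants, p0, priors, rel_tol = 1e-10) {
  stopifnot(all(c("gene", "var_class", "ac_case", "ac_control") %in%
                  names(variants)))
  unknown <- setdiff(unique(variants$var_class), names(priors))
  if (length(unknown) > 0) {
    stop("no prior supplied for class(es): ", paste(unknown, collapse = ", "))
  }
  total <- variants$ac_case + variants$ac_control
  key <- paste(variants$var_class, variants$ac_case, total, sep = ":")
  uniq <- !duplicated(key)
  ukey <- key[uniq]
  ubf <- vapply(which(uniq), function(i) {
    pr <- priors[[variants$var_class[i]]]
    .variant_bf_one(variants$ac_case[i], total[i], p0,
                    pr$gamma_bar, pr$sigma, rel_tol)
  }, numeric(1))
  variants$bf <- ubf[match(key, ukey)]
  variants
}
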