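#' Gene Bayes factor from variant Bayes factors
#'
#' Under the mixture model a variant in a risk gene is itself a risk variant
#' with class probability `eta_c`; marginalising the per-variant indicator
#' gives the gene Bayes factor
#' \deqn{BF_{gene} = \prod_j \left[(1 - \eta_{c(j)}) + \eta_{c(j)} BF_j\right].}
#' A gene with no variants has BF 1.
#'
#' @param bf Numeric vector of per-variant Bayes factors (>= 0).
#' @param var_class Class label per variant.
#' @param eta Named vector of per-class risk-variant proportions in `[0, 1]`.
#' @return The gene Bayes factor (scalar).
#' @export
gene_bayes_factor <- function(bf, var_class, eta) {
  if (length(bf) == 0) return(1)
  unknown <- setdiff(unique(var_class), names(eta))
  if (length(unknown) > 0) {
    stop("no eta for class(es): ", paste(unknown, collapse = ", "))
  }
  e <- eta[var_class]
  stopifnot(all(e >= 0 & e <= 1), all(bf >= 0))
  prod((1 - e) + e * bf)
}

# Grouped sum of log mixture terms -> per-gene log Bayes factor.
# gi: gene index 1..n_genes per variant; returns length-n_genes vector
# (0 for genes without variants).
.gene_loglr <- function(log_term, gi, n_genes) {
  out <- numeric(n_genes)
  s <- rowsum(log_term, gi)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Marginal log-likelihood (relative: the constant null binomial term is
# dropped) given per-gene log BFs. Stable for very large |loglr|.
.mix_loglik <- function(loglr, delta) {
  m <- pmax(loglr, 0)
  sum(m + log((1 - delta) * exp(-m) + delta * exp(loglr - m)))
}

# Collapse a variant table to unique (class, bf) configurations.
# Ultra-rare counts admit only a handful of distinct Bayes factors, so the
# EM iterates over a dense genes x configurations count matrix instead of
# the raw variant list.
.em_collapse <- function(gi, ci, bf, n_genes, classes) {
  key <- paste(ci, bf, sep = ":")
  ukey <- unique(key)
  ui <- match(key, ukey)
  first <- match(ukey, key)
  C <- matrix(0, nrow = n_genes, ncol = length(ukey))
  tab <- table(factor(gi, levels = seq_len(n_genes)),
               factor(ui, levels = seq_along(ukey)))
  C[] <- tab
  list(C = C, bf_u = bf[first],
       class_u = match(ci[first], classes))
}

# One EM run from a single start. eta_fixed: named logical per class;
# fixed classes keep their start value (used by the boundary LRT refit).
.em_run <- function(collapsed, n_classes, delta, eta, eta_fixed,
                    tol, max_iter) {
  C <- collapsed$C
  bf_u <- collapsed$bf_u
  cu <- collapsed$class_u
  class_mask <- lapply(seq_len(n_classes), function(k) cu == k)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    e <- eta[cu]
    term_u <- (1 - e) + e * bf_u
    loglr <- drop(C %*% log(term_u))
    ll <- .mix_loglik(loglr, delta)
    trace[iter] <- ll
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-8)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
    # E-step: posterior risk-gene and (conditional) risk-variant indicators
    Tg <- 1 / (1 + ((1 - delta) / delta) * exp(-loglr))
    U_u <- e * bf_u / term_u
    # M-step; s_u is the T-weighted variant count of each configuration
    delta <- min(max(mean(Tg), 1e-12), 1 - 1e-12)
    s_u <- drop(crossprod(C, Tg))
    for (k in seq_len(n_classes)) {
      if (eta_fixed[k]) next
      m <- class_mask[[k]]
      den <- sum(s_u[m])
      if (den > 0) eta[k] <- sum(s_u[m] * U_u[m]) / den
    }
  }
  list(delta = delta, eta = eta, loglik = trace[iter],
       loglik_trace = trace, converged = converged, n_iter = iter)
}

#' Fit the two-level rare-variant mixture by EM
#'
#' Estimates the proportion of risk genes (`delta`) and the per-class
#' proportions of risk variants (`eta`) from per-variant Bayes factors.
#' The E-step computes each gene's posterior risk probability
#' `T_i = delta * lr_i / ((1 - delta) + delta * lr_i)` and each variant's
#' conditional risk probability
#' `U_ij = eta_c * bf_ij / ((1 - eta_c) + eta_c * bf_ij)`; the M-step sets
#' `delta` to the mean of `T_i` and `eta_c` to the `T`-weighted mean of `U`
#' within the class. Genes without variants contribute a neutral Bayes
#' factor of 1 (and posterior `delta`), so `delta` refers to the whole gene
#' universe passed in `genes`.
#'
#' Because `eta = 0` is an absorbing fixed point, the fit is run from
#' several spread starting values and the run with the best final
#' log-likelihood is returned.
#'
#' @param bf_tab Data.frame with columns `gene`, `var_class`, `bf`
#'   (see [variant_bf_table()]).
#' @param genes Character vector: the gene universe. Defaults to the genes
#'   present in `bf_tab`; pass the full constraint-gene list to include
#'   genes with zero retained variants.
#' @param classes Class labels in model order (default `c("I", "II")`).
#' @param init Named start values `c(delta = , eta1 = , eta2 = )` used as
#'   the first start of the multistart.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap per start (default 5000).
#' @param fix_eta Optional named vector pinning some classes' eta (e.g.
#'   `c(II = 0)` for the boundary likelihood-ratio refit).
#' @param multistart Run 5 spread starts and keep the best (default TRUE).
#' @return A `model_estimate`: `delta`, named `eta`, `loglik` (relative to
#'   the null constant), `loglik_trace`, `converged`, `n_iter`, and
#'   `gene_results` (per-gene `lr` and `posterior` at the fitted
#'   parameters).
#' @export
em_fit <- function(bf_tab, genes = NULL, classes = c("I", "II"),
                   init = c(delta = 0.1, eta1 = 0.1, eta2 = 0.1),
                   tol = 1e-8, max_iter = 5000, fix_eta = NULL,
                   multistart = TRUE) {
  stopifnot(all(c("gene", "var_class", "bf") %in% names(bf_tab)))
  if (nrow(bf_tab) == 0) stop("no variants: nothing to fit")
  if (any(!is.finite(bf_tab$bf)) || any(bf_tab$bf < 0)) {
    stop("variant Bayes factors must be finite and non-negative")
  }
  if (is.null(genes)) genes <- sort(unique(bf_tab$gene))
  gi <- match(bf_tab$gene, genes)
  if (anyNA(gi)) stop("bf_tab contains genes outside the supplied universe")
  ci <- bf_tab$var_class
  if (!all(ci %in% classes)) {
    stop("unknown variant class(es): ",
         paste(setdiff(unique(ci), classes), collapse = ", "))
  }
  n_genes <- length(genes)
  n_classes <- length(classes)

  eta_fixed <- rep(FALSE, n_classes)
  names(eta_fixed) <- classes
  fixval <- rep(NA_real_, n_classes)
  if (!is.null(fix_eta)) {
    stopifnot(all(names(fix_eta) %in% classes))
    eta_fixed[names(fix_eta)] <- TRUE
    fixval[match(names(fix_eta), classes)] <- fix_eta
  }

  starts <- list(c(init[["delta"]], init[["eta1"]],
                   if (n_classes > 1) init[["eta2"]] else NULL))
  if (multistart) {
    extra <- list(c(0.3, 0.3, 0.3), c(0.5, 0.6, 0.1),
                  c(0.2, 0.8, 0.3), c(0.7, 0.4, 0.6))
    starts <- c(starts, lapply(extra, function(s) s[seq_len(1 + n_classes)]))
  }

  collapsed <- .em_collapse(gi, ci, bf_tab$bf, n_genes, classes)
  best <- NULL
  for (s in starts) {
    delta0 <- s[1]
    eta0 <- s[-1]
    eta0[eta_fixed] <- fixval[eta_fixed]
    names(eta0) <- classes
    run <- .em_run(collapsed, n_classes, delta0, eta0, eta_fixed,
                   tol, max_iter)
    if (is.null(best) || run$loglik > best$loglik + 1e-12) best <- run
  }

  e <- best$eta[ci]
  term <- (1 - e) + e * bf_tab$bf
  loglr <- .gene_loglr(log(term), gi, n_genes)
  lr <- exp(loglr)
  posterior <- 1 / (1 + ((1 - best$delta) / best$delta) * exp(-loglr))
  structure(list(delta = best$delta,
                 eta = best$eta,
                 loglik = best$loglik,
                 loglik_trace = best$loglik_trace,
                 converged = best$converged,
                 n_iter = best$n_iter,
                 eta_pvalues = NULL,
                 classes = classes,
                 gene_results = data.frame(gene = genes, lr = lr,
                                           posterior = posterior,
                                           stringsAsFactors = FALSE)),
            class = "model_estimate")
}

#' @export
print.model_estimate <- function(x, ...) {
  cat("Two-level rare-variant mixture fit\n")
  cat(sprintf("  delta (risk-gene proportion): %.4f\n", x$delta))
  for (k in seq_along(x$eta)) {
    pv <- if (!is.null(x$eta_pvalues)) {
      sprintf("  (LRT p = %.3g)", x$eta_pvalues[k])
    } else ""
    cat(sprintf("  eta[%s] (risk-variant proportion): %.4f%s\n",
                names(x$eta)[k], x$eta[k], pv))
  }
  cat(sprintf("  log-likelihood (rel.): %.6f after %d iteration(s)%s\n",
              x$loglik, x$n_iter,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Boundary likelihood-ratio test for a class's risk-variant proportion
#'
#' Tests `eta_c = 0` for one variant class by refitting the mixture with
#' that class's eta pinned at zero (all other parameters re-optimised).
#' Because the null lies on the boundary of the parameter space, the test
#' statistic is referred to the 50:50 mixture of a point mass at 0 and a
#' chi-squared with 1 degree of freedom, so
#' `p = 0.5 * P(chisq_1 > stat)`.
#'
#' @param bf_tab,genes,classes As in [em_fit()].
#' @param fit The unconstrained `model_estimate` from [em_fit()].
#' @param var_class The class label to test.
#' @param ... Passed to the constrained [em_fit()] call.
#' @return List with `stat` (the LRT statistic) and `p`.
#' @export
lrt_eta <- function(bf_tab, fit, var_class, genes = NULL,
                    classes = c("I", "II"), ...) {
  stopifnot(inherits(fit, "model_estimate"), var_class %in% classes)
  fix <- stats::setNames(0, var_class)
  fit0 <- em_fit(bf_tab, genes = genes, classes = classes,
                 fix_eta = fix, ...)
  stat <- 2 * (fit$loglik - fit0$loglik)
  if (stat < -1e-6) {
    warning("constrained fit beat the full fit (stat = ", signif(stat, 3),
            "); reporting 0")
  }
  stat <- max(stat, 0)
  list(stat = stat, p = 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fit the mixture and test each class's risk-variant proportion
#'
#' Convenience wrapper: [em_fit()] followed by [lrt_eta()] for every class,
#' attaching `eta_pvalues` to the returned estimate.
#'
#' @inheritParams em_fit
#' @return A `model_estimate` with `eta_pvalues` filled in.
#' @export
fit_mixture <- function(bf_tab, genes = NULL, classes = c("I", "II"), ...) {
  fit <- em_fit(bf_tab, genes = genes, classes = classes, ...)
  pv <- vapply(classes, function(cl) {
    lrt_eta(bf_tab, fit, cl, genes = genes, classes = classes, ...)$p
  }, numeric(1))
  fit$eta_pvalues <- pv
  fit
}
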