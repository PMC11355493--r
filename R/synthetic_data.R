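#' Simulation configuration for schizophrenia-scale exome count data
#'
#' Defaults mirror the study conditions of a large schizophrenia
#' case-control exome analysis: 24,248 cases vs 97,322 controls, about 3000
#' constraint genes, 45.1% of them risk genes, two variant classes with
#' risk-variant proportions 67.66% (class I: PTV and high-MPC missense) and
#' 8.1% (class II: MPC 2-3 missense), Gamma effect-size priors with means
#' 3 and 1, and ultra-rare totals capped at 5. Variant counts per gene are
#' Poisson with means 10 (class I) and 20 (class II): across roughly 120,000
#' exomes a constraint gene harbours tens of distinct ultra-rare sites, with
#' moderately damaging missense variants outnumbering protein-truncating and
#' high-MPC ones. Total minor-allele counts are uniform on `1..mac_max`.
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Cohort sizes.
#' @param delta_true Risk-gene proportion.
#' @param eta_true Named per-class risk-variant proportions.
#' @param gamma_bar_true Named per-class prior mean relative risks.
#' @param sigma_true Gamma prior rate (shared across classes).
#' @param variants_per_gene_mean Named per-class Poisson means.
#' @param mac_max Ultra-rare cap on the total minor-allele count.
#' @param total_count_probs Probabilities over totals `1..mac_max`.
#' @param seed Mandatory RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 3000,
                       n_case = 24248, n_control = 97322,
                       delta_true = 0.451,
                       eta_true = c(I = 0.6766, II = 0.081),
                       gamma_bar_true = c(I = 3, II = 1),
                       sigma_true = 1,
                       variants_per_gene_mean = c(I = 10, II = 20),
                       mac_max = 5,
                       total_count_probs = NULL,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(total_count_probs)) {
    total_count_probs <- rep(1 / mac_max, mac_max)
  }
  if (length(total_count_probs) != mac_max ||
      any(total_count_probs < 0) ||
      abs(sum(total_count_probs) - 1) > 1e-8) {
    stop("total_count_probs must be ", mac_max,
         " non-negative values summing to 1")
  }
  stopifnot(n_genes >= 1, n_case >= 1, n_control >= 1,
            delta_true >= 0, delta_true <= 1,
            all(eta_true >= 0 & eta_true <= 1),
            all(gamma_bar_true > 0), sigma_true > 0,
            all(variants_per_gene_mean >= 0), mac_max >= 1)
  stopifnot(identical(names(eta_true), names(gamma_bar_true)),
            identical(names(eta_true), names(variants_per_gene_mean)))
  structure(list(n_genes = n_genes, n_case = n_case, n_control = n_control,
                 delta_true = delta_true, eta_true = eta_true,
                 gamma_bar_true = gamma_bar_true, sigma_true = sigma_true,
                 variants_per_gene_mean = variants_per_gene_mean,
                 mac_max = mac_max, total_count_probs = total_count_probs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a case-control ultra-rare variant count dataset
#'
#' Realises the two-level generative model with known ground truth: each
#' gene is a risk gene with probability `delta_true`; per class, the gene's
#' variant count is Poisson; each variant of a risk gene is a risk variant
#' with the class probability `eta_true`; risk variants draw a relative
#' risk from `Gamma(gamma_bar * sigma, sigma)` (non-risk variants have
#' relative risk 1); the variant's total minor-allele count is drawn from
#' `total_count_probs` and split between cases and controls binomially with
#' the (possibly tilted) case share. Class I variants are emitted as PTVs
#' and class II as missense with MPC 2.5 so the table round-trips through
#' [assign_variant_class()] unchanged.
#'
#' @param config A [sim_config()].
#' @return List with `variants` (standard variant table including
#'   `var_class`) and `truth` (`gene`, `variant`, `z_gene`, `u_variant`,
#'   `gamma`; `z_gene` is also defined for genes with zero variants via the
#'   `gene_truth` attribute-free companion data.frame `genes`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p0 <- null_case_share(config$n_case, config$n_control)
  classes <- names(config$eta_true)
  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  z <- stats::rbinom(config$n_genes, 1, config$delta_true)

  per_class <- lapply(classes, function(cl) {
    m <- stats::rpois(config$n_genes, config$variants_per_gene_mean[[cl]])
    gi <- rep(seq_len(config$n_genes), m)
    nv <- length(gi)
    if (nv == 0) return(NULL)
    u <- stats::rbinom(nv, 1, config$eta_true[[cl]] * z[gi])
    gam <- rep(1, nv)
    nrisk <- sum(u == 1)
    if (nrisk > 0) {
      gam[u == 1] <- stats::rgamma(nrisk,
                                   shape = config$gamma_bar_true[[cl]] *
                                     config$sigma_true,
                                   rate = config$sigma_true)
    }
    tot <- sample.int(config$mac_max, nv, replace = TRUE,
                      prob = config$total_count_probs)
    acc <- stats::rbinom(nv, tot, risk_case_share(gam, p0))
    data.frame(gene = gene_ids[gi],
               var_class = cl,
               annotation = if (cl == "I") "PTV" else "missense",
               mpc = if (cl == "I") NA_real_ else 2.5,
               ac_case = acc, ac_control = tot - acc,
               z_gene = z[gi], u_variant = u, gamma = gam,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_class)
  if (is.null(all)) {
    all <- data.frame(gene = character(0), var_class = character(0),
                      annotation = character(0), mpc = numeric(0),
                      ac_case = integer(0), ac_control = integer(0),
                      z_gene = integer(0), u_variant = integer(0),
                      gamma = numeric(0))
  }
  # stable order: by gene then class, with per-gene variant ids
  all <- all[order(all$gene, all$var_class), , drop = FALSE]
  if (nrow(all) > 0) {
    idx <- stats::ave(seq_len(nrow(all)), all$gene, FUN = seq_along)
    all$variant <- paste0(all$gene, "_v", idx)
  } else {
    all$variant <- character(0)
  }
  rownames(all) <- NULL
  variants <- all[c("gene", "variant", "annotation", "mpc",
                    "ac_case", "ac_control", "var_class")]
  truth <- all[c("gene", "variant", "z_gene", "u_variant", "gamma")]
  list(variants = variants, truth = truth,
       genes = data.frame(gene = gene_ids, z_gene = z,
                          stringsAsFactors = FALSE))
}

#' Realized false discovery proportion against simulation truth
#'
#' Fraction of the selected genes that are truly null (`z_gene = 0`).
#' An empty selection has FDP 0 by convention, so calibration averages are
#' not inflated by replicates that select nothing.
#'
#' @param selected Character vector of selected gene ids.
#' @param gene_truth Data.frame `gene`, `z_gene` (the `genes` element of
#'   [simulate_dataset()]).
#' @return The realized false discovery proportion in `[0, 1]`.
#' @export
truth_fdp <- function(selected, gene_truth) {
  if (length(selected) == 0) return(0)
  idx <- match(selected, gene_truth$gene)
  if (anyNA(idx)) {
    stop("selected gene(s) not in truth: ",
         paste(utils::head(selected[is.na(idx)], 5), collapse = ", "))
  }
  mean(gene_truth$z_gene[idx] == 0)
}
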