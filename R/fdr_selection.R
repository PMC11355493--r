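#' Nominate candidate risk genes by Bayesian FDR
#'
#' Ranks genes by posterior risk probability (descending; ties broken by
#' gene symbol so output is deterministic) and computes the running Bayesian
#' FDR of each prefix, the cumulative mean of the local false-discovery
#' probabilities `1 - posterior`. The selected set is the largest prefix
#' whose running FDR is strictly below `level`.
#'
#' @param gene_results Data.frame with columns `gene`, `posterior` and
#'   optionally `lr` (gene Bayes factor, carried through as `bf`).
#' @param level Bayesian FDR level in `[0, 1)`, default 0.05; at 0 nothing
#'   can be selected (the running FDR must be strictly below the level).
#' @return Data.frame `gene`, `bf`, `posterior`, `rank`, `cum_fdr`,
#'   `selected`, ordered by rank.
#' @export
bayesian_fdr_select <- function(gene_results, level = 0.05) {
  stopifnot(level >= 0, level < 1)
  if (nrow(gene_results) == 0) {
    return(data.frame(gene = character(0), bf = numeric(0),
                      posterior = numeric(0), rank = integer(0),
                      cum_fdr = numeric(0), selected = logical(0)))
  }
  post <- gene_results$posterior
  stopifnot(all(post >= 0 & post <= 1))
  ord <- order(-post, gene_results$gene)
  out <- data.frame(
    gene = gene_results$gene[ord],
    bf = if ("lr" %in% names(gene_results)) gene_results$lr[ord] else NA_real_,
    posterior = post[ord],
    stringsAsFactors = FALSE
  )
  out$rank <- seq_len(nrow(out))
  out$cum_fdr <- cumsum(1 - out$posterior) / out$rank
  out$selected <- out$cum_fdr < level
  rownames(out) <- NULL
  out
}
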