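#' Overlap between two gene sets
#'
#' Exact set intersection with the overlap reported both as a count and as
#' a percentage of the reference set B. When only the overlap members of a
#' published comparison are available, pass them as `b` and give the full
#' reference-set size through `size_b`.
#'
#' @param a,b `gene_set` objects or character vectors.
#' @param size_b Size of the reference set B used as the percentage
#'   denominator (default `length of b`).
#' @return List with `members` (sorted symbols), `count` and `pct_of_b`.
#' @export
gene_set_overlap <- function(a, b, size_b = NULL) {
  am <- if (inherits(a, "gene_set")) a$members else sort(unique(toupper(a)))
  bm <- if (inherits(b, "gene_set")) b$members else sort(unique(toupper(b)))
  if (is.null(size_b)) size_b <- length(bm)
  if (size_b == 0) stop("reference set B is empty; percentage undefined")
  members <- sort(intersect(am, bm))
  list(members = members, count = length(members),
       pct_of_b = 100 * length(members) / size_b)
}

#' Fisher exact test on a 2x2 table
#'
#' `a` counts genes in both sets, `b` in the query only, `c` in the
#' reference only, `d` in neither. One-sided (`"greater"`, enrichment
#' direction) p-values are hypergeometric upper tails; two-sided p-values
#' and the conditional-MLE odds ratio come from [stats::fisher.test()].
#' If any margin is zero the table carries no information and p = 1.
#'
#' @param a,b,c,d Non-negative integer cells.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List with `p` and `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == floor(cells)))
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    warning("a margin of the 2x2 table is zero; p = 1")
    or <- tryCatch(unname(stats::fisher.test(matrix(cells, 2, byrow = TRUE))$estimate),
                   error = function(e) NA_real_)
    return(list(p = 1, odds_ratio = or))
  }
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(m, alternative = alternative)
  p <- if (alternative == "greater") {
    # hypergeometric upper tail: X >= a with margins fixed
    stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  } else {
    ft$p.value
  }
  list(p = min(p, 1), odds_ratio = unname(ft$estimate))
}

#' Enrichment of a query gene list in reference gene sets
#'
#' For each reference set, builds the 2x2 table (query-and-reference, query
#' only, reference only, neither) inside the gene universe and applies
#' [fisher_exact_2x2()]. The query and every reference set are clipped to
#' the universe first (with a warning if the query loses members); the
#' universe is typically the constraint-gene list the analysis ran over.
#'
#' @param query `gene_set` or character vector of nominated genes.
#' @param reference_sets List of `gene_set`s (or character vectors).
#' @param universe `gene_set` or character vector.
#' @param alternative Passed to [fisher_exact_2x2()].
#' @return Data.frame, one row per reference set: `set_name`,
#'   `universe_size`, `query_size`, `ref_size`, `overlap_count`, `pct_of_ref`,
#'   `odds_ratio`, `fisher_p`, plus a semicolon-joined `overlap_members`
#'   column.
#' @export
set_enrichment <- function(query, reference_sets, universe,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  uni <- if (inherits(universe, "gene_set")) universe$members
         else sort(unique(toupper(universe)))
  if (length(uni) == 0) stop("empty universe")
  qm <- if (inherits(query, "gene_set")) query$members
        else sort(unique(toupper(query)))
  dropped <- setdiff(qm, uni)
  if (length(dropped) > 0) {
    warning(length(dropped), " query gene(s) outside the universe dropped")
  }
  qm <- intersect(qm, uni)
  if (is.null(names(reference_sets))) names(reference_sets) <-
    vapply(reference_sets, function(s) {
      if (inherits(s, "gene_set")) s$name else "reference"
    }, character(1))
  rows <- lapply(names(reference_sets), function(nm) {
    s <- reference_sets[[nm]]
    rm_ <- if (inherits(s, "gene_set")) s$members else sort(unique(toupper(s)))
    rm_ <- intersect(rm_, uni)
    ov <- intersect(qm, rm_)
    a <- length(ov)
    b <- length(qm) - a
    cc <- length(rm_) - a
    d <- length(uni) - a - b - cc
    ft <- fisher_exact_2x2(a, b, cc, d, alternative = alternative)
    data.frame(set_name = nm, universe_size = length(uni),
               query_size = length(qm), ref_size = length(rm_),
               overlap_count = a,
               pct_of_ref = if (length(rm_) > 0) 100 * a / length(rm_) else NA_real_,
               odds_ratio = ft$odds_ratio, fisher_p = ft$p,
               overlap_members = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fold-change term enrichment of a query list
#'
#' Database-agnostic analogue of a GO over-representation test: for each
#' term with at least one annotated reference gene, the fold change is
#' `(k/n) / (K/N)` where `k` of the `n` query genes and `K` of the `N`
#' reference genes carry the term, with a hypergeometric upper-tail p-value
#' and Bonferroni correction across all tested terms.
#'
#' @param query `gene_set` or character vector; genes absent from the
#'   reference are dropped with a warning.
#' @param term_map Data.frame with columns `gene`, `term` (one row per
#'   annotation).
#' @param reference `gene_set` or character vector: the annotation universe.
#' @return Data.frame `term`, `k`, `n`, `K`, `N`, `fold`, `p`, `p_adj`,
#'   sorted by fold descending (ties by term id).
#' @export
term_fold_enrichment <- function(query, term_map, reference) {
  stopifnot(all(c("gene", "term") %in% names(term_map)))
  ref <- if (inherits(reference, "gene_set")) reference$members
         else sort(unique(toupper(reference)))
  qm <- if (inherits(query, "gene_set")) query$members
        else sort(unique(toupper(query)))
  outside <- setdiff(qm, ref)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) absent from the reference dropped")
    qm <- intersect(qm, ref)
  }
  tm <- data.frame(gene = toupper(term_map$gene),
                   term = as.character(term_map$term),
                   stringsAsFactors = FALSE)
  tm <- unique(tm[tm$gene %in% ref, , drop = FALSE])
  n <- length(qm)
  N <- length(ref)
  K_tab <- table(tm$term)
  k_tab <- table(tm$term[tm$gene %in% qm])
  terms <- names(K_tab)[K_tab >= 1]
  if (length(terms) == 0 || n == 0) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), fold = numeric(0),
                      p = numeric(0), p_adj = numeric(0)))
  }
  K <- as.integer(K_tab[terms])
  k <- as.integer(k_tab[terms])
  k[is.na(k)] <- 0L
  fold <- (k / n) / (K / N)
  p <- ifelse(k == 0, 1,
              stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  p_adj <- stats::p.adjust(p, method = "bonferroni")
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    fold = fold, p = p, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
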