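test_that("overlap counting is exact and percentage uses the reference size", {
  a <- gene_set("query", c("x1", "x2", "x3", "x4"))
  b <- gene_set("ref", c("X3", "X4", "X5"))
  ov <- gene_set_overlap(a, b)
  expect_equal(ov$members, c("X3", "X4"))
  expect_equal(ov$count, 2)
  expect_equal(ov$pct_of_b, 100 * 2 / 3)
  # symmetric count, asymmetric percentage
  expect_equal(gene_set_overlap(b, a)$count, 2)
  expect_equal(gene_set_overlap(b, a)$pct_of_b, 50)
  expect_equal(gene_set_overlap(gene_set("a", "G1"),
                                gene_set("b", "G2"))$count, 0)
  same <- gene_set("s", paste0("G", 1:7))
  expect_equal(gene_set_overlap(same, same)$pct_of_b, 100)
  expect_error(gene_set_overlap(a, gene_set("empty", character(0))),
               "empty")
})

test_that("Fisher exact matches hand-enumerable tables", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1, "two.sided")$p, 1)
  # margins 4/4 in N = 8: P(X >= 3) = (16 + 1) / 70
  expect_equal(fisher_exact_2x2(3, 1, 1, 3, "greater")$p, 17 / 70,
               tolerance = 1e-12)
  expect_warning(res <- fisher_exact_2x2(0, 0, 3, 4), "margin")
  expect_equal(res$p, 1)
})

test_that("one-sided p never increases as the diagonal strengthens", {
  # margins fixed at 10/10 row, 10/10 column in N = 20
  ps <- vapply(0:10, function(a) {
    fisher_exact_2x2(a, 10 - a, 10 - a, a, "greater")$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("Fisher agrees with the enumeration oracle on random tables", {
  set.seed(77)
  for (i in 1:60) {
    cells <- as.integer(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    for (alt in c("greater", "two.sided")) {
      got <- suppressWarnings(
        fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4], alt)$p)
      exp_ <- fisher_enum_oracle(cells[1], cells[2], cells[3], cells[4], alt)
      expect_equal(got, exp_, tolerance = 1e-12)
    }
  }
})

test_that("set enrichment builds the 2x2 table inside the universe", {
  uni <- paste0("U", 1:100)
  query <- uni[1:10]
  ref <- uni[1:10]
  res <- set_enrichment(query, list(hit = ref), uni)
  # single-table tail: all 10 query genes in a 10-gene reference
  expect_equal(res$fisher_p, prod((10 - 0:9) / (100 - 0:9)), tolerance = 1e-12)
  expect_equal(res$overlap_count, 10)
  expect_equal(res$pct_of_ref, 100)
  # no discrimination when the query is the whole universe (the degenerate
  # margin also warns, by contract)
  all_res <- suppressWarnings(set_enrichment(uni, list(hit = ref), uni))
  expect_equal(all_res$fisher_p, 1)
  disj <- set_enrichment(uni[1:10], list(miss = uni[51:60]), uni)
  expect_equal(disj$fisher_p, 1)
  expect_warning(set_enrichment(c(query, "ELSEWHERE"), list(hit = ref), uni),
                 "outside the universe")
})

test_that("fold-change enrichment follows the k/n over K/N formula", {
  ref <- paste0("R", 1:50)
  query <- ref[1:5]
  tm <- rbind(
    data.frame(gene = query, term = "EXACT"),          # only the query
    data.frame(gene = ref, term = "ALL"),              # whole reference
    data.frame(gene = ref[11:20], term = "NONE")       # disjoint from query
  )
  res <- term_fold_enrichment(query, tm, ref)
  expect_equal(res$fold[res$term == "EXACT"], (5 / 5) / (5 / 50)) # = 10
  expect_equal(res$fold[res$term == "ALL"], 1)
  expect_equal(res$p[res$term == "ALL"], 1)
  expect_equal(res$fold[res$term == "NONE"], 0)
  expect_equal(res$p[res$term == "NONE"], 1)
  expect_equal(res$p_adj, pmin(1, res$p * 3))
  expect_true(!is.unsorted(rev(res$fold)))
})

test_that("null term maps give no spurious enrichment", {
  # large-margin hypergeometric p-values are near-continuous; the one-sided
  # Kolmogorov test checks the upper tail is not anti-conservative
  set.seed(99)
  ref <- sprintf("R%04d", 1:1000)
  query <- sample(ref, 100)
  terms <- lapply(1:2000, function(i) sample(ref, 200))
  tm <- data.frame(gene = unlist(terms),
                   term = rep(sprintf("T%04d", 1:2000), each = 200))
  res <- term_fold_enrichment(query, tm, ref)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(res$p), 0.45)
})
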