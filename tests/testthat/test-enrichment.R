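test_that("top-percentile cut size and membership follow the documented
           rounding and tie-breaking rules", {
  gr <- make_gene_results(p = (1:200) / 200)
  expect_length(top_percentile_membership(gr, 1), 2) # round(2.0) = 2
  expect_length(top_percentile_membership(gr, 5), 10)
  expect_length(top_percentile_membership(make_gene_results((1:30) / 30), 1),
                1) # minimum cut of one gene
  # distinct p: equals the m smallest by a full sort oracle
  set.seed(111)
  p <- sample(seq(0.001, 0.999, length.out = 150))
  gr2 <- make_gene_results(p)
  top <- top_percentile_membership(gr2, 10)
  expect_setequal(top, gr2$gene_id[order(p)][1:15])
  # total ties: ordering settled by observed_sum then gene id, stable
  gr3 <- make_gene_results(rep(0.5, 100),
                           observed_sum = rep(c(2, 1), 50))
  t1 <- top_percentile_membership(gr3, 5)
  expect_identical(t1, top_percentile_membership(gr3, 5))
  expect_true(all(gr3$observed_sum[match(t1, gr3$gene_id)] == 2))
})

test_that("percentile permutation p matches the exact hypergeometric tail", {
  set.seed(113)
  gr <- make_gene_results(sample(seq(1e-4, 1, length.out = 200)))
  top <- top_percentile_membership(gr, 10) # m = 20
  # a set with 4 of its 10 genes in the top decile
  set_genes <- c(sample(top, 4), sample(setdiff(gr$gene_id, top), 6))
  res <- percentile_enrichment_test(gr, set_genes, 10,
                                    n_perm_initial = 10000,
                                    n_perm_escalated = 10000, seed = 3)
  expect_identical(res$observed, 4L)
  p_exact <- phyper(3, 20, 180, 10, lower.tail = FALSE)
  expect_lt(abs(res$p_empirical - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 10000))
})

test_that("percentile test degenerate cases and escalation rule", {
  gr <- make_gene_results((1:100) / 100)
  none <- percentile_enrichment_test(gr, gr$gene_id[90:99], 5, seed = 5)
  expect_identical(none$observed, 0L)
  expect_identical(none$p_empirical, 1)
  # set = whole universe: every permutation reproduces it
  all_set <- percentile_enrichment_test(gr, gr$gene_id, 5, seed = 7)
  expect_identical(all_set$p_empirical, 1)
  expect_identical(all_set$k, 100L)
  # a clearly enriched set escalates from 1000 to 10000 permutations
  hit <- percentile_enrichment_test(gr, gr$gene_id[1:5], 5, seed = 9)
  expect_identical(hit$n_perm, 10000L)
  expect_lt(hit$p_empirical, 0.05)
  expect_error(percentile_enrichment_test(gr, c("nope1", "nope2"), 5),
               "no genes in the universe")
})

test_that("escalated and initial permutation p agree within combined
           Monte-Carlo error", {
  set.seed(115)
  gr <- make_gene_results(sample(seq(1e-3, 1, length.out = 300)))
  top <- top_percentile_membership(gr, 10)
  set_genes <- c(sample(top, 3), sample(setdiff(gr$gene_id, top), 17))
  res_init <- percentile_enrichment_test(gr, set_genes, 10,
                                         n_perm_initial = 1000,
                                         n_perm_escalated = 1000, seed = 11)
  res_esc <- percentile_enrichment_test(gr, set_genes, 10,
                                        n_perm_initial = 1000,
                                        n_perm_escalated = 10000, seed = 11)
  p <- res_esc$p_empirical
  se <- sqrt(p * (1 - p)) * sqrt(1 / 1000 + 1 / 10000)
  expect_lt(abs(res_init$p_empirical - p), max(3 * se, 1e-3))
})

test_that("increasing the observed overlap never increases the permutation p
           under a fixed seed", {
  set.seed(117)
  gr <- make_gene_results(sample(seq(1e-3, 1, length.out = 200)))
  top <- top_percentile_membership(gr, 10)
  out <- setdiff(gr$gene_id, top)
  p_at <- vapply(0:4, function(o) {
    set_genes <- c(sample(top, o), sample(out, 10 - o))
    percentile_enrichment_test(gr, set_genes, 10, n_perm_initial = 2000,
                               n_perm_escalated = 2000, seed = 13)$p_empirical
  }, numeric(1))
  expect_true(all(diff(p_at) <= 0))
})

test_that("GSEA enrichment score: single top gene gives ES = 1 and the 5-gene
           fixture matches the hand-computed running sum", {
  gr <- make_gene_results(c(0.01, 0.02, 0.03, 0.04, 0.05),
                          observed_sum = 5:1)
  single <- gsea_test(gr, gr$gene_id[1], n_perm_initial = 200, seed = 15)
  expect_equal(single$observed, 1)
  # scores s = -log10 p; set = ranks {1, 3}; hand walk of the running sum:
  # steps: +s1/(s1+s3), -1/3, +s3/(s1+s3), -1/3, -1/3; peak at step 3
  s <- -log10(c(0.01, 0.02, 0.03, 0.04, 0.05))
  es_hand <- max(abs(cumsum(c(s[1] / (s[1] + s[3]), -1 / 3,
                              s[3] / (s[1] + s[3]), -1 / 3, -1 / 3))))
  both <- gsea_test(gr, gr$gene_id[c(1, 3)], n_perm_initial = 200, seed = 17)
  expect_equal(both$observed, es_hand, tolerance = 1e-12)
  expect_error(gsea_test(gr, gr$gene_id, n_perm_initial = 100),
               "whole universe")
})

test_that("GSEA enrichment score agrees with the fgsea reference
           implementation on random rankings", {
  skip_if_not_installed("fgsea")
  set.seed(119)
  for (i in 1:5) {
    N <- 50
    p <- sample(seq(1e-4, 1, length.out = N))
    gr <- make_gene_results(p, observed_sum = rank(-p))
    set_genes <- sample(gr$gene_id, 8)
    mine <- gsea_test(gr, set_genes, n_perm_initial = 100, seed = i)
    ord <- order(gr$p_empirical, -gr$observed_sum, gr$gene_id)
    stats <- -log10(pmax(gr$p_empirical, 0.5 / gr$n_sims))[ord]
    names(stats) <- gr$gene_id[ord]
    ref <- fgsea::calcGseaStat(stats,
                               selectedStats = which(names(stats) %in% set_genes),
                               gseaParam = 1, scoreType = "pos")
    expect_equal(abs(mine$observed), abs(ref), tolerance = 1e-6)
  }
})

test_that("GSEA null p-values are roughly uniform for random sets under a
           null ranking", {
  set.seed(121)
  pvals <- vapply(1:40, function(i) {
    gr <- make_gene_results(runif(120), observed_sum = runif(120))
    gsea_test(gr, sample(gr$gene_id, 12), n_perm_initial = 400,
              n_perm_escalated = 400, seed = 1000 + i)$p_empirical
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.005)
})

test_that("percentile permutation p is uniform over replicated null gene
           rankings at nominal type-I error", {
  set.seed(123)
  hits <- vapply(1:500, function(i) {
    gr <- make_gene_results(runif(150))
    percentile_enrichment_test(gr, sample(gr$gene_id, 15), 10,
                               n_perm_initial = 500, n_perm_escalated = 2000,
                               seed = 2000 + i)$p_empirical <= 0.05
  }, logical(1))
  # discrete null: the attainable rejection rate at 0.05 for N=150, m=15,
  # k=15 is P(X >= 4) of the hypergeometric
  target <- phyper(3, 15, 135, 15, lower.tail = FALSE)
  band <- 2.576 * sqrt(target * (1 - target) / 500)
  expect_lt(abs(mean(hits) - target), band + 0.01)
})

test_that("subcomplex scan: disjoint subcomplex counts add up to the pathway
           count; empty subcomplexes are skipped with a warning", {
  set.seed(125)
  gr <- make_gene_results(sample(seq(1e-3, 1, length.out = 120)))
  pathway <- sample(gr$gene_id, 30)
  subs <- split(pathway, rep(1:3, each = 10))
  names(subs) <- paste0("complex_", 1:3)
  res <- subcomplex_scan(gr, subs, q_values = c(5, 10), seed = 19)
  expect_identical(nrow(res), 6L)
  path_res <- percentile_enrichment_test(gr, pathway, 10, seed = 21)
  expect_identical(sum(res$observed[res$test == "pct10"]),
                   path_res$observed)
  expect_warning(
    subcomplex_scan(gr, c(subs, list(ghost = c("zz1", "zz2"))),
                    q_values = 5, seed = 23),
    "ghost")
})

test_that("signal confined to one subcomplex surfaces as its smallest
           subcomplex p", {
  set.seed(127)
  reps_best <- vapply(1:15, function(i) {
    p <- runif(200)
    pathway <- sprintf("gene%05d", sample(200, 30))
    subs <- split(pathway, rep(1:3, each = 10))
    names(subs) <- paste0("complex_", 1:3)
    p[match(subs$complex_2, sprintf("gene%05d", 1:200))] <-
      runif(10, 0, 0.02) # planted signal in complex 2 only
    gr <- make_gene_results(p)
    res <- subcomplex_scan(gr, subs, q_values = 5, seed = 3000 + i)
    res$set[which.min(res$p_empirical)]
  }, character(1))
  expect_gte(mean(reps_best == "complex_2"), 0.8)
})
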