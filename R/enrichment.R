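# Canonical gene ranking: ascending empirical p, ties broken by larger
# observed sum, then lexicographic gene id. Shared by the percentile and
# GSEA tests so both see the same ordering.
rank_genes <- function(gene_results) {
  order(gene_results$p_empirical, -gene_results$observed_sum,
        gene_results$gene_id)
}

#' Genes in the top percentile of the gene-level ranking
#'
#' The cut size is `m = round(q * N / 100)` (half-up, minimum 1). Genes are
#' ranked by ascending empirical p; ties are broken by larger observed sum and
#' then lexicographic gene id, so the cut is deterministic.
#'
#' @param gene_results gene table from [gene_scan()].
#' @param q percentile in (0, 100).
#' @return character vector of the top `m` gene ids.
#' @export
top_percentile_membership <- function(gene_results, q) {
  stopifnot(q > 0, q < 100, nrow(gene_results) > 0)
  N <- nrow(gene_results)
  m <- max(1L, round_half_up(q * N / 100))
  gene_results$gene_id[rank_genes(gene_results)][seq_len(m)]
}

#' Top-percentile permutation enrichment test
#'
#' Counts how many genes of the set fall in the top `q` percent of the
#' gene-level ranking, then compares that count against random gene sets of
#' the same size drawn uniformly without replacement from the gene universe.
#' The empirical p is the proportion of permuted sets with as many or more
#' genes in the percentile. When the initial `n_perm_initial` draws give
#' p < 0.05, the test is rerun with `n_perm_escalated` fresh draws and the
#' escalated result is reported.
#'
#' @param gene_results gene table from [gene_scan()] (the gene universe).
#' @param set_genes character vector of gene ids (intersected with the
#'   universe; the intersected size is reported as `k`).
#' @param q percentile in (0, 100).
#' @param n_perm_initial,n_perm_escalated permutation counts (defaults 1000
#'   and 10000).
#' @param seed RNG seed; the escalation stage derives a fresh seed from it.
#' @param set_name,stratum labels carried into the result row.
#' @return one-row data frame (`set`, `stratum`, `test`, `N`, `k`, `m`,
#'   `observed`, `n_perm`, `n_as_extreme`, `p_empirical`).
#' @export
percentile_enrichment_test <- function(gene_results, set_genes, q,
                                       n_perm_initial = 1000,
                                       n_perm_escalated = 10000,
                                       seed = 1, set_name = "set",
                                       stratum = NA_character_) {
  universe <- gene_results$gene_id
  N <- length(universe)
  k <- sum(set_genes %in% universe)
  if (k == 0)
    stop("gene set '", set_name, "' has no genes in the universe",
         call. = FALSE)
  if (k > N) stop("set size exceeds universe size", call. = FALSE)
  top <- top_percentile_membership(gene_results, q)
  m <- length(top)
  observed <- sum(set_genes %in% top)
  in_top <- universe %in% top

  perm_counts <- function(n_perm, stage_seed) {
    set.seed(stage_seed)
    vapply(seq_len(n_perm),
           function(i) sum(in_top[sample.int(N, k)]), integer(1))
  }
  counts <- perm_counts(n_perm_initial, derive_seed(seed, "perm-initial"))
  n_perm <- n_perm_initial
  p <- sum(counts >= observed) / n_perm
  if (p < 0.05 && n_perm_escalated > n_perm_initial) {
    counts <- perm_counts(n_perm_escalated, derive_seed(seed, "perm-escalated"))
    n_perm <- n_perm_escalated
    p <- sum(counts >= observed) / n_perm
  }
  data.frame(set = set_name, stratum = stratum,
             test = paste0("pct", sub("\\.?0+$", "", sprintf("%.6f", q))),
             N = N, k = k, m = m, observed = observed,
             n_perm = as.integer(n_perm), n_as_extreme = sum(counts >= observed),
             p_empirical = p, stringsAsFactors = FALSE)
}

# Weighted running-sum enrichment score over a ranked score vector.
# hit_idx indexes the ranked positions belonging to the set.
gsea_es <- function(scores_ranked, hit_idx, weight_exponent = 1) {
  N <- length(scores_ranked)
  k <- length(hit_idx)
  steps <- rep(-1 / (N - k), N)
  w <- abs(scores_ranked[hit_idx])^weight_exponent
  if (sum(w) == 0) w <- rep(1, k) # all-zero scores: unweighted hits
  steps[hit_idx] <- w / sum(w)
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

#' GSEA-style running-sum enrichment test
#'
#' Genes are ranked by score `s = -log10(p_empirical)` (zero empirical
#' p-values are floored at half the smallest resolvable value, `0.5/n_sims`).
#' The running sum increments by `|s|^weight / sum_set |s|^weight` at set
#' members and decrements by `1/(N - k)` elsewhere; the enrichment score (ES)
#' is the running sum at its maximum deviation from zero. The null is built
#' from random same-size gene sets, mirroring the percentile test's sampling
#' scheme, and p is the proportion of null ES greater than or equal to the
#' observed ES. The same p < 0.05 escalation rule as the percentile test
#' applies.
#'
#' @inheritParams percentile_enrichment_test
#' @param n_perm_initial,n_perm_escalated permutation counts.
#' @param weight_exponent exponent on the gene scores (default 1).
#' @return one-row data frame as in [percentile_enrichment_test()], with the
#'   ES in `observed` and `m = NA`.
#' @export
gsea_test <- function(gene_results, set_genes, n_perm_initial = 1000,
                      n_perm_escalated = 10000, seed = 1,
                      weight_exponent = 1, set_name = "set",
                      stratum = NA_character_) {
  universe <- gene_results$gene_id
  N <- length(universe)
  k <- sum(set_genes %in% universe)
  if (k == 0)
    stop("gene set '", set_name, "' has no genes in the universe",
         call. = FALSE)
  if (k >= N)
    stop("set covers the whole universe; miss decrement undefined",
         call. = FALSE)
  ord <- rank_genes(gene_results)
  p_floor <- pmax(gene_results$p_empirical, 0.5 / gene_results$n_sims)
  scores <- -log10(p_floor)[ord]
  ranked_ids <- gene_results$gene_id[ord]
  observed <- gsea_es(scores, which(ranked_ids %in% set_genes),
                      weight_exponent)

  perm_es <- function(n_perm, stage_seed) {
    set.seed(stage_seed)
    vapply(seq_len(n_perm), function(i)
      gsea_es(scores, sort(sample.int(N, k)), weight_exponent), numeric(1))
  }
  es <- perm_es(n_perm_initial, derive_seed(seed, "gsea-initial"))
  n_perm <- n_perm_initial
  p <- sum(es >= observed) / n_perm
  if (p < 0.05 && n_perm_escalated > n_perm_initial) {
    es <- perm_es(n_perm_escalated, derive_seed(seed, "gsea-escalated"))
    n_perm <- n_perm_escalated
    p <- sum(es >= observed) / n_perm
  }
  data.frame(set = set_name, stratum = stratum, test = "gsea",
             N = N, k = k, m = NA_integer_, observed = observed,
             n_perm = as.integer(n_perm), n_as_extreme = sum(es >= observed),
             p_empirical = p, stringsAsFactors = FALSE)
}

#' Percentile enrichment scan over pathway subcomplexes
#'
#' Runs the top-percentile permutation test for each subcomplex at each
#' requested percentile. Results are reported raw, with no multiplicity
#' adjustment within the scan. Subcomplexes with no genes in the universe are
#' skipped with a warning.
#'
#' @param gene_results gene table from [gene_scan()].
#' @param subcomplexes named list of gene-id vectors.
#' @param q_values percentiles (default `c(1, 5, 10)`).
#' @param n_perm_initial,n_perm_escalated,seed,stratum as in
#'   [percentile_enrichment_test()]; per-subcomplex seeds are derived.
#' @return data frame of enrichment rows, one per subcomplex x percentile.
#' @export
subcomplex_scan <- function(gene_results, subcomplexes, q_values = c(1, 5, 10),
                            n_perm_initial = 1000, n_perm_escalated = 10000,
                            seed = 1, stratum = NA_character_) {
  rows <- list()
  for (nm in names(subcomplexes)) {
    if (!any(subcomplexes[[nm]] %in% gene_results$gene_id)) {
      warning("subcomplex '", nm, "' has no genes in the universe; skipped",
              call. = FALSE)
      next
    }
    for (q in q_values) {
      rows[[length(rows) + 1L]] <- percentile_enrichment_test(
        gene_results, subcomplexes[[nm]], q,
        n_perm_initial = n_perm_initial, n_perm_escalated = n_perm_escalated,
        seed = derive_seed(seed, paste0("sub-", nm, "-q", q)),
        set_name = nm, stratum = stratum)
    }
  }
  if (!length(rows))
    return(data.frame(set = character(), stratum = character(),
                      test = character(), N = integer(), k = integer(),
                      m = integer(), observed = numeric(), n_perm = integer(),
                      n_as_extreme = integer(), p_empirical = numeric()))
  do.call(rbind, rows)
}
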