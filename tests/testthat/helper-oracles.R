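# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct enumeration, closed forms, or brute force.

# Levene-Haldane exact HWE p by direct log-factorial enumeration over all
# heterozygote counts of matching parity.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  r <- min(n_a, n_b)
  if (r == 0) return(1)
  hets <- seq(r %% 2, r, by = 2)
  lp <- vapply(hets, function(h) {
    hom_rare <- (r - h) / 2
    hom_common <- n - h - hom_rare
    lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_common) + h * log(2) +
      lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  p_obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

# Cochran-Armitage trend chi-squared via the closed form N * cor(g, y)^2
# (population-moment correlation; identical to the textbook CA statistic for
# scores 0/1/2).
trend_chi2_oracle <- function(g, y) {
  length(y) * stats::cor(g, y)^2
}

# Method-of-moments pi-hat recomputed by direct counting of IBS classes
# (independent of the package's matrix implementation).
pihat_oracle <- function(gi, gj, freqs) {
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]; p <- freqs[ok]; q <- 1 - p
  d <- abs(gi - gj)
  pr <- c(ibs0 = mean(d == 2), ibs1 = mean(d == 1))
  e0_0 <- mean(2 * p^2 * q^2)
  e1_0 <- mean(4 * p^3 * q + 4 * p * q^3)
  e1_1 <- mean(2 * p^2 * q + 2 * p * q^2)
  p0 <- min(max(pr["ibs0"] / e0_0, 0), 1)
  p1 <- min(max((pr["ibs1"] - p0 * e1_0) / e1_1, 0), 1)
  p2 <- min(max(1 - p0 - p1, 0), 1)
  unname(min(max(p2 + p1 / 2, 0), 1))
}

# Small gene-results table with chosen empirical p-values (distinct unless
# stated); used by the enrichment tests.
make_gene_results <- function(p, observed_sum = NULL, n_sims = 1000) {
  N <- length(p)
  data.frame(gene_id = sprintf("gene%05d", seq_len(N)),
             chrom = "chr1",
             start = seq_len(N) * 1000, end = seq_len(N) * 1000 + 500,
             n_snps = 2L,
             observed_sum = observed_sum %||% rev(seq_len(N)),
             n_sims = n_sims,
             n_exceed = as.integer(round(p * n_sims)),
             p_empirical = p,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Compact cohort used by several module tests: clean, no structure.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_controls = 60, n_cases_mli_la = 30, n_cases_ili = 30,
         n_genes = 30, pathway_size = 10, missing_rate = 0.02, seed = 42),
    list(...))
  do.call(sim_config, args)
}
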