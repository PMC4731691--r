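test_that("exact HWE test: monomorphic site and error cases", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 100), 1)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("exact HWE test matches the enumeration oracle on canonical and
           extreme tables", {
  expect_equal(hwe_exact_test(10, 5, 10), hwe_oracle(10, 5, 10),
               tolerance = 1e-12)
  # maximal heterozygosity, N = 50
  expect_equal(hwe_exact_test(0, 100, 0), hwe_oracle(0, 100, 0),
               tolerance = 1e-12)
  expect_equal(hwe_exact_test(57, 2, 1), hwe_oracle(57, 2, 1),
               tolerance = 1e-12)
})

test_that("variant QC labels each designed failure and keeps the rest", {
  # 10 variants: v1 fails MAF, v2 missingness, v3 is A/T ambiguous,
  # v4 fails HWE in controls, v5 fails differential missingness, v6-v10 pass
  set.seed(7)
  n <- 200
  status <- rep(c("case", "control"), each = n / 2)
  G <- sapply(1:10, function(j) rbinom(n, 2, 0.3))
  G[, 1] <- rbinom(n, 2, 0.002)                  # maf << 0.01
  G[sample(n, 20), 2] <- NA                      # 10% missing
  G[, 4] <- rep(c(0L, 2L), n / 2)                # no hets at 50% freq
  G[1:6, 5] <- NA                                # case-only missingness
                                                 # (rate 3%: miss filter spared)
  storage.mode(G) <- "integer"
  rownames(G) <- sprintf("S%03d", 1:n)
  colnames(G) <- paste0("v", 1:10)
  variants <- data.frame(variant_id = paste0("v", 1:10), chrom = "chr1",
                         pos = 1:10 * 100L,
                         ref = c("A", "A", "A", "A", "A", rep("A", 5)),
                         alt = c("G", "G", "T", "G", "G", rep("C", 5)))
  samples <- data.frame(sample_id = rownames(G), status = status)
  res <- variant_qc(G, samples, variants)
  expect_identical(res$variants$variant_id[!res$variants$pass],
                   paste0("v", 1:5))
  expect_true(res$variants$fail_maf[1])
  expect_true(res$variants$fail_miss[2])
  expect_true(res$variants$fail_ambiguous[3])
  expect_true(res$variants$fail_hwe[4])
  expect_true(res$variants$fail_diffmiss[5])
  expect_identical(colnames(res$genotypes), paste0("v", 6:10))
})

test_that("a variant at exactly the MAF threshold is retained", {
  n <- 200
  g <- c(rep(1L, 4), rep(0L, n - 4)) # maf = 4/400 = 0.01 exactly
  G <- cbind(v1 = g, v2 = rbinom(n, 2, 0.4))
  storage.mode(G) <- "integer"
  rownames(G) <- sprintf("S%03d", 1:n)
  variants <- data.frame(variant_id = c("v1", "v2"), chrom = "chr1",
                         pos = c(100L, 200L), ref = "A", alt = "G")
  res <- variant_qc(G, variants = variants,
                    thresholds = list(hwe_p = NA, diffmiss_p = NA))
  expect_equal(res$variants$maf[1], 0.01)
  expect_true(res$variants$pass[1])
})

test_that("all-pass input leaves the genotype matrix untouched and the
           filters are idempotent", {
  s <- simulate_study(tiny_config(missing_rate = 0))
  res <- variant_qc(s$genotypes, s$samples, s$variants,
                    thresholds = list(maf = 0.01, miss = 0.03,
                                      hwe_p = 1e-12, diffmiss_p = NA))
  keep_amb <- !res$variants$ambiguous
  res2 <- variant_qc(res$genotypes, s$samples,
                     res$variants[res$variants$pass,
                                  c("variant_id", "chrom", "pos", "ref", "alt")],
                     thresholds = list(maf = 0.01, miss = 0.03,
                                       hwe_p = 1e-12, diffmiss_p = NA))
  expect_identical(res2$genotypes, res$genotypes)
  expect_true(all(res2$variants$pass))
})

test_that("injected case-only missingness is caught by the differential
           missingness filter", {
  s <- simulate_study(tiny_config(n_genes = 100, missing_rate = 0))
  targets <- s$variants$variant_id[c(10, 50)]
  s2 <- inject_differential_missingness(s, targets, extra_rate = 0.25,
                                        seed = 9)
  res <- variant_qc(s2$genotypes, s2$samples, s2$variants,
                    thresholds = list(hwe_p = NA))
  expect_true(all(res$variants$fail_diffmiss[
    res$variants$variant_id %in% targets]))
  expect_lt(sum(res$variants$fail_diffmiss), 10)
})

test_that("HWE-in-controls filter demands controls", {
  s <- simulate_study(tiny_config())
  cases <- s$samples[s$samples$status == "case", ]
  expect_error(variant_qc(s$genotypes[cases$sample_id, ], cases, s$variants),
               "no controls")
})

test_that("pi-hat: duplicate pair near 1, unrelated near 0, half-shared pair
           matches the counting oracle", {
  set.seed(31)
  m <- 2000
  p <- runif(m, 0.1, 0.5)
  h <- function() rbinom(m, 1, p)
  a1 <- h(); a2 <- h(); b1 <- h(); b2 <- h()
  G <- rbind(A = a1 + a2, B = b1 + b2, A_dup = a1 + a2, C = a1 + h())
  colnames(G) <- paste0("v", 1:m)
  expect_gte(estimate_pihat(G, "A", "A_dup", freqs = p), 0.95)
  expect_lt(estimate_pihat(G, "A", "B", freqs = p), 0.15)
  # C shares exactly one haplotype with A at every locus
  expect_equal(estimate_pihat(G, "A", "C", freqs = p),
               pihat_oracle(G["A", ], G["C", ], p), tolerance = 1e-12)
  expect_lt(abs(estimate_pihat(G, "A", "C", freqs = p) - 0.5), 0.15)
})

test_that("pi-hat of a duplicated sample converges towards 1 with SNP count", {
  set.seed(33)
  devs <- vapply(c(500, 2000, 10000), function(m) {
    p <- runif(m, 0.1, 0.5)
    g <- rbinom(m, 1, p) + rbinom(m, 1, p)
    G <- rbind(A = g, B = g)
    colnames(G) <- paste0("v", 1:m)
    abs(1 - estimate_pihat(G, "A", "B", freqs = p))
  }, numeric(1))
  expect_true(all(diff(devs) <= 0))
  expect_lt(devs[3], 0.02)
})

test_that("pi-hat refuses insufficient overlap, and the pairwise matrix agrees
           with the per-pair estimator", {
  set.seed(35)
  G <- matrix(rbinom(50 * 400, 2, 0.3), 50, 400,
              dimnames = list(sprintf("S%02d", 1:50), sprintf("v%03d", 1:400)))
  G2 <- G; G2[1, 1:350] <- NA
  expect_error(estimate_pihat(G2, 1, 2), "insufficient")
  ph <- pathperm:::pihat_matrix(G)
  f <- colMeans(G) / 2
  expect_equal(ph["S01", "S07"],
               estimate_pihat(G, "S01", "S07", freqs = f), tolerance = 1e-10)
  G[3, c(5, 50, 200)] <- NA # missing entries engage the indicator path
  ph2 <- pathperm:::pihat_matrix(G)
  f2 <- colMeans(G, na.rm = TRUE) / 2
  # S05/S11 are complete, so the matrix path and the per-pair estimator see
  # identical data (pairs touching the NAs differ slightly: the matrix path
  # averages expectations over all loci)
  expect_equal(ph2["S05", "S11"],
               estimate_pihat(G, "S05", "S11", freqs = f2), tolerance = 1e-10)
})

test_that("sample QC: clean cohort keeps everyone; designed failures are
           removed for the right reasons", {
  # enough variants that pi-hat noise sits well clear of the 0.1875 cutoff
  s <- simulate_study(sim_config(n_controls = 60, n_cases_mli_la = 30,
                                 n_cases_ili = 30, n_genes = 1000,
                                 pathway_size = 10, missing_rate = 0,
                                 seed = 44))
  clean <- sample_qc(s$genotypes)
  expect_identical(clean$keep, rownames(s$genotypes))
  expect_true(all(clean$report$removed_reason == "none"))

  G <- s$genotypes
  G["S00005", sample(ncol(G), round(0.1 * ncol(G)))] <- NA  # 10% missing
  G <- rbind(G, S99999 = G["S00010", ])                     # duplicate pair
  res <- sample_qc(G)
  expect_identical(
    res$report$sample_id[res$report$removed_reason == "missingness"],
    "S00005")
  rel <- res$report$sample_id[res$report$removed_reason == "relatedness"]
  expect_length(rel, 1)
  expect_true(rel %in% c("S00010", "S99999"))
  expect_identical(rel, "S99999") # tie on missingness: later id removed
})

test_that("LD pruning keeps one of an identical pair, all of an independent
           set, and follows the greedy window rule on a known fixture", {
  set.seed(51)
  n <- 300
  x <- rbinom(n, 2, 0.4)
  G <- cbind(v1 = x, v2 = x, v3 = rbinom(n, 2, 0.4))
  variants <- data.frame(variant_id = c("v1", "v2", "v3"), chrom = "chr1",
                         pos = c(100L, 200L, 300L))
  expect_identical(ld_prune(G, variants, r2_max = 0.5), c("v1", "v3"))

  G_ind <- sapply(1:8, function(i) rbinom(n, 2, 0.4))
  colnames(G_ind) <- paste0("v", 1:8)
  v_ind <- data.frame(variant_id = paste0("v", 1:8), chrom = "chr1",
                      pos = (1:8) * 100L)
  expect_identical(ld_prune(G_ind, v_ind, r2_max = 0.2), paste0("v", 1:8))

  # 5-SNP fixture: a=b, c=d highly correlated, e independent; expected
  # greedy outcome (keep earlier of each correlated pair) computed by hand
  a <- rbinom(n, 2, 0.5)
  c_ <- rbinom(n, 2, 0.5)
  G5 <- cbind(s1 = a, s2 = a, s3 = c_,
              s4 = ifelse(runif(n) < 0.95, c_, rbinom(n, 2, 0.5)),
              s5 = rbinom(n, 2, 0.5))
  v5 <- data.frame(variant_id = paste0("s", 1:5), chrom = "chr1",
                   pos = (1:5) * 50L)
  expect_identical(ld_prune(G5, v5, r2_max = 0.5), c("s1", "s3", "s5"))
  # exclusion intervals are honoured
  expect_identical(
    ld_prune(G5, v5, r2_max = 0.5,
             exclude = data.frame(chrom = "chr1", start = 40L, end = 60L)),
    c("s2", "s3", "s5")) # s1 dropped by interval, s2 then survives
})

test_that("iterative PC outlier removal drops exactly a planted divergent
           subgroup and matches an independent eigendecomposition", {
  set.seed(61)
  n_main <- 295; n_out <- 5; m <- 400
  p_main <- runif(m, 0.2, 0.5)
  # strongly shifted allele frequencies for the outlier group
  p_out <- plogis(qlogis(p_main) + rnorm(m, 0, 2.5))
  G <- rbind(matrix(rbinom(n_main * m, 2, rep(p_main, each = n_main)),
                    n_main, m, byrow = FALSE),
             matrix(rbinom(n_out * m, 2, rep(p_out, each = n_out)),
                    n_out, m, byrow = FALSE))
  G <- matrix(as.integer(G), nrow(G), ncol(G))
  rownames(G) <- sprintf("S%03d", seq_len(n_main + n_out))
  colnames(G) <- sprintf("v%03d", seq_len(m))
  res <- pc_outlier_removal(G, sd_cutoff = 6)
  expect_setequal(res$removed$sample_id, sprintf("S%03d", 296:300))
  expect_length(res$keep, n_main)

  # oracle: one smartpca-style round via prcomp on the standardized matrix
  X <- pathperm:::standardize_genotypes(G)
  pc <- prcomp(X, center = FALSE, scale. = FALSE)$x[, 1:2]
  out_oracle <- rownames(G)[abs(pc[, 1] - mean(pc[, 1])) > 6 * sd(pc[, 1]) |
                            abs(pc[, 2] - mean(pc[, 2])) > 6 * sd(pc[, 2])]
  expect_setequal(res$removed$sample_id[res$removed$iteration == 1],
                  out_oracle)

  # homogeneous cohort: early stop, nobody removed
  res0 <- pc_outlier_removal(G[1:n_main, ], sd_cutoff = 6)
  expect_length(res0$keep, n_main)
  expect_identical(nrow(res0$removed), 0L)
  # determinism up to component sign
  res1 <- pc_outlier_removal(G, sd_cutoff = 6)
  expect_identical(res$keep, res1$keep)
  expect_true(all(abs(abs(res$pcs) - abs(res1$pcs)) < 1e-12))
  expect_error(pc_outlier_removal(G[1:2, ]), "n_pcs")
})

test_that("exact HWE agrees with the enumeration oracle across a randomized
           sweep of count triples (n <= 200)", {
  set.seed(71)
  for (i in 1:150) {
    n <- sample(3:200, 1)
    n_ab <- sample(0:n, 1)
    n_aa <- sample(0:(n - n_ab), 1)
    n_bb <- n - n_ab - n_aa
    expect_equal(hwe_exact_test(n_aa, n_ab, n_bb),
                 hwe_oracle(n_aa, n_ab, n_bb), tolerance = 1e-12)
  }
})
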