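#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided Levene-Haldane exact test: conditioning on the observed allele
#' counts, the p-value is the sum of the probabilities of all heterozygote
#' counts whose probability does not exceed that of the observed count.
#' Probabilities are computed by the standard mid-outwards recurrence
#' (as in PLINK's SNPHWE), which is numerically stable for large samples.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return the exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0))
    stop("genotype counts must be non-negative", call. = FALSE)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  n_rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_rare == 0) return(1) # monomorphic: a single configuration
  hets <- seq.int(n_rare %% 2, n_rare, by = 2)
  T_ <- length(hets)
  probs <- numeric(T_)
  # start at the mode and apply the ratio recurrence in both directions:
  # P(h+2)/P(h) = 4 * n_rr(h) * n_cc(h) / ((h+2) * (h+1))
  # with n_rr = (n_rare - h)/2 rare homozygotes, n_cc = n - h - n_rr.
  mid_target <- n_rare * (2 * n - n_rare) / (2 * n - 1)
  k <- which.min(abs(hets - mid_target))
  probs[k] <- 1
  n_rr <- (n_rare - hets) / 2
  n_cc <- n - hets - n_rr
  if (k < T_) {
    up <- k:(T_ - 1L)
    probs[(k + 1L):T_] <-
      cumprod(4 * n_rr[up] * n_cc[up] / ((hets[up] + 2) * (hets[up] + 1)))
  }
  if (k > 1) {
    dn <- k:2L
    probs[(k - 1L):1L] <-
      cumprod(hets[dn] * (hets[dn] - 1) / (4 * (n_rr[dn] + 1) * (n_cc[dn] + 1)))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs))
    stop("heterozygote count inconsistent with allele-count parity",
         call. = FALSE)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# Two-sided exact test on a 2x2 table (Fisher), by direct enumeration of the
# conditional hypergeometric distribution. Used for differential missingness,
# where cell counts are routinely tiny.
exact_2x2_test <- function(a, b, c_, d) {
  m <- a + c_; n_ <- b + d; k <- a + b
  if (m == 0 || n_ == 0 || k == 0 || (c_ + d) == 0) return(1)
  x <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(x, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Per-variant quality control
#'
#' Applies the standard exclusion filters: minor allele frequency < `maf_min`,
#' genotype missingness > `miss_max`, exact Hardy-Weinberg p in controls
#' < `hwe_p_min`, strand-ambiguous allele pair (A/T or C/G), and differential
#' missingness by case/control status at `diffmiss_p_min` (two-sided exact
#' 2x2 test). A variant is excluded if any enabled filter fails. MAF is
#' computed on non-missing calls across all samples.
#'
#' @param genotypes samples x variants dosage matrix.
#' @param samples sample table with `sample_id` and `status`; required when
#'   the HWE-in-controls or differential-missingness filter is enabled.
#' @param variants variant table with `variant_id`, `ref`, `alt`.
#' @param thresholds named list overriding any of `maf` (0.01), `miss` (0.03),
#'   `hwe_p` (1e-6), `diffmiss_p` (0.05); set an entry to `NA` to disable
#'   that filter.
#' @return list with `variants` (the table plus per-filter verdict columns and
#'   a `pass` flag) and `genotypes` (matrix restricted to passing variants).
#' @export
variant_qc <- function(genotypes, samples = NULL, variants,
                       thresholds = list()) {
  th <- utils::modifyList(list(maf = 0.01, miss = 0.03, hwe_p = 1e-6,
                               diffmiss_p = 0.05), thresholds)
  stopifnot(identical(colnames(genotypes), variants$variant_id))
  need_status <- !is.na(th$hwe_p) || !is.na(th$diffmiss_p)
  if (need_status) {
    if (is.null(samples) || !"status" %in% names(samples))
      stop("HWE-in-controls / differential-missingness filters require a ",
           "sample table with a status column", call. = FALSE)
    controls <- samples$sample_id[samples$status == "control"]
    if (!is.na(th$hwe_p) && length(controls) == 0)
      stop("HWE-in-controls filter enabled but no controls present",
           call. = FALSE)
  }
  n <- nrow(genotypes)
  n_obs <- colSums(!is.na(genotypes))
  miss_rate <- 1 - n_obs / n
  af <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  ambiguous <- paste0(variants$ref, variants$alt) %in% c("AT", "TA", "CG", "GC")

  hwe_p <- rep(NA_real_, ncol(genotypes))
  if (!is.na(th$hwe_p)) {
    Gc <- genotypes[controls, , drop = FALSE]
    n0 <- colSums(Gc == 0L, na.rm = TRUE)
    n1 <- colSums(Gc == 1L, na.rm = TRUE)
    n2 <- colSums(Gc == 2L, na.rm = TRUE)
    hwe_p <- vapply(seq_along(n0), function(j) {
      if (n0[j] + n1[j] + n2[j] == 0) return(NA_real_)
      hwe_exact_test(n0[j], n1[j], n2[j])
    }, numeric(1))
  }
  diffmiss_p <- rep(NA_real_, ncol(genotypes))
  if (!is.na(th$diffmiss_p)) {
    is_case <- samples$status[match(rownames(genotypes), samples$sample_id)] == "case"
    miss <- is.na(genotypes)
    miss_case <- colSums(miss[is_case, , drop = FALSE])
    miss_ctrl <- colSums(miss[!is_case, , drop = FALSE])
    nc <- sum(is_case); nk <- sum(!is_case)
    diffmiss_p <- rep(1, ncol(genotypes)) # no missing calls: nothing to test
    todo <- which(miss_case + miss_ctrl > 0)
    diffmiss_p[todo] <- vapply(todo, function(j)
      exact_2x2_test(miss_case[j], nc - miss_case[j],
                     miss_ctrl[j], nk - miss_ctrl[j]), numeric(1))
  }

  fail_maf <- !is.na(th$maf) & maf < th$maf
  fail_miss <- !is.na(th$miss) & miss_rate > th$miss
  fail_hwe <- !is.na(th$hwe_p) & !is.na(hwe_p) & hwe_p < th$hwe_p
  fail_amb <- ambiguous
  fail_dm <- !is.na(th$diffmiss_p) & !is.na(diffmiss_p) & diffmiss_p < th$diffmiss_p
  pass <- !(fail_maf | fail_miss | fail_hwe | fail_amb | fail_dm)

  out <- variants
  out$maf <- maf
  out$missing_rate <- miss_rate
  out$hwe_p_controls <- hwe_p
  out$diffmiss_p <- diffmiss_p
  out$ambiguous <- ambiguous
  out$fail_maf <- fail_maf; out$fail_miss <- fail_miss
  out$fail_hwe <- fail_hwe; out$fail_ambiguous <- fail_amb
  out$fail_diffmiss <- fail_dm
  out$pass <- pass
  list(variants = out,
       genotypes = genotypes[, pass, drop = FALSE])
}

# Per-locus expected IBS-class probabilities under IBD states 0/1/2
# (method-of-moments identities, averaged over loci).
ibs_expectations <- function(p) {
  q <- 1 - p
  list(e0_ibd0 = mean(2 * p^2 * q^2),
       e1_ibd0 = mean(4 * p^3 * q + 4 * p * q^3),
       e2_ibd0 = mean(p^4 + q^4 + 4 * p^2 * q^2),
       e1_ibd1 = mean(2 * p^2 * q + 2 * p * q^2),
       e2_ibd1 = mean(p^3 + q^3 + p^2 * q + p * q^2))
}

pihat_from_ibs <- function(pr_ibs0, pr_ibs1, ex) {
  p0 <- pr_ibs0 / ex$e0_ibd0
  p1 <- (pr_ibs1 - p0 * ex$e1_ibd0) / ex$e1_ibd1
  p0 <- pmin(pmax(p0, 0), 1)
  p1 <- pmin(pmax(p1, 0), 1)
  p2 <- pmin(pmax(1 - p0 - p1, 0), 1)
  pmin(pmax(p2 + 0.5 * p1, 0), 1)
}

#' Method-of-moments IBD sharing (pi-hat) for one sample pair
#'
#' Estimates P(IBD=0/1/2) from identity-by-state sharing and allele
#' frequencies (PLINK's method-of-moments estimator) and returns
#' pi-hat = P(IBD=2) + P(IBD=1)/2, truncated to `[0, 1]`.
#'
#' @param genotypes samples x variants dosage matrix.
#' @param sample_i,sample_j sample ids or row indices.
#' @param freqs alt-allele frequencies per variant; estimated from the full
#'   matrix when omitted.
#' @param min_overlap minimum number of jointly observed variants.
#' @return pi-hat in `[0, 1]`.
#' @export
estimate_pihat <- function(genotypes, sample_i, sample_j, freqs = NULL,
                           min_overlap = 100) {
  gi <- genotypes[sample_i, ]
  gj <- genotypes[sample_j, ]
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < min_overlap)
    stop("insufficient overlapping non-missing variants (", sum(ok), " < ",
         min_overlap, ")", call. = FALSE)
  if (is.null(freqs)) freqs <- colMeans(genotypes, na.rm = TRUE) / 2
  ex <- ibs_expectations(freqs[ok])
  d <- abs(gi[ok] - gj[ok])
  pihat_from_ibs(mean(d == 2), mean(d == 1), ex)
}

# All-pairs pi-hat via matrix products; returns a symmetric matrix.
# Expectations use locus-averaged frequencies (adequate at low missingness).
# IBS1 only occurs between a het and a hom, and IBS0 only between opposite
# homs, so with complete data two products (dosage and het-indicator Gram
# matrices) recover the full IBS decomposition.
pihat_matrix <- function(genotypes, freqs = NULL) {
  if (is.null(freqs)) freqs <- colMeans(genotypes, na.rm = TRUE) / 2
  ex <- ibs_expectations(freqs)
  if (!anyNA(genotypes)) {
    G <- genotypes; storage.mode(G) <- "double"
    H <- (G == 1) * 1
    m <- ncol(G)
    sq <- rowSums(G * G)
    S <- outer(sq, sq, "+") - 2 * tcrossprod(G)      # = ibs1 + 4*ibs0
    hr <- rowSums(H)
    ibs1 <- outer(hr, hr, "+") - 2 * tcrossprod(H)
    ibs0 <- (S - ibs1) / 4
    n_ov <- matrix(m, nrow(G), nrow(G))
  } else {
    E0 <- (!is.na(genotypes) & genotypes == 0L) * 1
    E1 <- (!is.na(genotypes) & genotypes == 1L) * 1
    E2 <- (!is.na(genotypes) & genotypes == 2L) * 1
    M <- E0 + E1 + E2
    n_ov <- tcrossprod(M)
    ibs0 <- tcrossprod(E0, E2); ibs0 <- ibs0 + t(ibs0)
    ibs2 <- tcrossprod(E0) + tcrossprod(E1) + tcrossprod(E2)
    ibs1 <- n_ov - ibs0 - ibs2
  }
  ph <- pihat_from_ibs(ibs0 / pmax(n_ov, 1), ibs1 / pmax(n_ov, 1), ex)
  dimnames(ph) <- list(rownames(genotypes), rownames(genotypes))
  ph
}

#' Per-sample quality control
#'
#' Applies, in this fixed order: (1) removal of samples with genotype
#' missingness above `miss_max`; (2) removal of heterozygosity outliers,
#' defined as |z| > `het_sd` standard deviations from the mean heterozygous
#' rate of the remaining samples; (3) relatedness removal: for every pair with
#' pi-hat > `pihat_max` (worst pair first), the member with the higher
#' missingness is dropped (ties broken by removing the lexicographically later
#' id).
#'
#' @param genotypes samples x variants dosage matrix.
#' @param thresholds named list overriding `miss` (0.03), `het_sd` (3),
#'   `pihat` (0.1875); `NA` disables a step.
#' @param pihat_variants variant ids used for the pairwise pi-hat matrix; by
#'   default an evenly spaced subset of at most `max_pihat_snps` variants.
#' @param max_pihat_snps cap on the relatedness variant subset.
#' @return list with `report` (per-sample data frame: missing_rate, het_rate,
#'   het_z, removed_reason), `keep` (retained sample ids) and `pairs`
#'   (flagged related pairs with their pi-hat).
#' @export
sample_qc <- function(genotypes, thresholds = list(), pihat_variants = NULL,
                      max_pihat_snps = 4000) {
  th <- utils::modifyList(list(miss = 0.03, het_sd = 3, pihat = 0.1875),
                          thresholds)
  if (nrow(genotypes) == 0) stop("empty genotype matrix", call. = FALSE)
  ids <- rownames(genotypes)
  miss_rate <- rowMeans(is.na(genotypes))
  n_obs <- rowSums(!is.na(genotypes))
  het_rate <- rowSums(genotypes == 1L, na.rm = TRUE) / pmax(n_obs, 1)
  reason <- rep("none", length(ids))
  names(reason) <- ids

  if (!is.na(th$miss)) reason[miss_rate > th$miss] <- "missingness"
  keep <- ids[reason == "none"]

  het_z <- rep(NA_real_, length(ids)); names(het_z) <- ids
  if (!is.na(th$het_sd) && length(keep) > 1) {
    mu <- mean(het_rate[ids %in% keep])
    sdv <- stats::sd(het_rate[ids %in% keep])
    z <- if (sdv > 0) (het_rate - mu) / sdv else rep(0, length(ids))
    het_z[] <- z
    out <- ids %in% keep & abs(z) > th$het_sd
    reason[out] <- "heterozygosity"
    keep <- ids[reason == "none"]
  }

  pairs <- data.frame(sample_i = character(), sample_j = character(),
                      pihat = numeric())
  if (!is.na(th$pihat) && length(keep) > 1) {
    if (is.null(pihat_variants)) {
      m <- ncol(genotypes)
      pihat_variants <- colnames(genotypes)[
        unique(round(seq(1, m, length.out = min(m, max_pihat_snps))))]
    }
    ph <- pihat_matrix(genotypes[keep, pihat_variants, drop = FALSE])
    ph[lower.tri(ph, diag = TRUE)] <- -1
    hit <- which(ph > th$pihat, arr.ind = TRUE)
    if (nrow(hit)) {
      pairs <- data.frame(sample_i = rownames(ph)[hit[, 1]],
                          sample_j = colnames(ph)[hit[, 2]],
                          pihat = ph[hit], stringsAsFactors = FALSE)
      pairs <- pairs[order(-pairs$pihat, pairs$sample_i, pairs$sample_j), ]
      for (r in seq_len(nrow(pairs))) {
        a <- pairs$sample_i[r]; b <- pairs$sample_j[r]
        if (reason[a] != "none" || reason[b] != "none") next
        drop_id <- if (miss_rate[a] > miss_rate[b]) a
                   else if (miss_rate[b] > miss_rate[a]) b
                   else max(a, b)
        reason[drop_id] <- "relatedness"
      }
      keep <- ids[reason == "none"]
    }
  }

  list(report = data.frame(sample_id = ids, missing_rate = miss_rate,
                           het_rate = het_rate, het_z = unname(het_z),
                           removed_reason = unname(reason),
                           stringsAsFactors = FALSE),
       keep = keep, pairs = pairs)
}

#' Greedy sliding-window LD pruning
#'
#' Walks each chromosome in windows of `window_snps` variants, advancing by
#' `step`; within a window, for every pair with squared dosage correlation
#' above `r2_max` the later-position variant is removed. Variants inside
#' caller-supplied exclusion intervals (long-range LD regions) are dropped
#' first.
#'
#' @param genotypes samples x variants dosage matrix.
#' @param variants variant table (`variant_id`, `chrom`, `pos`).
#' @param window_snps,step window size and slide, in variants.
#' @param r2_max pruning threshold on r^2.
#' @param exclude optional data frame of intervals (`chrom`, `start`, `end`,
#'   1-based inclusive) removed outright.
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, variants, window_snps = 50, step = 5,
                     r2_max = 0.2, exclude = NULL) {
  stopifnot(window_snps >= step, step >= 1)
  keep_ids <- character(0)
  drop_long_range <- rep(FALSE, nrow(variants))
  if (!is.null(exclude) && nrow(exclude)) {
    for (r in seq_len(nrow(exclude)))
      drop_long_range <- drop_long_range |
        (variants$chrom == exclude$chrom[r] &
           variants$pos >= exclude$start[r] & variants$pos <= exclude$end[r])
  }
  for (ch in unique(variants$chrom)) {
    sel <- which(variants$chrom == ch & !drop_long_range)
    sel <- sel[order(variants$pos[sel])]
    if (!length(sel)) next
    ids <- variants$variant_id[sel]
    # missing entries are mean-imputed for the pruning correlations; the
    # columns are pre-standardized so window r^2 is a single crossprod
    X <- genotypes[, ids, drop = FALSE] * 1.0
    mu <- colMeans(X, na.rm = TRUE)
    if (anyNA(X)) for (j in seq_along(ids)) X[is.na(X[, j]), j] <- mu[j]
    sdv <- sqrt(col_vars(X))
    sdv[sdv == 0] <- Inf
    X <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
    denom <- nrow(X) - 1
    kept <- rep(TRUE, length(sel))
    start <- 1L
    repeat {
      end <- min(start + window_snps - 1L, length(sel))
      w <- start:end
      active <- w[kept[w]]
      if (length(active) > 1) {
        r2 <- (crossprod(X[, active, drop = FALSE]) / denom)^2
        r2[lower.tri(r2, diag = TRUE)] <- 0
        hits <- which(r2 > r2_max, arr.ind = TRUE)
        if (nrow(hits)) {
          hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
          for (h in seq_len(nrow(hits))) {
            i <- active[hits[h, 1]]; j <- active[hits[h, 2]]
            if (kept[i] && kept[j]) kept[j] <- FALSE
          }
        }
      }
      if (end == length(sel)) break
      start <- start + step
    }
    keep_ids <- c(keep_ids, ids[kept])
  }
  keep_ids
}

# EIGENSTRAT-standardized genotype matrix: centre at 2*p-hat, scale by
# sqrt(2*p*(1-p)), missing entries set to 0 (the mean after centring).
standardize_genotypes <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  sdv <- sqrt(2 * p * (1 - p))
  sdv[sdv == 0] <- Inf # monomorphic columns carry no information
  X <- sweep(G, 2, 2 * p, "-")
  X <- sweep(X, 2, sdv, "/")
  X[is.na(X)] <- 0
  X
}

#' Iterative principal-component ancestry outlier removal
#'
#' Repeats up to `n_iterations` times: compute principal components of the
#' frequency-standardized genotype matrix on the retained samples, remove any
#' sample further than `sd_cutoff` standard deviations from the mean on either
#' of the first two components, and stop early when an iteration removes
#' nobody. The components returned are recomputed on the final retained set
#' and feed the association model as covariates.
#'
#' @param genotypes samples x variants dosage matrix (typically LD-pruned).
#' @param variant_ids optional variant subset used for the PCA.
#' @param n_iterations maximum outlier-removal rounds (default 8).
#' @param sd_cutoff removal threshold in standard deviations (default 6).
#' @param n_pcs number of components to return (>= 2).
#' @return list with `keep` (retained sample ids), `pcs` (retained samples x
#'   `n_pcs` coordinate matrix), `removed` (data frame of removals with the
#'   iteration index) and `iterations` (rounds actually run).
#' @export
pc_outlier_removal <- function(genotypes, variant_ids = NULL,
                               n_iterations = 8, sd_cutoff = 6, n_pcs = 2) {
  stopifnot(n_pcs >= 2)
  if (!is.null(variant_ids))
    genotypes <- genotypes[, variant_ids, drop = FALSE]
  keep <- rownames(genotypes)
  removed <- data.frame(sample_id = character(), iteration = integer())
  pcs <- NULL
  iters <- 0L
  repeat {
    if (length(keep) < n_pcs + 1)
      stop("fewer retained samples (", length(keep), ") than n_pcs + 1",
           call. = FALSE)
    pcs <- compute_pcs(genotypes[keep, , drop = FALSE], n_pcs)
    if (iters >= n_iterations) break
    iters <- iters + 1L
    out <- rep(FALSE, length(keep))
    for (k in 1:2) {
      x <- pcs[, k]
      out <- out | abs(x - mean(x)) > sd_cutoff * stats::sd(x)
    }
    if (!any(out)) break
    removed <- rbind(removed, data.frame(sample_id = keep[out],
                                         iteration = iters))
    keep <- keep[!out]
  }
  list(keep = keep, pcs = pcs, removed = removed, iterations = iters)
}

compute_pcs <- function(G, n_pcs) {
  X <- standardize_genotypes(G)
  K <- tcrossprod(X) / ncol(X)
  eg <- eigen(K, symmetric = TRUE)
  k <- min(n_pcs, ncol(eg$vectors))
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  coords <- apply(coords, 2, canonical_sign)
  rownames(coords) <- rownames(G)
  colnames(coords) <- paste0("PC", seq_len(k))
  coords
}
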