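#' Assign SNPs to gene windows
#'
#' A gene's window is its body extended by `window_kb` kilobases on both
#' sides (1-based inclusive); every variant whose position falls inside the
#' window on the same chromosome is a member, so a variant may belong to
#' several windows. Genes with no member SNPs are excluded from the gene
#' universe and reported in the `"empty_genes"` attribute.
#'
#' @param variants variant table (`variant_id`, `chrom`, `pos`).
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @param window_kb window half-width in kb (default 50).
#' @return data frame (`gene_id`, `chrom`, `win_start`, `win_end`, `n_snps`)
#'   with a `members` list-column of variant ids ordered by position.
#' @export
map_snps_to_genes <- function(variants, genes, window_kb = 50) {
  w <- window_kb * 1000
  win_start <- pmax(genes$start - w, 1)
  win_end <- genes$end + w
  ord <- order(variants$chrom, variants$pos)
  v <- variants[ord, , drop = FALSE]
  members <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- v$chrom == genes$chrom[i] & v$pos >= win_start[i] & v$pos <= win_end[i]
    v$variant_id[hit]
  })
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    win_start = win_start, win_end = win_end,
                    n_snps = lengths(members), stringsAsFactors = FALSE)
  out$members <- members
  empty <- out$gene_id[out$n_snps == 0]
  out <- out[out$n_snps > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "empty_genes") <- empty
  out
}

#' LD correlation matrix for a set of member SNPs
#'
#' Pairwise Pearson correlation of dosages over pairwise-complete samples,
#' repaired to positive semi-definite by flooring eigenvalues at `eig_floor`
#' and rescaling to unit diagonal. Pairwise-complete estimation can produce
#' an indefinite matrix, and duplicated SNPs make it singular; both break the
#' multivariate-normal draw without the repair.
#'
#' @param genotypes samples x variants dosage matrix.
#' @param member_ids variant ids (columns of `genotypes`).
#' @param eig_floor eigenvalue floor (default 1e-8).
#' @return the repaired correlation matrix.
#' @export
ld_correlation <- function(genotypes, member_ids, eig_floor = 1e-8) {
  X <- genotypes[, member_ids, drop = FALSE]
  v <- if (anyNA(X)) apply(X, 2, stats::var, na.rm = TRUE) else col_vars(X)
  if (any(!is.finite(v) | v == 0))
    stop("zero-variance member variant(s): ",
         paste(member_ids[!is.finite(v) | v == 0], collapse = ", "),
         call. = FALSE)
  if (length(member_ids) == 1L)
    return(matrix(1, 1, 1, dimnames = list(member_ids, member_ids)))
  C <- if (anyNA(X)) stats::cor(X, use = "pairwise.complete.obs")
       else stats::cor(X)
  # a successful Cholesky certifies positive definiteness; only indefinite /
  # singular matrices (duplicate SNPs, pairwise-complete artefacts) pay for
  # the eigen repair
  if (inherits(tryCatch(chol(C), error = function(e) e), "error")) {
    eg <- eigen(C, symmetric = TRUE)
    vals <- pmax(eg$values, eig_floor)
    C <- eg$vectors %*% (vals * t(eg$vectors))
    C <- stats::cov2cor(C)
  }
  dimnames(C) <- list(member_ids, member_ids)
  C
}

#' Gene-level sum-of-chi-squared test with a simulated LD-aware null
#'
#' The observed gene statistic is the sum of the member SNPs' 1-df
#' chi-squared statistics. The null is simulated by drawing zero-mean
#' multivariate-normal vectors with the gene's LD correlation matrix as
#' covariance, squaring and summing; the empirical p-value is the proportion
#' of simulated sums greater than or equal to the observed sum (ties count as
#' exceedance). The simulation count escalates along `schedule` until at
#' least `min_exceed` exceedances are seen or the schedule is exhausted, so
#' small p-values keep adequate relative precision.
#'
#' @param chi2s observed per-SNP chi-squared statistics (length k).
#' @param corr k x k correlation matrix (see [ld_correlation()]).
#' @param n_sims fixed simulation count; overrides `schedule` when given.
#' @param seed RNG seed; each escalation stage uses a seed derived from it.
#' @param schedule escalating simulation counts (default 1e3, 1e4, 1e5).
#' @param min_exceed escalation stops once this many exceedances are seen.
#' @param plus_one if `TRUE`, report the (r+1)/(n+1) empirical p instead of
#'   the plain proportion.
#' @return list (`n_snps`, `observed_sum`, `n_sims`, `n_exceed`,
#'   `p_empirical`).
#' @export
vegas_gene_test <- function(chi2s, corr, n_sims = NULL, seed = 1,
                            schedule = c(1e3, 1e4, 1e5), min_exceed = 10,
                            plus_one = FALSE) {
  k <- length(chi2s)
  stopifnot(k == nrow(corr), k == ncol(corr))
  if (!is.null(n_sims)) {
    stopifnot(n_sims >= 100)
    schedule <- n_sims
  }
  ch <- tryCatch(chol(corr), error = function(e) NULL)
  A <- if (!is.null(ch)) t(ch) else {
    eg <- eigen(corr, symmetric = TRUE)
    if (min(eg$values) < -1e-6)
      stop("correlation matrix is not positive semi-definite after repair",
           call. = FALSE)
    eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), k)
  }
  observed <- sum(chi2s)
  n_exceed <- 0L; used <- 0L
  for (s in seq_along(schedule)) {
    n <- as.integer(schedule[s])
    set.seed(derive_seed(seed, paste0("vegas-stage-", s)))
    sums <- mvn_chi2_sums(A, k, n)
    n_exceed <- sum(sums >= observed)
    used <- n
    if (n_exceed >= min_exceed) break
  }
  p <- if (plus_one) (n_exceed + 1) / (used + 1) else n_exceed / used
  list(n_snps = k, observed_sum = observed, n_sims = used,
       n_exceed = as.integer(n_exceed), p_empirical = p)
}

# n simulated sums of squared correlated normals; A is a square root of the
# covariance (cov = A A'). Chunked to bound memory for large n * k.
mvn_chi2_sums <- function(A, k, n, chunk = 262144L %/% max(k, 1L)) {
  chunk <- max(chunk, 1L)
  out <- numeric(n)
  done <- 0L
  while (done < n) {
    nb <- min(chunk, n - done)
    Z <- matrix(stats::rnorm(nb * k), nb, k) %*% t(A)
    out[done + seq_len(nb)] <- rowSums(Z * Z)
    done <- done + nb
  }
  out
}

#' Gene-level scan over all gene windows
#'
#' Computes one gene result per gene with at least one testable member SNP:
#' members missing from the association table (untestable SNPs) are dropped
#' with a log attribute, members are put in canonical position order, the LD
#' matrix is estimated from the supplied genotypes, and the simulated-null
#' gene test is run with a per-gene seed derived from `seed` and the gene id.
#' The resulting table defines the gene universe for enrichment testing.
#'
#' @param assoc association table from [genome_scan()].
#' @param windows gene windows from [map_snps_to_genes()].
#' @param genotypes samples x variants dosage matrix used for LD estimation
#'   (the full post-QC sample of the analyzed stratum).
#' @param seed master seed for the gene simulations.
#' @param schedule,min_exceed,plus_one passed to [vegas_gene_test()].
#' @param corr_cache optional environment memoising LD matrices across
#'   repeated scans of the same genotypes (keyed by the member-id set).
#' @return data frame (`gene_id`, `chrom`, `start`, `end`, `n_snps`,
#'   `observed_sum`, `n_sims`, `n_exceed`, `p_empirical`); genes losing all
#'   members are listed in the `"dropped_genes"` attribute.
#' @export
gene_scan <- function(assoc, windows, genotypes, seed = 1,
                      schedule = c(1e3, 1e4, 1e5), min_exceed = 10,
                      plus_one = FALSE, corr_cache = NULL) {
  chi2 <- assoc$chi2
  names(chi2) <- assoc$variant_id
  pos <- assoc$pos
  names(pos) <- assoc$variant_id
  ord <- order(windows$chrom, windows$start, windows$gene_id)
  windows <- windows[ord, , drop = FALSE]
  ng <- nrow(windows)
  n_snps <- n_sims <- n_exceed <- rep(NA_integer_, ng)
  observed_sum <- p_emp <- rep(NA_real_, ng)
  dropped <- character(0)
  for (i in seq_len(ng)) {
    mem <- windows$members[[i]]
    mem <- mem[mem %in% names(chi2)]
    # canonical member order: position when known, variant id otherwise, so
    # the simulation stream does not depend on input ordering
    mem <- if (anyNA(pos[mem])) mem[order(mem)] else
      mem[order(pos[mem], mem)]
    if (!length(mem)) {
      dropped <- c(dropped, windows$gene_id[i])
      next
    }
    corr <- if (!is.null(corr_cache)) {
      key <- paste(mem, collapse = ",")
      corr_cache[[key]] %||% (corr_cache[[key]] <- ld_correlation(genotypes, mem))
    } else ld_correlation(genotypes, mem)
    gt <- vegas_gene_test(chi2[mem], corr,
                          seed = derive_seed(seed, windows$gene_id[i]),
                          schedule = schedule, min_exceed = min_exceed,
                          plus_one = plus_one)
    n_snps[i] <- gt$n_snps; observed_sum[i] <- gt$observed_sum
    n_sims[i] <- gt$n_sims; n_exceed[i] <- gt$n_exceed
    p_emp[i] <- gt$p_empirical
  }
  keep <- !is.na(n_snps)
  if (!any(keep))
    stop("empty gene universe: no gene has a testable member SNP",
         call. = FALSE)
  out <- data.frame(gene_id = windows$gene_id[keep],
                    chrom = windows$chrom[keep],
                    start = windows$start[keep], end = windows$end[keep],
                    n_snps = n_snps[keep], observed_sum = observed_sum[keep],
                    n_sims = n_sims[keep], n_exceed = n_exceed[keep],
                    p_empirical = p_emp[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped_genes") <- dropped
  out
}
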