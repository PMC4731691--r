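#' Logistic score test for a single SNP
#'
#' Rao's score test of the additive dosage term in a logistic model, with the
#' covariates fitted under the null (no per-SNP alternative fit). With an
#' intercept-only null this reduces exactly to the Cochran-Armitage trend
#' test. Samples with missing dosage are dropped for the SNP.
#'
#' @param dosage numeric vector of dosages in {0, 1, 2, NA}.
#' @param status case/control status: logical, 0/1, or "case"/"control".
#' @param covariates optional numeric matrix of covariates (no intercept
#'   column; one is added).
#' @return a list (`n_used`, `chi2`, `p`, `direction`, `testable`). An
#'   untestable SNP (monomorphic after missing-data drop, or fewer than two
#'   cases or two controls observed) has `testable = FALSE` and `NA`
#'   statistics.
#' @export
score_test <- function(dosage, status, covariates = NULL) {
  y <- to_binary_status(status)
  ok <- !is.na(dosage) & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  g <- dosage[ok]; yy <- y[ok]
  X <- cbind(`(Intercept)` = rep(1, length(g)), if (!is.null(covariates))
    covariates[ok, , drop = FALSE])
  rec <- score_test_fitted(g, yy, X, null_fit = NULL)
  rec
}

to_binary_status <- function(status) {
  if (is.character(status) || is.factor(status)) {
    s <- as.character(status)
    bad <- !s %in% c("case", "control")
    if (any(bad)) stop("status must be 'case' or 'control'", call. = FALSE)
    as.integer(s == "case")
  } else as.integer(status)
}

# Newton-Raphson logistic null fit, optionally warm-started; returns the
# quantities the score statistic needs. Warm starting from the full-sample
# coefficients makes the per-SNP refits (missing-dosage subsets) cheap.
logistic_null_fit <- function(X, y, beta0 = NULL, tol = 1e-10, max_iter = 50) {
  beta <- beta0 %||% rep(0, ncol(X))
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    W <- mu * (1 - mu)
    XtWX <- crossprod(X, X * W)
    delta <- tryCatch(solve(XtWX, crossprod(X, y - mu)),
                      error = function(e) NULL)
    if (is.null(delta)) return(NULL)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  mu <- stats::plogis(drop(X %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  W <- mu * (1 - mu)
  XtWX_inv <- tryCatch(solve(crossprod(X, X * W)), error = function(e) NULL)
  if (is.null(XtWX_inv)) return(NULL)
  list(mu = mu, W = W, XtWX_inv = XtWX_inv, beta = beta)
}

# Core score statistic given observed data and (optionally) a pre-fitted null.
# null_fit: list(mu, W, XtWX_inv) matching X row-for-row.
score_test_fitted <- function(g, y, X, null_fit = NULL, beta0 = NULL) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2 || length(unique(g)) < 2)
    return(list(n_used = length(g), chi2 = NA_real_, p = NA_real_,
                direction = NA_integer_, testable = FALSE))
  if (is.null(null_fit)) {
    null_fit <- logistic_null_fit(X, y, beta0 = beta0)
    if (is.null(null_fit))
      return(list(n_used = length(g), chi2 = NA_real_, p = NA_real_,
                  direction = NA_integer_, testable = FALSE))
  }
  mu <- null_fit$mu; W <- null_fit$W
  U <- sum(g * (y - mu))
  gW <- g * W
  Vgg <- sum(gW * g)
  VgX <- crossprod(X, gW) # p x 1
  V <- Vgg - drop(crossprod(VgX, null_fit$XtWX_inv %*% VgX))
  if (!is.finite(V) || V <= 0)
    return(list(n_used = length(g), chi2 = NA_real_, p = NA_real_,
                direction = NA_integer_, testable = FALSE))
  chi2 <- U^2 / V
  list(n_used = length(g), chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       direction = sign(U), testable = TRUE)
}

#' Per-SNP association scan for one phenotype contrast
#'
#' Runs the logistic score test for every variant on the selected cases plus
#' all controls, with the first `n_pcs` principal components as covariates.
#' Variants that become monomorphic in the analysis subset (or retain fewer
#' than two cases or controls) are untestable and reported separately.
#'
#' @param genotypes samples x variants dosage matrix (post-QC).
#' @param samples sample table (`sample_id`, `status`, `stratum`).
#' @param pcs principal-component coordinate matrix with sample ids as
#'   rownames (from [pc_outlier_removal()]); may be `NULL` for no covariates.
#' @param stratum one of `"all"` (every case), `"MLI_LA"` or `"ILI"`.
#' @param variants optional variant table supplying `chrom`/`pos` columns for
#'   the output.
#' @param n_pcs number of leading components used as covariates (default 2).
#' @return data frame (`variant_id`, `chrom`, `pos`, `n_used`, `chi2`, `p`,
#'   `direction`) for testable variants, with untestable variant ids in the
#'   `"untestable"` attribute.
#' @export
genome_scan <- function(genotypes, samples, pcs = NULL,
                        stratum = c("all", "MLI_LA", "ILI"),
                        variants = NULL, n_pcs = 2) {
  stratum <- match.arg(stratum)
  sel_cases <- if (stratum == "all") samples$sample_id[samples$status == "case"]
               else samples$sample_id[samples$stratum == stratum]
  controls <- samples$sample_id[samples$status == "control"]
  if (length(sel_cases) == 0)
    stop("empty case stratum: ", stratum, call. = FALSE)
  if (length(controls) == 0)
    stop("no controls available for association", call. = FALSE)
  ids <- c(sel_cases, controls)
  ids <- ids[ids %in% rownames(genotypes)]
  if (!is.null(pcs)) ids <- ids[ids %in% rownames(pcs)]
  G <- genotypes[ids, , drop = FALSE]
  y <- as.integer(ids %in% sel_cases)
  X <- cbind(`(Intercept)` = rep(1, length(ids)),
             if (!is.null(pcs)) pcs[ids, seq_len(n_pcs), drop = FALSE])

  # shared null fit for complete-dosage variants; per-missingness-pattern
  # refit otherwise, warm-started from the full-sample coefficients
  full_fit <- logistic_null_fit(X, y)
  if (is.null(full_fit))
    stop("null model fit failed (collinear covariates?)", call. = FALSE)

  m <- ncol(G)
  complete <- colSums(is.na(G)) == 0L
  n_used <- chi2 <- pval <- direction <- rep(NA_real_, m)
  testable <- rep(FALSE, m)

  if (any(complete)) {
    # all complete-dosage variants share the null fit; score statistics in
    # a handful of matrix operations
    Gc <- G[, complete, drop = FALSE]
    storage.mode(Gc) <- "double"
    mono <- col_vars(Gc) == 0
    mu <- full_fit$mu; W <- full_fit$W
    U <- drop(crossprod(Gc, y - mu))
    Vgg <- drop(crossprod(Gc * Gc, W))
    VgX <- crossprod(Gc, X * W) # m x p
    V <- Vgg - rowSums((VgX %*% full_fit$XtWX_inv) * VgX)
    ok <- !mono & is.finite(V) & V > 0 & sum(y) >= 2 & sum(1 - y) >= 2
    idx <- which(complete)
    n_used[idx] <- length(y)
    chi2[idx][ok] <- (U^2 / V)[ok]
    pval[idx][ok] <- stats::pchisq(chi2[idx][ok], 1, lower.tail = FALSE)
    direction[idx][ok] <- sign(U)[ok]
    testable[idx] <- ok
  }
  for (j in which(!complete)) {
    gj <- G[, j]
    obs <- !is.na(gj)
    r <- score_test_fitted(gj[obs], y[obs], X[obs, , drop = FALSE],
                           beta0 = full_fit$beta)
    n_used[j] <- r$n_used; chi2[j] <- r$chi2; pval[j] <- r$p
    direction[j] <- r$direction; testable[j] <- r$testable
  }
  out <- data.frame(variant_id = colnames(G),
                    chrom = if (!is.null(variants))
                      variants$chrom[match(colnames(G), variants$variant_id)]
                    else NA_character_,
                    pos = if (!is.null(variants))
                      variants$pos[match(colnames(G), variants$variant_id)]
                    else NA_integer_,
                    n_used = n_used,
                    chi2 = chi2,
                    p = pval,
                    direction = direction,
                    stringsAsFactors = FALSE)
  untestable <- out$variant_id[!testable]
  out <- out[testable, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "untestable") <- untestable
  attr(out, "stratum") <- stratum
  attr(out, "n_cases") <- sum(y == 1)
  attr(out, "n_controls") <- sum(y == 0)
  out
}

# column variances without an apply() loop
col_vars <- function(X) {
  n <- nrow(X)
  (colSums(X * X) - n * colMeans(X)^2) / (n - 1)
}

#' Genomic inflation factor
#'
#' Median observed 1-df chi-squared statistic divided by the null median
#' (`qchisq(0.5, 1)` = 0.4549); approximately 1 for a well-calibrated scan.
#'
#' @param chi2 vector of 1-df chi-squared statistics.
#' @return lambda.
#' @export
genomic_inflation <- function(chi2) {
  stats::median(chi2, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
}
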