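#' Configuration for a synthetic case/control cohort
#'
#' Defines the study conditions for the synthetic-data generator: cohort sizes
#' for the two radiologic case strata (multiple lacunar infarcts / leukoaraiosis
#' and isolated lacunar infarct) plus shared controls, the gene-centric genome
#' layout, the LD model, and the planted pathway effect.
#'
#' Genotypes are generated gene block by gene block from a latent AR(1)
#' Gaussian copula: each haplotype is a correlated Gaussian vector (correlation
#' `ld_rho` between adjacent SNPs, independence across genes) thresholded at
#' the allele-frequency quantile, and dosage is the sum of two independent
#' haplotypes, so sites are in Hardy-Weinberg equilibrium by construction.
#' Population structure, when requested, follows the Balding-Nichols model
#' with fixation index `structure_shift` between two subpopulations.
#'
#' @param n_controls,n_cases_mli_la,n_cases_ili,n_cases_unclassified cohort
#'   sizes; `mli_la` is the stratum that carries the planted genetic effect,
#'   `ili` never does. Unclassified cases enter only the all-cases contrast.
#' @param n_genes number of genes tiled on synthetic autosomes (1,000 genes
#'   per chromosome).
#' @param snps_per_gene SNPs per gene; a scalar or a `c(min, max)` range.
#' @param gene_span_bp,intergene_gap_bp gene body length and gap between
#'   consecutive genes, in bp. The default 100 kb gap keeps gene windows
#'   disjoint, as for typical human genes; shrink the gap below twice the
#'   analysis window to exercise SNP sharing between neighbouring windows.
#' @param ld_rho latent AR(1) correlation between adjacent SNPs within a gene,
#'   in `[0, 1)`.
#' @param maf_range minor-allele-frequency interval within `(0, 0.5]`.
#' @param pathway_size number of genes in the focal pathway gene set.
#' @param n_causal_genes number of pathway genes carrying causal SNPs
#'   (`<= pathway_size`); 0 gives a null study.
#' @param causal_snps_per_gene causal SNPs planted per causal gene.
#' @param causal_or per-alt-allele odds ratio (>= 1) applied when sampling
#'   MLI/LA cases.
#' @param baseline_prevalence disease probability for a subject carrying no
#'   risk alleles' worth of liability, used to solve the logistic intercept.
#' @param missing_rate per-genotype missingness probability (completely at
#'   random), in `[0, 1)`.
#' @param structure_shift Balding-Nichols fixation index between the two
#'   subpopulations; 0 disables structure.
#' @param ambiguous_frac fraction of variants written as strand-ambiguous
#'   (A/T or C/G) allele pairs, to exercise the corresponding QC filter.
#' @param seed integer master seed for the generator.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_controls = 400,
                       n_cases_mli_la = 200,
                       n_cases_ili = 200,
                       n_cases_unclassified = 0,
                       n_genes = 800,
                       snps_per_gene = 4,
                       gene_span_bp = 20000,
                       intergene_gap_bp = 100000,
                       ld_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       pathway_size = 80,
                       n_causal_genes = 0,
                       causal_snps_per_gene = 2,
                       causal_or = 1,
                       baseline_prevalence = 0.1,
                       missing_rate = 0.01,
                       structure_shift = 0,
                       ambiguous_frac = 0.05,
                       seed = 1) {
  cfg <- list(n_controls = n_controls, n_cases_mli_la = n_cases_mli_la,
              n_cases_ili = n_cases_ili,
              n_cases_unclassified = n_cases_unclassified,
              n_genes = n_genes, snps_per_gene = snps_per_gene,
              gene_span_bp = gene_span_bp, intergene_gap_bp = intergene_gap_bp,
              ld_rho = ld_rho, maf_range = maf_range,
              pathway_size = pathway_size, n_causal_genes = n_causal_genes,
              causal_snps_per_gene = causal_snps_per_gene,
              causal_or = causal_or,
              baseline_prevalence = baseline_prevalence,
              missing_rate = missing_rate, structure_shift = structure_shift,
              ambiguous_frac = ambiguous_frac, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  counts <- c(cfg$n_controls, cfg$n_cases_mli_la, cfg$n_cases_ili)
  stop_if(any(counts <= 0), "degenerate config: sample counts must be positive")
  stop_if(cfg$n_cases_unclassified < 0, "n_cases_unclassified must be >= 0")
  stop_if(cfg$n_genes <= 0, "degenerate config: n_genes must be positive")
  stop_if(any(cfg$snps_per_gene < 1), "snps_per_gene must be >= 1")
  stop_if(!(length(cfg$snps_per_gene) %in% 1:2), "snps_per_gene must be a scalar or c(min, max)")
  stop_if(cfg$ld_rho < 0 || cfg$ld_rho >= 1, "ld_rho must lie in [0, 1)")
  stop_if(length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
            cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2],
          "maf_range must be an interval within (0, 0.5]")
  stop_if(cfg$pathway_size > cfg$n_genes,
          "pathway_size must not exceed n_genes")
  stop_if(cfg$n_causal_genes > cfg$pathway_size,
          "n_causal_genes must not exceed pathway_size")
  stop_if(cfg$causal_or < 1, "causal_or must be >= 1")
  stop_if(cfg$baseline_prevalence <= 0 || cfg$baseline_prevalence >= 1,
          "baseline_prevalence must lie in (0, 1)")
  stop_if(cfg$missing_rate < 0 || cfg$missing_rate >= 1,
          "missing_rate must lie in [0, 1)")
  stop_if(cfg$structure_shift < 0 || cfg$structure_shift >= 1,
          "structure_shift must lie in [0, 1)")
  stop_if(cfg$gene_span_bp < 1 || cfg$intergene_gap_bp < 0,
          "gene layout lengths must be positive")
  invisible(cfg)
}

# Deterministic variant-level layout: gene coordinates, per-SNP positions,
# allele frequencies (including Balding-Nichols subpopulation frequencies) and
# ref/alt allele pairs. All variant-level randomness is isolated on its own
# derived seed so that sample batches of any size share one layout.
variant_layout <- function(config) {
  set.seed(derive_seed(config$seed, "variant-layout"))
  ng <- config$n_genes
  span <- config$gene_span_bp
  gap <- config$intergene_gap_bp
  genes_per_chrom <- 1000L
  chrom_idx <- (seq_len(ng) - 1L) %/% genes_per_chrom + 1L
  within_idx <- (seq_len(ng) - 1L) %% genes_per_chrom
  g_start <- as.integer(gap + within_idx * (span + gap) + 1)
  genes <- data.frame(gene_id = sprintf("gene%05d", seq_len(ng)),
                      chrom = paste0("chr", chrom_idx),
                      start = g_start, end = as.integer(g_start + span - 1),
                      stringsAsFactors = FALSE)
  spg <- config$snps_per_gene
  n_snps_per_gene <- if (length(spg) == 1L) rep.int(as.integer(spg), ng) else
    sample(seq.int(spg[1], spg[2]), ng, replace = TRUE)
  gene_of_snp <- rep(seq_len(ng), n_snps_per_gene)
  pos <- as.integer(unlist(lapply(seq_len(ng), function(g) {
    k <- n_snps_per_gene[g]
    unique(round(seq(genes$start[g], genes$end[g], length.out = max(k, 2))))[seq_len(k)]
  }), use.names = FALSE))
  m <- length(pos)
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  f1 <- f2 <- maf
  if (config$structure_shift > 0) {
    fst <- config$structure_shift
    a <- maf * (1 - fst) / fst
    b <- (1 - maf) * (1 - fst) / fst
    f1 <- pmin(pmax(stats::rbeta(m, a, b), 1e-3), 0.999)
    f2 <- pmin(pmax(stats::rbeta(m, a, b), 1e-3), 0.999)
  }
  ambiguous <- stats::runif(m) < config$ambiguous_frac
  amb_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"), ncol = 2, byrow = TRUE)
  ok_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                       "G", "A", "C", "A", "G", "T", "C", "T"), ncol = 2, byrow = TRUE)
  pick_a <- sample.int(nrow(amb_pairs), m, replace = TRUE)
  pick_o <- sample.int(nrow(ok_pairs), m, replace = TRUE)
  ref <- ifelse(ambiguous, amb_pairs[pick_a, 1], ok_pairs[pick_o, 1])
  alt <- ifelse(ambiguous, amb_pairs[pick_a, 2], ok_pairs[pick_o, 2])
  variants <- data.frame(variant_id = sprintf("snp%06d", seq_len(m)),
                         chrom = genes$chrom[gene_of_snp],
                         pos = pos,
                         ref = ref, alt = alt,
                         gene_id = genes$gene_id[gene_of_snp],
                         maf = maf, f1 = f1, f2 = f2,
                         ambiguous = ambiguous,
                         stringsAsFactors = FALSE)
  list(genes = genes, variants = variants,
       n_snps_per_gene = n_snps_per_gene)
}

# Generate n individuals' dosages for one layout (no missingness). Returns an
# integer matrix n x m with a "subpop" attribute.
gen_dosage_batch <- function(config, layout, n, seed) {
  set.seed(seed)
  v <- layout$variants
  m <- nrow(v)
  subpop <- rep_len(1:2, n)
  hap_sub <- rep(subpop, each = 2)
  rho <- config$ld_rho
  thr_all <- stats::qnorm(rbind(v$f1, v$f2)) # 2 x m, per-subpop quantiles
  odd <- seq(1L, 2L * n, 2L)
  even <- odd + 1L
  m <- nrow(v)
  sc <- sqrt(1 - rho^2)
  lens <- layout$n_snps_per_gene
  if (length(unique(lens)) == 1L) {
    # equal-sized blocks: run the AR(1) recurrence across all genes at once,
    # one contiguous matrix per within-gene SNP index, then put columns back
    # in gene-major order
    L <- lens[1]
    ng <- length(lens)
    Zs <- vector("list", L)
    for (k in seq_len(L)) Zs[[k]] <- matrix(stats::rnorm(2L * n * ng), 2L * n, ng)
    if (L > 1L && rho > 0)
      for (k in 2:L) Zs[[k]] <- rho * Zs[[k - 1L]] + sc * Zs[[k]]
    Z <- do.call(cbind, Zs)[, as.vector(t(matrix(seq_len(m), ng, L))),
                            drop = FALSE]
    H <- Z < thr_all[hap_sub, , drop = FALSE]
    G <- H[odd, , drop = FALSE] + H[even, , drop = FALSE]
  } else {
    blocks <- vector("list", length(lens))
    col0 <- 0L
    for (g in seq_along(blocks)) {
      L <- lens[g]
      idx <- col0 + seq_len(L)
      Z <- matrix(stats::rnorm(2L * n * L), 2L * n, L)
      if (L > 1L && rho > 0)
        for (k in 2:L) Z[, k] <- rho * Z[, k - 1L] + sc * Z[, k]
      H <- Z < thr_all[hap_sub, idx, drop = FALSE]
      blocks[[g]] <- H[odd, , drop = FALSE] + H[even, , drop = FALSE]
      col0 <- col0 + L
    }
    G <- do.call(cbind, blocks)
  }
  storage.mode(G) <- "integer"
  colnames(G) <- v$variant_id
  attr(G, "subpop") <- subpop
  G
}

#' Simulate LD-blocked genotypes for a synthetic cohort
#'
#' Draws dosages for `n` individuals (by default the configured total cohort
#' size) under the latent AR(1)-threshold haplotype model, lays variants out
#' on synthetic autosomes, and applies completely-at-random missingness.
#'
#' @param config a [sim_config()].
#' @param n number of individuals; defaults to the configured cohort total.
#' @param seed overrides the seed derived from `config$seed`.
#' @return a list with `genotypes` (integer matrix, samples x variants,
#'   `NA` = missing, `"subpop"` attribute), `variants` (data frame) and
#'   `genes` (data frame, 1-based inclusive coordinates).
#' @export
simulate_genotypes <- function(config, n = NULL, seed = NULL) {
  validate_sim_config(config)
  n <- n %||% (config$n_controls + config$n_cases_mli_la +
                 config$n_cases_ili + config$n_cases_unclassified)
  if (n <= 0) stop("degenerate config: no samples requested", call. = FALSE)
  layout <- variant_layout(config)
  G <- gen_dosage_batch(config, layout, n,
                        seed %||% derive_seed(config$seed, "genotype-batch-1"))
  G <- apply_missingness(G, config$missing_rate,
                         derive_seed(seed %||% config$seed, "missingness"))
  rownames(G) <- sprintf("S%05d", seq_len(n))
  list(genotypes = G, variants = layout$variants, genes = layout$genes)
}

apply_missingness <- function(G, rate, seed) {
  if (rate <= 0) return(G)
  sp <- attr(G, "subpop")
  set.seed(seed)
  G[stats::runif(length(G)) < rate] <- NA_integer_
  attr(G, "subpop") <- sp
  G
}

# Solve the logistic intercept so that the population mean of
# plogis(alpha + score) equals the target prevalence; `score` is the genetic
# liability of a reference sample of individuals.
solve_intercept <- function(score, prevalence) {
  if (all(score == 0)) return(stats::qlogis(prevalence))
  stats::uniroot(function(a) mean(stats::plogis(a + score)) - prevalence,
                 interval = c(-40, 10), tol = 1e-10)$root
}

#' Assign case/control status and phenotype strata over a genotype pool
#'
#' Walks a pool of simulated individuals and fills the configured quotas:
#' ILI-like cases, unclassified cases and controls are population draws with no
#' genetic effect; MLI/LA-like cases are accepted by rejection sampling from a
#' logistic liability with per-alt-allele log-odds `log(causal_or)` at the
#' causal SNPs and an intercept solving the baseline prevalence. When all
#' effects are null the MLI/LA quota is filled directly (the liability is then
#' independent of genotype).
#'
#' @param genotypes pool genotype matrix (samples x variants; rownames are ids).
#' @param effects named numeric vector of per-allele log odds ratios, one
#'   entry per causal SNP (may be empty).
#' @param config the [sim_config()] holding quotas and prevalence.
#' @param seed RNG seed for the liability draws.
#' @return a data frame (`sample_id`, `status`, `stratum`, `subpop`), one row
#'   per selected pool member.
#' @export
assign_phenotypes <- function(genotypes, effects, config, seed = NULL) {
  validate_sim_config(config)
  if (length(effects) && !all(names(effects) %in% colnames(genotypes)))
    stop("effects must be named by causal variant ids present in the pool",
         call. = FALSE)
  n_pool <- nrow(genotypes)
  quotas <- c(MLI_LA = config$n_cases_mli_la, ILI = config$n_cases_ili,
              unclassified = config$n_cases_unclassified,
              control = config$n_controls)
  set.seed(seed %||% derive_seed(config$seed, "phenotypes"))
  score <- rep(0, n_pool)
  genetic <- length(effects) > 0 && any(effects != 0)
  if (genetic) {
    Gc <- genotypes[, names(effects), drop = FALSE]
    Gc[is.na(Gc)] <- 0L
    score <- as.vector(Gc %*% effects)
  }
  alpha <- solve_intercept(score, config$baseline_prevalence)
  assign <- character(n_pool)
  need <- quotas
  u <- stats::runif(n_pool)
  for (i in seq_len(n_pool)) {
    if (need["ILI"] > 0) {
      assign[i] <- "ILI"; need["ILI"] <- need["ILI"] - 1
    } else if (need["unclassified"] > 0) {
      assign[i] <- "unclassified"; need["unclassified"] <- need["unclassified"] - 1
    } else if (need["control"] > 0) {
      assign[i] <- "control"; need["control"] <- need["control"] - 1
    } else if (need["MLI_LA"] > 0) {
      if (!genetic || u[i] < stats::plogis(alpha + score[i])) {
        assign[i] <- "MLI_LA"; need["MLI_LA"] <- need["MLI_LA"] - 1
      }
    } else break
  }
  if (any(need > 0))
    stop("genotype pool exhausted before stratum quotas were met (",
         sum(need), " assignments short); supply a larger pool", call. = FALSE)
  keep <- which(assign != "")
  sp <- attr(genotypes, "subpop") %||% rep(1L, n_pool)
  data.frame(sample_id = rownames(genotypes)[keep],
             status = ifelse(assign[keep] == "control", "control", "case"),
             stratum = assign[keep],
             subpop = paste0("pop", sp[keep]),
             stringsAsFactors = FALSE)
}

make_gene_sets <- function(layout, config) {
  set.seed(derive_seed(config$seed, "gene-sets"))
  gene_ids <- layout$genes$gene_id
  pathway <- sort(sample(gene_ids, config$pathway_size))
  complexes <- paste0("complex_", c("I", "II", "III", "IV", "V"))
  split_idx <- sort(rep_len(seq_along(complexes), length(pathway)))
  subsets <- split(pathway, complexes[split_idx])
  sets <- c(list(OXPHOS_like = pathway), subsets)
  attr(sets, "parent") <- c(NA_character_,
                            rep("OXPHOS_like", length(subsets)))
  names(attr(sets, "parent")) <- names(sets)
  sets
}

pick_causal <- function(layout, gene_sets, config) {
  set.seed(derive_seed(config$seed, "causal"))
  pathway <- gene_sets[[1L]]
  causal_genes <- sort(sample(pathway, config$n_causal_genes))
  v <- layout$variants
  causal_snps <- unlist(lapply(causal_genes, function(g) {
    ids <- v$variant_id[v$gene_id == g]
    sort(sample(ids, min(config$causal_snps_per_gene, length(ids))))
  }), use.names = FALSE)
  effects <- rep(log(config$causal_or), length(causal_snps))
  names(effects) <- causal_snps
  list(causal_genes = causal_genes, causal_snps = causal_snps,
       effects = effects)
}

#' Simulate a complete synthetic case/control study
#'
#' Orchestrates the generator: builds the variant layout, gene sets and causal
#' structure, then draws genotype batches and assigns phenotypes until every
#' stratum quota is filled (rejection sampling for the MLI/LA stratum when a
#' genetic effect is planted). Missingness is applied after selection so that
#' it is independent of status.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_study`: a list with `genotypes`,
#'   `variants`, `samples`, `genes`, `gene_sets`, `truth` and `config`.
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  layout <- variant_layout(config)
  gene_sets <- make_gene_sets(layout, config)
  truth <- pick_causal(layout, gene_sets, config)
  quotas <- c(MLI_LA = config$n_cases_mli_la, ILI = config$n_cases_ili,
              unclassified = config$n_cases_unclassified,
              control = config$n_controls)
  genetic <- length(truth$effects) > 0 && any(truth$effects != 0)

  batches <- list(); samples <- NULL
  need <- quotas
  batch <- 0L
  alpha <- NULL
  id0 <- 0L
  while (any(need > 0)) {
    batch <- batch + 1L
    if (batch > 60L)
      stop("stratum quotas unreachable at the configured prevalence",
           call. = FALSE)
    n_direct <- sum(need[c("ILI", "unclassified", "control")])
    n_rej <- if (genetic) ceiling(need[["MLI_LA"]] /
                                    config$baseline_prevalence * 1.3) + 20L
             else need[["MLI_LA"]]
    n <- n_direct + n_rej
    G <- gen_dosage_batch(config, layout, n,
                          derive_seed(config$seed, paste0("genotype-batch-", batch)))
    rownames(G) <- sprintf("S%05d", id0 + seq_len(n))
    set.seed(derive_seed(config$seed, paste0("liability-", batch)))
    score <- rep(0, n)
    if (genetic) {
      Gc <- G[, names(truth$effects), drop = FALSE]
      score <- as.vector(Gc %*% truth$effects)
      if (is.null(alpha)) alpha <- solve_intercept(score, config$baseline_prevalence)
    }
    u <- stats::runif(n)
    assign <- character(n)
    for (i in seq_len(n)) {
      if (need[["ILI"]] > 0) {
        assign[i] <- "ILI"; need[["ILI"]] <- need[["ILI"]] - 1
      } else if (need[["unclassified"]] > 0) {
        assign[i] <- "unclassified"; need[["unclassified"]] <- need[["unclassified"]] - 1
      } else if (need[["control"]] > 0) {
        assign[i] <- "control"; need[["control"]] <- need[["control"]] - 1
      } else if (need[["MLI_LA"]] > 0) {
        if (!genetic || u[i] < stats::plogis(alpha + score[i])) {
          assign[i] <- "MLI_LA"; need[["MLI_LA"]] <- need[["MLI_LA"]] - 1
        }
      } else break
    }
    keep <- which(assign != "")
    sp <- attr(G, "subpop")
    batches[[batch]] <- G[keep, , drop = FALSE]
    samples <- rbind(samples, data.frame(
      sample_id = rownames(G)[keep],
      status = ifelse(assign[keep] == "control", "control", "case"),
      stratum = assign[keep],
      subpop = paste0("pop", sp[keep]),
      stringsAsFactors = FALSE))
    id0 <- id0 + n
  }
  G <- do.call(rbind, batches)
  # relabel selected samples contiguously, cases first
  ord <- order(factor(samples$stratum,
                      levels = c("MLI_LA", "ILI", "unclassified", "control")),
               samples$sample_id)
  samples <- samples[ord, , drop = FALSE]
  G <- G[samples$sample_id, , drop = FALSE]
  new_ids <- sprintf("S%05d", seq_len(nrow(G)))
  samples$sample_id <- new_ids
  rownames(G) <- new_ids
  rownames(samples) <- NULL
  G <- apply_missingness(G, config$missing_rate,
                         derive_seed(config$seed, "missingness"))
  structure(list(genotypes = G, variants = layout$variants,
                 samples = samples, genes = layout$genes,
                 gene_sets = gene_sets, truth = truth, config = config),
            class = "synthetic_study")
}

#' Inject extra missingness into cases at selected variants
#'
#' Adds case-only missingness at the given variants, producing differential
#' missingness by status. Exists to exercise the corresponding QC filter.
#'
#' @param study a `synthetic_study`.
#' @param variant_ids variants to perturb.
#' @param extra_rate additional per-genotype missing probability in cases.
#' @param seed RNG seed.
#' @return the modified study.
#' @export
inject_differential_missingness <- function(study, variant_ids, extra_rate,
                                            seed = 1) {
  stopifnot(all(variant_ids %in% colnames(study$genotypes)))
  set.seed(seed)
  cases <- study$samples$sample_id[study$samples$status == "case"]
  sub <- study$genotypes[cases, variant_ids, drop = FALSE]
  sub[stats::runif(length(sub)) < extra_rate] <- NA_integer_
  study$genotypes[cases, variant_ids] <- sub
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  tab <- table(x$samples$stratum)
  cat("synthetic case/control study\n")
  cat("  samples: ", nrow(x$genotypes), " (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  variants:", nrow(x$variants), "in", nrow(x$genes), "genes\n")
  cat("  gene sets:", paste(names(x$gene_sets), collapse = ", "), "\n")
  cat("  causal genes:", length(x$truth$causal_genes), "\n")
  invisible(x)
}
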