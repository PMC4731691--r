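#' Bonferroni per-test significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param n_tests number of tests in the family.
#' @return list with `threshold` (full precision) and `rounded` (4 decimal
#'   places, the conventional reporting precision).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 12) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  t <- alpha / n_tests
  list(threshold = t, rounded = round(t, 4))
}

default_settings <- function() {
  list(maf = 0.01, miss = 0.03, hwe_p = 1e-6, diffmiss_p = 0.05,
       het_sd = 3, pihat = 0.1875,
       prune_window = 32, prune_step = 16, prune_r2 = 0.2,
       pc_sd = 6, pc_iter = 8, n_pcs = 2,
       window_kb = 50, vegas_schedule = c(1e3, 1e4, 1e5), vegas_min_exceed = 10,
       q_values = c(1, 5, 10), n_perm = 1000, n_perm_max = 10000,
       alpha = 0.05, n_tests = 12,
       max_pihat_snps = 4000, force_subcomplex = FALSE)
}

stage <- function(name, stratum = NULL, expr) {
  tryCatch(expr, error = function(e) {
    where <- if (is.null(stratum)) name else paste0(name, " [", stratum, "]")
    stop("pipeline stage '", where, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full stratified enrichment study
#'
#' Executes the complete analysis: variant and sample QC, LD pruning,
#' iterative principal-component outlier removal, then per phenotype contrast
#' (all cases, MLI/LA, ILI, each versus the shared controls) the per-SNP
#' score-test scan, the LD-aware gene-level scan, the pathway top-percentile
#' tests at 1/5/10 percent and the GSEA running-sum test. The 3 x 4 grid of
#' enrichment p-values is compared against the Bonferroni threshold
#' `alpha / n_tests` (0.05/12 = 0.0042 by default), and subcomplex scans are
#' run as follow-up in any stratum whose top-1% test is significant (or
#' always, with `force_subcomplex`). All stochastic stages consume seeds
#' derived from the single master seed.
#'
#' @param x a `sim_config` (the study is simulated), a `synthetic_study`, or
#'   a named list of file paths (`vcf`, `samples`, `genes`, `gene_sets`) as
#'   written by [write_study()].
#' @param seed master seed for every stochastic stage.
#' @param pathway name of the focal pathway gene set (default: the first set
#'   with no parent annotation, else the largest set).
#' @param strata phenotype contrasts to run (default all three).
#' @param settings named list overriding any of the defaults in
#'   `pathperm:::default_settings()` (QC thresholds, window size, simulation
#'   schedule, permutation counts, alpha, ...).
#' @return an object of class `study_report`: list with `cells` (one row per
#'   stratum x test), `alpha_star`, `subcomplexes`, `gene_results` (per
#'   stratum), and a `provenance` block (seeds, QC counts, universe sizes).
#' @export
run_study <- function(x, seed = 1, pathway = NULL,
                      strata = c("all", "MLI_LA", "ILI"),
                      settings = list()) {
  st <- utils::modifyList(default_settings(), settings)
  strata <- match.arg(strata, c("all", "MLI_LA", "ILI"), several.ok = TRUE)

  data <- stage("input", NULL, {
    if (inherits(x, "sim_config")) simulate_study(x)
    else if (inherits(x, "synthetic_study")) x
    else if (is.list(x) && !is.null(x$vcf)) {
      d <- read_vcf_dosages(x$vcf)
      samples <- utils::read.delim(x$samples, stringsAsFactors = FALSE)
      list(genotypes = d$genotypes[samples$sample_id, , drop = FALSE],
           variants = d$variants, samples = samples,
           genes = read_bed_genes(x$genes), gene_sets = read_gmt(x$gene_sets))
    } else stop("x must be a sim_config, a synthetic_study, or a list of paths")
  })
  if (!nrow(data$samples)) stop("empty sample table", call. = FALSE)

  if (is.null(pathway)) {
    parent <- attr(data$gene_sets, "parent")
    pathway <- if (!is.null(parent) && any(is.na(parent)))
      names(data$gene_sets)[is.na(parent)][1]
    else names(data$gene_sets)[which.max(lengths(data$gene_sets))]
  }
  subcomplex_sets <- data$gene_sets[setdiff(names(data$gene_sets), pathway)]
  pathway_genes <- data$gene_sets[[pathway]]
  if (is.null(pathway_genes))
    stop("pathway gene set '", pathway, "' not found", call. = FALSE)

  vqc <- stage("variant_qc", NULL,
               variant_qc(data$genotypes, data$samples, data$variants,
                          thresholds = st[c("maf", "miss", "hwe_p", "diffmiss_p")]))
  sqc <- stage("sample_qc", NULL,
               sample_qc(vqc$genotypes,
                         thresholds = list(miss = st$miss, het_sd = st$het_sd,
                                           pihat = st$pihat),
                         max_pihat_snps = st$max_pihat_snps))
  G <- vqc$genotypes[sqc$keep, , drop = FALSE]
  variants_pass <- vqc$variants[vqc$variants$pass, , drop = FALSE]

  pruned <- stage("ld_prune", NULL,
                  ld_prune(G, variants_pass, window_snps = st$prune_window,
                           step = st$prune_step, r2_max = st$prune_r2))
  pca <- stage("pc_outlier_removal", NULL,
               pc_outlier_removal(G, variant_ids = pruned,
                                  n_iterations = st$pc_iter,
                                  sd_cutoff = st$pc_sd, n_pcs = st$n_pcs))
  G <- G[pca$keep, , drop = FALSE]
  samples <- data$samples[data$samples$sample_id %in% pca$keep, , drop = FALSE]

  windows <- stage("map_snps_to_genes", NULL,
                   map_snps_to_genes(variants_pass, data$genes,
                                     window_kb = st$window_kb))

  alpha_star <- bonferroni_threshold(st$alpha, st$n_tests)$threshold
  ld_cache <- new.env(parent = emptyenv()) # LD is shared across contrasts
  cells <- list(); gene_results <- list(); subs <- list()
  universe_n <- integer(0)
  for (s in strata) {
    assoc <- stage("genome_scan", s,
                   genome_scan(G, samples, pcs = pca$pcs, stratum = s,
                               variants = variants_pass, n_pcs = st$n_pcs))
    gr <- stage("gene_scan", s,
                gene_scan(assoc, windows, G,
                          seed = derive_seed(seed, paste0("genescan:", s)),
                          schedule = st$vegas_schedule,
                          min_exceed = st$vegas_min_exceed,
                          corr_cache = ld_cache))
    gene_results[[s]] <- gr
    universe_n[s] <- nrow(gr)
    for (q in st$q_values)
      cells[[paste(s, q)]] <- stage("percentile_enrichment", s,
        percentile_enrichment_test(gr, pathway_genes, q,
                                   n_perm_initial = st$n_perm,
                                   n_perm_escalated = st$n_perm_max,
                                   seed = derive_seed(seed, paste0("enrich:", s, ":q", q)),
                                   set_name = pathway, stratum = s))
    cells[[paste(s, "gsea")]] <- stage("gsea", s,
      gsea_test(gr, pathway_genes, n_perm_initial = st$n_perm,
                n_perm_escalated = st$n_perm_max,
                seed = derive_seed(seed, paste0("gsea:", s)),
                set_name = pathway, stratum = s))
    pct1 <- cells[[paste(s, st$q_values[1])]]
    if (length(subcomplex_sets) &&
        (st$force_subcomplex || pct1$p_empirical < alpha_star)) {
      subs[[s]] <- stage("subcomplex_scan", s,
        subcomplex_scan(gr, subcomplex_sets, q_values = st$q_values,
                        n_perm_initial = st$n_perm,
                        n_perm_escalated = st$n_perm_max,
                        seed = derive_seed(seed, paste0("subcomplex:", s)),
                        stratum = s))
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  cells$significant <- cells$p_empirical < alpha_star

  report <- list(
    cells = cells,
    alpha_star = alpha_star,
    pathway = pathway,
    subcomplexes = if (length(subs)) do.call(rbind, subs) else NULL,
    gene_results = gene_results,
    provenance = list(
      seed = seed,
      package_version = as.character(utils::packageVersion("pathperm")),
      settings = st,
      strata = strata,
      n_variants_input = nrow(data$variants),
      n_variants_pass = nrow(variants_pass),
      n_variants_pruned = length(pruned),
      n_samples_input = nrow(data$samples),
      n_samples_pass_qc = length(sqc$keep),
      n_samples_final = length(pca$keep),
      pca_iterations = pca$iterations,
      n_cases_by_stratum = table(samples$stratum[samples$status == "case"]),
      n_controls = sum(samples$status == "control"),
      universe_size = universe_n))
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Pathway enrichment study report\n")
  cat(sprintf("  pathway: %s   per-test threshold: %.4g (alpha %.3g / %d tests)\n",
              x$pathway, x$alpha_star, x$provenance$settings$alpha,
              x$provenance$settings$n_tests))
  cat(sprintf("  samples: %d -> %d after QC; variants: %d -> %d\n",
              x$provenance$n_samples_input, x$provenance$n_samples_final,
              x$provenance$n_variants_input, x$provenance$n_variants_pass))
  cells <- x$cells
  for (s in unique(cells$stratum)) {
    cat("  stratum ", s, " (universe N=", x$provenance$universe_size[[s]],
        "):\n", sep = "")
    sub <- cells[cells$stratum == s, ]
    for (r in seq_len(nrow(sub))) {
      lab <- if (sub$test[r] == "gsea")
        sprintf("gsea  ES=%.3f", sub$observed[r])
      else
        sprintf("%-5s %d/%d in top %d", sub$test[r], sub$observed[r],
                sub$k[r], sub$m[r])
      cat(sprintf("    %-24s p=%-8.4g perms=%-6d%s\n", lab,
                  sub$p_empirical[r], sub$n_perm[r],
                  if (sub$significant[r]) " *" else ""))
    }
  }
  if (!is.null(x$subcomplexes))
    cat("  subcomplex follow-up rows:", nrow(x$subcomplexes), "\n")
  invisible(x)
}

#' Write a study report to machine-readable files
#'
#' Emits `enrichment.tsv` (the 12-cell grid), `subcomplexes.tsv` when
#' present, `genes_<stratum>.tsv` per stratum, and `provenance.json`.
#'
#' @param report a `study_report`.
#' @param out_dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  utils::write.table(report$cells, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$subcomplexes))
    utils::write.table(report$subcomplexes,
                       file.path(out_dir, "subcomplexes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(report$gene_results))
    utils::write.table(report$gene_results[[s]],
                       file.path(out_dir, paste0("genes_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- report$provenance
  prov$n_cases_by_stratum <- as.list(prov$n_cases_by_stratum)
  prov$universe_size <- as.list(prov$universe_size)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
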