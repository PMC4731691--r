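#' Write a synthetic study to standard interchange formats
#'
#' Emits `genotypes.vcf` (VCF 4.2, GT-only, missing as `./.`), `samples.tsv`,
#' `genes.bed` (0-based half-open, name column = gene id), `genesets.gmt` and
#' `truth.tsv` into `out_dir`. The files round-trip losslessly through
#' [read_study()].
#'
#' @param study a `synthetic_study` (or any list with the same fields).
#' @param out_dir output directory, created if absent.
#' @return invisibly, the named vector of file paths written.
#' @export
write_study <- function(study, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             samples = file.path(out_dir, "samples.tsv"),
             genes = file.path(out_dir, "genes.bed"),
             gene_sets = file.path(out_dir, "genesets.gmt"),
             truth = file.path(out_dir, "truth.tsv"))
  write_vcf(study$genotypes, study$variants, paths["vcf"])
  utils::write.table(study$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(study$genes, paths["genes"])
  write_gmt(study$gene_sets, paths["gene_sets"])
  truth_df <- if (length(study$truth$causal_snps)) {
    data.frame(variant_id = study$truth$causal_snps,
               gene_id = study$variants$gene_id[
                 match(study$truth$causal_snps, study$variants$variant_id)],
               beta = unname(study$truth$effects[study$truth$causal_snps]))
  } else data.frame(variant_id = character(), gene_id = character(),
                    beta = numeric())
  utils::write.table(truth_df, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# GT-only VCF 4.2. Genotype matrix is samples x variants; VCF data lines are
# one per variant.
write_vcf <- function(genotypes, variants, path) {
  gt <- c("0/0", "0/1", "1/1")
  codes <- matrix("./.", nrow(genotypes), ncol(genotypes))
  obs <- !is.na(genotypes)
  codes[obs] <- gt[genotypes[obs] + 1L]
  body <- apply(codes, 2L, paste, collapse = "\t") # one string per variant
  header <- c("##fileformat=VCFv4.2",
              "##source=pathperm",
              paste0("##contig=<ID=", unique(variants$chrom), ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  lines <- paste(variants$chrom, variants$pos, variants$variant_id,
                 variants$ref, variants$alt, ".", ".", ".", "GT", body,
                 sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read genotypes from a GT-only VCF
#'
#' @param path VCF file (plain text or gzipped).
#' @return list with `genotypes` (samples x variants integer dosage matrix,
#'   `NA` = missing) and `variants` (data frame with id, chrom, pos, ref, alt).
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  rownames(dos) <- variants$variant_id
  list(genotypes = t(dos), variants = variants)
}

# Gene table (1-based inclusive) -> BED4 (0-based half-open) via the
# GenomicRanges/rtracklayer machinery, which owns the coordinate conversion.
write_bed <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               name = genes$gene_id)
  rtracklayer::export(gr, as.character(path), format = "BED")
  invisible(path)
}

#' Read gene annotation from a BED file
#'
#' @param path BED file with the gene id in the name column.
#' @return data frame `gene_id`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

write_gmt <- function(gene_sets, path) {
  parent <- attr(gene_sets, "parent")
  desc <- if (is.null(parent)) rep("na", length(gene_sets)) else
    ifelse(is.na(parent), "na", paste0("parent=", parent))
  lines <- vapply(seq_along(gene_sets), function(i)
    paste(c(names(gene_sets)[i], desc[i], gene_sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated name, description, gene ids.
#' A `parent=<set>` description marks a subcomplex of a parent set and is
#' returned in the `"parent"` attribute.
#'
#' @param path GMT file.
#' @return named list of gene-id vectors with a `"parent"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  desc <- vapply(fields, `[`, character(1), 2L)
  parent <- ifelse(grepl("^parent=", desc), sub("^parent=", "", desc),
                   NA_character_)
  names(parent) <- names(sets)
  attr(sets, "parent") <- parent
  sets
}

#' Read a study back from files written by [write_study()]
#'
#' @param dir directory holding `genotypes.vcf`, `samples.tsv`, `genes.bed`
#'   and `genesets.gmt` (a `truth.tsv`, if present, is read too).
#' @return a list shaped like a `synthetic_study` (without `config`).
#' @export
read_study <- function(dir) {
  vcf <- read_vcf_dosages(file.path(dir, "genotypes.vcf"))
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  genes <- read_bed_genes(file.path(dir, "genes.bed"))
  gene_sets <- read_gmt(file.path(dir, "genesets.gmt"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- NULL
  if (file.exists(truth_path)) {
    tdf <- utils::read.delim(truth_path, stringsAsFactors = FALSE)
    effects <- tdf$beta
    names(effects) <- tdf$variant_id
    truth <- list(causal_genes = unique(tdf$gene_id),
                  causal_snps = tdf$variant_id, effects = effects)
  }
  geno <- vcf$genotypes[samples$sample_id, , drop = FALSE]
  list(genotypes = geno, variants = vcf$variants, samples = samples,
       genes = genes, gene_sets = gene_sets, truth = truth)
}
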