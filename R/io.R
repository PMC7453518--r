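## Plain-text I/O: TSV matrices with a sample_id column, BED-style
## annotation files (0-based half-open), a minimal VCF dosage writer.
## Truth tables are written under a separate truth/ subdirectory so that
## pipeline stages can consume a cohort directory without ever seeing
## ground truth.

.write_matrix_tsv <- function(m, path, id_col = "sample_id") {
  dt <- data.table::as.data.table(m)
  dt[[id_col]] <- if (is.null(rownames(m))) seq_len(nrow(m)) else rownames(m)
  data.table::setcolorder(dt, id_col)
  data.table::fwrite(dt, path, sep = "\t")
}

.read_matrix_tsv <- function(path, id_col = "sample_id") {
  dt <- data.table::fread(path, sep = "\t")
  ids <- dt[[id_col]]
  dt[[id_col]] <- NULL
  m <- as.matrix(dt)
  rownames(m) <- as.character(ids)
  m
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Dosages, expression (latent and counts), methylation and covariates as
#' TSV; SNP map as TSV; gene and probe maps as BED-like TSV (0-based
#' half-open intervals derived from the 1-based point annotations); the
#' generator config as JSON.  Ground truth goes to `truth/` and is never
#' read by pipeline stages.
#'
#' @param cohort a `gimeth_cohort`.
#' @param dir output directory (created).
#' @param vcf also write dosages as a minimal VCF with a DS FORMAT field.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, vcf = FALSE) {
  stopifnot(inherits(cohort, "gimeth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  .write_matrix_tsv(cohort$dosages, file.path(dir, "dosages.tsv"))
  .write_matrix_tsv(cohort$expression, file.path(dir, "expression_latent.tsv"))
  .write_matrix_tsv(cohort$expression_counts,
                    file.path(dir, "expression_counts.tsv"))
  .write_matrix_tsv(cohort$methylation, file.path(dir, "methylation.tsv"))
  data.table::fwrite(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t")
  data.table::fwrite(cohort$snp_map, file.path(dir, "snp_map.tsv"),
                     sep = "\t")
  gm <- cohort$gene_map
  gene_bed <- data.frame(chrom = gm$chrom,
                         start = pmin(gm$tss, gm$tes) - 1L,
                         end = pmax(gm$tss, gm$tes),
                         gene = gm$gene, tss = gm$tss, tes = gm$tes)
  data.table::fwrite(gene_bed, file.path(dir, "gene_map.bed"), sep = "\t")
  pm <- cohort$probe_map
  probe_bed <- data.frame(chrom = pm$chrom, start = pm$pos - 1L,
                          end = pm$pos, probe = pm$probe)
  if ("gc" %in% names(pm)) probe_bed$gc <- pm$gc
  data.table::fwrite(probe_bed, file.path(dir, "probe_map.bed"),
                     sep = "\t")
  data.table::fwrite(cohort$truth$trans_map,
                     file.path(dir, "truth", "trans_map.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth$cis_effects,
                     file.path(dir, "truth", "cis_effects.tsv"), sep = "\t")
  .write_matrix_tsv(cohort$truth$genetic_value,
                    file.path(dir, "truth", "genetic_value.tsv"))
  meta <- list(n_samples = cohort$config$n_samples,
               n_cohorts = cohort$config$n_cohorts,
               methylation_scale = cohort$methylation_scale,
               seed = cohort$config$seed)
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (vcf) {
    write_vcf_dosages(cohort$dosages, cohort$snp_map,
                      file.path(dir, "dosages.vcf"))
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param truth also load the `truth/` tables (default FALSE: pipeline
#'   stages stay blind to ground truth).
#' @return a list with the same data fields as a `gimeth_cohort`.
#' @export
read_cohort <- function(dir, truth = FALSE) {
  gene_bed <- data.table::fread(file.path(dir, "gene_map.bed"))
  probe_bed <- data.table::fread(file.path(dir, "probe_map.bed"))
  out <- list(
    dosages = .read_matrix_tsv(file.path(dir, "dosages.tsv")),
    expression = .read_matrix_tsv(file.path(dir, "expression_latent.tsv")),
    expression_counts = .read_matrix_tsv(file.path(dir, "expression_counts.tsv")),
    methylation = .read_matrix_tsv(file.path(dir, "methylation.tsv")),
    covariates = as.data.frame(
      data.table::fread(file.path(dir, "covariates.tsv"))),
    snp_map = as.data.frame(data.table::fread(file.path(dir, "snp_map.tsv"))),
    gene_map = data.frame(gene = gene_bed$gene, chrom = gene_bed$chrom,
                          tss = gene_bed$tss, tes = gene_bed$tes),
    probe_map = data.frame(probe = probe_bed$probe,
                           chrom = probe_bed$chrom, pos = probe_bed$end))
  if ("gc" %in% names(probe_bed)) out$probe_map$gc <- probe_bed$gc
  if (truth) {
    out$truth <- list(
      trans_map = as.data.frame(
        data.table::fread(file.path(dir, "truth", "trans_map.tsv"))),
      cis_effects = as.data.frame(
        data.table::fread(file.path(dir, "truth", "cis_effects.tsv"))),
      genetic_value = .read_matrix_tsv(file.path(dir, "truth",
                                                 "genetic_value.tsv")))
  }
  class(out) <- "gimeth_cohort"
  out
}

#' Write dosages as a minimal VCF with a DS FORMAT field
#'
#' One record per SNP (REF A, ALT G placeholders), genotypes omitted
#' (`./.`), dosage carried in the DS field — the common exchange format
#' for imputed genotypes.
#'
#' @param dosages samples x SNPs matrix.
#' @param snp_map data.frame `snp`, `chrom`, `pos`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_dosages <- function(dosages, snp_map, path) {
  samples <- rownames(dosages)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  for (j in seq_len(nrow(snp_map))) {
    ds <- format(dosages[, snp_map$snp[j]], trim = TRUE)
    writeLines(paste(c(snp_map$chrom[j], snp_map$pos[j], snp_map$snp[j],
                       "A", "G", ".", "PASS", ".", "DS", ds),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write an instrument store
#'
#' Two TSVs mirroring the conventional instrument release format: per-SNP
#' weights (`gene`, `snp`, `weight`) and a per-gene summary (`n_snps`,
#' `lambda1`, `lambda2`, `f_test`, `partial_r2`, `valid`).
#'
#' @param built output of [build_instruments()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_instruments <- function(built, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  weights <- data.table::rbindlist(lapply(built$instruments, function(gi) {
    data.table::data.table(gene = gi$gene, snp = gi$snps,
                           weight = gi$weights)
  }))
  if (nrow(weights) == 0) {
    weights <- data.table::data.table(gene = character(),
                                      snp = character(),
                                      weight = numeric())
  }
  summary <- built$summary
  if (is.null(summary)) {
    summary <- data.frame(gene = character(), n_snps = integer(),
                          lambda1 = numeric(), lambda2 = numeric(),
                          f_test = numeric(), partial_r2 = numeric(),
                          valid = logical())
  }
  data.table::fwrite(weights, file.path(dir, "instrument_weights.tsv"),
                     sep = "\t")
  data.table::fwrite(summary,
                     file.path(dir, "instrument_summary.tsv"), sep = "\t")
  invisible(dir)
}
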