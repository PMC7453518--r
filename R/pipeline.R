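#' Pipeline configuration
#'
#' Thresholds and toggles for [run_pipeline()], defaulting to the study
#' design: cis window 100 kb, trans distance 10 Mb, neighbour window 1 Mb,
#' correlation cutoff 0.95, instrument validity F > 10, residual
#' pleiotropy F > 5, family-wise alpha 0.05, training fraction 1/3, five
#' covariate PCs.
#'
#' @param split_ratio training fraction.
#' @param seed master seed; all stage seeds derive from it.
#' @param cis_window,trans_distance,neighbour_window,r_cutoff,f_valid,f_pleio,alpha
#'   thresholds (see description).
#' @param n_pcs number of covariate principal components.
#' @param scan_pc_source `"methylation"` (default) or `"expression"`:
#'   which matrix supplies the scan's covariate PCs.
#' @param min_median_cpm expression filter threshold.
#' @param wbc_snps SNP ids for the WBC filter stage.
#' @param stages character vector of cascade/characterization stages to
#'   run (all by default).
#' @return a `gimeth_config` list.
#' @export
pipeline_config <- function(split_ratio = 1 / 3, seed = 1L,
                            cis_window = .gimeth_defaults$cis_window,
                            trans_distance = .gimeth_defaults$trans_distance,
                            neighbour_window = .gimeth_defaults$neighbour_window,
                            r_cutoff = .gimeth_defaults$r_cutoff,
                            f_valid = .gimeth_defaults$f_valid,
                            f_pleio = .gimeth_defaults$f_pleio,
                            alpha = .gimeth_defaults$alpha,
                            n_pcs = 5,
                            scan_pc_source = c("methylation", "expression"),
                            min_median_cpm = 1,
                            wbc_snps = character(),
                            stages = c("scan", "cascade", "characterize",
                                       "power")) {
  stopifnot(split_ratio > 0, split_ratio < 1, cis_window > 0,
            trans_distance > 0, neighbour_window > 0, r_cutoff > 0,
            f_valid > 0, f_pleio > 0, alpha > 0, alpha < 1)
  structure(list(split_ratio = split_ratio, seed = as.integer(seed),
                 cis_window = cis_window, trans_distance = trans_distance,
                 neighbour_window = neighbour_window, r_cutoff = r_cutoff,
                 f_valid = f_valid, f_pleio = f_pleio, alpha = alpha,
                 n_pcs = n_pcs,
                 scan_pc_source = match.arg(scan_pc_source),
                 min_median_cpm = min_median_cpm, wbc_snps = wbc_snps,
                 stages = stages),
            class = "gimeth_config")
}

#' Run the full pipeline on a cohort
#'
#' Stage order: expression filter (median CPM), rank-INT of expression and
#' methylation within cohort, covariate PCs, stratified split, two-step
#' LASSO instruments with test-set validation (F > 10), genome-wide trans
#' scan, bias/inflation calibration, Bonferroni thresholding, the
#' specificity cascade (neighbour conditioning, correlation exclusion,
#' residual pleiotropy, long-range joint models, WBC variants), then
#' characterization (direction skew, region collapsing) and per-gene
#' power profiles.  All stage tables are written as TSV plus a
#' machine-readable JSON run log; identical config and cohort reproduce
#' the outputs bit for bit.
#'
#' @param cohort a `gimeth_cohort` (or the list returned by
#'   [read_cohort()]).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results
#'   (instruments, scan records, calibration, cascade, characterization,
#'   power table, thresholds).
#' @export
run_pipeline <- function(cohort, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("gimeth")))
  ## -- preprocessing ------------------------------------------------
  expressed <- filter_expressed(cohort$expression_counts,
                                min_median_cpm = config$min_median_cpm,
                                gene_annotation = cohort$gene_map)
  expr_int <- rank_inverse_normal(
    cohort$expression[, expressed, drop = FALSE],
    cohort$covariates$cohort)
  meth_int <- rank_inverse_normal(cohort$methylation,
                                  cohort$covariates$cohort)
  gene_map <- cohort$gene_map[cohort$gene_map$gene %in% expressed, ]
  log$n_genes_expressed <- length(expressed)
  ## -- split + instruments ------------------------------------------
  samples <- rownames(cohort$dosages)
  if (is.null(samples)) samples <- as.character(seq_len(nrow(cohort$dosages)))
  split <- split_train_test(samples, cohort$covariates$cohort,
                            cohort$covariates$sex,
                            ratio = config$split_ratio,
                            seed = .child_seed(config$seed, 11L))
  built <- build_instruments(cohort$dosages, expr_int, cohort$covariates,
                             gene_map, cohort$snp_map, split,
                             window = config$cis_window,
                             seed = .child_seed(config$seed, 12L),
                             n_pcs = config$n_pcs)
  write_instruments(built, out_dir)
  valid <- built$summary$gene[built$summary$valid]
  log$n_instruments <- nrow(built$summary)
  log$n_valid <- length(valid)
  if (length(valid) == 0) {
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    message("no valid instruments; stopping after validation")
    return(invisible(list(instruments = built, split = split)))
  }
  if (!any(c("scan", "cascade", "characterize", "power") %in%
             config$stages)) {
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(list(instruments = built, split = split)))
  }
  gi_matrix <- vapply(valid, function(g)
    instrument_scores(built$instruments[[g]], cohort$dosages),
    numeric(nrow(cohort$dosages)))
  ## calibrate each instrument to the expression scale on the held-out
  ## test split (slope of expression on GI), so that phi estimates are SD
  ## methylation per SD expression rather than per raw dosage-sum unit
  idx_test_cal <- which(split$assignment == "test")
  for (g in valid) {
    gt <- gi_matrix[idx_test_cal, g]
    b <- cov(expr_int[idx_test_cal, g], gt) / var(gt)
    gi_matrix[, g] <- gi_matrix[, g] * b
  }
  ## -- trans scan ----------------------------------------------------
  pc_source <- if (config$scan_pc_source == "methylation") meth_int else
    expr_int
  C_scan <- covariate_design(cohort$covariates, expression = pc_source,
                             k = config$n_pcs)
  records <- run_scan(gi_matrix, meth_int, C_scan, gene_map,
                      cohort$probe_map,
                      min_distance = config$trans_distance)
  n_tests <- length(valid) * ncol(meth_int)
  threshold <- bonferroni_threshold(config$alpha, n_tests)
  gene_threshold <- bonferroni_threshold(config$alpha, ncol(meth_int))
  ## the mixture fit needs a sizeable null ensemble; on small synthetic
  ## scans it can hallucinate bias/inflation, so fall back to identity
  calibration <- if (nrow(records) >= 1000) {
    suppressWarnings(correct_bias_inflation(records$z, min_tests = 0))
  } else {
    identity_calibration(nrow(records))
  }
  records <- apply_calibration(records, calibration)
  data.table::fwrite(records, file.path(out_dir, "scan.tsv"), sep = "\t")
  data.table::fwrite(
    data.frame(bias = calibration$bias, inflation = calibration$inflation,
               pi0 = calibration$pi0, n_tests = calibration$n_tests,
               method = calibration$method),
    file.path(out_dir, "calibration.tsv"), sep = "\t")
  log$threshold <- threshold
  log$gene_threshold <- gene_threshold
  out <- list(instruments = built, split = split, records = records,
              calibration = calibration, threshold = threshold,
              gene_threshold = gene_threshold, gi_matrix = gi_matrix)
  ## -- specificity cascade -------------------------------------------
  if ("cascade" %in% config$stages) {
    cascade <- run_cascade(records, gi_matrix, meth_int, expr_int, C_scan,
                           cohort$dosages, gene_map, calibration,
                           threshold, gene_threshold,
                           wbc_snps = config$wbc_snps)
    data.table::fwrite(cascade$records,
                       file.path(out_dir, "cascade_records.tsv"),
                       sep = "\t")
    data.table::fwrite(cascade$accounting,
                       file.path(out_dir, "stage_accounting.tsv"),
                       sep = "\t")
    out$cascade <- cascade
    finals <- cascade$records[cascade$records$final == TRUE, ]
    gene_counts <- if (nrow(finals) > 0) {
      setNames(as.data.frame(table(finals$gene), stringsAsFactors = FALSE),
               c("gene", "n_target_cpgs"))
    } else {
      data.frame(gene = character(), n_target_cpgs = integer())
    }
    data.table::fwrite(gene_counts, file.path(out_dir, "final_genes.tsv"),
                       sep = "\t")
    log$n_final_genes <- nrow(gene_counts)
    log$n_final_cpgs <- length(unique(finals$probe))
    ## -- characterization --------------------------------------------
    if ("characterize" %in% config$stages && nrow(finals) > 0) {
      signs <- split(sign(finals$phi_cond), finals$gene)
      skew <- direction_skew(signs)
      data.table::fwrite(skew, file.path(out_dir, "direction_skew.tsv"),
                         sep = "\t")
      pm <- cohort$probe_map
      tgt <- pm[pm$probe %in% unique(finals$probe), ]
      regions <- collapse_regions(tgt[, c("chrom", "pos")])
      data.table::fwrite(regions$regions,
                         file.path(out_dir, "target_regions.tsv"),
                         sep = "\t")
      log$n_regions <- regions$n_regions
      log$coloc_fraction <- regions$coloc_fraction
      out$skew <- skew
      out$regions <- regions
    }
  }
  ## -- power ----------------------------------------------------------
  if ("power" %in% config$stages) {
    idx_test <- which(split$assignment == "test")
    C_instr <- covariate_design(cohort$covariates, expression = expr_int,
                                train_idx = which(split$assignment == "train"),
                                k = config$n_pcs)
    contexts <- neighbour_contexts(gi_matrix, gene_map,
                                   window = config$neighbour_window,
                                   cutoff = config$r_cutoff)
    summ <- data.frame(
      gene = valid,
      r2_marginal = built$summary$partial_r2[match(valid, built$summary$gene)],
      r2_partial = vapply(valid, function(g) {
        nb <- contexts[[g]]$pruned
        Cx <- cbind(C_instr[idx_test, , drop = FALSE],
                    if (length(nb)) gi_matrix[idx_test, nb, drop = FALSE])
        .partial_r2(expr_int[idx_test, g], gi_matrix[idx_test, g], Cx)
      }, numeric(1)))
    power_tab <- power_profile(summ, n = nrow(meth_int),
                               alpha = threshold)
    data.table::fwrite(power_tab, file.path(out_dir, "power.tsv"),
                       sep = "\t")
    out$power <- power_tab
  }
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

## Added R^2 of x over covariates C on y.
.partial_r2 <- function(y, x, C) {
  rss_red <- sum(.residualize(y, C)^2)
  rss_full <- sum(.residualize(y, cbind(C, x = x))^2)
  max(0, (rss_red - rss_full) / rss_red)
}
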