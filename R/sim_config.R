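#' Simulation configuration for a synthetic cohort
#'
#' Describes the stated world the generator draws from: an LD-blocked SNP
#' map, a cis-genetic expression architecture, trans effects of regulator
#' expression on methylation probes, covariate confounding, and optional
#' pleiotropy scenarios.  Defaults mirror a blood-cohort setting: cis
#' heritabilities in the 0.01-0.3 range (median near 0.04), trans effects
#' of 0.25-1 SD methylation per SD expression.
#'
#' @param n_samples number of individuals.
#' @param n_cohorts number of biobank cohorts (balanced assignment).
#' @param snp_map data.frame with columns `snp`, `chrom`, `pos`,
#'   `maf` (in \[0.01, 0.5\]), `block` (LD block id; NA = unlinked) and
#'   `block_r` (latent within-block correlation target in \[0,1)).
#' @param gene_map data.frame with columns `gene`, `chrom`, `tss`, `tes`,
#'   `h2_cis` (in \[0,1)) and optionally `base_log_cpm` (default log(50))
#'   and `biotype`.
#' @param cis_effects data.frame `gene`, `snp`, `effect` giving relative
#'   per-SD-dosage weights of the cis architecture; rescaled so the genetic
#'   component has variance `h2_cis` under the simulated LD.
#' @param trans_map data.frame `gene`, `probe`, `phi`: SD methylation per
#'   SD expression; every pair must satisfy the trans criterion (other
#'   chromosome, or > 10 Mb from both TSS and TES and outside the body).
#' @param probe_map data.frame `probe`, `chrom`, `pos`, optional `gc`.
#' @param covariate_effects list with data.frames `expression`
#'   (`covariate`, `gene`, `effect`) and `methylation` (`covariate`,
#'   `probe`, `effect`); effects are per SD of the (standardized) covariate.
#' @param scenarios list of scenario specs from [scenario_shared_eqtl()],
#'   [scenario_direct_snp_to_cpg()] or [scenario_cell_confounder()].
#' @param cell_reliability squared correlation between the measured and the
#'   true cell-composition latent (measurement quality of cell fractions).
#' @param methylation_scale `"latent"` (default; pipeline rank-INTs anyway)
#'   or `"beta"` (inverse-logit squashed, flagged on the dataset).
#' @param seed integer seed; the config is fully deterministic given it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples,
                       n_cohorts = 2,
                       snp_map,
                       gene_map,
                       cis_effects,
                       trans_map = NULL,
                       probe_map,
                       covariate_effects = NULL,
                       scenarios = list(),
                       cell_reliability = 0.6,
                       methylation_scale = c("latent", "beta"),
                       seed = 1L) {
  methylation_scale <- match.arg(methylation_scale)
  stopifnot(n_samples > 0, n_cohorts >= 1)
  snp_map <- as.data.frame(snp_map)
  gene_map <- as.data.frame(gene_map)
  probe_map <- as.data.frame(probe_map)
  cis_effects <- as.data.frame(cis_effects)
  stopifnot(all(c("snp", "chrom", "pos", "maf") %in% names(snp_map)),
            all(c("gene", "chrom", "tss", "tes", "h2_cis") %in% names(gene_map)),
            all(c("probe", "chrom", "pos") %in% names(probe_map)),
            all(c("gene", "snp", "effect") %in% names(cis_effects)))
  if (!"block" %in% names(snp_map)) snp_map$block <- NA
  if (!"block_r" %in% names(snp_map)) snp_map$block_r <- 0
  if (!"base_log_cpm" %in% names(gene_map)) gene_map$base_log_cpm <- log(50)
  if (any(snp_map$maf < 0.01 | snp_map$maf > 0.5)) {
    stop("MAFs must lie in [0.01, 0.5]")
  }
  if (any(snp_map$block_r < 0 | snp_map$block_r >= 1, na.rm = TRUE)) {
    stop("LD block correlation targets must lie in [0, 1)")
  }
  if (any(gene_map$h2_cis < 0 | gene_map$h2_cis >= 1)) {
    stop("h2_cis must lie in [0, 1)")
  }
  stopifnot(all(cis_effects$gene %in% gene_map$gene),
            all(cis_effects$snp %in% snp_map$snp))
  ## every cis SNP must fall in its gene's cis window (body +/- 100 kb)
  for (i in seq_len(nrow(cis_effects))) {
    g <- gene_map[gene_map$gene == cis_effects$gene[i], ]
    s <- snp_map[snp_map$snp == cis_effects$snp[i], ]
    lo <- min(g$tss, g$tes) - .gimeth_defaults$cis_window
    hi <- max(g$tss, g$tes) + .gimeth_defaults$cis_window
    if (s$chrom != g$chrom || s$pos < lo || s$pos > hi) {
      stop("cis SNP ", s$snp, " outside the cis window of gene ", g$gene)
    }
  }
  if (!is.null(trans_map)) {
    trans_map <- as.data.frame(trans_map)
    stopifnot(all(c("gene", "probe", "phi") %in% names(trans_map)),
              all(trans_map$gene %in% gene_map$gene),
              all(trans_map$probe %in% probe_map$probe))
    for (i in seq_len(nrow(trans_map))) {
      g <- gene_map[gene_map$gene == trans_map$gene[i], ]
      p <- probe_map[probe_map$probe == trans_map$probe[i], ]
      if (!.is_trans(g$chrom, g$tss, g$tes, p$chrom, p$pos)) {
        stop("trans_map pair (", g$gene, ", ", p$probe,
             ") violates the trans criterion")
      }
    }
  } else {
    trans_map <- data.frame(gene = character(), probe = character(),
                            phi = numeric())
  }
  for (sc in scenarios) {
    stopifnot(inherits(sc, "gimeth_scenario"))
    ids <- c(sc$snp, sc$gene, sc$gene_a, sc$gene_b, sc$probe)
    known <- c(snp_map$snp, gene_map$gene, probe_map$probe)
    if (!all(ids %in% known)) {
      stop("scenario references unknown ids: ",
           paste(setdiff(ids, known), collapse = ", "))
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_cohorts = as.integer(n_cohorts),
                 snp_map = snp_map, gene_map = gene_map,
                 cis_effects = cis_effects, trans_map = trans_map,
                 probe_map = probe_map,
                 covariate_effects = covariate_effects,
                 scenarios = scenarios,
                 cell_reliability = cell_reliability,
                 methylation_scale = methylation_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## The trans criterion: another chromosome, or > 10 Mb from both TSS and
## TES with the probe outside the gene body (strict >).
.is_trans <- function(g_chrom, tss, tes, p_chrom, pos,
                      min_distance = .gimeth_defaults$trans_distance) {
  if (g_chrom != p_chrom) return(TRUE)
  lo <- min(tss, tes); hi <- max(tss, tes)
  if (pos >= lo && pos <= hi) return(FALSE)
  min(abs(pos - tss), abs(pos - tes)) > min_distance
}

#' Pleiotropy scenarios for the generator
#'
#' `scenario_shared_eqtl` makes one SNP part of the cis architecture of two
#' genes so their genetic instruments are correlated: `share` is the
#' fraction of each gene's cis-genetic variance carried by the shared SNP,
#' which equals the expected correlation between the two true genetic
#' scores (share = 0.8 targets an instrument correlation near 0.8, the
#' classic bystander situation).  Only effects declared in `trans_map` are
#' causal; the other gene is a bystander.
#'
#' `scenario_direct_snp_to_cpg` adds a dosage effect on a probe that
#' bypasses expression (horizontal pleiotropy), `effect` in SD methylation
#' per SD dosage.
#'
#' `scenario_cell_confounder` routes a SNP through the (imperfectly
#' measured) cell-composition latent into both a gene's expression and a
#' probe's methylation, emulating residual white-blood-cell confounding:
#' `snp_share` is the fraction of the cell latent's variance explained by
#' the SNP; `cell_to_expr`/`cell_to_meth` are effects of the latent (in SD
#' units) on expression and methylation.
#'
#' @param snp,gene,gene_a,gene_b,probe actor ids present in the maps.
#' @param share,effect,snp_share,cell_to_expr,cell_to_meth magnitudes (see
#'   above).
#' @return a `gimeth_scenario` object for `sim_config(scenarios = ...)`.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_shared_eqtl <- function(snp, gene_a, gene_b, share = 0.8) {
  stopifnot(share > 0, share < 1)
  structure(list(kind = "shared_eqtl", snp = snp, gene_a = gene_a,
                 gene_b = gene_b, share = share),
            class = "gimeth_scenario")
}

#' @rdname scenarios
#' @export
scenario_direct_snp_to_cpg <- function(snp, probe, effect = 0.4) {
  structure(list(kind = "direct_snp_to_cpg", snp = snp, probe = probe,
                 effect = effect),
            class = "gimeth_scenario")
}

#' @rdname scenarios
#' @export
scenario_cell_confounder <- function(snp, gene, probe, snp_share = 0.5,
                                     cell_to_expr = 0.6,
                                     cell_to_meth = 0.7) {
  stopifnot(snp_share > 0, snp_share < 1)
  structure(list(kind = "cell_composition_confounder", snp = snp,
                 gene = gene, probe = probe, snp_share = snp_share,
                 cell_to_expr = cell_to_expr, cell_to_meth = cell_to_meth),
            class = "gimeth_scenario")
}

#' A small demonstration world
#'
#' A ready-made [sim_config()] used by the examples and the command-line
#' `simulate` subcommand: two chromosomes, LD-blocked SNPs, six genes with
#' cis heritabilities spanning 0.05-0.3, one true trans regulator
#' (phi = 0.75), a shared-eQTL bystander pair, and modest age/sex/cell
#' covariate effects on expression and methylation.
#'
#' @param n_samples cohort size (default 800).
#' @param seed generator seed.
#' @return a `sim_config`.
#' @export
sim_config_demo <- function(n_samples = 800, seed = 1L) {
  snp_map <- data.frame(
    snp = paste0("rs", 1:18),
    chrom = rep(c("chr1", "chr2"), each = 9),
    pos = rep(c(1.00e6, 1.02e6, 1.05e6, 5.0e6, 5.03e6, 30e6, 30.02e6,
                60e6, 60.05e6), 2),
    maf = rep(c(0.3, 0.25, 0.4, 0.2, 0.35, 0.3, 0.25, 0.45, 0.2), 2),
    block = rep(c(NA, NA, NA, 2, 2, 3, 3, 4, 4), 2),
    block_r = rep(c(0, 0, 0, 0.5, 0.5, 0.6, 0.6, 0.4, 0.4), 2))
  gene_map <- data.frame(
    gene = paste0("G", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    tss = c(1.01e6, 1.04e6, 5.01e6, 30.01e6, 1.01e6, 60.02e6),
    tes = c(1.03e6, 1.06e6, 5.05e6, 30.05e6, 1.05e6, 60.08e6),
    h2_cis = c(0.30, 0.30, 0.15, 0.05, 0.20, 0.10))
  cis_effects <- data.frame(
    gene = c("G1", "G1", "G2", "G2", "G3", "G4", "G5", "G5", "G6"),
    snp = c("rs1", "rs2", "rs2", "rs3", "rs4", "rs6", "rs10", "rs11",
            "rs17"),
    effect = c(1, 0.5, 0.5, 1, 1, 1, 1, 0.6, 1))
  probe_map <- data.frame(
    probe = sprintf("cg%03d", 1:20),
    chrom = rep(c("chr1", "chr2"), each = 10),
    pos = rep(seq(20e6, 96.5e6, length.out = 10), 2),
    gc = rep(seq(0.3, 0.7, length.out = 10), 2))
  trans_map <- data.frame(gene = c("G1", "G1", "G5"),
                          probe = c("cg011", "cg013", "cg003"),
                          phi = c(0.75, 0.5, 0.6))
  covariate_effects <- list(
    expression = data.frame(covariate = c("age", "cf1"),
                            gene = c("G3", "G4"),
                            effect = c(0.15, 0.2)),
    methylation = data.frame(covariate = c("age", "sex", "cf1"),
                             probe = c("cg001", "cg005", "cg012"),
                             effect = c(0.2, 0.15, 0.2)))
  sim_config(n_samples = n_samples, n_cohorts = 2, snp_map = snp_map,
             gene_map = gene_map, cis_effects = cis_effects,
             trans_map = trans_map, probe_map = probe_map,
             covariate_effects = covariate_effects,
             scenarios = list(scenario_shared_eqtl("rs2", "G1", "G2")),
             seed = seed)
}

#' Deserialize a simulation config from JSON
#'
#' Reads a JSON file whose top-level fields mirror the [sim_config()]
#' arguments (tables as arrays of records; scenarios as objects with a
#' `kind` field plus the scenario's own arguments).
#'
#' @param path JSON file path.
#' @return a `sim_config`.
#' @export
sim_config_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scen <- lapply(
    if (is.data.frame(x$scenarios)) split(x$scenarios, seq_len(nrow(x$scenarios)))
    else x$scenarios,
    function(s) {
      s <- as.list(s)
      kind <- s$kind
      s$kind <- NULL
      s <- s[!vapply(s, function(v) all(is.na(v)), logical(1))]
      do.call(switch(kind,
                     shared_eqtl = scenario_shared_eqtl,
                     direct_snp_to_cpg = scenario_direct_snp_to_cpg,
                     cell_composition_confounder = scenario_cell_confounder),
              s)
    })
  sim_config(n_samples = x$n_samples,
             n_cohorts = if (is.null(x$n_cohorts)) 2 else x$n_cohorts,
             snp_map = x$snp_map, gene_map = x$gene_map,
             cis_effects = x$cis_effects, trans_map = x$trans_map,
             probe_map = x$probe_map,
             covariate_effects = x$covariate_effects,
             scenarios = scen,
             cell_reliability = if (is.null(x$cell_reliability)) 0.6 else
               x$cell_reliability,
             methylation_scale = if (is.null(x$methylation_scale)) "latent"
             else x$methylation_scale,
             seed = if (is.null(x$seed)) 1L else x$seed)
}
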