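#' Endophenotype MR for candidate targets
#'
#' Re-runs the full instrument-selection and MR pass using each candidate
#' protein as exposure and each quantitative endophenotype (e.g.
#' intraocular pressure, retinal nerve fibre layer thickness) as outcome.
#' Effects are reported as betas with 95\% CIs at raw alpha 0.05, not as
#' odds ratios. Targets with no surviving instruments get a flagged row
#' rather than being dropped silently.
#'
#' @param exposures named list of exposure `sumstats` per gene id.
#' @param regions gene-region data.frame.
#' @param ld_list named list of `ld_block`s per gene id.
#' @param endo_outcomes named list of quantitative-outcome `sumstats`.
#' @param config an [mr_config()].
#' @return data.frame with one row per gene x endophenotype: gene_id,
#'   endophenotype, method, n_snps, beta, ci_low, ci_high (beta scale),
#'   pval, significant, flag.
#' @export
endophenotype_mr <- function(exposures, regions, ld_list, endo_outcomes,
                             config = mr_config()) {
  rows <- list()
  for (g in names(exposures)) {
    region <- regions[regions$gene_id == g, , drop = FALSE]
    clumped <- cis_clump(exposures[[g]], region, ld_list[[g]], config)
    for (e in names(endo_outcomes)) {
      iset <- select_instruments(exposures[[g]], endo_outcomes[[e]], region,
                                 ld_list[[g]], config, clumped = clumped)
      res <- run_mr(iset, config = config)
      rows[[paste(g, e, sep = ".")]] <- if (is.null(res)) {
        data.frame(gene_id = g, endophenotype = e, method = NA_character_,
                   n_snps = 0L, beta = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, pval = NA_real_, significant = NA,
                   flag = "no_instruments", stringsAsFactors = FALSE)
      } else {
        data.frame(gene_id = g, endophenotype = e, method = res$method,
                   n_snps = res$n_snps, beta = res$beta,
                   ci_low = res$beta - config$ci_z * res$se,
                   ci_high = res$beta + config$ci_z * res$se,
                   pval = res$pval,
                   significant = res$pval < config$endo_alpha,
                   flag = "ok", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phenome-wide MR scan for one target
#'
#' Screens one exposure against a catalogue of disease outcomes for
#' co-therapeutic and adverse-effect signals. Outcomes with `n_cases`
#' strictly greater than `case_min` are scanned; for each, the standard
#' instrument-selection and MR pass is run, and Benjamini-Hochberg FDR
#' correction is applied across the scanned set. The outcome-independent
#' clumping step is computed once and reused.
#'
#' @param exposure exposure `sumstats` for the target.
#' @param region the target's gene region.
#' @param ld `ld_block` for the locus.
#' @param catalogue list of outcome entries, each a list with
#'   `phenotype_id`, `category`, `n_cases` and `stats` (a binary-trait
#'   `sumstats`).
#' @param config an [mr_config()]; uses `phewas_case_min` and
#'   `phewas_alpha_fdr`.
#' @return data.frame with one row per scanned outcome that yielded an
#'   estimate: phenotype_id, category, n_cases, method, n_snps, beta, se,
#'   pval, or, ci_low, ci_high, p_fdr, significant.
#' @export
phewas_scan <- function(exposure, region, ld, catalogue,
                        config = mr_config()) {
  keep <- vapply(catalogue, function(o) o$n_cases > config$phewas_case_min,
                 logical(1))
  catalogue <- catalogue[keep]
  clumped <- cis_clump(exposure, region, ld, config)
  rows <- list()
  for (o in catalogue) {
    iset <- select_instruments(exposure, o$stats, region, ld, config,
                               clumped = clumped)
    res <- run_mr(iset, config = config)
    if (is.null(res)) next
    rows[[o$phenotype_id]] <- data.frame(
      phenotype_id = o$phenotype_id, category = o$category,
      n_cases = o$n_cases, method = res$method, n_snps = res$n_snps,
      beta = res$beta, se = res$se, pval = res$pval, or = res$or,
      ci_low = res$ci_low, ci_high = res$ci_high, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) return(out)
  out$p_fdr <- bh_fdr(out$pval)
  out$significant <- out$p_fdr < config$phewas_alpha_fdr
  rownames(out) <- NULL
  out
}

#' Direction-concordance report between two MR result tables
#'
#' Compares discovery and replication MR results gene by gene on the sign
#' of the estimate, mirroring a replication-cohort check; no formal
#' meta-analysis is performed.
#'
#' @param discovery,replication `mr_result` data.frames sharing gene_id.
#' @return data.frame with gene_id, beta_discovery, beta_replication,
#'   concordant (logical).
#' @export
direction_concordance <- function(discovery, replication) {
  m <- merge(discovery[, c("gene_id", "beta")],
             replication[, c("gene_id", "beta")],
             by = "gene_id", suffixes = c("_discovery", "_replication"))
  m$concordant <- sign(m$beta_discovery) == sign(m$beta_replication)
  m
}
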