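#' Wald ratio causal estimate from a single instrument
#'
#' `beta_mr = beta_out / beta_exp` with first-order delta-method standard
#' error `se_mr = se_out / |beta_exp|` and a two-sided normal p-value.
#' The second-order variance term is omitted; it is negligible for the
#' strong instruments (F >= 10) this pipeline enforces.
#'
#' @param pair one-row `harmonised` data.frame.
#' @param gene_id optional gene label for the result row.
#' @param ci_z CI multiplier (default 1.96 for 95\% limits).
#' @return one-row `mr_result` data.frame (see [mr_result_row()]).
#' @export
wald_ratio <- function(pair, gene_id = NA_character_, ci_z = 1.96) {
  if (nrow(pair) != 1) stop("wald_ratio expects exactly one instrument")
  if (pair$beta_exp == 0) stop("wald_ratio undefined: exposure beta is zero")
  b <- pair$beta_out / pair$beta_exp
  se <- pair$se_out / abs(pair$beta_exp)
  mr_result_row(gene_id, "wald_ratio", 1L, b, se, ci_z = ci_z)
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect combination of per-SNP Wald ratios `r_i` with weights
#' `w_i = 1 / se_i^2`, where `se_i` is the first-order ratio SE:
#' `beta_mr = sum(w r) / sum(w)`, `se_mr = 1 / sqrt(sum(w))`. Algebraically
#' identical to a zero-intercept weighted regression of outcome betas on
#' exposure betas with weights `1 / se_out^2`.
#'
#' @param pairs `harmonised` data.frame with at least two instruments.
#' @param gene_id optional gene label.
#' @param ci_z CI multiplier.
#' @return one-row `mr_result` data.frame.
#' @export
ivw <- function(pairs, gene_id = NA_character_, ci_z = 1.96) {
  if (nrow(pairs) < 2) {
    stop("ivw requires >= 2 instruments; use wald_ratio for a single SNP")
  }
  if (any(pairs$beta_exp == 0)) stop("ivw undefined: an exposure beta is zero")
  r <- pairs$beta_out / pairs$beta_exp
  se_r <- pairs$se_out / abs(pairs$beta_exp)
  w <- 1 / se_r^2
  b <- sum(w * r) / sum(w)
  se <- 1 / sqrt(sum(w))
  mr_result_row(gene_id, "ivw", nrow(pairs), b, se, ci_z = ci_z)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Weighted linear regression (weights `1 / se_out^2`) of outcome betas on
#' exposure betas with a free intercept, after orienting every exposure
#' beta non-negative (the outcome beta's sign is flipped along with it).
#' A non-zero intercept indicates directional horizontal pleiotropy. Used
#' here as a diagnostic gate only; the causal estimate is always Wald/IVW.
#'
#' @param pairs `harmonised` data.frame with at least three instruments.
#' @return list with `intercept`, `intercept_se`, `intercept_pval`,
#'   `slope`, `slope_se`, `n_snps`.
#' @export
egger_intercept <- function(pairs) {
  if (nrow(pairs) < 3) {
    stop("egger_intercept requires >= 3 instruments")
  }
  s <- sign(pairs$beta_exp)
  s[s == 0] <- 1
  bx <- abs(pairs$beta_exp)
  by <- pairs$beta_out * s
  w <- 1 / pairs$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  df <- nrow(pairs) - 2L
  list(
    intercept = unname(cf[1, 1]),
    intercept_se = unname(cf[1, 2]),
    intercept_pval = 2 * stats::pt(-abs(cf[1, 1] / cf[1, 2]), df),
    slope = unname(cf[2, 1]),
    slope_se = unname(cf[2, 2]),
    n_snps = nrow(pairs)
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Thin validating wrapper around `p.adjust(method = "BH")`; adjusted
#' values are returned in input order.
#'
#' @param pvals numeric p-values, all in (0, 1].
#' @return adjusted q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Assemble one MR result row
#'
#' @param gene_id gene label.
#' @param method `"wald_ratio"` or `"ivw"`.
#' @param n_snps instrument count.
#' @param beta,se estimate and standard error on the analysis scale
#'   (log-OR for binary outcomes).
#' @param egger optional list from [egger_intercept()].
#' @param ci_z CI multiplier.
#' @return one-row data.frame with columns gene_id, method, n_snps, beta,
#'   se, pval, or, ci_low, ci_high, egger_intercept, egger_intercept_pval,
#'   p_fdr.
#' @export
mr_result_row <- function(gene_id, method, n_snps, beta, se, egger = NULL,
                          ci_z = 1.96) {
  pval <- 2 * stats::pnorm(-abs(beta / se))
  data.frame(
    gene_id = gene_id, method = method, n_snps = as.integer(n_snps),
    beta = beta, se = se, pval = pval,
    or = exp(beta), ci_low = exp(beta - ci_z * se),
    ci_high = exp(beta + ci_z * se),
    egger_intercept = if (is.null(egger)) NA_real_ else egger$intercept,
    egger_intercept_pval = if (is.null(egger)) NA_real_ else egger$intercept_pval,
    p_fdr = NA_real_, stringsAsFactors = FALSE
  )
}

#' Run the MR estimator appropriate for an instrument set
#'
#' Wald ratio for a single instrument, IVW for several; the MR-Egger
#' intercept diagnostic is attached when three or more instruments are
#' available. Returns `NULL` when no instruments survived selection.
#'
#' @param iset an `instrument_set` from [select_instruments()], or a
#'   `harmonised` data.frame of retained pairs.
#' @param gene_id gene label (taken from the instrument set when absent).
#' @param config an [mr_config()].
#' @return one-row `mr_result` data.frame, or `NULL` if no instruments.
#' @export
run_mr <- function(iset, gene_id = NULL, config = mr_config()) {
  pairs <- if (inherits(iset, "instrument_set")) iset$pairs else iset
  if (is.null(gene_id)) {
    gene_id <- if (inherits(iset, "instrument_set")) iset$gene_id else NA_character_
  }
  n <- nrow(pairs)
  if (n == 0) return(NULL)
  res <- if (n == 1) {
    wald_ratio(pairs, gene_id, ci_z = config$ci_z)
  } else {
    ivw(pairs, gene_id, ci_z = config$ci_z)
  }
  if (n >= 3) {
    eg <- egger_intercept(pairs)
    res$egger_intercept <- eg$intercept
    res$egger_intercept_pval <- eg$intercept_pval
  }
  res
}

#' Proteome- or transcriptome-wide MR across many genes
#'
#' Runs instrument selection and MR per gene against one outcome, then
#' applies Benjamini-Hochberg FDR correction across the genes that
#' produced an estimate.
#'
#' @param exposures named list of exposure `sumstats`, one per gene id.
#' @param outcome outcome `sumstats`.
#' @param regions gene-region data.frame (one row per gene id).
#' @param ld_list named list of `ld_block`s, one per gene id.
#' @param config an [mr_config()].
#' @return `mr_result` data.frame with one row per gene with instruments;
#'   `p_fdr` filled in across the tested set.
#' @export
mr_scan <- function(exposures, outcome, regions, ld_list,
                    config = mr_config()) {
  rows <- list()
  for (g in names(exposures)) {
    region <- regions[regions$gene_id == g, , drop = FALSE]
    if (nrow(region) != 1) stop("no unique region for gene ", g)
    iset <- select_instruments(exposures[[g]], outcome, region,
                               ld_list[[g]], config)
    res <- run_mr(iset, config = config)
    if (!is.null(res)) rows[[g]] <- res
  }
  out <- do.call(rbind, rows)
  if (!is.null(out) && nrow(out)) {
    out$p_fdr <- bh_fdr(out$pval)
    rownames(out) <- NULL
  }
  out
}
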