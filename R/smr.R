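#' Summary-data-based MR (SMR) test
#'
#' Links gene expression to an outcome through the top cis-eQTL. With
#' z-scores `z_e = b_eqtl/se_eqtl` and `z_g = b_gwas/se_gwas`, the SMR
#' statistic is `T = z_g^2 z_e^2 / (z_g^2 + z_e^2)`, referred to a
#' chi-square distribution with 1 df. The effect estimate is the ratio
#' `b_smr = b_gwas / b_eqtl` with `se_smr = |b_smr| / sqrt(T)`.
#'
#' @param b_eqtl,se_eqtl top cis-eQTL effect and SE on expression.
#' @param b_gwas,se_gwas the same SNP's effect and SE on the outcome,
#'   harmonised to the same effect allele.
#' @return list with `b_smr`, `se_smr`, `p_smr`, `t_smr`.
#' @export
smr_test <- function(b_eqtl, se_eqtl, b_gwas, se_gwas) {
  if (b_eqtl == 0) stop("smr_test undefined: eQTL beta is zero")
  z_e <- b_eqtl / se_eqtl
  z_g <- b_gwas / se_gwas
  t_smr <- (z_g^2 * z_e^2) / (z_g^2 + z_e^2)
  b_smr <- b_gwas / b_eqtl
  list(
    b_smr = b_smr,
    se_smr = abs(b_smr) / sqrt(t_smr),
    p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE),
    t_smr = t_smr
  )
}

#' HEIDI test: heterogeneity in dependent instruments
#'
#' Distinguishes a single causal variant shared by expression and outcome
#' (where every cis-SNP's SMR ratio estimates the same quantity) from
#' linkage of two distinct causal variants (where ratios differ across
#' SNPs). Eligible SNPs have squared correlation with the top SNP strictly
#' inside `r2_window` and eQTL p-value below `eligibility_p`
#' (chi-square(1) >= 10 at the default 1.57e-3); at most `max_snps` (the
#' most significant eQTLs) are used. For each eligible SNP `i` the deviation
#' `d_i = b_smr(i) - b_smr(top)` is formed; its covariance follows from the
#' LD correlations and per-SNP SEs by the first-order delta method, with
#' eQTL and GWAS errors independent across the two datasets. The statistic
#' `sum_i (d_i / sd_i)^2` is a quadratic form in correlated normals; its
#' null distribution is approximated by Satterthwaite moment matching on
#' the eigenvalues of the correlation matrix of `d`.
#'
#' @param eqtl_block `sumstats` for the cis eQTL SNPs.
#' @param gwas_block `sumstats` for the same SNPs on the outcome,
#'   harmonised to the eQTL effect alleles.
#' @param ld `ld_block` covering the SNPs.
#' @param top_snp id of the top cis-eQTL.
#' @param r2_window numeric `(low, high)`: eligibility window for r^2 with
#'   the top SNP (default `c(0.05, 0.9)`).
#' @param max_snps maximum SNPs used (default 20).
#' @param eligibility_p per-SNP eQTL significance required (default
#'   1.57e-3).
#' @return list with `p_heidi` (NA when fewer than 3 eligible SNPs),
#'   `n_used`, and `flag` (`"ok"` or `"insufficient_snps"`).
#' @export
heidi_test <- function(eqtl_block, gwas_block, ld, top_snp,
                       r2_window = c(0.05, 0.9), max_snps = 20,
                       eligibility_p = 1.57e-3) {
  if (!top_snp %in% eqtl_block$snp) stop("top SNP absent from eQTL block")
  common <- intersect(intersect(eqtl_block$snp, gwas_block$snp), ld$snp_ids)
  if (!top_snp %in% common) stop("top SNP absent from GWAS block or LD")
  eq <- eqtl_block[match(common, eqtl_block$snp), , drop = FALSE]
  gw <- gwas_block[match(common, gwas_block$snp), , drop = FALSE]
  r_top <- ld$R[common, top_snp]
  r2_top <- r_top^2
  eligible <- common != top_snp &
    r2_top > r2_window[1] & r2_top < r2_window[2] &
    eq$pval < eligibility_p
  cand <- which(eligible)
  if (length(cand) > max_snps) {
    cand <- cand[order(eq$pval[cand], eq$snp[cand])][seq_len(max_snps)]
  }
  if (length(cand) < 3) {
    return(list(p_heidi = NA_real_, n_used = length(cand),
                flag = "insufficient_snps"))
  }
  # deterministic ordering so the result is invariant to block ordering
  cand <- cand[order(common[cand])]
  sel <- c(match(top_snp, common), cand)
  snps <- common[sel]
  R <- ld$R[snps, snps, drop = FALSE]
  bg <- gw$beta[sel]; sg <- gw$se[sel]
  be <- eq$beta[sel]; se <- eq$se[sel]
  k <- length(cand)

  # d_i = bg_i/be_i - bg_1/be_1, i = 2..k+1 (index 1 is the top SNP).
  # Jacobian wrt (bg, be); z-score correlations across SNPs equal LD r,
  # eQTL and GWAS samples independent.
  d <- bg[-1] / be[-1] - bg[1] / be[1]
  J_bg <- cbind(-1 / be[1], diag(1 / be[-1], k))
  J_be <- cbind(bg[1] / be[1]^2, diag(-bg[-1] / be[-1]^2, k))
  cov_bg <- R * tcrossprod(sg)
  cov_be <- R * tcrossprod(se)
  V <- J_bg %*% cov_bg %*% t(J_bg) + J_be %*% cov_be %*% t(J_be)
  sd_d <- sqrt(diag(V))
  T_obs <- sum((d / sd_d)^2)
  C <- V / tcrossprod(sd_d)
  lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  # Satterthwaite: T ~ c * chisq(nu) with c = sum(l^2)/sum(l),
  # nu = sum(l)^2/sum(l^2)
  cc <- sum(lam^2) / sum(lam)
  nu <- sum(lam)^2 / sum(lam^2)
  p <- stats::pchisq(T_obs / cc, df = nu, lower.tail = FALSE)
  list(p_heidi = p, n_used = k, flag = "ok")
}

#' SMR/HEIDI scan over candidate genes
#'
#' For each gene: restrict the eQTL data to the cis window, apply the MAF
#' filter (`maf > maf_min` retained, so MAF <= 0.01 is removed at the
#' default), harmonise against the outcome with the 0.2
#' allele-frequency-difference filter, pick the most significant eQTL at
#' `P < p_threshold`, run [smr_test()] and [heidi_test()], and flag
#' `heidi_pleiotropy` when `p_heidi < heidi_call`. Genes with no
#' qualifying eQTL are omitted (with a message).
#'
#' @param genes gene-region data.frame.
#' @param eqtl_list named list of eQTL `sumstats` per gene id.
#' @param gwas outcome `sumstats`.
#' @param ld_list named list of `ld_block`s per gene id.
#' @param config an [mr_config()].
#' @return data.frame with one row per analysable gene: gene_id, top_snp,
#'   b_smr, se_smr, p_smr, or, ci_low, ci_high, p_heidi, n_heidi_snps,
#'   flag.
#' @export
smr_gene_scan <- function(genes, eqtl_list, gwas, ld_list,
                          config = mr_config()) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    region <- genes[i, , drop = FALSE]
    g <- region$gene_id
    eq <- eqtl_list[[g]]
    if (is.null(eq)) next
    maf <- pmin(eq$eaf, 1 - eq$eaf)
    eq <- eq[maf > config$smr_maf_min, , drop = FALSE]
    w <- config$window_kb * 1000
    eq <- eq[eq$chrom == region$chrom & eq$pos >= region$start - w &
               eq$pos <= region$end + w, , drop = FALSE]
    h <- harmonise(eq, gwas, af_diff_threshold = config$smr_af_diff,
                   drop_palindromic = config$drop_palindromic)
    hk <- harmonised_kept(h)
    sig <- hk[hk$pval_exp < config$p_threshold, , drop = FALSE]
    if (nrow(sig) == 0) {
      message(sprintf("smr_gene_scan: %s omitted (no cis-eQTL at P < %g)",
                      g, config$p_threshold))
      next
    }
    top <- sig[order(sig$pval_exp, sig$snp)[1], , drop = FALSE]
    smr <- smr_test(top$beta_exp, top$se_exp, top$beta_out, top$se_out)
    eq_block <- data.frame(snp = hk$snp, beta = hk$beta_exp, se = hk$se_exp,
                           pval = hk$pval_exp, stringsAsFactors = FALSE)
    gw_block <- data.frame(snp = hk$snp, beta = hk$beta_out, se = hk$se_out,
                           pval = hk$pval_out, stringsAsFactors = FALSE)
    hd <- heidi_test(eq_block, gw_block, ld_list[[g]], top$snp,
                     r2_window = config$heidi_r2_window,
                     max_snps = config$heidi_max_snps,
                     eligibility_p = config$heidi_eligibility_p)
    flag <- if (hd$flag == "insufficient_snps") {
      "insufficient_snps"
    } else if (hd$p_heidi < config$heidi_call) {
      "heidi_pleiotropy"
    } else "pass"
    rows[[g]] <- data.frame(
      gene_id = g, top_snp = top$snp,
      b_smr = smr$b_smr, se_smr = smr$se_smr, p_smr = smr$p_smr,
      or = exp(smr$b_smr),
      ci_low = exp(smr$b_smr - config$ci_z * smr$se_smr),
      ci_high = exp(smr$b_smr + config$ci_z * smr$se_smr),
      p_heidi = hd$p_heidi, n_heidi_snps = hd$n_used, flag = flag,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}
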