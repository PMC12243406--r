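#' Pipeline configuration
#'
#' Central list of thresholds used across the pipeline. Defaults reproduce
#' the analysis settings: a +/- 1000 kb cis window with genome-wide
#' significance P < 5e-8 for instrument discovery; PLINK-style clumping at
#' r^2 0.001 within 10,000 kb; removal of SNPs associated with the outcome
#' at P < 5e-5; instrument F-statistic >= 10; the SMR stage's MAF > 0.01 and
#' allele-frequency-difference <= 0.2 filters with HEIDI per-SNP eligibility
#' at P < 1.57e-3 (chi-square(1) = 10) and a pleiotropy call at
#' P_HEIDI < 0.01; coloc priors p1 = p2 = 1e-4, p12 = 1e-5 with a
#' colocalisation call at PP(H4) > 0.7; FDR significance at 0.05.
#'
#' @param ... named overrides of any default listed below.
#' @return a named list of class `mr_config`.
#' @export
mr_config <- function(...) {
  cfg <- list(
    # instrument selection
    window_kb = 1000,
    p_threshold = 5e-8,
    clump_r2 = 0.001,
    clump_kb = 10000,
    p_outcome_threshold = 5e-5,
    f_min = 10,
    steiger_method = "z2",      # or "maf_beta"
    # harmonisation
    drop_palindromic = TRUE,
    af_diff_threshold = Inf,    # MR stage default; SMR stage uses smr_af_diff
    # SMR / HEIDI
    smr_af_diff = 0.2,
    smr_maf_min = 0.01,
    smr_alpha = 0.05,
    heidi_r2_window = c(0.05, 0.9),
    heidi_max_snps = 20,
    heidi_eligibility_p = 1.57e-3,
    heidi_call = 0.01,
    heidi_gates_smr = TRUE,     # HEIDI failure vetoes the SMR criterion
    # colocalisation
    coloc_p1 = 1e-4,
    coloc_p2 = 1e-4,
    coloc_p12 = 1e-5,
    prior_sd_quant = 0.15,
    prior_sd_binary = 0.2,
    pph4_threshold = 0.7,
    # significance
    mr_alpha_fdr = 0.05,
    endo_alpha = 0.05,
    phewas_alpha_fdr = 0.05,
    phewas_case_min = 500,
    ci_z = 1.96
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown config key(s): ",
                              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  class(cfg) <- "mr_config"
  cfg
}
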