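#' Harmonise exposure and outcome summary statistics
#'
#' Joins two `sumstats` tables on SNP id and re-orients each outcome record
#' onto the exposure's effect allele. For each shared SNP the outcome is
#' either kept as-is (`kept`), sign-flipped when its alleles are the reverse
#' of the exposure's (`flipped`, with `beta -> -beta` and `eaf -> 1 - eaf`),
#' or dropped: `dropped_allele_mismatch` when the two allele pairs differ as
#' unordered sets, `dropped_palindromic` for A/T and C/G SNPs when
#' `drop_palindromic` is on (strand cannot be resolved from two summary
#' files alone), and `dropped_af_diff` when the post-orientation
#' effect-allele frequencies differ by more than `af_diff_threshold`.
#'
#' @param exposure,outcome `sumstats` data.frames.
#' @param af_diff_threshold maximum tolerated |eaf difference| after
#'   orientation; `Inf` disables the filter (the default used in the
#'   proteome-wide MR stage; the SMR stage uses 0.2).
#' @param drop_palindromic drop A/T and C/G SNPs (default TRUE).
#' @return data.frame of class `harmonised` with one row per shared SNP:
#'   `snp, chrom, pos, ea, oa, eaf_exp, beta_exp, se_exp, pval_exp, n_exp,
#'   eaf_out, beta_out, se_out, pval_out, n_out, n_cases_out, status`.
#'   Rows with `status` in `kept`/`flipped` carry identical effect alleles
#'   for both traits.
#' @export
harmonise <- function(exposure, outcome, af_diff_threshold = Inf,
                      drop_palindromic = TRUE) {
  m <- match(exposure$snp, outcome$snp)
  keep <- !is.na(m)
  ex <- exposure[keep, , drop = FALSE]
  ou <- outcome[m[keep], , drop = FALSE]
  n <- nrow(ex)

  status <- rep("kept", n)
  same <- ou$ea == ex$ea & ou$oa == ex$oa
  rev_ <- ou$ea == ex$oa & ou$oa == ex$ea
  status[!same & !rev_] <- "dropped_allele_mismatch"

  pal <- (ex$ea == "A" & ex$oa == "T") | (ex$ea == "T" & ex$oa == "A") |
    (ex$ea == "C" & ex$oa == "G") | (ex$ea == "G" & ex$oa == "C")
  if (drop_palindromic) {
    status[status != "dropped_allele_mismatch" & pal] <- "dropped_palindromic"
  }

  flip <- rev_ & status == "kept"
  beta_out <- ifelse(flip, -ou$beta, ou$beta)
  eaf_out <- ifelse(flip, 1 - ou$eaf, ou$eaf)
  status[flip] <- "flipped"

  live <- status %in% c("kept", "flipped")
  af_bad <- live & abs(ex$eaf - eaf_out) > af_diff_threshold
  status[af_bad] <- "dropped_af_diff"

  out <- data.frame(
    snp = ex$snp, chrom = ex$chrom, pos = ex$pos, ea = ex$ea, oa = ex$oa,
    eaf_exp = ex$eaf, beta_exp = ex$beta, se_exp = ex$se,
    pval_exp = ex$pval, n_exp = ex$n,
    eaf_out = eaf_out, beta_out = beta_out, se_out = ou$se,
    pval_out = ou$pval, n_out = ou$n, n_cases_out = ou$n_cases,
    status = status, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("harmonised", "data.frame")
  out
}

#' Retained rows of a harmonised table
#'
#' @param h a `harmonised` data.frame.
#' @return the rows with status `kept` or `flipped`.
#' @export
harmonised_kept <- function(h) {
  out <- h[h$status %in% c("kept", "flipped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
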