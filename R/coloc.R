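#' Wakefield log approximate Bayes factor for one SNP
#'
#' With sampling variance `V = se^2`, effect-size prior variance
#' `W = prior_sd^2` and `z = beta / se`, the log approximate Bayes factor
#' for association versus the null is
#' `log ABF = 0.5 * log(V / (V + W)) + (z^2 / 2) * W / (V + W)`.
#'
#' @param beta,se effect estimate and standard error (`se > 0`).
#' @param prior_sd prior SD of the true effect (> 0); 0.2 is a reasonable
#'   default for log-OR effects, 0.15 for quantitative traits.
#' @return log approximate Bayes factor (vectorised).
#' @export
abf <- function(beta, se, prior_sd) {
  if (any(prior_sd <= 0)) stop("prior_sd must be positive")
  if (any(se <= 0)) stop("se must be positive")
  V <- se^2
  W <- prior_sd^2
  z <- beta / se
  0.5 * log(V / (V + W)) + (z^2 / 2) * W / (V + W)
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Bayesian colocalisation posteriors over five hypotheses
#'
#' Evaluates, from per-SNP approximate Bayes factors over a shared locus,
#' the posterior probabilities of: H0 no association with either trait;
#' H1 association with trait 1 only; H2 trait 2 only; H3 both traits,
#' distinct causal variants; H4 both traits, one shared causal variant.
#' Assumes at most one causal variant per trait in the locus. All sums are
#' computed in log space.
#'
#' @param trait1,trait2 `sumstats` data.frames over the same SNPs in the
#'   same order (harmonised to a common effect allele).
#' @param priors numeric `(p1, p2, p12)`: per-SNP prior probabilities of
#'   association with trait 1, trait 2, and both (defaults 1e-4, 1e-4,
#'   1e-5).
#' @param prior_sds numeric `(sd1, sd2)` effect-size prior SDs; when NULL,
#'   chosen per trait from `trait_type` (0.2 binary, 0.15 quantitative).
#' @param config an [mr_config()] supplying the defaults above.
#' @return list of class `coloc_result`: `pp` (named numeric of length 5
#'   summing to one), `n_snps`, `priors`, `call` (logical, PP(H4) above
#'   the configured threshold).
#' @export
coloc_posteriors <- function(trait1, trait2, priors = NULL, prior_sds = NULL,
                             config = mr_config()) {
  if (is.null(priors)) priors <- c(config$coloc_p1, config$coloc_p2,
                                   config$coloc_p12)
  if (nrow(trait1) != nrow(trait2) || !all(trait1$snp == trait2$snp)) {
    stop("trait1 and trait2 must cover the same SNPs in the same order")
  }
  n <- nrow(trait1)
  if (n < 2) warning("coloc with < 2 SNPs: H3 is degenerate")
  if (is.null(prior_sds)) {
    pick <- function(tt) if (identical(tt[1], "binary")) config$prior_sd_binary
      else config$prior_sd_quant
    prior_sds <- c(pick(trait1$trait_type), pick(trait2$trait_type))
  }
  l1 <- abf(trait1$beta, trait1$se, prior_sds[1])
  l2 <- abf(trait2$beta, trait2$se, prior_sds[2])
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  p1 <- priors[1]; p2 <- priors[2]; p12 <- priors[3]
  logL <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = log(p1) + log(p2) + logdiffexp(s1 + s2, s12),
    h4 = log(p12) + s12
  )
  denom <- logsumexp(logL)
  pp <- exp(logL - denom)
  names(pp) <- c("pp_h0", "pp_h1", "pp_h2", "pp_h3", "pp_h4")
  structure(list(pp = pp, n_snps = n,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 call = unname(pp["pp_h4"] > config$pph4_threshold)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalisation over %d SNPs (p1=%g, p2=%g, p12=%g)\n",
              x$n_snps, x$priors["p1"], x$priors["p2"], x$priors["p12"]))
  print(round(x$pp, 4))
  cat(if (x$call) "call: colocalised\n" else "call: not colocalised\n")
  invisible(x)
}

#' Colocalise one gene's exposure signal with the outcome
#'
#' Takes all SNPs in the gene's cis window (no p-value filtering; the ABF
#' sums need the full local SNP set), harmonises the two traits, and runs
#' [coloc_posteriors()].
#'
#' @param exposure,outcome `sumstats` data.frames.
#' @param region gene region.
#' @param config an [mr_config()].
#' @return a `coloc_result`, or NULL when fewer than 2 shared SNPs remain.
#' @export
coloc_gene <- function(exposure, outcome, region, config = mr_config()) {
  w <- config$window_kb * 1000
  cis <- exposure[exposure$chrom == region$chrom &
                    exposure$pos >= region$start - w &
                    exposure$pos <= region$end + w, , drop = FALSE]
  h <- harmonise(cis, outcome, af_diff_threshold = config$af_diff_threshold,
                 drop_palindromic = config$drop_palindromic)
  hk <- harmonised_kept(h)
  if (nrow(hk) < 2) return(NULL)
  t1 <- data.frame(snp = hk$snp, beta = hk$beta_exp, se = hk$se_exp,
                   trait_type = cis$trait_type[match(hk$snp, cis$snp)],
                   stringsAsFactors = FALSE)
  t2 <- data.frame(snp = hk$snp, beta = hk$beta_out, se = hk$se_out,
                   trait_type = outcome$trait_type[match(hk$snp, outcome$snp)],
                   stringsAsFactors = FALSE)
  coloc_posteriors(t1, t2, config = config)
}
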