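# Shared builders for small in-memory fixtures.

make_sumstats <- function(beta, se, snp = sprintf("rs%03d", seq_along(beta)),
                          chrom = "1", pos = seq_along(beta) * 1000L,
                          ea = "A", oa = "G", eaf = 0.3, n = 10000,
                          n_cases = NA_real_, trait_type = "quantitative") {
  z <- beta / se
  sumstats(snp = snp, chrom = chrom, pos = pos, ea = ea, oa = oa, eaf = eaf,
           beta = beta, se = se, pval = pmax(2 * pnorm(-abs(z)), 1e-320),
           n = n, n_cases = n_cases, trait_type = trait_type)
}

# random harmonised pairs with given instrument count
make_pairs <- function(n, seed = 1, n_samp = 20000) {
  set.seed(seed)
  data.frame(
    snp = sprintf("rs%03d", seq_len(n)), chrom = "1",
    pos = seq_len(n) * 1000L, ea = "A", oa = "G",
    eaf_exp = runif(n, 0.1, 0.5),
    beta_exp = runif(n, 0.1, 0.6) * sample(c(-1, 1), n, replace = TRUE),
    se_exp = runif(n, 0.01, 0.05),
    pval_exp = runif(n, 1e-20, 1e-9), n_exp = n_samp,
    eaf_out = runif(n, 0.1, 0.5),
    beta_out = rnorm(n, 0, 0.1), se_out = runif(n, 0.01, 0.05),
    pval_out = runif(n, 0.05, 1), n_out = n_samp,
    n_cases_out = NA_real_,
    status = "kept", stringsAsFactors = FALSE
  )
}

# turn the outcome side of a harmonised table back into a sumstats table
outcome_from_harmonised <- function(h) {
  df <- data.frame(snp = h$snp, chrom = h$chrom, pos = h$pos,
                   ea = h$ea, oa = h$oa, eaf = h$eaf_out, beta = h$beta_out,
                   se = h$se_out, pval = h$pval_out, n = h$n_out,
                   n_cases = h$n_cases_out, trait_type = "quantitative",
                   stringsAsFactors = FALSE)
  class(df) <- c("sumstats", "data.frame")
  df
}

shared_scenario <- function(theta, seed, effects = list(c(50, 0.04), c(150, 0.04))) {
  scenario(causal_exposure = effects, theta = theta,
           n_exposure = 50000, n_outcome = 50000,
           outcome_type = "quantitative", seed = seed)
}

as_named_list <- function(x, name) stats::setNames(list(x), name)
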