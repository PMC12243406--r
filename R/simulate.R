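#' Define a synthetic-locus scenario
#'
#' Full parameterisation of one simulated cis-QTL locus: the LD structure,
#' the causal architecture linking exposure (protein or expression level)
#' and outcome (binary disease or quantitative endophenotype), sample
#' sizes and the random seed. Summary statistics are later drawn from the
#' multivariate-normal model for GWAS z-scores under LD (see
#' [simulate_locus()]).
#'
#' Defaults emulate the study conditions this package targets: a plasma
#' pQTL panel of 35,559 individuals, an eQTL panel of 31,864, and a
#' binary disease outcome whose multi-trait GWAS has power equivalent to
#' 20,582 cases and 119,318 controls; the test locus is 200 SNPs under
#' AR(1) LD with rho = 0.95 and MAFs uniform on (0.05, 0.5).
#'
#' @param causal_exposure list of `c(index, effect)` pairs: causal SNPs
#'   for the exposure with joint (conditional) effects in SD units. Under
#'   the `reverse` architecture these same variants act directly on the
#'   outcome instead.
#' @param theta true causal effect of exposure on outcome (log-OR per SD
#'   for binary outcomes, SD units otherwise); used by the `shared` and
#'   `pleiotropy` architectures.
#' @param architecture list with `type` one of `"shared"`, `"distinct"`,
#'   `"pleiotropy"`, `"reverse"`; `distinct` takes `causal_outcome` (same
#'   format as `causal_exposure`), `pleiotropy` takes `direct_effects`
#'   (per-SNP direct outcome effects, same format), `reverse` takes `phi`
#'   (effect of outcome liability on exposure).
#' @param n_snps number of SNPs in the locus.
#' @param ld_model list: `list(type = "ar1", rho = 0.95)` or
#'   `list(type = "block", sizes =, within_r =)`.
#' @param n_exposure,n_outcome sample sizes.
#' @param n_cases_outcome case count for binary outcomes (NA otherwise).
#' @param outcome_type `"binary"` or `"quantitative"`.
#' @param maf_range MAF bounds, within (0, 0.5].
#' @param chrom,pos_start,pos_step genomic placement of the SNP grid.
#' @param gene_id label for the synthetic gene.
#' @param seed integer random seed.
#' @return list of class `scenario`.
#' @export
scenario <- function(causal_exposure, theta,
                     architecture = list(type = "shared"),
                     n_snps = 200,
                     ld_model = list(type = "ar1", rho = 0.95),
                     n_exposure = 35559,
                     n_outcome = 139900, n_cases_outcome = 20582,
                     outcome_type = c("binary", "quantitative"),
                     maf_range = c(0.05, 0.5),
                     chrom = "1", pos_start = 1e6, pos_step = 5000,
                     gene_id = "GENE1", seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  if (!is.list(causal_exposure)) causal_exposure <- list(causal_exposure)
  idx <- vapply(causal_exposure, `[`, numeric(1), 1)
  if (any(idx < 1 | idx > n_snps)) stop("causal index outside the locus")
  if (ld_model$type == "ar1" && abs(ld_model$rho) >= 1) {
    stop("AR(1) rho must lie in (-1, 1)")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  arch_types <- c("shared", "distinct", "pleiotropy", "reverse")
  if (!architecture$type %in% arch_types) {
    stop("architecture type must be one of ", paste(arch_types, collapse = ", "))
  }
  if (outcome_type == "binary" &&
      (is.na(n_cases_outcome) || n_cases_outcome <= 0 ||
       n_cases_outcome >= n_outcome)) {
    stop("binary outcomes need 0 < n_cases_outcome < n_outcome")
  }
  structure(list(
    causal_exposure = causal_exposure, theta = theta,
    architecture = architecture, n_snps = as.integer(n_snps),
    ld_model = ld_model, n_exposure = n_exposure, n_outcome = n_outcome,
    n_cases_outcome = if (outcome_type == "binary") n_cases_outcome else NA_real_,
    outcome_type = outcome_type, maf_range = maf_range, chrom = chrom,
    pos_start = pos_start, pos_step = pos_step, gene_id = gene_id,
    seed = as.integer(seed)
  ), class = "scenario")
}

effects_vector <- function(pairs, n_snps) {
  v <- numeric(n_snps)
  for (p in pairs) v[p[1]] <- v[p[1]] + p[2]
  v
}

scenario_ld_matrix <- function(s) {
  if (s$ld_model$type == "ar1") {
    ld_ar1(s$n_snps, s$ld_model$rho)
  } else {
    ld_blockdiag(s$ld_model$sizes, s$ld_model$within_r)
  }
}

#' Simulate one locus of summary statistics under a scenario
#'
#' Draws exposure and outcome GWAS summary statistics directly from the
#' summary-level multivariate-normal model: with LD matrix `R` and joint
#' causal effects `beta`, marginal effects are `b = R beta`, per-SNP SEs
#' are `1/sqrt(n)` for quantitative traits (effects in SD units of
#' standardised genotype and phenotype) and `1/sqrt(n * phi * (1 - phi))`
#' on the log-OR scale for binary outcomes with case fraction `phi`, and
#' z-scores are drawn as `z ~ MVN(b / se, R)` with independent noise for
#' the two traits. Outcome marginal effects follow the scenario's causal
#' architecture: `shared` gives `b_out = theta * b_exp`; `distinct` gives
#' `b_out = R gamma` for outcome-specific causal variants; `pleiotropy`
#' adds direct effects, `b_out = theta * b_exp + R delta`; `reverse` puts
#' the causal variants on the outcome and regenerates the exposure as
#' `b_exp = phi * b_out`. A numerically singular `R` has its diagonal
#' jittered by 1e-8 (with a message) before factorisation.
#'
#' The global RNG state is saved and restored; the draw depends only on
#' the scenario's `seed`.
#'
#' @param s a [scenario()].
#' @return list of class `simulated_locus`: `ld` (an `ld_block`),
#'   `exposure_stats` and `outcome_stats` (`sumstats`), `region`
#'   (synthetic gene region covering the locus centre), and `truth` (the
#'   scenario plus realised marginal effect vectors).
#' @export
simulate_locus <- function(s) {
  stopifnot(inherits(s, "scenario"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(s$seed)

  n <- s$n_snps
  R <- scenario_ld_matrix(s)
  U <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(U)) {
    message("simulate_locus: singular LD matrix; jittering diagonal by 1e-8")
    R <- R + diag(1e-8, n)
    R <- R / sqrt(tcrossprod(diag(R)))
    U <- chol(R)
  }
  snps <- sprintf("rs%05d", seq_len(n))
  ld <- ld_block(snps, R)
  pos <- as.integer(s$pos_start + (seq_len(n) - 1) * s$pos_step)
  maf <- stats::runif(n, s$maf_range[1], s$maf_range[2])
  # non-palindromic allele pairs so strand-ambiguity filtering never bites
  ea_choices <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  pick <- sample.int(4, n, replace = TRUE)
  ea <- ea_choices[pick, 1]
  oa <- ea_choices[pick, 2]

  beta_joint <- effects_vector(s$causal_exposure, n)
  b_drive <- drop(R %*% beta_joint)

  arch <- s$architecture
  if (arch$type == "shared") {
    b_exp <- b_drive
    b_out <- s$theta * b_exp
  } else if (arch$type == "distinct") {
    b_exp <- b_drive
    b_out <- drop(R %*% effects_vector(arch$causal_outcome, n))
  } else if (arch$type == "pleiotropy") {
    b_exp <- b_drive
    b_out <- s$theta * b_exp + drop(R %*% effects_vector(arch$direct_effects, n))
  } else { # reverse: causal variants act on the outcome
    b_out <- b_drive
    b_exp <- arch$phi * b_out
  }

  se_exp <- rep(1 / sqrt(s$n_exposure), n)
  se_out <- if (s$outcome_type == "binary") {
    cf <- s$n_cases_outcome / s$n_outcome
    rep(1 / sqrt(s$n_outcome * cf * (1 - cf)), n)
  } else {
    rep(1 / sqrt(s$n_outcome), n)
  }

  z_exp <- b_exp / se_exp + drop(crossprod(U, stats::rnorm(n)))
  z_out <- b_out / se_out + drop(crossprod(U, stats::rnorm(n)))

  mk <- function(z, se, n_samp, n_cases, type) {
    beta <- z * se
    pval <- pmax(2 * stats::pnorm(-abs(z)), 1e-320)
    df <- data.frame(snp = snps, chrom = s$chrom, pos = pos, ea = ea, oa = oa,
                     eaf = maf, beta = beta, se = se, pval = pval,
                     n = n_samp, n_cases = n_cases, trait_type = type,
                     stringsAsFactors = FALSE)
    class(df) <- c("sumstats", "data.frame")
    df
  }
  exposure_stats <- mk(z_exp, se_exp, s$n_exposure, NA_real_, "quantitative")
  outcome_stats <- mk(z_out, se_out, s$n_outcome, s$n_cases_outcome,
                      s$outcome_type)

  mid <- pos[ceiling(n / 2)]
  region <- gene_region(s$gene_id, s$chrom, max(1, mid - 10000), mid + 10000)

  truth <- unclass(s)
  truth$b_exp_marginal <- b_exp
  truth$b_out_marginal <- b_out
  truth$beta_joint <- beta_joint

  structure(list(ld = ld, exposure_stats = exposure_stats,
                 outcome_stats = outcome_stats, region = region,
                 truth = truth),
            class = "simulated_locus")
}

#' Simulate a catalogue of binary outcomes at a fixed SNP set
#'
#' Builds a PheWAS-style outcome catalogue over the SNPs of an LD block:
#' each phenotype gets an independent summary-statistics draw
#' `z ~ MVN(b_marginal / se, R)`. With the default `b_marginal = 0` all
#' outcomes are null, which is the ground truth for testing FDR behaviour
#' of a phenome-wide scan.
#'
#' @param ld an `ld_block`.
#' @param template a `sumstats` over the same SNPs supplying chrom, pos,
#'   alleles and eaf (e.g. the exposure stats of a simulated locus).
#' @param n_outcomes number of phenotypes.
#' @param n_total total sample size per phenotype.
#' @param case_range range from which case counts are drawn (log-uniform).
#' @param b_marginal per-SNP true marginal log-OR vector (default all 0),
#'   or a named list mapping phenotype index to such a vector.
#' @param categories category labels recycled across phenotypes.
#' @param seed integer seed.
#' @return list of catalogue entries (`phenotype_id`, `category`,
#'   `n_cases`, `stats`) as consumed by [phewas_scan()].
#' @export
simulate_outcome_catalogue <- function(ld, template, n_outcomes,
                                       n_total = 200000,
                                       case_range = c(501, 20000),
                                       b_marginal = NULL,
                                       categories = "circulatory system",
                                       seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  stopifnot(all(template$snp == ld$snp_ids))
  n <- length(ld$snp_ids)
  U <- chol(ld$R + diag(1e-10, n))
  cats <- rep_len(categories, n_outcomes)
  out <- vector("list", n_outcomes)
  for (i in seq_len(n_outcomes)) {
    n_cases <- round(exp(stats::runif(1, log(case_range[1]),
                                      log(case_range[2]))))
    cf <- n_cases / n_total
    se <- rep(1 / sqrt(n_total * cf * (1 - cf)), n)
    b <- if (is.null(b_marginal)) {
      numeric(n)
    } else if (is.list(b_marginal)) {
      if (!is.null(b_marginal[[as.character(i)]]))
        b_marginal[[as.character(i)]] else numeric(n)
    } else b_marginal
    z <- b / se + drop(crossprod(U, stats::rnorm(n)))
    beta <- z * se
    stats_df <- data.frame(
      snp = template$snp, chrom = template$chrom, pos = template$pos,
      ea = template$ea, oa = template$oa, eaf = template$eaf,
      beta = beta, se = se, pval = pmax(2 * stats::pnorm(-abs(z)), 1e-320),
      n = n_total, n_cases = n_cases, trait_type = "binary",
      stringsAsFactors = FALSE
    )
    class(stats_df) <- c("sumstats", "data.frame")
    out[[i]] <- list(phenotype_id = sprintf("pheno_%04d", i),
                     category = cats[i], n_cases = n_cases, stats = stats_df)
  }
  out
}
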