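#' Select cis SNPs for a gene
#'
#' Retains SNPs on the gene's chromosome whose position lies inside
#' `[start - window, end + window]` (boundaries inclusive) and whose
#' exposure p-value is strictly below `p_threshold`.
#'
#' @param records a `sumstats` data.frame.
#' @param region one-row gene-region data.frame (see [gene_region()]).
#' @param window_kb cis-window half-width in kilobases (default 1000).
#' @param p_threshold significance threshold, strict `<` (default 5e-8).
#' @return the selected rows, genomic order preserved.
#' @export
select_cis <- function(records, region, window_kb = 1000, p_threshold = 5e-8) {
  w <- as.numeric(window_kb) * 1000
  keep <- records$chrom == region$chrom &
    records$pos >= region$start - w &
    records$pos <= region$end + w &
    records$pval < p_threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: SNPs are ranked by ascending p-value (ties broken
#' lexicographically by SNP id for determinism); the most significant
#' unclaimed SNP becomes an index and claims every unclaimed SNP within
#' `clump_kb` kilobases whose squared correlation with it is at least
#' `clump_r2`. Index SNPs are returned in genomic order. SNPs absent from
#' the LD block are dropped with a warning.
#'
#' @param records a `sumstats` data.frame.
#' @param ld an `ld_block` covering the records.
#' @param clump_r2 r-squared threshold (default 0.001); pairs at or above it
#'   are considered dependent.
#' @param clump_kb distance frame in kilobases (default 10000), measured
#'   between SNP positions.
#' @return the index SNPs as a `sumstats` subset, in genomic order.
#' @export
clump <- function(records, ld, clump_r2 = 0.001, clump_kb = 10000) {
  present <- records$snp %in% ld$snp_ids
  if (any(!present)) {
    warning(sprintf("clump: dropping %d SNP(s) absent from the LD reference",
                    sum(!present)))
    records <- records[present, , drop = FALSE]
  }
  if (nrow(records) == 0) return(records)
  ord <- order(records$pval, records$snp)
  x <- records[ord, , drop = FALSE]
  R2 <- ld$R[x$snp, x$snp, drop = FALSE]^2
  maxdist <- as.numeric(clump_kb) * 1000
  n <- nrow(x)
  claimed <- logical(n)
  index <- logical(n)
  for (i in seq_len(n)) {
    if (claimed[i]) next
    index[i] <- TRUE
    claimed[i] <- TRUE
    hit <- !claimed & abs(x$pos - x$pos[i]) <= maxdist & R2[i, ] >= clump_r2
    claimed[hit] <- TRUE
  }
  out <- x[index, , drop = FALSE]
  out <- out[order(out$pos, out$snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove instruments directly associated with the outcome
#'
#' Drops harmonised pairs whose outcome p-value is strictly below
#' `p_outcome_threshold`; pairs at or above the threshold are retained.
#'
#' @param pairs a `harmonised` data.frame (retained rows).
#' @param p_outcome_threshold significance level (default 5e-5).
#' @return filtered pairs.
#' @export
exclude_outcome_associated <- function(pairs, p_outcome_threshold = 5e-5) {
  out <- pairs[pairs$pval_out >= p_outcome_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Steiger directionality filter
#'
#' Guards against reverse causation by removing instruments that explain
#' more variance in the outcome than in the exposure. The per-trait
#' explained-variance proxy is `r2 = z^2 / (z^2 + n - 2)` with `z = beta/se`
#' (method `"z2"`, the default), or `2 * maf * (1 - maf) * beta^2` (method
#' `"maf_beta"`). A SNP is retained iff `r2_exposure >= r2_outcome` (ties
#' retained). SNPs with `n <= 2` on either trait are dropped.
#'
#' @param pairs a `harmonised` data.frame (retained rows).
#' @param method `"z2"` or `"maf_beta"`.
#' @return filtered pairs; dropped SNPs and reasons are recorded in
#'   `attr(x, "dropped")`.
#' @export
steiger_filter <- function(pairs, method = c("z2", "maf_beta")) {
  method <- match.arg(method)
  if (nrow(pairs) == 0) return(pairs)
  if (method == "z2") {
    bad_n <- !is.finite(pairs$n_exp) | !is.finite(pairs$n_out) |
      pairs$n_exp <= 2 | pairs$n_out <= 2
    z_exp <- pairs$beta_exp / pairs$se_exp
    z_out <- pairs$beta_out / pairs$se_out
    r2_exp <- z_exp^2 / (z_exp^2 + pairs$n_exp - 2)
    r2_out <- z_out^2 / (z_out^2 + pairs$n_out - 2)
  } else {
    bad_n <- rep(FALSE, nrow(pairs))
    maf_exp <- pmin(pairs$eaf_exp, 1 - pairs$eaf_exp)
    maf_out <- pmin(pairs$eaf_out, 1 - pairs$eaf_out)
    r2_exp <- 2 * maf_exp * (1 - maf_exp) * pairs$beta_exp^2
    r2_out <- 2 * maf_out * (1 - maf_out) * pairs$beta_out^2
  }
  keep <- !bad_n & r2_exp >= r2_out
  dropped <- data.frame(
    snp = pairs$snp[!keep],
    reason = ifelse(bad_n[!keep], "n <= 2", "more variance in outcome"),
    stringsAsFactors = FALSE
  )
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Instrument-strength (F-statistic) filter
#'
#' Per-SNP approximate F-statistic `F = (beta_exp / se_exp)^2`; instruments
#' with `F < f_min` are removed.
#'
#' @param pairs a `harmonised` data.frame (retained rows).
#' @param f_min minimum F (default 10); retained iff `F >= f_min`.
#' @return filtered pairs.
#' @export
f_statistic_filter <- function(pairs, f_min = 10) {
  f <- (pairs$beta_exp / pairs$se_exp)^2
  out <- pairs[f >= f_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cis selection and LD clumping of exposure SNPs
#'
#' The outcome-independent half of instrument selection: cis-window and
#' significance filtering followed by greedy clumping. Useful when one
#' exposure is tested against many outcomes (endophenotype MR, PheWAS).
#'
#' @param exposure exposure `sumstats`.
#' @param region gene region.
#' @param ld `ld_block` for the locus.
#' @param config an [mr_config()].
#' @return list with `snps` (clumped exposure records) and `filter_log`.
#' @export
cis_clump <- function(exposure, region, ld, config = mr_config()) {
  cis <- select_cis(exposure, region, config$window_kb, config$p_threshold)
  log <- data.frame(snp = character(0), filter = character(0),
                    stringsAsFactors = FALSE)
  missing_ld <- setdiff(cis$snp, ld$snp_ids)
  if (length(missing_ld)) {
    log <- rbind(log, data.frame(snp = missing_ld, filter = "missing_ld",
                                 stringsAsFactors = FALSE))
  }
  clumped <- suppressWarnings(clump(cis, ld, config$clump_r2, config$clump_kb))
  clumped_out <- setdiff(setdiff(cis$snp, missing_ld), clumped$snp)
  if (length(clumped_out)) {
    log <- rbind(log, data.frame(snp = clumped_out, filter = "clump",
                                 stringsAsFactors = FALSE))
  }
  list(snps = clumped, filter_log = log)
}

#' Full instrument-selection pass for one gene
#'
#' Applies, in order: cis-window + significance selection, LD clumping,
#' harmonisation with the outcome, Steiger directionality filtering,
#' exclusion of SNPs directly associated with the outcome, and the
#' F-statistic strength filter. Every SNP entering the pass is either
#' retained in the returned pairs or recorded in the filter log, so that
#' `n_input == n_retained + nrow(filter_log)`.
#'
#' @param exposure exposure `sumstats` (protein or expression trait).
#' @param outcome outcome `sumstats` (disease or endophenotype).
#' @param region one-row gene-region data.frame.
#' @param ld `ld_block` covering the locus.
#' @param config an [mr_config()].
#' @param clumped optional precomputed result of [cis_clump()] for this
#'   exposure/region/ld (avoids re-clumping across many outcomes).
#' @return list of class `instrument_set`: `gene_id`, `pairs` (retained
#'   harmonised rows), `filter_log` (snp, filter), `n_input`, `window_kb`,
#'   `p_threshold`.
#' @export
select_instruments <- function(exposure, outcome, region, ld,
                               config = mr_config(), clumped = NULL) {
  if (is.null(clumped)) clumped <- cis_clump(exposure, region, ld, config)
  log <- clumped$filter_log
  n_input <- nrow(clumped$snps) + nrow(log)
  add_log <- function(snps, filter) {
    if (length(snps)) {
      log <<- rbind(log, data.frame(snp = snps, filter = filter,
                                    stringsAsFactors = FALSE))
    }
  }

  h <- harmonise(clumped$snps, outcome,
                 af_diff_threshold = config$af_diff_threshold,
                 drop_palindromic = config$drop_palindromic)
  add_log(setdiff(clumped$snps$snp, h$snp), "missing_outcome")
  dropped_h <- h$snp[!h$status %in% c("kept", "flipped")]
  if (length(dropped_h)) {
    for (s in dropped_h) add_log(s, h$status[h$snp == s])
  }
  pairs <- harmonised_kept(h)

  st <- steiger_filter(pairs, method = config$steiger_method)
  add_log(setdiff(pairs$snp, st$snp), "steiger")

  oc <- exclude_outcome_associated(st, config$p_outcome_threshold)
  add_log(setdiff(st$snp, oc$snp), "outcome_associated")

  fs <- f_statistic_filter(oc, config$f_min)
  add_log(setdiff(oc$snp, fs$snp), "weak_instrument")

  structure(list(gene_id = region$gene_id, pairs = fs, filter_log = log,
                 n_input = n_input, window_kb = config$window_kb,
                 p_threshold = config$p_threshold),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d retained of %d cis SNP(s)\n",
              x$gene_id, nrow(x$pairs), x$n_input))
  if (nrow(x$filter_log)) {
    tab <- table(x$filter_log$filter)
    cat("  removed:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                            collapse = ", "), "\n")
  }
  invisible(x)
}
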