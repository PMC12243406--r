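#' Construct a summary-statistics table
#'
#' A `sumstats` object is a plain `data.frame` with one row per SNP holding
#' the marginal association of that SNP with a single trait, oriented to the
#' effect allele. Effects are on the log odds-ratio scale for binary traits
#' and in standard-deviation units for quantitative traits.
#'
#' @param snp character vector of SNP identifiers (must be unique).
#' @param chrom chromosome labels.
#' @param pos 1-based base-pair positions.
#' @param ea,oa effect and other alleles (single characters among A/C/G/T;
#'   lower case is accepted and normalised to upper case).
#' @param eaf effect-allele frequency in \[0, 1\].
#' @param beta per-allele effect estimate.
#' @param se standard error of `beta` (> 0).
#' @param pval two-sided p-value in (0, 1].
#' @param n total sample size.
#' @param n_cases number of cases for binary traits (NA otherwise).
#' @param trait_type `"quantitative"` or `"binary"`.
#'
#' @return A `data.frame` of class `c("sumstats", "data.frame")`.
#' @export
sumstats <- function(snp, chrom, pos, ea, oa, eaf, beta, se, pval, n,
                     n_cases = NA_real_, trait_type = "quantitative") {
  trait_type <- match.arg(trait_type, c("quantitative", "binary"))
  df <- data.frame(
    snp = as.character(snp), chrom = as.character(chrom),
    pos = as.integer(pos),
    ea = toupper(as.character(ea)), oa = toupper(as.character(oa)),
    eaf = as.numeric(eaf), beta = as.numeric(beta), se = as.numeric(se),
    pval = as.numeric(pval), n = as.numeric(n),
    n_cases = as.numeric(n_cases),
    trait_type = trait_type,
    stringsAsFactors = FALSE
  )
  bad <- validate_sumstats(df)
  if (any(bad$drop)) {
    stop("invalid summary-statistic rows: ",
         paste(unique(bad$reason[bad$drop]), collapse = ", "))
  }
  class(df) <- c("sumstats", "data.frame")
  df
}

#' Validate rows of a summary-statistics table
#'
#' Checks each row against the record invariants: alleles are single A/C/G/T
#' characters and differ, `se > 0`, `eaf` in \[0, 1\], `pval` in (0, 1], and
#' (when finite) `pval` agrees with the normal approximation
#' `2 * pnorm(-|beta/se|)` within 10\% relative tolerance. Indels and
#' multi-allelic records fail the single-character allele check.
#'
#' @param df data.frame with sumstats columns.
#' @param check_pval logical; verify the p-value/z-score consistency check.
#' @return list with logical vector `drop` and character vector `reason`.
#' @keywords internal
validate_sumstats <- function(df, check_pval = TRUE) {
  n <- nrow(df)
  drop <- logical(n)
  reason <- character(n)
  flag <- function(i, why) {
    newly <- i & !drop
    drop[newly] <<- TRUE
    reason[newly] <<- why
  }
  ok_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  flag(!is.finite(df$beta) | !is.finite(df$se), "non-numeric beta/se")
  flag(!drop & df$se <= 0, "se <= 0")
  flag(!ok_allele(df$ea) | !ok_allele(df$oa), "allele not a single A/C/G/T base")
  flag(!drop & df$ea == df$oa, "identical alleles")
  flag(!is.finite(df$eaf) | df$eaf < 0 | df$eaf > 1, "eaf outside [0,1]")
  flag(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1, "pval outside (0,1]")
  if (check_pval) {
    z <- abs(df$beta / df$se)
    p_norm <- 2 * stats::pnorm(-z)
    # skip the consistency check where the normal p underflows
    chk <- !drop & is.finite(df$pval) & p_norm > 1e-300
    bad <- chk & abs(df$pval - p_norm) / p_norm > 0.10
    flag(bad, "pval inconsistent with beta/se")
  }
  list(drop = drop, reason = reason)
}

#' Default column-name mapping for summary-statistics files
#'
#' @param ... named overrides, e.g. `snp = "rsid"`, mapping internal field
#'   names to column names in the file.
#' @return named character vector (internal name -> file column name).
#' @export
sumstats_dialect <- function(...) {
  d <- c(snp = "snp", chrom = "chr", pos = "pos", ea = "ea", oa = "oa",
         eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n",
         n_cases = "n_cases")
  over <- c(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(d))
    if (length(unknown)) stop("unknown dialect fields: ",
                              paste(unknown, collapse = ", "))
    d[names(over)] <- over
  }
  d
}

#' Read GWAS/QTL summary statistics from a tab-delimited file
#'
#' Reads a header-ed TSV, maps columns through `dialect`, normalises alleles
#' to upper case and drops rows violating the record invariants (zero or
#' negative SE, non-ACGT or identical alleles, frequencies outside \[0, 1\],
#' p-values outside (0, 1], non-numeric effect or SE, or a p-value that is
#' inconsistent with `beta/se` under the normal approximation). Skipped rows
#' are reported via a message.
#'
#' @param path file path.
#' @param dialect named mapping from internal field names to file column
#'   names, see [sumstats_dialect()].
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param check_pval verify p-value/z consistency (default TRUE).
#' @return a `sumstats` data.frame; the number of skipped rows is available
#'   as `attr(x, "n_skipped")`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          trait_type = "quantitative", check_pval = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  required <- setdiff(names(dialect), "n_cases")
  missing_cols <- setdiff(unname(dialect[required]), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  df <- data.frame(
    snp = raw[[dialect["snp"]]],
    chrom = raw[[dialect["chrom"]]],
    pos = as.integer(num(raw[[dialect["pos"]]])),
    ea = toupper(raw[[dialect["ea"]]]),
    oa = toupper(raw[[dialect["oa"]]]),
    eaf = num(raw[[dialect["eaf"]]]),
    beta = num(raw[[dialect["beta"]]]),
    se = num(raw[[dialect["se"]]]),
    pval = num(raw[[dialect["pval"]]]),
    n = num(raw[[dialect["n"]]]),
    n_cases = if (dialect["n_cases"] %in% names(raw))
      num(raw[[dialect["n_cases"]]]) else NA_real_,
    trait_type = match.arg(trait_type, c("quantitative", "binary")),
    stringsAsFactors = FALSE
  )
  bad <- validate_sumstats(df, check_pval = check_pval)
  n_skipped <- sum(bad$drop)
  if (n_skipped > 0) {
    message(sprintf("read_sumstats: skipped %d invalid row(s): %s", n_skipped,
                    paste(unique(bad$reason[bad$drop]), collapse = "; ")))
  }
  df <- df[!bad$drop, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sumstats", "data.frame")
  attr(df, "n_skipped") <- n_skipped
  df
}

#' Write summary statistics to a tab-delimited file
#'
#' Numeric fields are written with 17 significant digits so that
#' [read_sumstats()] round-trips all values bit-identically.
#'
#' @param x a `sumstats` data.frame.
#' @param path output file path.
#' @param dialect column-name mapping used for the header.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, dialect = sumstats_dialect()) {
  fmt <- function(v) {
    out <- vapply(v, function(z) {
      if (is.na(z)) "NA" else sprintf("%.17g", z)
    }, character(1))
    out
  }
  out <- data.frame(
    a = x$snp, b = x$chrom, c = as.character(x$pos), d = x$ea, e = x$oa,
    f = fmt(x$eaf), g = fmt(x$beta), h = fmt(x$se), i = fmt(x$pval),
    j = fmt(x$n), k = fmt(x$n_cases), stringsAsFactors = FALSE
  )
  names(out) <- unname(dialect[c("snp", "chrom", "pos", "ea", "oa", "eaf",
                                 "beta", "se", "pval", "n", "n_cases")])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read gene regions with druggability tiers
#'
#' Expects a BED-like tab-delimited file with columns gene_id, chrom, start,
#' end and optionally druggability_tier (one of 1, 2, 3A, 3B, none).
#' Positions are 1-based inclusive.
#'
#' @param path file path.
#' @param header logical; whether the file has a header line.
#' @return data.frame with columns gene_id, chrom, start, end,
#'   druggability_tier.
#' @export
read_gene_regions <- function(path, header = TRUE) {
  df <- utils::read.delim(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!header) {
    names(df)[1:min(5, ncol(df))] <-
      c("gene_id", "chrom", "start", "end", "druggability_tier")[1:min(5, ncol(df))]
  }
  if (!all(c("gene_id", "chrom", "start", "end") %in% names(df))) {
    stop("gene region file must have columns gene_id, chrom, start, end")
  }
  if (!"druggability_tier" %in% names(df)) df$druggability_tier <- "none"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$chrom <- as.character(df$chrom)
  df$druggability_tier <- as.character(df$druggability_tier)
  if (any(df$start > df$end)) stop("gene region with start > end")
  bad_tier <- !df$druggability_tier %in% c("1", "2", "3A", "3B", "none")
  if (any(bad_tier)) stop("invalid druggability tier: ",
                          paste(unique(df$druggability_tier[bad_tier]),
                                collapse = ", "))
  df
}

#' Construct a gene region
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param druggability_tier one of "1", "2", "3A", "3B", "none".
#' @return one-row data.frame.
#' @export
gene_region <- function(gene_id, chrom, start, end, druggability_tier = "none") {
  if (start > end) stop("start > end")
  druggability_tier <- match.arg(as.character(druggability_tier),
                                 c("1", "2", "3A", "3B", "none"))
  data.frame(gene_id = gene_id, chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             druggability_tier = druggability_tier,
             stringsAsFactors = FALSE)
}
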