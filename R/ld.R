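#' Construct an LD block
#'
#' Holds a square matrix of pairwise allelic correlations r (not r-squared)
#' for one locus, keyed by SNP id. The matrix must be symmetric with unit
#' diagonal.
#'
#' @param snp_ids character vector of SNP identifiers, in matrix order.
#' @param R square numeric correlation matrix.
#' @return list of class `ld_block` with elements `snp_ids` and `R`.
#' @export
ld_block <- function(snp_ids, R) {
  snp_ids <- as.character(snp_ids)
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("LD matrix must be square")
  if (length(snp_ids) != nrow(R)) {
    stop("LD matrix dimension does not match number of SNP ids")
  }
  if (anyDuplicated(snp_ids)) stop("duplicated SNP ids in LD block")
  if (max(abs(R - t(R))) > 1e-8) stop("LD matrix not symmetric within 1e-8")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  if (max(abs(R)) > 1 + 1e-8) stop("LD entries must lie in [-1, 1]")
  R <- (R + t(R)) / 2
  dimnames(R) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, R = R), class = "ld_block")
}

#' Subset an LD block to a set of SNPs
#'
#' @param ld an `ld_block`.
#' @param snps SNP ids to keep (order of `snps` is preserved).
#' @return a smaller `ld_block`.
#' @export
ld_subset <- function(ld, snps) {
  snps <- as.character(snps)
  missing <- setdiff(snps, ld$snp_ids)
  if (length(missing)) stop("SNPs absent from LD block: ",
                            paste(missing, collapse = ", "))
  ld_block(snps, ld$R[snps, snps, drop = FALSE])
}

#' Read an LD matrix from a plain-text file
#'
#' Format: first line is whitespace-delimited SNP ids; subsequent lines are
#' the rows of the correlation matrix.
#'
#' @param path file path.
#' @return an `ld_block`.
#' @export
read_ld_matrix <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  rows <- lapply(lines[-1], function(l) as.numeric(strsplit(trimws(l), "[ \t]+")[[1]]))
  R <- do.call(rbind, rows)
  ld_block(ids, R)
}

#' Write an LD matrix to a plain-text file
#'
#' Entries are written with 17 significant digits for exact round-tripping.
#'
#' @param ld an `ld_block`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ld$snp_ids, collapse = "\t"), con)
  apply(ld$R, 1, function(row) {
    writeLines(paste(sprintf("%.17g", row), collapse = "\t"), con)
  })
  invisible(path)
}

#' AR(1) correlation matrix
#'
#' Classic autoregressive LD decay: `r[i, j] = rho^|i - j|`.
#'
#' @param n_snps number of SNPs.
#' @param rho first-order autocorrelation, in (-1, 1).
#' @return numeric matrix.
#' @export
ld_ar1 <- function(n_snps, rho) {
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  idx <- seq_len(n_snps)
  rho^abs(outer(idx, idx, "-"))
}

#' Block-diagonal exchangeable correlation matrix
#'
#' @param sizes integer vector of block sizes.
#' @param within_r common within-block correlation.
#' @return numeric matrix of dimension `sum(sizes)`.
#' @export
ld_blockdiag <- function(sizes, within_r) {
  n <- sum(sizes)
  R <- diag(n)
  at <- 0L
  for (s in sizes) {
    idx <- at + seq_len(s)
    R[idx, idx] <- within_r
    at <- at + s
  }
  diag(R) <- 1
  R
}
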