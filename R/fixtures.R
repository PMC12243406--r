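#' Write a simulated locus to plain-text fixture files
#'
#' Emits `exposure.tsv`, `outcome.tsv` (summary statistics), `ld.txt`
#' (SNP-id header plus correlation matrix), `genes.bed` (the synthetic
#' gene region) and `truth.json` (the realised scenario) into `dir`.
#' Numeric values are written at full precision so that [read_fixture()]
#' reproduces the locus bit-identically.
#'
#' @param locus a `simulated_locus`.
#' @param dir output directory.
#' @param force overwrite a non-empty existing directory (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(locus, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("directory exists and is not empty; use force = TRUE to overwrite")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(locus$exposure_stats, file.path(dir, "exposure.tsv"))
  write_sumstats(locus$outcome_stats, file.path(dir, "outcome.tsv"))
  write_ld_matrix(locus$ld, file.path(dir, "ld.txt"))
  utils::write.table(locus$region, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(locus$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a simulated-locus fixture back from disk
#'
#' @param dir directory written by [write_fixture()].
#' @return list with `ld`, `exposure_stats`, `outcome_stats`, `region`,
#'   `truth` mirroring the `simulated_locus` layout.
#' @export
read_fixture <- function(dir) {
  exposure <- read_sumstats(file.path(dir, "exposure.tsv"),
                            trait_type = "quantitative")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  outcome <- read_sumstats(file.path(dir, "outcome.tsv"),
                           trait_type = truth$outcome_type)
  attr(exposure, "n_skipped") <- NULL
  attr(outcome, "n_skipped") <- NULL
  structure(list(
    ld = read_ld_matrix(file.path(dir, "ld.txt")),
    exposure_stats = exposure,
    outcome_stats = outcome,
    region = read_gene_regions(file.path(dir, "genes.bed")),
    truth = truth
  ), class = "simulated_locus")
}
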