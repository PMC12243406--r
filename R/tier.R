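#' Collate per-gene evidence for tier classification
#'
#' @param gene_id gene label.
#' @param mr one-row `mr_result` data.frame (protein-level MR) with
#'   `p_fdr` filled in; required.
#' @param smr optional one-row SMR result (from [smr_gene_scan()]); NULL
#'   when the gene has no expression data.
#' @param coloc optional `coloc_result`; NULL when colocalisation could
#'   not be evaluated.
#' @param druggability_tier druggability class of the gene ("1", "2",
#'   "3A", "3B" or "none"); carried through for reporting.
#' @return list of class `evidence_row`.
#' @export
evidence_row <- function(gene_id, mr, smr = NULL, coloc = NULL,
                         druggability_tier = "none") {
  if (is.null(mr) || nrow(mr) != 1) stop("evidence_row requires a one-row MR result")
  structure(list(gene_id = gene_id, mr = mr, smr = smr, coloc = coloc,
                 druggability_tier = druggability_tier),
            class = "evidence_row")
}

#' Three-tier evidence classification of a candidate drug target
#'
#' Every tier requires causal evidence at the protein level, so a gene
#' whose protein MR does not survive FDR correction is `not_significant`.
#' A gene whose expression-level (SMR) effect is significant but points in
#' the opposite direction from the protein-level effect is `excluded`
#' (potential dual effects). Otherwise three criteria are evaluated:
#' protein MR (by construction true at this point), SMR support
#' (significant, direction-consistent, and not attributed to linkage by
#' HEIDI), and colocalisation (PP(H4) above threshold). Tier 1 = both SMR
#' and coloc support; tier 2 = exactly one of them; tier 3 = neither.
#' Missing SMR or coloc evidence makes that criterion false with an
#' explanatory reason.
#'
#' @param row an `evidence_row`.
#' @param config an [mr_config()]; uses `mr_alpha_fdr`, `smr_alpha`,
#'   `pph4_threshold`, `heidi_call`, `heidi_gates_smr`.
#' @return list of class `tier_call` with `gene_id`, `tier` (one of "1",
#'   "2", "3", "excluded", "not_significant"), `reasons` (character),
#'   `direction_consistent` (logical or NA), `druggability_tier`.
#' @export
classify_tier <- function(row, config = mr_config()) {
  stopifnot(inherits(row, "evidence_row"))
  reasons <- character(0)
  mk <- function(tier, direction = NA) {
    structure(list(gene_id = row$gene_id, tier = tier, reasons = reasons,
                   direction_consistent = direction,
                   druggability_tier = row$druggability_tier),
              class = "tier_call")
  }
  if (is.na(row$mr$p_fdr)) stop("classify_tier requires mr$p_fdr")
  if (row$mr$p_fdr >= config$mr_alpha_fdr) {
    reasons <- "protein MR not FDR-significant"
    return(mk("not_significant"))
  }
  direction <- NA
  smr_sig <- FALSE
  if (!is.null(row$smr)) {
    smr_sig <- row$smr$p_smr < config$smr_alpha
    if (smr_sig) {
      direction <- sign(row$smr$b_smr) == sign(row$mr$beta)
      if (!direction) {
        reasons <- "expression effect opposite in direction to protein effect"
        return(mk("excluded", direction))
      }
    }
  }

  # criterion B: transcriptome-wide support
  if (is.null(row$smr)) {
    B <- FALSE
    reasons <- c(reasons, "SMR: no available gene expression data")
  } else if (!smr_sig) {
    B <- FALSE
    reasons <- c(reasons, "SMR: not significant")
  } else if (config$heidi_gates_smr && !is.na(row$smr$p_heidi) &&
             row$smr$p_heidi < config$heidi_call) {
    B <- FALSE
    reasons <- c(reasons, "SMR: HEIDI indicates linkage")
  } else {
    B <- TRUE
    reasons <- c(reasons, "SMR: pass")
  }

  # criterion C: colocalisation
  if (is.null(row$coloc)) {
    C <- FALSE
    reasons <- c(reasons, "coloc: no evidence")
  } else if (row$coloc$pp["pp_h4"] > config$pph4_threshold) {
    C <- TRUE
    reasons <- c(reasons, sprintf("coloc: PP(H4) = %.3f",
                                  row$coloc$pp["pp_h4"]))
  } else {
    C <- FALSE
    reasons <- c(reasons, sprintf("coloc: PP(H4) = %.3f below threshold",
                                  row$coloc$pp["pp_h4"]))
  }

  tier <- if (B && C) "1" else if (B || C) "2" else "3"
  mk(tier, direction)
}

#' @export
print.tier_call <- function(x, ...) {
  cat(sprintf("%s: tier %s (druggability %s)\n", x$gene_id, x$tier,
              x$druggability_tier))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Tier-classify a table of genes
#'
#' @param rows list of `evidence_row`s.
#' @param config an [mr_config()].
#' @return data.frame with gene_id, tier, druggability_tier,
#'   direction_consistent, reasons (collapsed with "; ").
#' @export
classify_tiers <- function(rows, config = mr_config()) {
  out <- lapply(rows, function(r) {
    tc <- classify_tier(r, config)
    data.frame(gene_id = tc$gene_id, tier = tc$tier,
               druggability_tier = tc$druggability_tier,
               direction_consistent = if (is.na(tc$direction_consistent))
                 NA else tc$direction_consistent,
               reasons = paste(tc$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
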