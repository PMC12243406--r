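fake_mr <- function(beta = -0.15, p_fdr = 0.01, gene = "G") {
  r <- mr_result_row(gene, "ivw", 2, beta, 0.03)
  r$p_fdr <- p_fdr
  r
}
fake_smr <- function(b_smr = -0.6, p_smr = 0.001, p_heidi = 0.5) {
  data.frame(gene_id = "G", top_snp = "rs1", b_smr = b_smr, se_smr = 0.2,
             p_smr = p_smr, p_heidi = p_heidi, n_heidi_snps = 10,
             flag = "pass", stringsAsFactors = FALSE)
}
fake_coloc <- function(pph4) {
  pp <- c(pp_h0 = 0, pp_h1 = 0, pp_h2 = 0, pp_h3 = 1 - pph4, pp_h4 = pph4)
  structure(list(pp = pp, n_snps = 100,
                 priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                 call = pph4 > 0.7), class = "coloc_result")
}

test_that("tier classifier reproduces the published evidence patterns", {
  # MR + consistent SMR + strong coloc -> tier 1
  t1 <- classify_tier(evidence_row("CPXM1-like", fake_mr(),
                                   smr = fake_smr(), coloc = fake_coloc(0.940)))
  expect_equal(t1$tier, "1")
  # MR + coloc, SMR not significant -> tier 2
  t2 <- classify_tier(evidence_row("INSR-like", fake_mr(),
                                   smr = fake_smr(p_smr = 0.4),
                                   coloc = fake_coloc(0.706)))
  expect_equal(t2$tier, "2")
  # MR only: no coloc support, no expression data -> tier 3
  t3 <- classify_tier(evidence_row("CPZ-like", fake_mr(), smr = NULL,
                                   coloc = fake_coloc(0.0008)))
  expect_equal(t3$tier, "3")
  expect_true(any(grepl("no available gene expression data", t3$reasons)))
  # MR only, coloc evaluated but weak, SMR not significant -> tier 3
  t3b <- classify_tier(evidence_row("PXDN-like", fake_mr(beta = 0.28),
                                    smr = fake_smr(b_smr = 0.2, p_smr = 0.3),
                                    coloc = fake_coloc(0.447)))
  expect_equal(t3b$tier, "3")
  # significant SMR with opposite direction -> excluded
  ex <- classify_tier(evidence_row("OMG-like", fake_mr(beta = -0.5),
                                   smr = fake_smr(b_smr = 0.5, p_smr = 0.004),
                                   coloc = fake_coloc(0.9)))
  expect_equal(ex$tier, "excluded")
  expect_false(ex$direction_consistent)
  # protein MR not FDR-significant -> not_significant
  ns <- classify_tier(evidence_row("NULL-like", fake_mr(p_fdr = 0.2)))
  expect_equal(ns$tier, "not_significant")
})

test_that("heidi failure vetoes the SMR criterion unless configured otherwise", {
  row <- evidence_row("G", fake_mr(), smr = fake_smr(p_heidi = 0.002),
                      coloc = fake_coloc(0.9))
  expect_equal(classify_tier(row)$tier, "2")
  expect_equal(classify_tier(row, mr_config(heidi_gates_smr = FALSE))$tier, "1")
})

test_that("classification is pure and monotone in added evidence", {
  row <- evidence_row("G", fake_mr(), smr = fake_smr(), coloc = fake_coloc(0.94))
  expect_identical(classify_tier(row), classify_tier(row))
  base <- evidence_row("G", fake_mr(), smr = NULL, coloc = NULL)
  expect_equal(classify_tier(base)$tier, "3")
  with_coloc <- evidence_row("G", fake_mr(), smr = NULL, coloc = fake_coloc(0.9))
  expect_equal(classify_tier(with_coloc)$tier, "2")  # never lower than 3
})

test_that("classify_tiers collates calls into a table", {
  rows <- list(evidence_row("A", fake_mr(), fake_smr(), fake_coloc(0.9)),
               evidence_row("B", fake_mr(), NULL, NULL,
                            druggability_tier = "3B"))
  tab <- classify_tiers(rows)
  expect_equal(tab$tier, c("1", "3"))
  expect_equal(tab$druggability_tier, c("none", "3B"))
})

test_that("endophenotype MR recovers a true negative effect with correct method labels", {
  covered <- vapply(1:200, function(i) {
    l <- simulate_locus(scenario(causal_exposure = list(c(100, 0.05)),
                                 theta = -0.2, n_exposure = 30000,
                                 n_outcome = 30000,
                                 outcome_type = "quantitative", seed = 4000 + i))
    res <- endophenotype_mr(as_named_list(l$exposure_stats, "GENE1"),
                            l$region, as_named_list(l$ld, "GENE1"),
                            list(iop = l$outcome_stats))
    if (res$flag != "ok") return(NA)
    res$ci_low <= -0.2 && -0.2 <= res$ci_high
  }, logical(1))
  expect_gte(mean(covered, na.rm = TRUE), 0.90)

  l <- simulate_locus(scenario(causal_exposure = list(c(100, 0.05)),
                               theta = -0.2, n_exposure = 30000,
                               n_outcome = 30000,
                               outcome_type = "quantitative", seed = 4001))
  res <- endophenotype_mr(as_named_list(l$exposure_stats, "GENE1"), l$region,
                          as_named_list(l$ld, "GENE1"),
                          list(iop = l$outcome_stats))
  expect_equal(res$n_snps, 1L)
  expect_equal(res$method, "wald_ratio")  # single instrument -> Wald ratio
})

test_that("targets with no surviving instruments get a flagged row", {
  l <- simulate_locus(scenario(causal_exposure = list(c(100, 0.001)),
                               theta = 0, n_exposure = 5000, n_outcome = 5000,
                               outcome_type = "quantitative", seed = 3))
  res <- endophenotype_mr(as_named_list(l$exposure_stats, "GENE1"), l$region,
                          as_named_list(l$ld, "GENE1"),
                          list(iop = l$outcome_stats))
  expect_equal(res$flag, "no_instruments")
  expect_equal(nrow(res), 1)
})

test_that("phewas scan applies the strict case-count filter", {
  l <- simulate_locus(shared_scenario(0, 12))
  iset_snps <- cis_clump(l$exposure_stats, l$region, l$ld)$snps$snp
  sub_ld <- ld_subset(l$ld, iset_snps)
  template <- l$exposure_stats[match(iset_snps, l$exposure_stats$snp), ]
  cat3 <- simulate_outcome_catalogue(sub_ld, template, 3, seed = 5)
  cat3[[1]]$n_cases <- 500   # boundary: excluded
  cat3[[2]]$n_cases <- 501   # included
  res <- phewas_scan(l$exposure_stats, l$region, l$ld, cat3)
  expect_false(cat3[[1]]$phenotype_id %in% res$phenotype_id)
  expect_true(cat3[[2]]$phenotype_id %in% res$phenotype_id)
})

test_that("raw phewas p-values do not depend on the rest of the scanned set", {
  l <- simulate_locus(shared_scenario(0, 13))
  snps <- cis_clump(l$exposure_stats, l$region, l$ld)$snps$snp
  sub_ld <- ld_subset(l$ld, snps)
  template <- l$exposure_stats[match(snps, l$exposure_stats$snp), ]
  cat10 <- simulate_outcome_catalogue(sub_ld, template, 10, seed = 6)
  full <- phewas_scan(l$exposure_stats, l$region, l$ld, cat10)
  part <- phewas_scan(l$exposure_stats, l$region, l$ld, cat10[1:3])
  shared <- intersect(full$phenotype_id, part$phenotype_id)
  expect_gt(length(shared), 0)
  expect_equal(full$pval[match(shared, full$phenotype_id)],
               part$pval[match(shared, part$phenotype_id)])
})

test_that("an outcome with a true effect ranks first among null outcomes", {
  first <- vapply(1:50, function(i) {
    l <- simulate_locus(shared_scenario(0, 6000 + i))
    snps <- cis_clump(l$exposure_stats, l$region, l$ld)$snps$snp
    if (!length(snps)) return(NA)
    sub_ld <- ld_subset(l$ld, snps)
    template <- l$exposure_stats[match(snps, l$exposure_stats$snp), ]
    # a moderate true effect: strong enough to rank first among nulls,
    # weak enough that instruments survive the outcome-association filter
    b_true <- 0.5 * l$truth$b_exp_marginal[match(snps, l$exposure_stats$snp)]
    cat3 <- simulate_outcome_catalogue(sub_ld, template, 3,
                                       case_range = c(15000, 16000),
                                       b_marginal = list("2" = b_true),
                                       seed = 6000 + i)
    res <- phewas_scan(l$exposure_stats, l$region, l$ld, cat3)
    if (is.null(res) || nrow(res) < 2) return(NA)
    res$phenotype_id[which.min(res$pval)] == "pheno_0002"
  }, logical(1))
  expect_gte(mean(first, na.rm = TRUE), 0.90)
})

test_that("direction concordance compares discovery and replication signs", {
  disc <- rbind(fake_mr(beta = -0.2, gene = "A"), fake_mr(beta = 0.3, gene = "B"))
  repl <- rbind(fake_mr(beta = -0.1, gene = "A"), fake_mr(beta = -0.2, gene = "B"))
  cc <- direction_concordance(disc, repl)
  expect_equal(cc$concordant, c(TRUE, FALSE))
})
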