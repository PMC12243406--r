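write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

header <- "snp\tchr\tpos\tea\toa\teaf\tbeta\tse\tpval\tn"

test_that("read_sumstats parses well-formed rows and normalises alleles", {
  path <- write_tsv_lines(c(
    header,
    "rs1\t1\t100\tA\tG\t0.2\t0.1\t0.05\t0.0455\t1000",
    "rs2\t1\t200\tC\tT\t0.4\t-0.2\t0.1\t0.0455\t1000",
    "rs3\t1\t300\ta\tg\t0.3\t0.3\t0.15\t0.0455\t1000"
  ))
  x <- read_sumstats(path)
  expect_equal(nrow(x), 3)
  expect_equal(attr(x, "n_skipped"), 0)
  expect_equal(x$ea[3], "A")
  expect_equal(x$oa[3], "G")
})

test_that("invalid rows are skipped with a logged count", {
  path <- write_tsv_lines(c(
    header,
    "rs1\t1\t100\tA\tG\t0.2\t0.1\t0\t0.5\t1000",        # se = 0
    "rs2\t1\t200\tC\tT\t0.4\tnotanumber\t0.1\t0.5\t1000", # non-numeric beta
    "rs3\t1\t300\tA\tG\t0.3\t0.1\t0.05\t0.0455\t1000"
  ))
  expect_message(x <- read_sumstats(path), "skipped 2")
  expect_equal(nrow(x), 1)
  expect_equal(x$snp, "rs3")
  expect_equal(attr(x, "n_skipped"), 2)
})

test_that("missing required column is fatal", {
  path <- write_tsv_lines(c(
    "snp\tchr\tpos\tea\toa\teaf\tbeta\tse\tn",
    "rs1\t1\t100\tA\tG\t0.2\t0.1\t0.05\t1000"
  ))
  expect_error(read_sumstats(path), "missing required column")
})

test_that("p-values inconsistent with beta/se are rejected", {
  path <- write_tsv_lines(c(
    header,
    "rs1\t1\t100\tA\tG\t0.2\t0.1\t0.05\t0.9\t1000"  # z = 2 implies p ~ 0.0455
  ))
  expect_message(x <- read_sumstats(path), "inconsistent")
  expect_equal(nrow(x), 0)
})

test_that("write/read round-trips all fields bit-identically", {
  set.seed(11)
  x <- make_sumstats(beta = rnorm(6, 0, 0.3) + 1e-9 * pi,
                     se = runif(6, 0.01, 0.2),
                     eaf = runif(6), n = 12345.5,
                     n_cases = c(NA, 17, NA, 3, NA, 99))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  y <- read_sumstats(path)
  attr(y, "n_skipped") <- NULL
  expect_identical(as.data.frame(y), as.data.frame(x))
})

test_that("harmonise flips reversed alleles, negating beta and eaf", {
  exp <- make_sumstats(0.5, 0.05, snp = "rs1", ea = "A", oa = "G", eaf = 0.30)
  out <- make_sumstats(-0.3, 0.04, snp = "rs1", ea = "G", oa = "A", eaf = 0.71)
  h <- harmonise(exp, out)
  expect_equal(h$status, "flipped")
  expect_equal(h$beta_out, 0.3)
  expect_equal(h$eaf_out, 0.29)
  expect_equal(h$ea, "A")
})

test_that("harmonise drops on allele-frequency difference above threshold", {
  exp <- make_sumstats(0.5, 0.05, snp = "rs1", eaf = 0.30)
  out <- make_sumstats(0.3, 0.04, snp = "rs1", eaf = 0.55)
  h <- harmonise(exp, out, af_diff_threshold = 0.2)
  expect_equal(h$status, "dropped_af_diff")
  # disabled by default (the MR-stage setting)
  expect_equal(harmonise(exp, out)$status, "kept")
})

test_that("palindromic and mismatched allele pairs are dropped", {
  exp <- make_sumstats(c(0.5, 0.5), c(0.05, 0.05), snp = c("rs1", "rs2"),
                       ea = c("A", "C"), oa = c("T", "G"))
  out <- make_sumstats(c(0.3, 0.3), c(0.04, 0.04), snp = c("rs1", "rs2"),
                       ea = c("A", "C"), oa = c("T", "G"))
  h <- harmonise(exp, out, drop_palindromic = TRUE)
  expect_equal(h$status, rep("dropped_palindromic", 2))
  h2 <- harmonise(exp, out, drop_palindromic = FALSE)
  expect_equal(h2$status, rep("kept", 2))

  exp2 <- make_sumstats(0.5, 0.05, snp = "rs1", ea = "A", oa = "G")
  out2 <- make_sumstats(0.3, 0.04, snp = "rs1", ea = "A", oa = "C")
  expect_equal(harmonise(exp2, out2)$status, "dropped_allele_mismatch")
})

test_that("harmonise is idempotent on kept pairs", {
  set.seed(3)
  exp <- make_sumstats(rnorm(5, 0, 0.3), runif(5, 0.02, 0.1),
                       ea = c("A", "G", "C", "T", "A"),
                       oa = c("G", "A", "T", "C", "C"), eaf = runif(5))
  out <- make_sumstats(rnorm(5, 0, 0.3), runif(5, 0.02, 0.1),
                       ea = c("G", "A", "C", "T", "A"),
                       oa = c("A", "G", "T", "C", "C"), eaf = runif(5))
  h1 <- harmonised_kept(harmonise(exp, out))
  h2 <- harmonise(exp[match(h1$snp, exp$snp), ], outcome_from_harmonised(h1))
  expect_true(all(h2$status == "kept"))
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)
})

test_that("flipping both inputs' allele orderings preserves the beta product", {
  set.seed(7)
  for (i in 1:20) {
    b_exp <- rnorm(1, 0, 0.3); b_out <- rnorm(1, 0, 0.3)
    eafs <- runif(2, 0.05, 0.95)
    exp1 <- make_sumstats(b_exp, 0.05, snp = "rs1", ea = "A", oa = "G", eaf = eafs[1])
    ea_out <- sample(c("A", "G"), 1)
    out1 <- make_sumstats(b_out, 0.05, snp = "rs1",
                          ea = ea_out, oa = setdiff(c("A", "G"), ea_out),
                          eaf = eafs[2])
    h1 <- harmonise(exp1, out1)
    # flip the stated allele ordering of both records
    exp2 <- exp1; exp2$ea <- exp1$oa; exp2$oa <- exp1$ea
    exp2$beta <- -exp1$beta; exp2$eaf <- 1 - exp1$eaf
    out2 <- out1; out2$ea <- out1$oa; out2$oa <- out1$ea
    out2$beta <- -out1$beta; out2$eaf <- 1 - out1$eaf
    h2 <- harmonise(exp2, out2)
    expect_equal(h1$beta_exp * h1$beta_out, h2$beta_exp * h2$beta_out)
  }
})

test_that("gene region reader validates coordinates and tiers", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("gene_id\tchrom\tstart\tend\tdruggability_tier",
               "CPXM1\t20\t2794070\t2821616\t3A"), path)
  g <- read_gene_regions(path)
  expect_equal(g$gene_id, "CPXM1")
  expect_equal(g$druggability_tier, "3A")
  writeLines(c("gene_id\tchrom\tstart\tend\tdruggability_tier",
               "BAD\t1\t100\t50\tnone"), path)
  expect_error(read_gene_regions(path), "start > end")
})

test_that("LD block validates symmetry, diagonal and round-trips", {
  R <- ld_ar1(4, 0.8)
  ld <- ld_block(sprintf("rs%d", 1:4), R)
  path <- withr::local_tempfile(fileext = ".txt")
  write_ld_matrix(ld, path)
  ld2 <- read_ld_matrix(path)
  expect_identical(ld2$snp_ids, ld$snp_ids)
  expect_identical(unname(ld2$R), unname(ld$R))
  bad <- R; bad[1, 2] <- 0.5
  expect_error(ld_block(sprintf("rs%d", 1:4), bad), "symmetric")
  bad2 <- R; diag(bad2)[2] <- 0.9
  expect_error(ld_block(sprintf("rs%d", 1:4), bad2), "diagonal")
})
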