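---
title: "Methods: multi-omics MR for drug-target prioritisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics MR for drug-target prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The problem

Druggable-genome screens ask, for each gene encoding a tractable protein,
whether genetically predicted protein abundance (or expression) causally
affects a disease. `targetmr` implements that screen as a pipeline over GWAS
summary statistics: cis-QTL instrument selection, two-sample Mendelian
randomization (MR), summary-data-based MR (SMR) with the HEIDI linkage test,
Bayesian colocalisation, a three-tier evidence classifier, endophenotype MR
and a phenome-wide MR scan. A summary-statistics simulator provides ground
truth for every stage.

Two-sample MR treats cis variants as instrumental variables under the usual
three assumptions: the variant is associated with the exposure (relevance),
affects the outcome only through the exposure (exclusion restriction), and is
independent of confounders. Restricting to cis instruments, filtering, and
the downstream colocalisation step are all aimed at making these assumptions
plausible in practice.

## Instrument selection

For a gene with region $[s, e]$ the cis window is $[s - w, e + w]$ with
$w = 1000$ kb, boundaries inclusive; the window is anchored on the gene body
(not the TSS) so it covers both common readings of "a region centred around
the gene". Candidate instruments must reach $P < 5 \times 10^{-8}$ (strict
inequality). The remaining filters run in this order:

1. **LD clumping** (greedy, PLINK-style): rank by ascending p-value, ties
   broken lexicographically by SNP id so the result is deterministic and
   independent of input order; the top unclaimed SNP claims all unclaimed
   SNPs within 10,000 kb having $r^2 \ge 0.001$ with it. Distance is
   measured between SNP positions.
2. **Harmonisation** with the outcome: reversed allele orderings flip the
   outcome beta and frequency; A/T and C/G (palindromic) SNPs are dropped by
   default because strand cannot be resolved from two summary files alone;
   allele pairs that differ as sets are dropped. The allele-frequency
   difference filter (0.2) is applied at the SMR stage by default and can be
   enabled for the MR stage via `mr_config(af_diff_threshold = 0.2)`.
3. **Steiger directionality**: a SNP is removed when it explains more
   variance in the outcome than in the exposure. The default proxy is
   $r^2 = z^2 / (z^2 + n - 2)$ for both traits (monotone in $|z|$ at fixed
   $n$); $2\,\mathrm{MAF}(1-\mathrm{MAF})\beta^2$ is available via
   `steiger_method = "maf_beta"`. Ties are retained.
4. **Outcome-association exclusion**: SNPs with outcome $P < 5 \times
   10^{-5}$ are removed (strictly below; a SNP exactly at the threshold is
   kept).
5. **Instrument strength**: per-SNP $F = (\beta/\mathrm{se})^2 \ge 10$.

Whether Steiger filtering preceded or followed clumping in the original
analysis narrative is ambiguous; we fix the order above (selection, clump,
harmonise, Steiger, outcome exclusion, F) and log every removed SNP with its
reason, so `n_input = n_retained + nrow(filter_log)` always holds.

## Causal estimation

A single instrument gives the Wald ratio
$\hat\theta = \beta_{out}/\beta_{exp}$ with first-order delta-method SE
$\mathrm{se}_{out}/|\beta_{exp}|$; the second-order term is omitted because
it is negligible at the enforced $F \ge 10$. Multiple instruments are
combined by fixed-effect IVW over per-SNP ratios with weights
$1/\mathrm{se}_i^2$, equivalently a zero-intercept weighted regression of
outcome on exposure betas with weights $1/\mathrm{se}_{out}^2$; fixed
effects are the right default because cis instrument counts are tiny (1–4).
Confidence intervals use the normal multiplier 1.96. With three or more
instruments the MR-Egger intercept (weighted regression with a free
intercept, exposure betas oriented non-negative, t-test on $n-2$ df) is
attached as a pleiotropy diagnostic; it flags but never switches or drops an
estimate, since the screen reports Wald/IVW only. FDR control across genes
is Benjamini–Hochberg at 0.05.

## SMR and HEIDI

SMR links expression to outcome through the top cis-eQTL:
$T_{SMR} = z_g^2 z_e^2/(z_g^2 + z_e^2) \sim \chi^2_1$,
$b_{SMR} = b_g/b_e$. Before the test, SNPs with MAF $\le 0.01$ and SNPs
whose allele frequencies differ by more than 0.2 between the eQTL and
outcome data are removed.

HEIDI distinguishes one shared causal variant from two distinct variants in
LD. Eligible SNPs have $r^2$ with the top SNP strictly inside $(0.05, 0.9)$
and eQTL $P < 1.57 \times 10^{-3}$ (the $\chi^2_1 = 10$ equivalent); at most
20 (the most significant) are used, and fewer than 3 yields an
`insufficient_snps` flag instead of a p-value. For each eligible SNP the
deviation $d_i = b_{SMR}(i) - b_{SMR}(\mathrm{top})$ has a delta-method
covariance built from the LD correlations and per-SNP SEs (eQTL and GWAS
errors independent across datasets). The statistic $\sum_i (d_i/s_i)^2$ is
referred to a Satterthwaite-matched scaled chi-square on the eigenvalues of
the correlation matrix of $d$ — a deliberate simplification of the original
software's saddlepoint approximation, validated by null simulation (the
observed call rate at $P < 0.01$ under a shared variant is at or below the
nominal 1%). Two thresholds co-exist deliberately: $1.57 \times 10^{-3}$ is
per-SNP eligibility, 0.01 is the pleiotropy call; both are configurable
because the source analyses are ambiguous about which gated reporting.

## Colocalisation

Per-SNP Wakefield approximate Bayes factors,
$\log\mathrm{ABF} = \tfrac12 \log\frac{V}{V+W} + \frac{z^2}{2}\frac{W}{V+W}$,
feed the standard five-hypothesis posterior (no association; trait 1 only;
trait 2 only; two distinct variants; one shared variant) with per-SNP priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and at most one causal variant per
trait. All hypothesis sums use log-sum-exp; $S_1 S_2 - S_{12}$ is computed
as a log-space difference. The effect-size prior SDs are not stated by the
source analyses; we default to 0.2 for log-OR (binary) traits and 0.15 for
quantitative traits, configurable per trait. The locus is the gene's
±1000 kb window with **no** p-value filtering, because the ABF sums need the
full local SNP set. A gene colocalises when $PP(H_4) > 0.7$.

## Evidence tiers

Every tier requires FDR-significant protein-level MR. A gene whose
significant SMR effect opposes the protein MR direction is excluded
outright (potential dual effects). Otherwise: tier 1 = SMR support and
colocalisation; tier 2 = exactly one of the two; tier 3 = neither. Missing
expression data or an unevaluable coloc makes that criterion false with an
explanatory reason (e.g. "no available gene expression data"). A HEIDI
pleiotropy call vetoes the SMR criterion by default — linkage is not shared
signal — with `mr_config(heidi_gates_smr = FALSE)` to ignore HEIDI, since
the source framework lists SMR passage without stating how HEIDI failures
fed the tiers. Tiers are assigned on discovery evidence only;
`direction_concordance()` reports replication-cohort sign agreement
separately, with no formal meta-analysis.

## Endophenotype MR and PheWAS

Endophenotype MR reruns the identical instrument pipeline against
quantitative outcomes (e.g. intraocular pressure, retinal nerve fibre layer
thickness) and reports betas with 95% CIs at raw $\alpha = 0.05$; targets
with no surviving instruments yield a flagged row. The PheWAS scan filters a
disease catalogue to more than 500 cases (strictly), reruns the pipeline per
outcome (the outcome-independent clumping is computed once), and applies BH
FDR across the scanned set at 0.05.

## The simulator

`simulate_locus()` draws summary statistics directly from the
regression-with-summary-statistics multivariate-normal model rather than
from individual-level genotypes: with LD matrix $R$ and joint causal
effects $\beta$, marginal effects are $b = R\beta$ and z-scores are drawn
as $z \sim \mathrm{MVN}(b/\mathrm{se}, R)$, with
$\mathrm{se} = 1/\sqrt{n}$ for quantitative traits and
$1/\sqrt{n\,\phi(1-\phi)}$ on the log-OR scale for binary traits with case
fraction $\phi$. This trades rare-variant realism for speed and exactness;
it does not model population structure, relatedness, multi-ancestry LD, or
genotype-level artefacts, so passing tests demonstrate statistical
correctness of the pipeline under its own model, not robustness to
real-data messiness (strand errors, mismatched LD panels, sample overlap).

Causal architectures: `shared` ($b_{out} = \theta\, b_{exp}$), `distinct`
(outcome-specific causal variants), `pleiotropy` (adds direct outcome
effects), and `reverse` (causal variants act on the outcome and the
exposure inherits $\phi_{rev} b_{out}$, the trap Steiger filtering must
catch). Defaults mirror the emulated study: exposure panels of 35,559
(pQTL-like) individuals, a binary outcome with 20,582 effective cases and
119,318 controls, a 200-SNP locus under AR(1) LD with $\rho = 0.95$, MAF
uniform on (0.05, 0.5). Simulated allele pairs are non-palindromic by
construction so the default harmonisation never discards simulated SNPs.
P-values are clamped at `1e-320` to stay in $(0, 1]$ when the normal tail
underflows; the record validator correspondingly skips its z/p consistency
check below `1e-300`. A numerically singular LD matrix has its diagonal
jittered by $10^{-8}$.

## Validation choices and problem sizes

The test suite validates each estimator against an independent oracle
(normal-equations weighted least squares for IVW/Egger, an exhaustive
pairwise checker for clumping, numerical quadrature for the ABF, a
$10^6$-draw Monte-Carlo null for the SMR p-value) and then checks the
statistical behaviour of the whole pipeline on simulated loci: 95% CI
coverage of $\theta \in \{-0.3, 0, 0.3\}$ and type-I error at 500
replicates with $n = 50{,}000$ per trait and two causal cis variants of
0.04 SD; colocalisation and HEIDI discrimination of shared versus distinct
causal variants at 200 replicates each; and FDR behaviour of 40 null
PheWAS scans of 783 outcomes. The 0.04 SD effects were chosen so
instruments always clear genome-wide significance while the
outcome-association exclusion rarely removes true instruments at
$|\theta| = 0.3$; with far stronger effect pairs that exclusion filter —
faithfully reproduced from the screen it models — would discard genuine
instruments, a known tension of outcome-p filtering under strong causal
effects.

## Limitations

Single-variant-per-trait colocalisation (no conditioning or SuSiE-style
extension); no multi-SNP SMR or trans-QTLs; no weighted-median, mode-based
or multivariable MR estimators; LD arrives as matrices (no genotype-panel
processing, no GWAS-VCF/tabix/liftover); indels and multi-allelic sites are
rejected at parse time. The Egger intercept is a flag, never an exclusion
rule. Druggability tiers are consumed as input, not curated.
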