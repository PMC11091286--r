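fixture_path <- system.file("extdata", "icp_gwas_instruments.tsv",
                            package = "mrmediate")

test_that("the packaged instrument table reads into validated records", {
  ss <- read_sumstats(fixture_path)
  expect_equal(nrow(ss), 11L)
  expect_equal(ss$snp_id[1], "rs28929474")
  expect_equal(ss$beta[1], 1.958)
  expect_equal(ss$se[1], 0.176)
  expect_equal(attr(ss, "n_rejected"), 0L)
  expect_true(all(ss$pos == round(ss$pos)))  # 1-based integer positions
})

test_that("header-only and malformed rows degrade gracefully", {
  p <- write_tsv_fixture("Chr\tPos\tSNP\tEffect allele\tOther allele\tEaf\tBeta\tSe\tPval")
  expect_warning(ss <- read_sumstats(p), "no data rows")
  expect_equal(nrow(ss), 0L)

  p2 <- write_tsv_fixture(c(
    "Chr\tPos\tSNP\tEffect allele\tOther allele\tEaf\tBeta\tSe\tPval",
    "1\t100\trs1\tA\tG\t0.3\t0.5\t0.05\t1e-10",
    "1\t200\trs2\tA\tG\t0.3\t0.5\t-0.1\t1e-10",
    "1\t300\trs3\tT\tC\t0.4\t-0.2\t0.04\t1e-6"))
  expect_warning(ss2 <- read_sumstats(p2), "rejected")
  expect_equal(nrow(ss2), 2L)
  expect_equal(attr(ss2, "n_rejected"), 1L)
  expect_match(attr(ss2, "rejections"), "rs2")
  expect_error(read_sumstats(p2, strict = TRUE), "se must be")
})

test_that("dialect mapping resolves alternative headers and flags missing columns", {
  p <- write_tsv_fixture(c(
    "variant_id\tchromosome\tbase_pair_location\teffect_allele\tother_allele\teffect_allele_frequency\tbeta\tstandard_error\tp_value",
    "rs1\t1\t100\tA\tG\t0.3\t0.5\t0.05\t1e-10"))
  ss <- read_sumstats(p, dialect = "gwas-catalog")
  expect_equal(ss$snp_id, "rs1")
  expect_error(read_sumstats(p, dialect = "default"), "absent from the file header")
  expect_error(sumstats_dialect("default", nonsense = "X"), "unknown canonical field")
})

make_records <- function(snp_id, ea, oa, eaf, beta, se = 0.05,
                         pval = 1e-10, chrom = "1", pos = NULL) {
  n <- length(snp_id)
  if (is.null(pos)) pos <- seq(100, by = 1e6, length.out = n)
  data.frame(snp_id = snp_id, chrom = rep_len(chrom, n), pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = rep_len(se, n), pval = rep_len(pval, n),
             n = NA_real_, stringsAsFactors = FALSE)
}

test_that("harmonization aligns swapped, strand-flipped and palindromic alleles", {
  exposure <- make_records("rs1", "A", "G", 0.3, 0.5)
  outcome <- make_records("rs1", "G", "A", 0.7, -0.2)
  h <- harmonize(exposure, outcome)
  p <- kept_pairs(h)
  expect_equal(p$action, "flipped")
  expect_equal(p$outcome_beta, 0.2)
  expect_equal(p$outcome_eaf, 0.3)

  # strand-complement reported outcome (exposure A/G vs outcome T/C)
  h2 <- harmonize(make_records("rs2", "A", "G", 0.3, 0.5),
                  make_records("rs2", "T", "C", 0.3, 0.4))
  expect_equal(kept_pairs(h2)$action, "kept")
  expect_equal(kept_pairs(h2)$outcome_beta, 0.4)
  h2b <- harmonize(make_records("rs2", "A", "G", 0.3, 0.5),
                   make_records("rs2", "T", "C", 0.3, 0.4),
                   strand_flip = FALSE)
  expect_equal(h2b$pairs$action, "dropped_incompatible")

  # unambiguous palindrome kept, ambiguous dropped
  h3 <- harmonize(make_records("rs3", "A", "T", 0.10, 0.5),
                  make_records("rs3", "A", "T", 0.12, 0.3))
  expect_equal(kept_pairs(h3)$action, "kept")
  h4 <- harmonize(make_records("rs4", "C", "G", 0.49, 0.5),
                  make_records("rs4", "C", "G", 0.51, 0.3))
  expect_equal(h4$pairs$action, "dropped_palindromic")

  # irreconcilable allele sets
  h5 <- harmonize(make_records("rs5", "A", "G", 0.3, 0.5),
                  make_records("rs5", "A", "C", 0.3, 0.2))
  expect_equal(h5$pairs$action, "dropped_incompatible")
  expect_true(is.na(h5$pairs$outcome_beta))

  expect_error(harmonize(exposure, make_records("rs9", "A", "G", 0.3, 0.1)),
               "no overlapping instruments")
})

test_that("harmonization is idempotent", {
  exposure <- make_records(c("rs1", "rs2", "rs3"),
                           c("A", "C", "T"), c("G", "A", "C"),
                           c(0.3, 0.6, 0.2), c(0.5, -0.4, 0.3))
  outcome <- make_records(c("rs1", "rs2", "rs3"),
                          c("G", "C", "A"), c("A", "A", "G"),
                          c(0.7, 0.6, 0.8), c(-0.2, 0.1, -0.15))
  h1 <- kept_pairs(harmonize(exposure, outcome))
  out2 <- make_records(h1$snp_id, h1$effect_allele, h1$other_allele,
                       h1$outcome_eaf, h1$outcome_beta)
  h2 <- kept_pairs(harmonize(exposure, out2))
  expect_equal(h2$action, rep("kept", nrow(h2)))
  expect_equal(h2$outcome_beta, h1$outcome_beta)
  expect_equal(h2$outcome_eaf, h1$outcome_eaf)
})

test_that("recoding the exposure allele leaves causal estimates unchanged", {
  sc <- clean_sim_set(77, n_snps = 20)
  sim <- sc$sim
  flipped <- sim$exposure
  flipped$effect_allele <- sim$exposure$other_allele
  flipped$other_allele <- sim$exposure$effect_allele
  flipped$beta <- -sim$exposure$beta
  flipped$eaf <- 1 - sim$exposure$eaf
  e1 <- mr_ivw(harmonize(sim$exposure, sim$outcome))
  e2 <- mr_ivw(harmonize(flipped, sim$outcome))
  expect_equal(e2$beta, e1$beta, tolerance = 1e-14)
  expect_equal(e2$se, e1$se, tolerance = 1e-14)
})

test_that("pval_from_effect is tail-accurate, symmetric and monotone", {
  expect_equal(pval_from_effect(0, 1), 1)
  expect_equal(pval_from_effect(1.959964, 1), 0.05, tolerance = 1e-6)
  p <- pval_from_effect(0.242, 0.043)
  expect_lt(p, 5e-8)
  expect_gt(p, 1.995e-9)   # same order of magnitude as the audited value
  expect_lt(p, 1.995e-7)
  # symmetry in the sign of beta
  expect_equal(pval_from_effect(-0.7, 0.1), pval_from_effect(0.7, 0.1))
  # strictly decreasing in |beta/se|
  zs <- seq(0.1, 8, by = 0.5)
  ps <- pval_from_effect(zs, 1)
  expect_true(all(diff(ps) < 0))
  # representable far below 1e-300, and log10 output beyond that
  tiny <- pval_from_effect(38, 1)
  expect_gt(tiny, 0)
  expect_lt(tiny, 1e-300)
  expect_lt(pval_from_effect(50, 1, log10 = TRUE), -500)
  expect_error(pval_from_effect(1, 0), "se must be")
})
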