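fixture <- read_sumstats(system.file("extdata", "icp_gwas_instruments.tsv",
                                     package = "mrmediate"))

test_that("significance filtering uses a strict threshold and records provenance", {
  sel <- select_significant(fixture)
  expect_equal(nrow(sel), 11L)
  prov <- attr(sel, "provenance")
  expect_equal(prov$n_before - prov$n_removed, prov$n_after)

  expect_equal(nrow(select_significant(fixture, 0)), 0L)

  df <- fixture[1:3, ]
  df$pval <- c(1e-9, 1e-7, 0.5)
  expect_equal(nrow(select_significant(df)), 1L)
  # boundary is strict: p exactly at the threshold is removed
  df$pval <- c(5e-8, 4.9e-8, 1)
  expect_equal(select_significant(df)$snp_id, df$snp_id[2])
})

test_that("greedy clumping prunes dominated neighbours and respects the window", {
  two <- data.frame(snp_id = c("rsA", "rsB"), chrom = "1",
                    pos = c(1000, 2000),
                    effect_allele = "A", other_allele = "G", eaf = 0.3,
                    beta = 0.5, se = 0.05, pval = c(1e-20, 1e-10),
                    n = NA_real_, stringsAsFactors = FALSE)
  ld <- ld_matrix_lookup(matrix(c(1, 0.9, 0.9, 1), 2, 2,
                                dimnames = list(c("rsA", "rsB"),
                                                c("rsA", "rsB"))))
  expect_equal(clump(two, ld = ld)$snp_id, "rsA")
  # outside the 10 Mb window both survive regardless of r2
  two$pos <- c(1, 2e7)
  expect_equal(nrow(clump(two, ld = ld)), 2L)
  # distance-only clumping prunes on proximity alone
  two$pos <- c(1000, 2000)
  expect_equal(clump(two)$snp_id, "rsA")
  two$pos[2] <- NA
  expect_error(clump(two), "position")
})

test_that("clumping matches brute-force enumeration of the greedy rule", {
  ids <- paste0("rs", 1:5)
  recs <- data.frame(snp_id = ids, chrom = c("1", "1", "1", "2", "1"),
                     pos = c(100, 5e5, 3e7, 100, 6e5),
                     effect_allele = "A", other_allele = "G", eaf = 0.3,
                     beta = 0.5, se = 0.05,
                     pval = c(1e-12, 1e-15, 1e-9, 1e-10, 1e-15),
                     n = NA_real_, stringsAsFactors = FALSE)
  r2m <- matrix(0, 5, 5, dimnames = list(ids, ids))
  r2m["rs1", "rs2"] <- r2m["rs2", "rs1"] <- 0.5
  r2m["rs1", "rs5"] <- r2m["rs5", "rs1"] <- 0.0005
  r2m["rs2", "rs5"] <- r2m["rs5", "rs2"] <- 0.8
  ld <- ld_matrix_lookup(r2m)
  spec <- clump_spec(r2_threshold = 0.001, window_bp = 1e7)
  kept <- clump(recs, spec, ld)$snp_id

  # independent brute-force: walk SNPs by (pval, id), testing each
  # against every previously accepted SNP
  ord <- order(recs$pval, recs$snp_id)
  acc <- character(0)
  for (i in ord) {
    conflict <- FALSE
    for (a in acc) {
      k <- match(a, recs$snp_id)
      same_chr <- recs$chrom[i] == recs$chrom[k]
      close <- abs(recs$pos[i] - recs$pos[k]) <= 1e7
      high_ld <- r2m[recs$snp_id[i], a] >= 0.001
      if (same_chr && close && high_ld) conflict <- TRUE
    }
    if (!conflict) acc <- c(acc, recs$snp_id[i])
  }
  expect_setequal(kept, acc)

  # invariant: no kept pair violates the (window, r2) rule
  for (a in kept) for (b in kept) {
    if (a >= b) next
    ia <- match(a, recs$snp_id); ib <- match(b, recs$snp_id)
    if (recs$chrom[ia] == recs$chrom[ib] &&
        abs(recs$pos[ia] - recs$pos[ib]) <= 1e7) {
      expect_lt(r2m[a, b], 0.001)
    }
  }
  # idempotence
  expect_equal(clump(clump(recs, spec, ld), spec, ld)$snp_id, kept)
})

test_that("F statistics screen weak instruments under both formulas", {
  fs <- f_statistics(fixture)
  expect_gt(fs$report$min_f, 10)
  expect_equal(nrow(fs$records), 11L)
  expect_equal(fs$report$formula_used, "ratio")

  one <- fixture[9, ]  # beta 0.242, se 0.043
  f1 <- f_statistics(one)$report$per_snp_f$f
  expect_equal(f1, (0.242 / 0.043)^2, tolerance = 1e-12)
  expect_equal(round(f1, 2), 31.67)

  # a null instrument is removed at any positive threshold
  z <- fixture[1:2, ]
  z$beta[2] <- 0
  fz <- f_statistics(z, f_min = 1e-6)
  expect_equal(fz$records$snp_id, z$snp_id[1])
  expect_equal(fz$report$per_snp_f$f[2], 0)

  # ratio formula invariant to allele-sign flips
  flip <- fixture
  flip$beta <- -flip$beta
  expect_equal(f_statistics(flip)$report$per_snp_f$f,
               f_statistics(fixture)$report$per_snp_f$f)

  # r2_based needs n; invariant to eaf -> 1 - eaf
  expect_error(f_statistics(fixture, formula = "r2_based"),
               "sample size")
  fa <- f_statistics(fixture, n = 154780, formula = "r2_based")
  mirr <- fixture
  mirr$eaf <- 1 - mirr$eaf
  fb <- f_statistics(mirr, n = 154780, formula = "r2_based")
  expect_equal(fa$report$per_snp_f$f, fb$report$per_snp_f$f)

  big <- fixture
  big$beta <- big$beta * 50
  expect_error(f_statistics(big, n = 154780, formula = "r2_based"),
               "explained variance")
})

test_that("blocklist exclusion removes rsIDs and interval hits", {
  expect_equal(nrow(exclude_blocklist(fixture, character(0))), 11L)
  kept <- exclude_blocklist(fixture, "rs1800961")
  expect_equal(nrow(kept), 10L)
  expect_false("rs1800961" %in% kept$snp_id)

  recs <- fixture[1:4, ]
  iv <- data.frame(chrom = c("14", "19"),
                   start = c(94378600, 1), end = c(94378620, 4e7))
  out <- exclude_blocklist(recs, iv)
  # brute-force membership check
  inside <- vapply(seq_len(4), function(i) {
    any(recs$chrom[i] == iv$chrom & recs$pos[i] >= iv$start &
          recs$pos[i] <= iv$end)
  }, logical(1))
  expect_setequal(out$snp_id, recs$snp_id[!inside])

  bad <- data.frame(chrom = "1", start = 10, end = 5)
  expect_error(exclude_blocklist(recs, bad), "start > end")

  p <- write_tsv_fixture(c("rs1800961", "19:1-40000000", "# comment"))
  bl <- read_blocklist(p)
  expect_equal(bl$rsids, "rs1800961")
  expect_equal(nrow(bl$intervals), 1L)
  # removes rs1800961 plus the one chr19 SNP inside the interval
  expect_equal(nrow(exclude_blocklist(fixture, bl)), 9L)
})

test_that("the selection cascade is idempotent and provenance-consistent", {
  sel <- select_instruments(fixture, n = 154780)
  expect_equal(nrow(sel$records), 11L)
  for (st in sel$provenance) {
    expect_equal(st$n_before - st$n_removed, st$n_after)
  }
  again <- select_instruments(sel$records, n = 154780)
  expect_equal(again$records$snp_id, sel$records$snp_id)
})
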