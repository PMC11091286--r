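test_that("Wald ratios are elementwise outcome/exposure divisions", {
  s <- make_set(0.5, 0.05, 0.1, 0.02)
  wr <- wald_ratios(s)
  expect_equal(wr$theta, 0.2)
  expect_equal(wr$se_theta, 0.04)
  expect_equal(wr$weight, 1 / 0.04^2)

  # sign cancellation
  s2 <- make_set(-0.5, 0.05, -0.1, 0.02)
  expect_equal(wald_ratios(s2)$theta, 0.2)

  bx <- c(0.5, -0.3, 0.8); by <- c(0.1, 0.06, -0.2); sy <- c(0.02, 0.03, 0.05)
  wr3 <- wald_ratios(make_set(bx, 0.05, by, sy))
  for (i in 1:3) {
    expect_equal(wr3$theta[i], by[i] / bx[i])
    expect_equal(wr3$se_theta[i], sy[i] / abs(bx[i]))
  }
  expect_error(wald_ratios(make_set(c(0.5, 0), 0.05, c(0.1, 0.1), 0.02)),
               "snp_2")
})

test_that("IVW collapses to the Wald ratio and the equal-weight mean", {
  expect_warning(e1 <- mr_ivw(make_set(0.5, 0.05, 0.1, 0.02)),
                 "single instrument")
  expect_equal(e1$beta, 0.2)
  expect_equal(e1$se, 0.04)

  s <- make_set(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.6), c(0.05, 0.05, 0.05))
  expect_equal(mr_ivw(s)$beta, mean(c(0.1, 0.2, 0.6)))
})

test_that("IVW equals weighted through-origin regression and a meta-analytic fit", {
  bx <- c(0.5, -0.3, 0.8, 0.2, -0.6)
  by <- c(0.11, -0.05, 0.15, 0.05, -0.13)
  sy <- c(0.02, 0.03, 0.05, 0.02, 0.04)
  s <- make_set(bx, 0.01, by, sy)
  est <- mr_ivw(s, model = "fixed")
  orc <- oracle_ivw(bx, by, sy)
  expect_equal(est$beta, orc$beta, tolerance = 1e-12)
  expect_equal(est$se, orc$se_fixed, tolerance = 1e-12)

  skip_if_not_installed("metafor")
  wr <- wald_ratios(s)
  fe <- metafor::rma(yi = wr$theta, sei = wr$se_theta, method = "FE")
  expect_equal(est$beta, as.numeric(fe$beta), tolerance = 1e-10)
  expect_equal(est$se, as.numeric(fe$se), tolerance = 1e-10)

  # multiplicative random effects only widens the interval
  expect_gte(mr_ivw(s)$se, est$se)
})

test_that("MR-Egger matches the closed-form weighted normal equations", {
  bx <- c(0.4, -0.6, 0.9, 0.3)
  by <- c(0.09, -0.11, 0.21, 0.08)
  sy <- c(0.02, 0.04, 0.03, 0.02)
  est <- mr_egger(make_set(bx, 0.01, by, sy))

  # orientation: all exposure betas positive
  sg <- sign(bx)
  o <- oracle_wls2(sg * bx, sg * by, 1 / sy^2)
  expect_equal(est$beta, o$slope, tolerance = 1e-12)
  expect_equal(est$extras$intercept, o$intercept, tolerance = 1e-12)
  scale2 <- max(1, o$rss / 2)
  expect_equal(est$se, sqrt(scale2 * o$var_b), tolerance = 1e-12)
  expect_equal(est$extras$intercept_se, sqrt(scale2 * o$var_a),
               tolerance = 1e-12)
  tt <- o$slope / sqrt(scale2 * o$var_b)
  expect_equal(est$pval, 2 * pt(-abs(tt), df = 2), tolerance = 1e-12)

  # exact-fit case: all ratios c, positive exposure betas
  bx2 <- c(0.2, 0.5, 0.9)
  est2 <- mr_egger(make_set(bx2, 0.01, 0.3 * bx2, 0.02))
  expect_equal(est2$beta, 0.3, tolerance = 1e-10)
  expect_equal(est2$extras$intercept, 0, tolerance = 1e-10)

  expect_error(mr_egger(make_set(c(1, 1), 0.1, c(1, 1), 0.1)),
               "at least 3")
})

test_that("Egger intercept p-values are null-calibrated across seeds", {
  # distributional property: under no pleiotropy the intercept test
  # should reject near (not above ~8% at) the nominal 5% level
  rej <- vapply(1:150, function(i) {
    sc <- clean_sim_set(6000 + i, n_snps = 30)
    mr_egger(sc$set)$extras$intercept_pval < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.10)
})

test_that("weighted median interpolates the cumulative weight function", {
  s <- make_set(c(1, 1, 1), 0.01, c(1, 2, 9), c(1, 1, 1))
  expect_warning(e <- mr_weighted_median(s, n_boot = 50, seed = 1),
                 "n_boot")
  expect_equal(e$beta, 2)

  # majority weight on one instrument pins the estimate near its ratio
  s2 <- make_set(c(1, 1, 1), 0.001, c(1, 2, 9), c(0.01, 1, 1))
  e2 <- mr_weighted_median(s2, n_boot = 200, seed = 1)
  expect_equal(e2$beta, 1, tolerance = 1e-3)

  bx <- c(0.5, -0.4, 0.7, 0.2, -0.9)
  by <- c(0.12, -0.02, 0.2, 0.01, -0.4)
  sy <- c(0.02, 0.05, 0.04, 0.01, 0.06)
  e3 <- mr_weighted_median(make_set(bx, 0.01, by, sy), n_boot = 200,
                           seed = 9)
  wr <- wald_ratios(make_set(bx, 0.01, by, sy))
  expect_equal(e3$beta, oracle_weighted_median(wr$theta, wr$weight),
               tolerance = 1e-12)
  expect_error(mr_weighted_median(s), "seed is required")
})

test_that("weighted mode finds the modal cluster, not the mean", {
  s <- make_set(c(1, 1, 1), 0.001, c(1.0, 1.01, 5.0), c(0.05, 0.05, 0.05))
  e <- mr_weighted_mode(s, bandwidth_factor = 0.5, n_boot = 100, seed = 3)
  expect_lt(abs(e$beta - 1.005), 0.05)
  expect_gt(abs(e$beta - mean(c(1, 1.01, 5))), 1)

  # degenerate density: identical ratios give back that value exactly
  s2 <- make_set(c(1, 2, 4), 0.01, c(0.3, 0.6, 1.2), c(0.05, 0.05, 0.05))
  e2 <- mr_weighted_mode(s2, n_boot = 100, seed = 3)
  expect_equal(e2$beta, 0.3)

  expect_error(mr_weighted_mode(s, bandwidth_factor = 0, n_boot = 100,
                                seed = 1), "bandwidth")
})

test_that("weighted mode maximizer agrees with a dense grid-search oracle", {
  bx <- c(0.5, -0.4, 0.7, 0.2, -0.9, 0.6)
  by <- c(0.11, -0.09, 0.13, 0.05, -0.16, 0.14)
  sy <- c(0.02, 0.05, 0.04, 0.01, 0.06, 0.03)
  s <- make_set(bx, 0.01, by, sy)
  e <- mr_weighted_mode(s, n_boot = 100, seed = 5)
  wr <- wald_ratios(s)
  h <- e$extras$bandwidth
  expect_equal(e$beta, oracle_kde_mode(wr$theta, wr$weight, h),
               tolerance = 1e-10)
})

test_that("multivariable IVW recovers conditional effects", {
  # hand-set instance against explicit generalized least squares
  x <- cbind(a = c(0.5, -0.3, 0.8, 0.2), b = c(0.1, 0.4, -0.2, 0.3))
  y <- c(0.2, 0.05, 0.15, 0.12)
  sy <- c(0.02, 0.03, 0.04, 0.02)
  ests <- mvmr_ivw(y, sy, x)
  orc <- oracle_gls(x, y, 1 / sy^2)
  expect_equal(ests[[1]]$beta, orc[1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ests[[2]]$beta, orc[2], tolerance = 1e-12,
               ignore_attr = TRUE)

  # an all-zero second exposure reduces to univariable IVW
  x0 <- cbind(a = c(0.5, -0.3, 0.8, 0.2), b = 0)
  e0 <- mvmr_ivw(y, sy, x0)
  uni <- oracle_ivw(x0[, 1], y, sy)
  expect_equal(e0[[1]]$beta, uni$beta, tolerance = 1e-12)
  expect_true(isTRUE(e0[[2]]$extras$degenerate))

  expect_error(mvmr_ivw(y, sy, cbind(x[, 1], 2 * x[, 1])),
               "collinear")

  # parameter recovery on simulated data, true effects (0.3, -0.2)
  set.seed(88)
  j <- 50
  g1 <- rnorm(j, 0, 0.3); g2 <- rnorm(j, 0, 0.3)
  se_y <- rep(0.01, j)
  yy <- 0.3 * g1 - 0.2 * g2 + rnorm(j, 0, se_y)
  rec <- mvmr_ivw(yy, se_y, cbind(g1, g2))
  expect_lt(abs(rec[[1]]$beta - 0.3), 2 * rec[[1]]$se)
  expect_lt(abs(rec[[2]]$beta + 0.2), 2 * rec[[2]]$se)
})

test_that("odds-ratio conversion exponentiates estimate and bounds", {
  e <- mr_ivw(make_set(c(1, 1, 1), 0.01, c(0.004, 0.004, 0.004),
                       c(0.001, 0.001, 0.001)))
  o <- to_odds_ratio(e)
  expect_equal(unname(o["or"]), exp(e$beta))
  expect_equal(unname(o["ci_low"]), exp(e$ci_low))
  expect_equal(to_odds_ratio(e, format = TRUE)[["or"]], "1.004")

  z <- mr_ivw(make_set(c(1, 1), 0.01, c(0.1, -0.1), c(0.05, 0.05)),
              model = "fixed")
  oz <- to_odds_ratio(z)
  expect_equal(unname(oz["or"]), 1)
  expect_equal(unname(oz["ci_high"]), exp(1.959964 * z$se))
})

test_that("estimators are scale-equivariant in the exposure", {
  sc <- clean_sim_set(55, n_snps = 12)
  p <- kept_pairs(sc$set)
  c0 <- 2.5
  scaled <- harmonized_set(p$exposure_beta * c0, p$exposure_se * c0,
                           p$outcome_beta, p$outcome_se)
  base <- harmonized_set(p$exposure_beta, p$exposure_se,
                         p$outcome_beta, p$outcome_se)
  expect_equal(mr_ivw(scaled)$beta, mr_ivw(base)$beta / c0,
               tolerance = 1e-12)
  expect_equal(mr_egger(scaled)$beta, mr_egger(base)$beta / c0,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(scaled, n_boot = 100, seed = 4)$beta,
               mr_weighted_median(base, n_boot = 100, seed = 4)$beta / c0,
               tolerance = 1e-12)
})

test_that("estimate tables serialize one tidy row per method", {
  sc <- clean_sim_set(66, n_snps = 10)
  ests <- mr_all_methods(sc$set, seed = 2, n_boot = 100)
  tab <- estimates_table(ests)
  expect_equal(nrow(tab), 4L)
  expect_true(all(c("method", "beta", "se", "pval", "or") %in% names(tab)))
  expect_equal(tab$or, exp(tab$beta))
})
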