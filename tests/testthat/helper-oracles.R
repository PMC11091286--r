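# Independent brute-force oracles used to cross-check the estimators.
# These deliberately recompute everything with plain loops and explicit
# normal equations, sharing no code with the package internals.

make_set <- function(bx, sx, by, sy, snp_id = NULL) {
  harmonized_set(exposure_beta = bx, exposure_se = sx,
                 outcome_beta = by, outcome_se = sy, snp_id = snp_id)
}

# Weighted through-origin regression slope and SE via explicit sums.
oracle_ivw <- function(bx, by, sy) {
  w <- 1 / sy^2
  slope <- sum(w * bx * by) / sum(w * bx^2)
  se <- sqrt(1 / sum(w * bx^2))
  list(beta = slope, se_fixed = se)
}

# Two-parameter weighted least squares (intercept + slope) via the
# closed-form normal equations.
oracle_wls2 <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy_ <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  b <- (sw * sxy - sx * sy_) / det
  a <- (sxx * sy_ - sx * sxy) / det
  resid <- y - a - b * x
  rss <- sum(w * resid^2)
  var_b <- sw / det
  var_a <- sxx / det
  list(intercept = a, slope = b, rss = rss, var_a = var_a, var_b = var_b)
}

# General weighted normal equations for a no-intercept multi-column fit.
oracle_gls <- function(x, y, w) {
  xtx <- t(x) %*% diag(w) %*% x
  xty <- t(x) %*% diag(w) %*% y
  drop(solve(xtx, xty))
}

# Weighted quantile by direct evaluation of the midpoint cumulative
# weight function, no interpolation code shared with the package.
oracle_weighted_median <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]; ww <- w[o] / sum(w)
  s <- numeric(length(th))
  acc <- 0
  for (i in seq_along(th)) {
    s[i] <- acc + ww[i] / 2
    acc <- acc + ww[i]
  }
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(th)])
  i <- max(which(s < 0.5))
  th[i] + (th[i + 1] - th[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

# Weighted-KDE maximizer: coarse grid bracketing plus a root of the
# analytic density derivative, independent of the package's optimizer.
oracle_kde_mode <- function(theta, w, h) {
  wn <- w / sum(w)
  dens <- function(m) sum(wn * dnorm((m - theta) / h)) / h
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 1e5)
  vals <- vapply(grid, dens, numeric(1))
  i <- which.max(vals)
  dderiv <- function(m) -sum(wn * ((m - theta) / h) *
                               dnorm((m - theta) / h)) / h^2
  lo <- grid[max(1, i - 2)]; hi <- grid[min(length(grid), i + 2)]
  uniroot(dderiv, c(lo, hi), tol = 1e-15)$root
}

# Clean simulated instrument set shared by several sensitivity tests.
clean_sim_set <- function(seed, n_snps = 30, theta = 0.1) {
  cfg <- sim_config(n_snps = n_snps, n_exposure = 1e5, n_outcome = 1e5,
                    gamma_sd = 0.3, theta = theta, flip_frac = 0,
                    palindromic_frac = 0, seed = seed)
  sim <- simulate_pair(cfg)
  list(sim = sim, set = harmonize(sim$exposure, sim$outcome))
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
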