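#' Configuration for the synthetic summary-statistics generator
#'
#' Describes a two-sample (optionally three-sample, with a mediator)
#' GWAS summary-statistics study with known causal structure. The
#' defaults emulate the scale of the intrahepatic-cholestasis study the
#' package is built around: 11 independent instruments for a rare
#' pregnancy liver disorder measured in a GWAS of ~155,000 women
#' (effect-size spread matching the published instrument table), a
#' binary cardiovascular outcome GWAS of ~485,000 participants on the
#' log-odds scale, and a small true causal effect (log-OR 0.004 per
#' exposure log-odds unit).
#'
#' @param n_snps number of exposure instruments.
#' @param n_exposure,n_outcome,n_mediator GWAS sample sizes.
#' @param gamma_sd SD of the true SNP-exposure effects.
#' @param theta true causal effect of exposure on outcome.
#' @param pleiotropy `"none"`, or a list `list(type = "balanced", sd =)`
#'   / `list(type = "directional", mean =, sd =)` applied to
#'   `pleiotropy_frac` of the instruments.
#' @param pleiotropy_frac fraction of instruments receiving a
#'   pleiotropic offset (default 0.3 when pleiotropy is requested).
#' @param mediator_chain optional list `list(beta_a =, beta_b =,
#'   direct =)` describing an exposure-mediator-outcome chain; the
#'   implied total effect is `direct + beta_a * beta_b` and `theta` is
#'   ignored.
#' @param n_mediator_snps number of mediator-specific instruments
#'   (disjoint rsIDs from the exposure's), used when `mediator_chain`
#'   is set.
#' @param delta_sd SD of true SNP-mediator effects at the mediator's
#'   own instruments.
#' @param eaf_range effect-allele frequency interval.
#' @param flip_frac fraction of outcome (and mediator) records emitted
#'   with swapped alleles, to exercise harmonization.
#' @param palindromic_frac fraction of SNPs given palindromic (A/T or
#'   C/G) allele pairs with unambiguous frequencies.
#' @param seed integer seed (mandatory; generation is a pure function
#'   of the config).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 11, n_exposure = 154780,
                       n_outcome = 484598, n_mediator = 115082,
                       gamma_sd = 0.65, theta = 0.004,
                       pleiotropy = "none", pleiotropy_frac = 0.3,
                       mediator_chain = NULL, n_mediator_snps = 20,
                       delta_sd = 0.1,
                       eaf_range = c(0.05, 0.95),
                       flip_frac = 0.25, palindromic_frac = 0.1,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_snps >= 1, n_exposure >= 2, n_outcome >= 2, n_mediator >= 2,
            gamma_sd > 0, length(eaf_range) == 2,
            eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] < eaf_range[2],
            flip_frac >= 0, flip_frac <= 1,
            palindromic_frac >= 0, palindromic_frac <= 1,
            pleiotropy_frac >= 0, pleiotropy_frac <= 1)
  if (is.character(pleiotropy)) {
    stopifnot(pleiotropy == "none")
    pleiotropy <- list(type = "none")
  }
  stopifnot(pleiotropy$type %in% c("none", "balanced", "directional"))
  if (!is.null(mediator_chain)) {
    stopifnot(all(c("beta_a", "beta_b", "direct") %in%
                    names(mediator_chain)))
  }
  structure(
    list(n_snps = n_snps, n_exposure = n_exposure, n_outcome = n_outcome,
         n_mediator = n_mediator, gamma_sd = gamma_sd, theta = theta,
         pleiotropy = pleiotropy, pleiotropy_frac = pleiotropy_frac,
         mediator_chain = mediator_chain,
         n_mediator_snps = n_mediator_snps, delta_sd = delta_sd,
         eaf_range = eaf_range, flip_frac = flip_frac,
         palindromic_frac = palindromic_frac, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# GWAS standard error of a per-allele effect at frequency p and sample
# size n (unit-variance trait approximation).
gwas_se <- function(eaf, n) 1 / sqrt(2 * eaf * (1 - eaf) * n)

# Allele assignment: non-palindromic base pairs by default, palindromic
# (A/T, C/G) for a chosen subset.
draw_alleles <- function(n, palindromic) {
  non_pal <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  pal <- list(c("A", "T"), c("C", "G"))
  pick_np <- sample.int(4, n, replace = TRUE)
  pick_p <- sample.int(2, n, replace = TRUE)
  ea <- oa <- character(n)
  for (i in seq_len(n)) {
    pair <- if (palindromic[i]) pal[[pick_p[i]]] else non_pal[[pick_np[i]]]
    ea[i] <- pair[1]; oa[i] <- pair[2]
  }
  list(ea = ea, oa = oa)
}

build_records <- function(snp_id, chrom, pos, ea, oa, eaf, true_beta, n,
                          flip) {
  se <- gwas_se(eaf, n)
  beta <- stats::rnorm(length(true_beta), true_beta, se)
  ea_out <- ea; oa_out <- oa; eaf_out <- eaf; beta_out <- beta
  if (any(flip)) {
    # Emit with effect/other alleles swapped: same association, opposite
    # reported sign and complementary frequency.
    ea_out[flip] <- oa[flip]; oa_out[flip] <- ea[flip]
    eaf_out[flip] <- 1 - eaf[flip]
    beta_out[flip] <- -beta[flip]
  }
  data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = ea_out, other_allele = oa_out,
    eaf = eaf_out, beta = beta_out, se = se,
    pval = floored_pval(beta_out, se), n = n,
    stringsAsFactors = FALSE
  )
}

# Emitted p-values are floored at the smallest normalized double so
# they stay strictly positive through a text round trip.
floored_pval <- function(beta, se) {
  pmax(pval_from_effect(beta, se), .Machine$double.xmin)
}

#' Simulate a two-sample GWAS summary-statistics pair
#'
#' Per SNP j: allele frequency uniform on `eaf_range`; true
#' SNP-exposure effect `gamma_j ~ N(0, gamma_sd^2)`; true SNP-outcome
#' effect `theta * gamma_j + alpha_j`, where `alpha_j` is a pleiotropic
#' offset (zero under `pleiotropy = "none"`); observed effects drawn
#' from normal sampling distributions with SE
#' `1/sqrt(2 eaf (1-eaf) n)`. A configurable fraction of outcome
#' records is emitted with swapped alleles and a configurable fraction
#' of SNPs is palindromic, so harmonization is exercised end to end.
#' Instruments are generated independent (no LD), the state of
#' instruments after clumping.
#'
#' @param config a [sim_config()].
#' @return list with `exposure` and `outcome` summary-statistic data
#'   frames and `truth` (class `synthetic_truth`: the config plus the
#'   realized per-SNP `gamma`, pleiotropy offsets `alpha`, flip and
#'   palindromic indicators).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    j <- config$n_snps
    snp_id <- sprintf("rs%07d", seq_len(j))
    chrom <- as.character(rep_len(1:22, j))
    pos <- sample.int(2.4e8, j, replace = TRUE)
    eaf <- stats::runif(j, config$eaf_range[1], config$eaf_range[2])
    gamma <- stats::rnorm(j, 0, config$gamma_sd)
    alpha <- pleiotropy_offsets(config, j)
    # Palindromic status goes only to SNPs whose MAF is already
    # unambiguous, so stressing the allele coding never changes the
    # sampled effects themselves.
    pal <- (stats::runif(j) < config$palindromic_frac) &
      (pmin(eaf, 1 - eaf) < 0.40)
    al <- draw_alleles(j, pal)
    flip <- stats::runif(j) < config$flip_frac

    exposure <- build_records(snp_id, chrom, pos, al$ea, al$oa, eaf,
                              gamma, config$n_exposure,
                              flip = rep(FALSE, j))
    outcome <- build_records(snp_id, chrom, pos, al$ea, al$oa, eaf,
                             config$theta * gamma + alpha,
                             config$n_outcome, flip = flip)
    truth <- structure(
      list(config = config, gamma = gamma, alpha = alpha,
           flip = flip, palindromic = pal, snp_id = snp_id),
      class = "synthetic_truth"
    )
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

pleiotropy_offsets <- function(config, j) {
  pl <- config$pleiotropy
  alpha <- numeric(j)
  if (pl$type == "none") return(alpha)
  n_pl <- round(config$pleiotropy_frac * j)
  if (n_pl == 0) return(alpha)
  idx <- seq_len(n_pl)  # deterministic subset; draws below consume RNG
  alpha[idx] <- if (pl$type == "balanced") {
    stats::rnorm(n_pl, 0, pl$sd)
  } else {
    stats::rnorm(n_pl, pl$mean, pl$sd)
  }
  alpha
}

#' Simulate an exposure-mediator-outcome chain
#'
#' Generates three GWAS summary-statistic sets with known mediation
#' structure. Exposure instruments (`gamma_j`) affect the mediator with
#' slope `beta_a` and the outcome with slope `direct + beta_a * beta_b`
#' (the implied total effect); mediator-specific instruments
#' (`delta_k`, disjoint rsIDs) affect the outcome with slope `beta_b`
#' and the exposure not at all. All three GWAS report the union of SNPs
#' so instruments can be cross-looked-up.
#'
#' @param config a [sim_config()] with `mediator_chain` set.
#' @return list with `exposure`, `mediator`, `outcome` data frames and
#'   `truth` (includes the implied total effect `te`).
#' @export
simulate_mediation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chain <- config$mediator_chain
  if (is.null(chain)) stop("config has no mediator_chain", call. = FALSE)
  with_local_seed(config$seed, {
    j <- config$n_snps
    k <- config$n_mediator_snps
    snp_exp <- sprintf("rs%07d", seq_len(j))
    snp_med <- sprintf("rs9%06d", seq_len(k))
    if (length(intersect(snp_exp, snp_med))) {
      stop("overlapping instrument IDs between exposure and mediator sets",
           call. = FALSE)
    }
    all_id <- c(snp_exp, snp_med)
    m <- j + k
    chrom <- as.character(rep_len(1:22, m))
    pos <- sample.int(2.4e8, m, replace = TRUE)
    eaf <- stats::runif(m, config$eaf_range[1], config$eaf_range[2])
    al <- draw_alleles(m, rep(FALSE, m))

    gamma <- stats::rnorm(j, 0, config$gamma_sd)   # SNP -> exposure
    delta <- stats::rnorm(k, 0, config$delta_sd)   # SNP -> mediator (own)
    te <- chain$direct + chain$beta_a * chain$beta_b

    true_exp <- c(gamma, rep(0, k))
    true_med <- c(chain$beta_a * gamma, delta)
    true_out <- c(te * gamma, chain$beta_b * delta)

    exposure <- build_records(all_id, chrom, pos, al$ea, al$oa, eaf,
                              true_exp, config$n_exposure,
                              flip = rep(FALSE, m))
    mediator <- build_records(all_id, chrom, pos, al$ea, al$oa, eaf,
                              true_med, config$n_mediator,
                              flip = stats::runif(m) < config$flip_frac)
    outcome <- build_records(all_id, chrom, pos, al$ea, al$oa, eaf,
                             true_out, config$n_outcome,
                             flip = stats::runif(m) < config$flip_frac)
    truth <- structure(
      list(config = config, gamma = gamma, delta = delta,
           te = te, snp_exposure = snp_exp, snp_mediator = snp_med),
      class = "synthetic_truth"
    )
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         truth = truth)
  })
}

#' Shift one SNP's outcome effect by a multiple of its standard error
#'
#' Returns a perturbed copy of the records (the input is not modified),
#' for exercising outlier diagnostics with a known planted outlier.
#'
#' @param records summary-statistic data frame.
#' @param snp_id the SNP to perturb.
#' @param shift_in_ses shift expressed in units of that SNP's SE.
#' @return the perturbed data frame.
#' @export
inject_outlier <- function(records, snp_id, shift_in_ses) {
  i <- match(snp_id, records$snp_id)
  if (is.na(i)) stop("unknown snp_id: ", snp_id, call. = FALSE)
  records$beta[i] <- records$beta[i] + shift_in_ses * records$se[i]
  records$pval[i] <- floored_pval(records$beta[i], records$se[i])
  records
}

#' Write simulated records in a readable dialect
#'
#' Emits the same TSV layout that `read_sumstats(dialect = "default")`
#' consumes, closing the loop between the generator and the reader.
#'
#' @param records summary-statistic data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  out <- data.frame(
    Chr = records$chrom, Pos = records$pos, SNP = records$snp_id,
    `Effect allele` = records$effect_allele,
    `Other allele` = records$other_allele,
    Eaf = records$eaf, Beta = records$beta, Se = records$se,
    Pval = records$pval, N = records$n,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
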