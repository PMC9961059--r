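#' Configuration for the two-sample summary-data generator
#'
#' Defaults emulate the study conditions the package targets: 85
#' independent instruments for a continuous exposure measured on 423,796
#' individuals (jointly explaining 5.85% of exposure variance), a binary
#' outcome with 6,033 cases and 123,000 controls, and a true causal effect
#' of 0.551 on the log-odds scale per SD of exposure. Noise, allele
#' structure (including palindromic SNPs and swapped allele coding in the
#' outcome file), pleiotropy and LD blocks are all controllable.
#'
#' @param n_snps Instrument count.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_outcome_cases,n_outcome_controls Outcome case/control counts.
#' @param true_beta True causal log-odds per SD of exposure.
#' @param total_r2 Summed instrument variance explained, in (0, 1).
#' @param maf_range Range the per-SNP minor-allele frequency is drawn from.
#' @param palindromic_fraction Fraction of SNPs given A/T or C/G alleles.
#' @param swap_fraction Fraction of SNPs whose outcome-file allele coding is
#'   swapped (betas negated, frequencies mirrored) — harmonization must undo
#'   this.
#' @param missing_outcome_fraction Fraction of SNPs omitted from the outcome
#'   file (exercises proxy search when LD blocks are present).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the direct
#'   (pleiotropic) outcome effects given to the invalid fraction;
#'   `pleiotropy_mean != 0` is directional pleiotropy, `pleiotropy_mean = 0`
#'   with `pleiotropy_sd > 0` balanced pleiotropy.
#' @param invalid_fraction Fraction of SNPs receiving a pleiotropic effect.
#' @param ld_block_spec Optional list of LD blocks, each a list with `size`
#'   (number of SNPs) and `r2` (pairwise within-block r-squared). Block
#'   members are placed within 50 kb of each other; all remaining SNPs are
#'   mutually unlinked and far apart.
#' @param seed RNG seed; the same config (including seed) always produces
#'   byte-identical datasets.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 85, n_exposure = 423796,
                              n_outcome_cases = 6033,
                              n_outcome_controls = 123000,
                              true_beta = 0.551, total_r2 = 0.0585,
                              maf_range = c(0.05, 0.5),
                              palindromic_fraction = 0.05,
                              swap_fraction = 0.1,
                              missing_outcome_fraction = 0,
                              pleiotropy_mean = 0, pleiotropy_sd = 0,
                              invalid_fraction = 0,
                              ld_block_spec = NULL, seed = 1) {
  stopifnot(n_snps >= 1, n_exposure > 2, n_outcome_cases > 0,
            n_outcome_controls > 0, total_r2 > 0, total_r2 < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            swap_fraction >= 0, swap_fraction <= 1,
            missing_outcome_fraction >= 0, missing_outcome_fraction < 1,
            invalid_fraction >= 0, invalid_fraction <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

# Allele pairs: palindromic SNPs get {A,T} or {C,G} in random order; others
# a random ordered pair that is neither identical nor complementary.
draw_alleles <- function(n, palindromic) {
  ea <- character(n); oa <- character(n)
  nonpal <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                 c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  pal <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  for (i in seq_len(n)) {
    pick <- if (palindromic[i]) pal[[sample.int(4, 1)]] else
      nonpal[[sample.int(8, 1)]]
    ea[i] <- pick[1]; oa[i] <- pick[2]
  }
  list(ea = ea, oa = oa)
}

#' Simulate a two-sample MR dataset with known ground truth
#'
#' Generates exposure and outcome GWAS summary statistics directly at the
#' summary level. Per SNP j: a minor-allele frequency is drawn uniformly
#' from `maf_range`; true exposure effects gamma_j are drawn normal and
#' rescaled so that the variance explained `sum(2 maf (1-maf) gamma^2)`
#' equals `total_r2`; observed exposure betas are gamma_j plus noise with the
#' analytic standard error `1/sqrt(2 maf (1-maf) n_exposure)`. A fraction of
#' SNPs receives a pleiotropic direct effect alpha_j ~
#' N(pleiotropy_mean, pleiotropy_sd); the true outcome effect is
#' `true_beta * gamma_j + alpha_j`, observed with standard error
#' `1/sqrt(2 maf (1-maf) n_eff)` where `n_eff = 4 / (1/cases + 1/controls)`
#' is the effective sample size of a balanced binary GWAS. Planted allele
#' swaps and palindromic SNPs perturb the outcome file's coding; the LD
#' table carries within-block r-squared plus unit self-pairs.
#'
#' @param config A [simulation_config()].
#' @return A list with `exposure` and `outcome` (`summary_dataset`s), `ld`
#'   (an `ld_table`), and `truth` (class `simulation_truth`: the config plus
#'   a per-SNP data frame of generating values).
#' @export
simulate_two_sample <- function(config = simulation_config()) {
  set.seed(config$seed)
  J <- config$n_snps
  maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
  var_snp <- 2 * maf * (1 - maf)

  gamma_raw <- stats::rnorm(J)
  denom <- sum(var_snp * gamma_raw^2)
  if (denom <= 0) stop("degenerate draw; cannot scale to total_r2")
  gamma_true <- gamma_raw * sqrt(config$total_r2 / denom)
  if (any(var_snp * gamma_true^2 >= 1)) {
    stop("infeasible total_r2 for this n_snps/maf_range combination")
  }

  se_x <- 1 / sqrt(var_snp * config$n_exposure)
  beta_x <- stats::rnorm(J, gamma_true, se_x)

  # pleiotropy is planted relative to the exposure-increasing allele
  # (alpha multiplied by sign(gamma)); a nonzero mean is then directional in
  # the orientation every estimator actually analyses, while InSIDE holds
  # because the magnitudes are drawn independently of gamma
  n_invalid <- round(config$invalid_fraction * J)
  alpha <- numeric(J)
  invalid <- sort(sample.int(J, n_invalid))
  if (n_invalid > 0) {
    alpha[invalid] <- sign(gamma_true[invalid]) *
      stats::rnorm(n_invalid, config$pleiotropy_mean, config$pleiotropy_sd)
  }
  Gamma_true <- config$true_beta * gamma_true + alpha
  n_eff <- 4 / (1 / config$n_outcome_cases + 1 / config$n_outcome_controls)
  se_y <- 1 / sqrt(var_snp * n_eff)
  beta_y <- stats::rnorm(J, Gamma_true, se_y)

  n_pal <- round(config$palindromic_fraction * J)
  palindromic <- logical(J)
  palindromic[sample.int(J, n_pal)] <- TRUE
  al <- draw_alleles(J, palindromic)

  n_swap <- round(config$swap_fraction * J)
  swapped <- logical(J)
  swapped[sample.int(J, n_swap)] <- TRUE

  n_miss <- round(config$missing_outcome_fraction * J)
  missing_out <- logical(J)
  if (n_miss > 0) missing_out[sample.int(J, n_miss)] <- TRUE

  # coordinates: LD-block members sit 50 kb apart on a shared chromosome;
  # all other SNPs are >= 25 Mb apart (independent under default clumping)
  chrom <- integer(J); pos <- numeric(J)
  idx <- seq_len(J)
  block_id <- rep(0L, J)
  if (!is.null(config$ld_block_spec)) {
    cursor <- 1L
    for (bi in seq_along(config$ld_block_spec)) {
      size <- config$ld_block_spec[[bi]]$size
      members <- cursor:(cursor + size - 1)
      block_id[members] <- bi
      chrom[members] <- bi
      pos[members] <- 1e6 + 5e4 * (seq_len(size) - 1)
      cursor <- cursor + size
    }
    rest <- idx[block_id == 0L]
  } else {
    rest <- idx
  }
  if (length(rest) > 0) {
    k <- seq_along(rest)
    chrom[rest] <- ((k - 1) %% 22) + 1
    pos[rest] <- 5e7 + 2.5e7 * ((k - 1) %/% 22)
  }
  # block-mates share an allele pair so a proxy can be allele-aligned in
  # place of its missing tag SNP
  if (any(block_id > 0L)) {
    for (bi in unique(block_id[block_id > 0L])) {
      members <- which(block_id == bi)
      al$ea[members] <- al$ea[members[1]]
      al$oa[members] <- al$oa[members[1]]
    }
    palindromic <- unname(complement_base(al$ea) == al$oa)
  }

  rsid <- sprintf("rs%06d", idx)
  two_sided_p <- function(beta, se) pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)

  eaf_x <- maf
  exposure <- summary_dataset(
    data.frame(rsid = rsid, chrom = as.character(chrom), pos = pos,
               effect_allele = al$ea, other_allele = al$oa,
               eaf = eaf_x, beta = beta_x, se = se_x,
               pvalue = two_sided_p(beta_x, se_x),
               n = config$n_exposure, stringsAsFactors = FALSE),
    trait_name = "simulated_exposure", trait_type = "continuous"
  )

  # outcome file: allele frequency re-estimated with small sampling noise,
  # then planted coding swaps applied
  eaf_y <- pmin(pmax(maf + stats::rnorm(J, 0, 0.005), 1e-3), 1 - 1e-3)
  ea_y <- al$ea; oa_y <- al$oa
  beta_y_file <- beta_y
  eaf_y_file <- eaf_y
  ea_y[swapped] <- al$oa[swapped]
  oa_y[swapped] <- al$ea[swapped]
  beta_y_file[swapped] <- -beta_y[swapped]
  eaf_y_file[swapped] <- 1 - eaf_y[swapped]

  keep_y <- !missing_out
  outcome <- summary_dataset(
    data.frame(rsid = rsid, chrom = as.character(chrom), pos = pos,
               effect_allele = ea_y, other_allele = oa_y,
               eaf = eaf_y_file, beta = beta_y_file, se = se_y,
               pvalue = two_sided_p(beta_y_file, se_y),
               n = config$n_outcome_cases + config$n_outcome_controls,
               stringsAsFactors = FALSE)[keep_y, , drop = FALSE],
    trait_name = "simulated_outcome", trait_type = "binary",
    n_cases = config$n_outcome_cases, n_controls = config$n_outcome_controls
  )

  snp_a <- rsid; snp_b <- rsid; r2 <- rep(1, J)
  if (any(block_id > 0L)) {
    for (bi in unique(block_id[block_id > 0L])) {
      members <- rsid[block_id == bi]
      prs <- utils::combn(members, 2)
      snp_a <- c(snp_a, prs[1, ]); snp_b <- c(snp_b, prs[2, ])
      r2 <- c(r2, rep(config$ld_block_spec[[bi]]$r2, ncol(prs)))
    }
  }
  ld <- ld_table(snp_a, snp_b, r2)

  truth <- structure(list(
    config = config,
    true_beta = config$true_beta,
    snps = data.frame(rsid = rsid, maf = maf, gamma_true = gamma_true,
                      alpha = alpha, Gamma_true = Gamma_true,
                      se_gamma = se_x, se_Gamma = se_y,
                      palindromic = palindromic, swapped = swapped,
                      missing_outcome = missing_out, block = block_id,
                      stringsAsFactors = FALSE)
  ), class = "simulation_truth")

  list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d SNPs, true beta = %.3f, seed = %s\n",
              nrow(x$snps), x$true_beta, x$config$seed))
  invisible(x)
}

#' Simulate a multivariable MR system with known direct effects
#'
#' Extends [simulate_two_sample()] to K exposures. Each SNP is a primary
#' instrument of one exposure (round-robin assignment); on every other
#' exposure it carries `cross_loading` times its primary effect, so the
#' exposures share genetic architecture (correlated instruments) without the
#' effect matrix being collinear. The outcome's true effect is
#' `sum_k direct_effects[k] * gamma_jk` plus any pleiotropy and sampling
#' noise. Each exposure's total variance explained is `total_r2`.
#'
#' @param config A [simulation_config()]; `true_beta` is ignored in favour
#'   of `direct_effects`.
#' @param direct_effects Numeric vector of K >= 2 true direct effects.
#' @param cross_loading Cross-exposure loading in \[0, 1) (default 0.5).
#' @return A list with `exposures` (named list of K `summary_dataset`s),
#'   `outcome`, `ld`, and `truth` (config, direct effects, per-SNP true
#'   effect matrix).
#' @export
simulate_mvmr <- function(config = simulation_config(), direct_effects,
                          cross_loading = 0.5) {
  K <- length(direct_effects)
  if (K < 2) stop("need K >= 2 direct effects")
  set.seed(config$seed)
  J <- config$n_snps
  maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
  var_snp <- 2 * maf * (1 - maf)
  primary <- ((seq_len(J) - 1) %% K) + 1

  gamma_true <- matrix(0, J, K)
  for (k in seq_len(K)) {
    own <- primary == k
    raw <- stats::rnorm(sum(own))
    raw <- raw * sqrt(config$total_r2 / sum(var_snp[own] * raw^2))
    gamma_true[own, k] <- raw
  }
  # cross loadings off the primary column
  for (k in seq_len(K)) {
    own <- primary == k
    for (m in seq_len(K)[-k]) {
      gamma_true[own, m] <- cross_loading * gamma_true[own, k]
    }
  }

  se_x <- 1 / sqrt(var_snp * config$n_exposure)
  beta_x <- gamma_true + matrix(stats::rnorm(J * K), J, K) * se_x

  n_invalid <- round(config$invalid_fraction * J)
  alpha <- numeric(J)
  if (n_invalid > 0) {
    alpha[sort(sample.int(J, n_invalid))] <-
      stats::rnorm(n_invalid, config$pleiotropy_mean, config$pleiotropy_sd)
  }
  Gamma_true <- drop(gamma_true %*% direct_effects) + alpha
  n_eff <- 4 / (1 / config$n_outcome_cases + 1 / config$n_outcome_controls)
  se_y <- 1 / sqrt(var_snp * n_eff)
  beta_y <- stats::rnorm(J, Gamma_true, se_y)

  al <- draw_alleles(J, rep(FALSE, J))
  idx <- seq_len(J)
  chrom <- as.character(((idx - 1) %% 22) + 1)
  pos <- 5e7 + 2.5e7 * ((idx - 1) %/% 22)
  rsid <- sprintf("rs%06d", idx)
  two_sided_p <- function(beta, se) pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)

  make_exposure <- function(k) {
    summary_dataset(
      data.frame(rsid = rsid, chrom = chrom, pos = pos,
                 effect_allele = al$ea, other_allele = al$oa,
                 eaf = maf, beta = beta_x[, k], se = se_x,
                 pvalue = two_sided_p(beta_x[, k], se_x),
                 n = config$n_exposure, stringsAsFactors = FALSE),
      trait_name = paste0("exposure_", k), trait_type = "continuous"
    )
  }
  exposures <- stats::setNames(lapply(seq_len(K), make_exposure),
                               paste0("exposure_", seq_len(K)))
  outcome <- summary_dataset(
    data.frame(rsid = rsid, chrom = chrom, pos = pos,
               effect_allele = al$ea, other_allele = al$oa,
               eaf = pmin(pmax(maf + stats::rnorm(J, 0, 0.005), 1e-3), 1 - 1e-3),
               beta = beta_y, se = se_y, pvalue = two_sided_p(beta_y, se_y),
               n = config$n_outcome_cases + config$n_outcome_controls,
               stringsAsFactors = FALSE),
    trait_name = "simulated_outcome", trait_type = "binary",
    n_cases = config$n_outcome_cases, n_controls = config$n_outcome_controls
  )
  truth <- structure(list(
    config = config, direct_effects = direct_effects,
    cross_loading = cross_loading,
    snps = data.frame(rsid = rsid, maf = maf, primary = primary,
                      alpha = alpha, Gamma_true = Gamma_true,
                      stringsAsFactors = FALSE),
    gamma_true = gamma_true
  ), class = "simulation_truth")
  list(exposures = exposures, outcome = outcome,
       ld = ld_table(rsid, rsid, rep(1, J)), truth = truth)
}
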