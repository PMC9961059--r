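#' Statistical power of a two-sample MR analysis with a binary outcome
#'
#' Non-centrality approximation in the style of the mRnd calculator: with a
#' combined outcome sample of size `n_total`, case fraction `prop_case`,
#' instruments jointly explaining a fraction `r2_xz` of the exposure
#' variance, and a hypothesized odds ratio per SD of exposure, the power of
#' a two-sided Wald test at level `alpha` is
#' `pnorm(|log(OR)| * sqrt(n_total * r2_xz * prop_case * (1 - prop_case)) - z_{1-alpha/2})`.
#'
#' @param n_total Combined outcome sample size (cases + controls).
#' @param prop_case Case fraction in (0, 1).
#' @param r2_xz Instrument variance explained in (0, 1).
#' @param odds_ratio Hypothesized OR (> 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @return List with `power` (proportion) and `percent` (rounded to the
#'   nearest integer percent).
#' @export
mr_power_binary <- function(n_total, prop_case, r2_xz, odds_ratio,
                            alpha = 0.05) {
  stopifnot(n_total > 0, prop_case > 0, prop_case < 1,
            r2_xz > 0, r2_xz < 1, odds_ratio > 0, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(log(odds_ratio)) *
    sqrt(n_total * r2_xz * prop_case * (1 - prop_case))
  pw <- stats::pnorm(ncp - z)
  list(power = pw, percent = round(100 * pw))
}

#' Minimum detectable odds ratio at a target power
#'
#' Inverts [mr_power_binary()] by monotone bisection: the smallest OR above
#' 1 whose power reaches `target_power`, to relative tolerance 1e-6.
#'
#' @param n_total,prop_case,r2_xz,alpha As in [mr_power_binary()].
#' @param target_power Desired power, in (alpha, 1).
#' @return The minimum detectable odds ratio.
#' @export
minimum_detectable_or <- function(n_total, prop_case, r2_xz,
                                  target_power = 0.8, alpha = 0.05) {
  stopifnot(target_power > alpha, target_power < 1)
  pw <- function(or) mr_power_binary(n_total, prop_case, r2_xz, or, alpha)$power
  lo <- 1
  hi <- 2
  while (pw(hi) < target_power) {
    hi <- hi * 2
    if (hi > 1e6) stop("target power unreachable at these inputs")
  }
  while ((hi - lo) / hi > 1e-6) {
    mid <- (lo + hi) / 2
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}
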