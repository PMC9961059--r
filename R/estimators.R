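#' Per-SNP Wald ratios and first-order weights
#'
#' For each harmonized SNP j computes the ratio estimate b_j = Gamma_j /
#' gamma_j, its first-order standard error s_j = se_Gamma_j / |gamma_j|, and
#' the inverse-variance weight w_j = s_j^-2. These are the inputs of the
#' median- and mode-based estimators and of Cochran's Q.
#'
#' @param data A `harmonized_data` object.
#' @return Data frame with columns `rsid`, `b`, `s`, `w` in input order.
#' @export
wald_ratios <- function(data) {
  p <- data$pairs
  zero <- p$gamma == 0
  if (any(zero)) {
    stop("zero exposure effect for SNP(s): ",
         paste(p$rsid[zero], collapse = ", "),
         "; remove before computing Wald ratios")
  }
  b <- p$Gamma / p$gamma
  s <- p$se_Gamma / abs(p$gamma)
  data.frame(rsid = p$rsid, b = b, s = s, w = s^-2,
             stringsAsFactors = FALSE)
}

#' Convert a log-odds estimate to an odds ratio with confidence interval
#'
#' @param beta Estimate on the log-odds scale.
#' @param se Standard error (> 0).
#' @param level Confidence level (default 0.95).
#' @return List with `or_`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(beta, se, level = 0.95) {
  stopifnot(se >= 0, level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  list(or_ = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

new_mr_estimate <- function(method, n_snp, beta, se, pvalue, level = 0.95,
                            extras = list()) {
  ci <- to_odds_ratio(beta, se, level)
  structure(list(method = method, n_snp = n_snp, beta = beta, se = se,
                 pvalue = pvalue, or_ = ci$or_, ci_low = ci$ci_low,
                 ci_high = ci$ci_high, extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): beta = %.3f (SE %.3f), OR = %.3f (%.3f-%.3f), p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$or_, x$ci_low, x$ci_high,
              x$pvalue))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             or_ = x$or_, ci_low = x$ci_low, ci_high = x$ci_high,
             pvalue = x$pvalue, stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimate
#'
#' Weighted least-squares regression of the outcome effects on the exposure
#' effects through the origin, with weights `se_Gamma^-2` — equivalently the
#' inverse-variance weighted mean of the Wald ratios. The default
#' multiplicative random-effects model scales the standard error by the
#' square root of the weighted residual mean square on J-1 degrees of
#' freedom, floored at 1 (so it never shrinks below the fixed-effect SE);
#' `flavor = "fixed"` disables the scaling. The p-value is two-sided normal.
#'
#' @param data A `harmonized_data` object with at least 2 SNPs.
#' @param flavor `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @param level Confidence level for the odds-ratio interval.
#' @return An `mr_estimate`.
#' @export
ivw <- function(data, flavor = c("random", "fixed"), level = 0.95) {
  flavor <- match.arg(flavor)
  p <- data$pairs
  J <- nrow(p)
  if (J < 2) {
    stop("IVW needs at least 2 SNPs; use wald_ratios() for a single instrument")
  }
  w <- p$se_Gamma^-2
  g <- p$gamma
  beta <- sum(w * g * p$Gamma) / sum(w * g^2)
  se_fixed <- sqrt(1 / sum(w * g^2))
  resid <- p$Gamma - beta * g
  sigma2 <- sum(w * resid^2) / (J - 1)
  scale <- if (flavor == "random") max(1, sqrt(sigma2)) else 1
  se <- se_fixed * scale
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("IVW", J, beta, se, pval, level,
                  extras = list(flavor = flavor, sigma = sqrt(sigma2)))
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with a free intercept (weights `se_Gamma^-2`), after orienting every pair
#' so the exposure effect is non-negative. The slope is the causal estimate
#' under the InSIDE assumption; the intercept estimates the average
#' directional pleiotropic effect, and its test (t, J-2 df) is the standard
#' pleiotropy diagnostic. Standard errors are scaled by the square root of
#' the weighted residual mean square on J-2 df, floored at 1.
#'
#' @param data A `harmonized_data` object with at least 3 SNPs.
#' @param level Confidence level for the odds-ratio interval.
#' @return An `mr_estimate` for the slope; `$extras$intercept` holds the
#'   intercept block (`estimate`, `se`, `pvalue`).
#' @export
egger <- function(data, level = 0.95) {
  p <- data$pairs
  J <- nrow(p)
  if (J < 3) stop("MR-Egger needs at least 3 SNPs")
  flip <- p$gamma < 0
  g <- ifelse(flip, -p$gamma, p$gamma)
  G <- ifelse(flip, -p$Gamma, p$Gamma)
  w <- p$se_Gamma^-2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swg <- sum(w * g); swg2 <- sum(w * g^2)
  swG <- sum(w * G); swgG <- sum(w * g * G)
  det <- sw * swg2 - swg^2
  if (det <= 0 || !is.finite(det)) stop("degenerate exposure effects in MR-Egger")
  slope <- (sw * swgG - swg * swG) / det
  inter <- (swg2 * swG - swg * swgG) / det
  resid <- G - inter - slope * g
  sigma2 <- sum(w * resid^2) / (J - 2)
  scale <- max(1, sqrt(sigma2))
  se_slope <- sqrt(sw / det) * scale
  se_inter <- sqrt(swg2 / det) * scale
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = J - 2)
  p_inter <- 2 * stats::pt(-abs(inter / se_inter), df = J - 2)
  new_mr_estimate(
    "MR-Egger", J, slope, se_slope, p_slope, level,
    extras = list(intercept = list(estimate = inter, se = se_inter,
                                   pvalue = p_inter, df = J - 2),
                  sigma = sqrt(sigma2))
  )
}

# Weighted median of ratios b with weights w, mid-cumulative convention:
# the estimate interpolates linearly between the sorted ratios whose
# shifted cumulative weights (cumsum(w) - w/2, normalized) bracket 0.5.
weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  # snap floating-point ties: a cumulative weight within 1e-12 of 0.5 is an
  # exact hit, otherwise rounding can leak a vanishing interpolation weight
  # onto an arbitrarily distant neighbour
  hit <- which(abs(p - 0.5) <= 1e-12)
  if (length(hit) > 0) return(b[hit[1]])
  if (p[1] > 0.5) return(b[1])
  if (p[length(p)] < 0.5) return(b[length(b)])
  k <- max(which(p < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

# Parametric bootstrap SE: resample each ratio from N(b_j, s_j), recompute
# the point estimate, summarise the spread over draws. Weights stay fixed.
# The median uses the SD; the mode estimators use the MAD, because a
# minority of bootstrap draws can hop between density modes, making the SD
# grossly anticonservative as a scale estimate of the central sampling
# distribution.
bootstrap_se <- function(b, s, n_boot, seed, point_fun,
                         summary = c("sd", "mad")) {
  summary <- match.arg(summary)
  set.seed(seed)
  est <- vapply(seq_len(n_boot), function(i) {
    point_fun(stats::rnorm(length(b), b, s))
  }, numeric(1))
  if (summary == "sd") stats::sd(est) else stats::mad(est)
}

#' Weighted median estimate
#'
#' The 50th weighted percentile of the per-SNP Wald ratios with
#' inverse-variance weights, interpolated with the mid-cumulative
#' convention. Consistent when valid instruments carry more than half of the
#' total weight. The standard error comes from a parametric bootstrap
#' (resampling each ratio from its first-order normal distribution); the
#' p-value is a two-sided normal approximation.
#'
#' @param data A `harmonized_data` object with at least 3 SNPs.
#' @param n_boot Bootstrap draw count (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @param level Confidence level for the odds-ratio interval.
#' @return An `mr_estimate`; `$extras$n_boot` records the draw count.
#' @export
weighted_median <- function(data, n_boot = 1000, seed = 1, level = 0.95) {
  r <- wald_ratios(data)
  J <- nrow(r)
  if (J < 3) stop("weighted median needs at least 3 SNPs")
  beta <- weighted_median_point(r$b, r$w)
  se <- bootstrap_se(r$b, r$s, n_boot, seed,
                     function(bb) weighted_median_point(bb, r$w))
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("Weighted median", J, beta, se, pval, level,
                  extras = list(n_boot = n_boot, seed = seed))
}

# Silverman-type bandwidth over the ratios; phi is a user multiplier.
# If exactly one of sd/mad is zero (e.g. a strict majority at one value)
# the positive scale is used so the kernel stays proper.
mode_bandwidth <- function(b, phi) {
  s1 <- stats::sd(b)
  s2 <- stats::mad(b)  # default constant 1.4826 = 1/0.6745 on the raw MAD
  scale <- min(s1, s2)
  if (scale == 0) scale <- max(s1, s2)
  phi * 0.9 * scale * length(b)^(-1 / 5)
}

# Exact weighted Gaussian KDE evaluated at arbitrary points.
kde_at <- function(x, b, w, h) {
  wn <- w / sum(w)
  drop(stats::dnorm(outer(x, b, "-") / h) %*% wn) / h
}

# Argmax of the weighted Gaussian KDE of ratios b over a 10,000-point grid
# spanning [min(b) - 2h, max(b) + 2h]; ties resolve to the lowest grid
# value. The exact KDE is only evaluated at fine-grid points pre-screened
# by a binned FFT density (bin width <= h/3, so binning error is far below
# the 5% screening margin); the screen keeps every region within 5% of the
# binned maximum, expanded by two bins.
mode_point <- function(b, w, h, grid_n = 10000) {
  if (h <= 0 || !is.finite(h)) return(sort(b)[1])
  lo <- min(b) - 2 * h
  hi <- max(b) + 2 * h
  grid <- seq(lo, hi, length.out = grid_n)
  step <- (hi - lo) / (grid_n - 1)
  nb <- 2^ceiling(log2(max(512, 3 * (hi - lo) / h)))
  cand <- if (nb > 32768) {
    seq_len(grid_n)
  } else {
    d <- stats::density(b, weights = w / sum(w), bw = h, kernel = "gaussian",
                        from = lo, to = hi, n = nb)
    # coarse bin width <= h/3, so binning error is well under the 5%
    # screening margin; expand each kept run by two bins
    keep <- d$y >= 0.95 * max(d$y)
    runs <- rle(keep)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    idx <- integer(0)
    for (ri in which(runs$values)) {
      xlo <- d$x[max(1L, starts[ri] - 2L)]
      xhi <- d$x[min(nb, ends[ri] + 2L)]
      ilo <- max(1L, as.integer(ceiling((xlo - lo) / step - 1e-9)) + 1L)
      ihi <- min(grid_n, as.integer(floor((xhi - lo) / step + 1e-9)) + 1L)
      if (ihi >= ilo) idx <- c(idx, ilo:ihi)
    }
    unique(idx)
  }
  dens <- kde_at(grid[cand], b, w, h)
  grid[cand[which.max(dens)]]
}

#' Mode-based estimate (weighted or simple)
#'
#' The argmax of a Gaussian-kernel density over the per-SNP Wald ratios,
#' weighted by inverse-variance weights (weighted mode) or uniformly (simple
#' mode). Consistent when the largest cluster of instruments is valid (the
#' ZEMPA assumption), even if more than half are pleiotropic. The bandwidth
#' is `phi * 0.9 * min(sd(b), mad(b)) * J^(-1/5)`; the density is maximised
#' over a 10,000-point grid spanning the ratio range extended by two
#' bandwidths. Standard errors use the same parametric bootstrap as the
#' weighted median, summarised by the MAD of the bootstrap estimates (the
#' mode can hop between density peaks in a minority of draws, which would
#' inflate an SD beyond the scale of the central sampling distribution). If all ratios are identical the common ratio is returned
#' with SE 0.
#'
#' @param data A `harmonized_data` object with at least 3 SNPs.
#' @param weighted Use inverse-variance weights (`TRUE`, the weighted mode)
#'   or uniform weights (`FALSE`, the simple mode).
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap draw count (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param level Confidence level for the odds-ratio interval.
#' @return An `mr_estimate`; `$extras` records `phi`, the bandwidth and
#'   `n_boot`.
#' @export
mode_estimate <- function(data, weighted = TRUE, phi = 1, n_boot = 1000,
                          seed = 1, level = 0.95) {
  r <- wald_ratios(data)
  J <- nrow(r)
  if (J < 3) stop("mode estimate needs at least 3 SNPs")
  method <- if (weighted) "Weighted mode" else "Simple mode"
  w <- if (weighted) r$w else rep(1 / J, J)
  if (length(unique(r$b)) == 1) {
    return(new_mr_estimate(method, J, r$b[1], 0, NA_real_, level,
                           extras = list(phi = phi, bandwidth = 0,
                                         n_boot = 0, seed = seed)))
  }
  h <- mode_bandwidth(r$b, phi)
  beta <- mode_point(r$b, w, h)
  se <- bootstrap_se(r$b, r$s, n_boot, seed, function(bb) {
    if (length(unique(bb)) == 1) return(bb[1])
    mode_point(bb, w, mode_bandwidth(bb, phi))
  }, summary = "mad")
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(method, J, beta, se, pval, level,
                  extras = list(phi = phi, bandwidth = h, n_boot = n_boot,
                                seed = seed))
}

#' Run the five standard two-sample MR estimators
#'
#' Computes IVW, MR-Egger, weighted median, weighted mode and simple mode on
#' one harmonized dataset and returns them in that order.
#'
#' @param data A `harmonized_data` object.
#' @param n_boot Bootstrap draw count for median/mode SEs.
#' @param phi Mode bandwidth multiplier.
#' @param seed RNG seed for the bootstraps.
#' @param flavor IVW flavor, `"random"` or `"fixed"`.
#' @param level Confidence level.
#' @return A list of `mr_estimate` objects; `as.data.frame` on it (via
#'   [estimates_table()]) gives the familiar results table (method, n_snp,
#'   beta, se, OR, CI, p).
#' @export
run_all_methods <- function(data, n_boot = 1000, phi = 1, seed = 1,
                            flavor = "random", level = 0.95) {
  list(
    ivw = ivw(data, flavor = flavor, level = level),
    egger = egger(data, level = level),
    weighted_median = weighted_median(data, n_boot = n_boot, seed = seed,
                                      level = level),
    weighted_mode = mode_estimate(data, weighted = TRUE, phi = phi,
                                  n_boot = n_boot, seed = seed + 1,
                                  level = level),
    simple_mode = mode_estimate(data, weighted = FALSE, phi = phi,
                                n_boot = n_boot, seed = seed + 2,
                                level = level)
  )
}

#' Flatten a list of MR estimates into a results table
#'
#' @param estimates A list of `mr_estimate` objects (e.g. from
#'   [run_all_methods()]).
#' @return Data frame with one row per method.
#' @export
estimates_table <- function(estimates) {
  do.call(rbind, lapply(unname(estimates), as.data.frame))
}
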