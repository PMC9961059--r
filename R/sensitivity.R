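#' Cochran's Q heterogeneity test
#'
#' Q is the inverse-variance weighted sum of squared deviations of the
#' per-SNP Wald ratios from the pooled IVW estimate, using first-order
#' ratio standard errors; under homogeneity Q is chi-square with J-1
#' degrees of freedom. I-squared = max(0, (Q - df)/Q) summarises the excess
#' heterogeneity fraction.
#'
#' @param data A `harmonized_data` object with at least 2 SNPs.
#' @param around Optional `mr_estimate` (or numeric beta) to centre Q on;
#'   defaults to the IVW estimate of `data`.
#' @return List with `q`, `df`, `pvalue`, `i2`.
#' @export
cochran_q <- function(data, around = NULL) {
  r <- wald_ratios(data)
  J <- nrow(r)
  if (J < 2) stop("Cochran's Q needs at least 2 SNPs")
  beta <- if (is.null(around)) {
    ivw(data)$beta
  } else if (inherits(around, "mr_estimate")) {
    around$beta
  } else {
    as.numeric(around)
  }
  q <- sum(r$w * (r$b - beta)^2)
  df <- J - 1
  list(q = q, df = df,
       pvalue = stats::pchisq(q, df = df, lower.tail = FALSE),
       i2 = if (q > 0) max(0, (q - df) / q) else 0)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exposes the intercept block of the [egger()] fit as a standalone
#' diagnostic: an intercept close to 0 (p > 0.05) is the conventional
#' indication of no directional horizontal pleiotropy.
#'
#' @param data A `harmonized_data` object with at least 3 SNPs.
#' @return List with `estimate`, `se`, `pvalue`, `df`.
#' @export
egger_intercept_test <- function(data) {
  egger(data)$extras$intercept
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Re-estimates the IVW effect J times, omitting each SNP in turn, and
#' appends the all-SNP estimate; a single influential SNP shows up as a
#' large shift on omission.
#'
#' @param data A `harmonized_data` object with at least 3 SNPs.
#' @param flavor IVW flavor passed through to [ivw()].
#' @return Data frame with J + 1 rows: `omitted` (rsid or `"none"`), `beta`,
#'   `se`, `pvalue`, `or_`, `ci_low`, `ci_high`.
#' @export
leave_one_out <- function(data, flavor = "random") {
  p <- data$pairs
  J <- nrow(p)
  if (J < 3) stop("leave-one-out needs at least 3 SNPs")
  one_row <- function(est, label) {
    data.frame(omitted = label, beta = est$beta, se = est$se,
               pvalue = est$pvalue, or_ = est$or_, ci_low = est$ci_low,
               ci_high = est$ci_high, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(J), function(j) {
    sub <- data
    sub$pairs <- p[-j, , drop = FALSE]
    one_row(ivw(sub, flavor = flavor), p$rsid[j])
  })
  rows[[J + 1]] <- one_row(ivw(data, flavor = flavor), "none")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-SNP forest table
#'
#' The data matrix behind a single-SNP forest plot: each SNP's Wald ratio
#' with its first-order SE and normal confidence interval, plus the pooled
#' IVW row.
#'
#' @param data A `harmonized_data` object.
#' @param level Confidence level (default 0.95).
#' @param flavor IVW flavor for the pooled row.
#' @return Data frame with columns `rsid`, `beta`, `se`, `ci_low`, `ci_high`
#'   (log-odds scale) and `or_`, `or_low`, `or_high`; the last row is the
#'   pooled estimate (`rsid = "All - IVW"`).
#' @export
single_snp_forest <- function(data, level = 0.95, flavor = "random") {
  r <- wald_ratios(data)
  z <- stats::qnorm((1 + level) / 2)
  tab <- data.frame(rsid = r$rsid, beta = r$b, se = r$s,
                    ci_low = r$b - z * r$s, ci_high = r$b + z * r$s,
                    stringsAsFactors = FALSE)
  if (nrow(r) >= 2) {
    est <- ivw(data, flavor = flavor, level = level)
    tab <- rbind(tab, data.frame(rsid = "All - IVW", beta = est$beta,
                                 se = est$se, ci_low = est$beta - z * est$se,
                                 ci_high = est$beta + z * est$se))
  } else {
    tab <- rbind(tab, data.frame(rsid = "All - IVW", beta = r$b[1],
                                 se = r$s[1], ci_low = r$b[1] - z * r$s[1],
                                 ci_high = r$b[1] + z * r$s[1]))
  }
  tab$or_ <- exp(tab$beta)
  tab$or_low <- exp(tab$ci_low)
  tab$or_high <- exp(tab$ci_high)
  rownames(tab) <- NULL
  tab
}

#' Funnel-plot table
#'
#' Each SNP's Wald ratio against its precision (1/SE); asymmetry about the
#' pooled estimate suggests directional pleiotropy. Reference lines at the
#' IVW and (when J >= 3) MR-Egger estimates are attached as an attribute.
#'
#' @param data A `harmonized_data` object.
#' @return Data frame with columns `rsid`, `b`, `precision`; attribute
#'   `"reference"` holds named reference betas.
#' @export
funnel_data <- function(data) {
  r <- wald_ratios(data)
  out <- data.frame(rsid = r$rsid, b = r$b, precision = 1 / r$s,
                    stringsAsFactors = FALSE)
  refs <- c(IVW = if (nrow(r) >= 2) ivw(data)$beta else r$b[1])
  if (nrow(r) >= 3) refs <- c(refs, `MR-Egger` = egger(data)$beta)
  attr(out, "reference") <- refs
  out
}
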