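#' Multivariable MR input container
#'
#' Per-SNP genetic effects on K exposures together with the outcome effect,
#' all expressed on a common effect allele.
#'
#' @param rsid SNP identifiers.
#' @param gamma J x K matrix of exposure effects (columns named by
#'   exposure).
#' @param se_gamma J x K matrix of exposure standard errors.
#' @param Gamma,se_Gamma Outcome effects and standard errors (length J).
#' @param exposure_names Optional exposure labels; default from `gamma`'s
#'   column names.
#' @return An object of class `mvmr_input`.
#' @export
mvmr_input <- function(rsid, gamma, se_gamma, Gamma, se_Gamma,
                       exposure_names = colnames(gamma)) {
  gamma <- as.matrix(gamma)
  se_gamma <- as.matrix(se_gamma)
  K <- ncol(gamma)
  if (K < 2) stop("multivariable MR needs K >= 2 exposures")
  if (is.null(exposure_names)) exposure_names <- paste0("exposure_", seq_len(K))
  stopifnot(nrow(gamma) == length(Gamma), length(Gamma) == length(se_Gamma),
            all(dim(gamma) == dim(se_gamma)), all(se_Gamma > 0),
            !anyNA(gamma), !anyNA(Gamma))
  colnames(gamma) <- colnames(se_gamma) <- exposure_names
  structure(list(rsid = rsid, gamma = gamma, se_gamma = se_gamma,
                 Gamma = Gamma, se_Gamma = se_Gamma,
                 exposure_names = exposure_names),
            class = "mvmr_input")
}

#' @export
print.mvmr_input <- function(x, ...) {
  cat(sprintf("<mvmr_input> %d SNPs x %d exposures (%s)\n",
              nrow(x$gamma), ncol(x$gamma),
              paste(x$exposure_names, collapse = ", ")))
  invisible(x)
}

# Shared weighted no-intercept regression core used by mvmr_ivw and the
# K = 1 degenerate case. Returns coefficients, unscaled SEs and sigma.
wls_no_intercept <- function(X, y, w, df_resid) {
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  qrx <- qr(XtWX)
  if (qrx$rank < ncol(X)) {
    stop("rank-deficient exposure matrix; collinear exposure(s): ",
         paste(colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]], collapse = ", "))
  }
  XtWX_inv <- solve(XtWX)
  coef <- drop(XtWX_inv %*% (XtW %*% y))
  resid <- y - drop(X %*% coef)
  sigma2 <- sum(w * resid^2) / df_resid
  list(coef = coef, se_unscaled = sqrt(diag(XtWX_inv)), sigma = sqrt(sigma2))
}

#' Multivariable IVW regression
#'
#' Weighted least squares of the outcome effects on the K-column matrix of
#' exposure effects with no intercept and weights `se_Gamma^-2`; coefficient
#' k is exposure k's direct causal effect conditional on the other
#' exposures. Standard errors are scaled by the square root of the weighted
#' residual mean square on J-K degrees of freedom, floored at 1; p-values
#' use the t distribution on J-K df.
#'
#' @param input An [mvmr_input()] with J > K.
#' @param level Confidence level for odds-ratio intervals.
#' @return A list of `mr_estimate` objects, one per exposure, named by
#'   exposure.
#' @export
mvmr_ivw <- function(input, level = 0.95) {
  X <- input$gamma
  J <- nrow(X); K <- ncol(X)
  if (J <= K) stop("need more SNPs than exposures (J = ", J, ", K = ", K, ")")
  w <- input$se_Gamma^-2
  fit <- wls_no_intercept(X, input$Gamma, w, df_resid = J - K)
  scale <- max(1, fit$sigma)
  out <- lapply(seq_len(K), function(k) {
    se <- unname(fit$se_unscaled[k]) * scale
    pval <- 2 * stats::pt(-abs(fit$coef[k] / se), df = J - K)
    new_mr_estimate(paste0("MVMR-IVW: ", input$exposure_names[k]), J,
                    unname(fit$coef[k]), se, pval, level,
                    extras = list(df = J - K, sigma = fit$sigma))
  })
  stats::setNames(out, input$exposure_names)
}

#' Assemble a multivariable MR input from raw summary datasets
#'
#' Selects instruments per exposure (p-value screen), clumps the union
#' jointly (ranking SNPs by the minimum p-value across exposures), then for
#' every retained SNP requires an effect in all exposures and harmonizes
#' every dataset to the first exposure's allele orientation against the
#' outcome. SNPs missing from any exposure or failing harmonization are
#' dropped and logged.
#'
#' @param exposures Named list of `summary_dataset` objects (K >= 2).
#' @param outcome The outcome `summary_dataset`.
#' @param ld Optional `ld_table` for joint clumping.
#' @param config A [selection_config()].
#' @param maf_threshold Palindrome ambiguity cutoff.
#' @return An `mvmr_input` with attribute `"drop_log"`.
#' @export
assemble_mvmr_input <- function(exposures, outcome, ld = NULL,
                                config = selection_config(),
                                maf_threshold = 0.3) {
  K <- length(exposures)
  if (K < 2) stop("need at least 2 exposure datasets")
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    names(exposures) <- vapply(exposures, function(d) d$trait_name, "")
  }
  selected <- lapply(exposures, select_by_pvalue, threshold = config$p_threshold)
  union_rsid <- unique(unlist(lapply(selected, function(d) d$records$rsid)))
  if (length(union_rsid) == 0) stop("no instrument passes the p-value screen")

  # joint ranking dataset: per SNP, min p across exposures; coordinates from
  # the first exposure that carries the SNP
  min_p <- rep(Inf, length(union_rsid)); names(min_p) <- union_rsid
  coord <- list()
  for (d in exposures) {
    rec <- d$records
    hit <- rec$rsid %in% union_rsid
    for (i in which(hit)) {
      id <- rec$rsid[i]
      if (!is.na(rec$pvalue[i]) && rec$pvalue[i] < min_p[[id]]) {
        min_p[[id]] <- rec$pvalue[i]
      }
      if (is.null(coord[[id]])) coord[[id]] <- rec[i, c("chrom", "pos")]
    }
  }
  rank_rec <- data.frame(
    rsid = union_rsid,
    chrom = vapply(union_rsid, function(id) as.character(coord[[id]]$chrom), ""),
    pos = vapply(union_rsid, function(id) as.numeric(coord[[id]]$pos), 0),
    effect_allele = "A", other_allele = "G", eaf = NA_real_,
    beta = 0, se = 1, pvalue = unname(min_p), n = NA_real_,
    stringsAsFactors = FALSE
  )
  rank_ds <- summary_dataset(rank_rec, trait_name = "joint", trait_type = "continuous")
  clumped <- clump(rank_ds, ld = ld, config = config)$records$rsid

  ref <- exposures[[1]]
  ref_rec <- ref$records; rownames(ref_rec) <- ref_rec$rsid
  drop_log <- list()
  rows <- list()
  for (id in clumped) {
    if (!id %in% ref_rec$rsid) {
      drop_log[[length(drop_log) + 1]] <-
        data.frame(rsid = id, reason = paste0("missing_from_", names(exposures)[1]))
      next
    }
    xref <- ref_rec[id, ]
    g <- se_g <- rep(NA_real_, K)
    g[1] <- xref$beta; se_g[1] <- xref$se
    ok <- TRUE
    for (k in seq_len(K)[-1]) {
      rec_k <- exposures[[k]]$records
      j <- match(id, rec_k$rsid)
      if (is.na(j)) {
        drop_log[[length(drop_log) + 1]] <-
          data.frame(rsid = id, reason = paste0("missing_from_", names(exposures)[k]))
        ok <- FALSE; break
      }
      h <- harmonize_pair(xref, rec_k[j, ], maf_threshold = maf_threshold)
      if (is.null(h$pair)) {
        drop_log[[length(drop_log) + 1]] <-
          data.frame(rsid = id, reason = paste0(h$drop_reason, "_",
                                                names(exposures)[k]))
        ok <- FALSE; break
      }
      g[k] <- h$pair$Gamma; se_g[k] <- h$pair$se_Gamma
    }
    if (!ok) next
    jo <- match(id, outcome$records$rsid)
    if (is.na(jo)) {
      drop_log[[length(drop_log) + 1]] <-
        data.frame(rsid = id, reason = "absent_from_outcome")
      next
    }
    h <- harmonize_pair(xref, outcome$records[jo, ], maf_threshold = maf_threshold)
    if (is.null(h$pair)) {
      drop_log[[length(drop_log) + 1]] <-
        data.frame(rsid = id, reason = paste0(h$drop_reason, "_outcome"))
      next
    }
    rows[[length(rows) + 1]] <-
      list(rsid = id, g = g, se_g = se_g, G = h$pair$Gamma,
           se_G = h$pair$se_Gamma)
  }
  if (length(rows) == 0) stop("empty joint instrument set after assembly")
  out <- mvmr_input(
    rsid = vapply(rows, `[[`, "", "rsid"),
    gamma = do.call(rbind, lapply(rows, `[[`, "g")),
    se_gamma = do.call(rbind, lapply(rows, `[[`, "se_g")),
    Gamma = vapply(rows, `[[`, 0, "G"),
    se_Gamma = vapply(rows, `[[`, 0, "se_G"),
    exposure_names = names(exposures)
  )
  attr(out, "drop_log") <- if (length(drop_log) > 0) do.call(rbind, drop_log)
    else data.frame(rsid = character(0), reason = character(0))
  out
}

#' Univariable IVW through the multivariable machinery
#'
#' Runs the multivariable weighted regression with a single exposure
#' column; numerically identical to [ivw()] (used as an internal
#' consistency check of the two fitting paths).
#'
#' @param data A `harmonized_data` object.
#' @param flavor `"random"` or `"fixed"`.
#' @return An `mr_estimate` (p-value from the t distribution on J-1 df).
#' @export
mvmr_ivw_univariable <- function(data, flavor = "random") {
  p <- data$pairs
  J <- nrow(p)
  if (J < 2) stop("need at least 2 SNPs")
  X <- matrix(p$gamma, ncol = 1, dimnames = list(NULL, "exposure"))
  fit <- wls_no_intercept(X, p$Gamma, p$se_Gamma^-2, df_resid = J - 1)
  scale <- if (flavor == "random") max(1, fit$sigma) else 1
  se <- unname(fit$se_unscaled[1]) * scale
  pval <- 2 * stats::pt(-abs(fit$coef[1] / se), df = J - 1)
  new_mr_estimate("MVMR-IVW: exposure", J, unname(fit$coef[1]), se, pval,
                  extras = list(df = J - 1, sigma = fit$sigma))
}
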