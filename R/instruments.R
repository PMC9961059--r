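#' Instrument selection configuration
#'
#' Thresholds governing instrument selection: the p-value screen, the greedy
#' LD-clumping rule (prune pairs on the same chromosome within
#' `clump_window_kb` at r-squared above `clump_r2`), the minimum LD for proxy
#' SNPs, and an optional exclusion list of variants associated with
#' confounding pathways (the offline replacement for a PhenoScanner screen).
#'
#' Defaults mirror common practice when genome-wide significance yields too
#' few instruments: p < 1e-5 screening, r2 = 0.001 within 10,000 kb
#' clumping, proxy r2 >= 0.8.
#'
#' @param p_threshold Significance cutoff in (0, 1).
#' @param clump_r2 LD pruning threshold in \[0, 1\].
#' @param clump_window_kb Clumping distance window in kb (> 0).
#' @param proxy_min_r2 Minimum r-squared for a proxy SNP.
#' @param exclusion_list Optional character vector of rsids to remove.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 1e-5, clump_r2 = 0.001,
                             clump_window_kb = 10000, proxy_min_r2 = 0.8,
                             exclusion_list = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 >= 0, clump_r2 <= 1,
            clump_window_kb > 0,
            proxy_min_r2 >= 0, proxy_min_r2 <= 1)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 proxy_min_r2 = proxy_min_r2,
                 exclusion_list = exclusion_list),
            class = "selection_config")
}

#' Filter SNPs by association p-value
#'
#' Keeps records with p strictly below the threshold, preserving order.
#' Records with missing p-values are dropped.
#'
#' @param dataset A `summary_dataset`.
#' @param threshold Cutoff in (0, 1).
#' @return A filtered `summary_dataset`.
#' @export
select_by_pvalue <- function(dataset, threshold = 1e-5) {
  stopifnot(threshold > 0, threshold < 1)
  rec <- dataset$records
  keep <- !is.na(rec$pvalue) & rec$pvalue < threshold
  if (!any(keep)) {
    warning("no SNP passes p < ", format(threshold), " in ", dataset$trait_name)
  }
  replace_records(dataset, rec[keep, , drop = FALSE])
}

replace_records <- function(dataset, records) {
  rownames(records) <- NULL
  dataset$records <- records
  dataset
}

#' Greedy LD clumping
#'
#' Iterates SNPs in ascending p-value (ties broken by position, then rsid)
#' and keeps each SNP unless it lies within `clump_window_kb` on the same
#' chromosome as an already-kept SNP with pairwise r-squared above
#' `clump_r2`. Pairs absent from the LD table count as r-squared 0; pairs
#' beyond the window are treated as independent regardless of the table.
#' Output order follows the dataset's (chrom, pos) sorting, so the result is
#' invariant to input record order.
#'
#' @param dataset A `summary_dataset`.
#' @param ld An `ld_table` or `NULL`.
#' @param config A [selection_config()].
#' @return A clumped `summary_dataset`.
#' @export
clump <- function(dataset, ld = NULL, config = selection_config()) {
  rec <- dataset$records
  if (nrow(rec) <= 1) return(dataset)
  ord <- order(rec$pvalue, rec$pos, rec$rsid)
  window_bp <- config$clump_window_kb * 1000
  kept_idx <- integer(0)
  for (i in ord) {
    if (length(kept_idx) == 0) {
      kept_idx <- i
      next
    }
    same_chr <- rec$chrom[kept_idx] == rec$chrom[i]
    in_window <- same_chr & abs(rec$pos[kept_idx] - rec$pos[i]) <= window_bp
    if (any(in_window)) {
      r2 <- ld_r2(ld, rec$rsid[kept_idx][in_window], rec$rsid[i])
      if (any(r2 > config$clump_r2)) next
    }
    kept_idx <- c(kept_idx, i)
  }
  replace_records(dataset, rec[sort(kept_idx), , drop = FALSE])
}

#' Find a proxy SNP in the outcome dataset
#'
#' When an instrument is absent from the outcome GWAS, searches the outcome
#' dataset for the SNP with maximal r-squared to the query among candidates
#' with r-squared at or above `min_r2`. Ties are broken by smaller base-pair
#' distance to the query (when `target_chrom`/`target_pos` are supplied),
#' then lexicographically by rsid.
#'
#' @param rsid Query SNP identifier (absent from `outcome`).
#' @param outcome A `summary_dataset` to search.
#' @param ld An `ld_table`.
#' @param min_r2 Minimum acceptable r-squared (default 0.8).
#' @param target_chrom,target_pos Optional coordinates of the query SNP for
#'   the distance tie-break.
#' @return The proxy rsid, or `NULL` if no candidate qualifies.
#' @export
find_proxy <- function(rsid, outcome, ld, min_r2 = 0.8,
                       target_chrom = NULL, target_pos = NULL) {
  rec <- outcome$records
  cand <- rec[rec$rsid != rsid, , drop = FALSE]
  if (nrow(cand) == 0 || is.null(ld)) return(NULL)
  r2 <- ld_r2(ld, cand$rsid, rsid)
  ok <- r2 >= min_r2
  if (!any(ok)) return(NULL)
  cand <- cand[ok, , drop = FALSE]
  r2 <- r2[ok]
  dist <- if (!is.null(target_pos) && !is.null(target_chrom)) {
    ifelse(cand$chrom == target_chrom, abs(cand$pos - target_pos), Inf)
  } else {
    rep(Inf, nrow(cand))
  }
  best <- order(-r2, dist, cand$rsid)[1]
  cand$rsid[best]
}

#' Remove listed SNPs from a dataset
#'
#' Offline confounder screen: removes records whose rsid appears in the
#' exclusion list (e.g. variants a PhenoScanner-style lookup linked to
#' mechanistic pathways of the outcome).
#'
#' @param dataset A `summary_dataset`.
#' @param exclusion_list Character vector of rsids (or `NULL`).
#' @return The filtered `summary_dataset`, with attribute `"n_removed"`.
#' @export
exclude_snps <- function(dataset, exclusion_list) {
  rec <- dataset$records
  drop <- rec$rsid %in% exclusion_list
  out <- replace_records(dataset, rec[!drop, , drop = FALSE])
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Per-SNP instrument strength
#'
#' Computes the proportion of exposure variance explained by one SNP,
#' r2 = beta^2 / (beta^2 + n se^2), and the corresponding F statistic
#' F = r2 (n - 2) / (1 - r2). When the sample size is unavailable the
#' chi-square approximation F = (beta/se)^2 is used and flagged; r2 is then
#' `NA`. F > 10 is the conventional screen against weak-instrument bias.
#'
#' @param record One-row records data frame (or list) with `beta` and `se`.
#' @param n Sample size; defaults to the record's `n` field.
#' @return A list with `rsid`, `f_stat`, `r2`, and logical `approximate`.
#' @export
instrument_strength <- function(record, n = record$n) {
  beta <- record$beta
  se <- record$se
  stopifnot(se > 0)
  if (is.null(n) || length(n) == 0 || is.na(n)) {
    return(list(rsid = record$rsid, f_stat = (beta / se)^2, r2 = NA_real_,
                approximate = TRUE))
  }
  stopifnot(n > 2)
  r2 <- beta^2 / (beta^2 + n * se^2)
  f <- r2 * (n - 2) / (1 - r2)
  list(rsid = record$rsid, f_stat = f, r2 = r2, approximate = FALSE)
}

#' Instrument strength for every SNP in a dataset
#'
#' @param dataset A `summary_dataset`.
#' @param n Sample size used for every SNP; defaults to each record's `n`.
#' @return Data frame with columns `rsid`, `f_stat`, `r2`, `approximate`.
#' @export
dataset_strengths <- function(dataset, n = NULL) {
  rec <- dataset$records
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    s <- instrument_strength(rec[i, ], n = if (is.null(n)) rec$n[i] else n)
    data.frame(rsid = s$rsid, f_stat = s$f_stat, r2 = s$r2,
               approximate = s$approximate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Total variance explained by independent instruments
#'
#' Sums per-SNP r2 over instruments, assuming approximate independence after
#' LD clumping.
#'
#' @param strengths Data frame from [dataset_strengths()] (or any frame with
#'   an `r2` column).
#' @return A list with `proportion` and `percent`.
#' @export
total_variance_explained <- function(strengths) {
  if (nrow(strengths) == 0) stop("no instruments supplied")
  prop <- sum(strengths$r2)
  list(proportion = prop, percent = 100 * prop)
}
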