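#' Is an allele pair palindromic?
#'
#' A palindromic (strand-ambiguous) SNP has alleles that are each other's
#' complement: A/T or C/G. For such SNPs the allele labels cannot resolve
#' which strand a study reported, so alignment must fall back on allele
#' frequency.
#'
#' @param effect_allele,other_allele Single upper-case bases.
#' @return Logical.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  complement_base(effect_allele) == other_allele
}

complement_base <- function(x) {
  c(A = "T", T = "A", C = "G", G = "C")[x]
}

#' Harmonize one exposure/outcome SNP pair onto the exposure's effect allele
#'
#' Expresses the outcome association on the exposure's effect allele. The
#' exposure orientation is never changed; the outcome effect is negated (and
#' its frequency mirrored) when the outcome file coded the opposite allele.
#' Non-palindromic pairs whose alleles match neither directly nor swapped are
#' retried after strand-complementing the outcome alleles, and dropped on
#' continued mismatch. Palindromic pairs are aligned by allele frequency:
#' both studies must show a minor-allele frequency below `maf_threshold`
#' (otherwise the SNP is ambiguous and dropped); if the two frequencies fall
#' on opposite sides of 0.5 the outcome effect is additionally negated.
#'
#' @param exposure,outcome One-row records (data frame row or list) sharing
#'   an rsid, or mapped through a proxy.
#' @param maf_threshold Palindrome ambiguity cutoff on the minor-allele
#'   frequency (default 0.3; frequencies in \[0.3, 0.7\] are ambiguous).
#' @param proxy_used Optional rsid of the outcome proxy actually used.
#' @return A list: either `pair` (a one-row harmonized data frame with
#'   columns `rsid, gamma, se_gamma, Gamma, se_Gamma, eaf_exposure,
#'   eaf_outcome, palindromic, flipped, proxy_used`) or `drop_reason`
#'   (one of `"allele_mismatch"`, `"ambiguous_palindrome"`).
#' @export
harmonize_pair <- function(exposure, outcome, maf_threshold = 0.3,
                           proxy_used = NA_character_) {
  if (is.na(proxy_used) && !identical(exposure$rsid, outcome$rsid)) {
    stop("rsid mismatch without proxy mapping: ",
         exposure$rsid, " vs ", outcome$rsid)
  }
  ea_x <- exposure$effect_allele; oa_x <- exposure$other_allele
  ea_y <- outcome$effect_allele;  oa_y <- outcome$other_allele
  palin <- is_palindromic(ea_x, oa_x)

  G <- outcome$beta
  eaf_y <- outcome$eaf
  matched <- FALSE
  flipped <- FALSE
  if (ea_y == ea_x && oa_y == oa_x) {
    matched <- TRUE
  } else if (ea_y == oa_x && oa_y == ea_x) {
    matched <- TRUE
    flipped <- TRUE
    G <- -G
    eaf_y <- if (is.na(eaf_y)) NA_real_ else 1 - eaf_y
  } else if (!palin) {
    # strand-complement the outcome alleles and retry
    cea <- unname(complement_base(ea_y)); coa <- unname(complement_base(oa_y))
    if (cea == ea_x && coa == oa_x) {
      matched <- TRUE
    } else if (cea == oa_x && coa == ea_x) {
      matched <- TRUE
      flipped <- TRUE
      G <- -G
      eaf_y <- if (is.na(eaf_y)) NA_real_ else 1 - eaf_y
    }
  }
  if (!matched) return(list(drop_reason = "allele_mismatch"))

  eaf_x <- exposure$eaf
  if (palin) {
    # allele labels cannot resolve strand; use frequencies
    if (is.na(eaf_x) || is.na(eaf_y)) {
      return(list(drop_reason = "ambiguous_palindrome"))
    }
    maf_x <- min(eaf_x, 1 - eaf_x)
    maf_y <- min(eaf_y, 1 - eaf_y)
    if (maf_x >= maf_threshold || maf_y >= maf_threshold) {
      return(list(drop_reason = "ambiguous_palindrome"))
    }
    if ((eaf_x < 0.5) != (eaf_y < 0.5)) {
      G <- -G
      eaf_y <- 1 - eaf_y
      flipped <- TRUE
    }
  }
  list(pair = data.frame(
    rsid = exposure$rsid,
    gamma = exposure$beta, se_gamma = exposure$se,
    Gamma = G, se_Gamma = outcome$se,
    eaf_exposure = eaf_x, eaf_outcome = eaf_y,
    palindromic = palin, flipped = flipped,
    proxy_used = proxy_used, stringsAsFactors = FALSE
  ))
}

#' Harmonize an instrument-selected exposure dataset against an outcome
#'
#' Looks up each exposure SNP in the outcome dataset (falling back to
#' [find_proxy()] when an LD table is supplied), harmonizes each pair with
#' [harmonize_pair()], and returns the harmonized dataset together with a
#' complete drop log: every input SNP is accounted for exactly once as kept
#' or dropped.
#'
#' @param exposure An instrument-selected `summary_dataset`.
#' @param outcome The outcome `summary_dataset`.
#' @param ld Optional `ld_table` enabling proxy search.
#' @param config A [selection_config()]; supplies `proxy_min_r2`.
#' @param maf_threshold Palindrome ambiguity cutoff (default 0.3).
#' @return An object of class `harmonized_data`: list with `pairs` (data
#'   frame, one row per kept SNP) and `drop_log` (data frame rsid/reason).
#' @export
harmonize_datasets <- function(exposure, outcome, ld = NULL,
                               config = selection_config(),
                               maf_threshold = 0.3) {
  xrec <- exposure$records
  yrec <- outcome$records
  rownames(yrec) <- yrec$rsid
  kept <- list()
  dropped <- list()
  for (i in seq_len(nrow(xrec))) {
    x <- xrec[i, ]
    proxy <- NA_character_
    if (x$rsid %in% yrec$rsid) {
      y <- yrec[x$rsid, ]
    } else {
      proxy <- if (!is.null(ld)) {
        p <- find_proxy(x$rsid, outcome, ld, min_r2 = config$proxy_min_r2,
                        target_chrom = x$chrom, target_pos = x$pos)
        if (is.null(p)) NA_character_ else p
      } else NA_character_
      if (is.na(proxy)) {
        dropped[[length(dropped) + 1]] <-
          data.frame(rsid = x$rsid, reason = "absent_from_outcome",
                     stringsAsFactors = FALSE)
        next
      }
      y <- yrec[proxy, ]
    }
    h <- harmonize_pair(x, y, maf_threshold = maf_threshold,
                        proxy_used = proxy)
    if (!is.null(h$pair)) {
      kept[[length(kept) + 1]] <- h$pair
    } else {
      dropped[[length(dropped) + 1]] <-
        data.frame(rsid = x$rsid, reason = h$drop_reason,
                   stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(kept) > 0) do.call(rbind, kept) else NULL
  if (is.null(pairs)) stop("no SNP could be harmonized; no analysis possible")
  drop_log <- if (length(dropped) > 0) do.call(rbind, dropped) else
    data.frame(rsid = character(0), reason = character(0))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, drop_log = drop_log),
            class = "harmonized_data")
}

#' @export
print.harmonized_data <- function(x, ...) {
  cat(sprintf("<harmonized_data> %d SNPs kept, %d dropped\n",
              nrow(x$pairs), nrow(x$drop_log)))
  invisible(x)
}

#' Build a harmonized dataset directly from effect vectors
#'
#' Convenience constructor for analyses starting from already-aligned
#' per-SNP effects (gamma on the exposure, Gamma on the outcome).
#'
#' @param rsid SNP identifiers (default `snp_1 ... snp_J`).
#' @param gamma,se_gamma Exposure effects and standard errors.
#' @param Gamma,se_Gamma Outcome effects and standard errors.
#' @return A `harmonized_data` object with an empty drop log.
#' @export
harmonized_data <- function(gamma, se_gamma, Gamma, se_Gamma,
                            rsid = paste0("snp_", seq_along(gamma))) {
  stopifnot(length(gamma) == length(se_gamma),
            length(gamma) == length(Gamma),
            length(gamma) == length(se_Gamma),
            all(se_gamma > 0), all(se_Gamma > 0))
  structure(list(
    pairs = data.frame(rsid = rsid, gamma = gamma, se_gamma = se_gamma,
                       Gamma = Gamma, se_Gamma = se_Gamma,
                       eaf_exposure = NA_real_, eaf_outcome = NA_real_,
                       palindromic = FALSE, flipped = FALSE,
                       proxy_used = NA_character_, stringsAsFactors = FALSE),
    drop_log = data.frame(rsid = character(0), reason = character(0))
  ), class = "harmonized_data")
}
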