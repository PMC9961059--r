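#' End-to-end two-sample MR pipeline configuration
#'
#' @param exposure,outcome `summary_dataset` objects, or file paths to
#'   canonical summary TSVs.
#' @param ld Optional `ld_table` or path to a 3-column LD TSV.
#' @param exclusion_list Optional character vector of rsids, or path to a
#'   one-rsid-per-line file.
#' @param selection A [selection_config()].
#' @param n_boot Bootstrap draws for median/mode standard errors.
#' @param phi Mode bandwidth multiplier.
#' @param seed RNG seed for the bootstraps (mandatory).
#' @param flavor IVW flavor (`"random"` or `"fixed"`).
#' @param maf_threshold Palindrome ambiguity cutoff.
#' @param power Optional list with `r2_xz` override for the power stage
#'   (defaults to the estimated total variance explained), plus optional
#'   `alpha`.
#' @param out_dir Output directory (created if absent); `NULL` disables
#'   file output.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(exposure, outcome, ld = NULL,
                            exclusion_list = NULL,
                            selection = selection_config(),
                            n_boot = 1000, phi = 1, seed = 1,
                            flavor = "random", maf_threshold = 0.3,
                            power = list(), out_dir = NULL) {
  if (is.null(seed)) stop("a seed is mandatory: bootstrap SEs must be reproducible")
  structure(as.list(environment()), class = "pipeline_config")
}

load_if_path <- function(x, loader, ...) {
  if (is.character(x) && length(x) == 1) loader(x, ...) else x
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full two-sample MR workflow
#'
#' Executes instrument selection (p-value screen, LD clumping, exclusion
#' list), harmonization, the five causal estimators, sensitivity
#' diagnostics (Cochran's Q, Egger intercept, leave-one-out, forest and
#' funnel tables), instrument-strength and power reporting, and writes all
#' result tables plus a JSON manifest recording parameters, seeds and
#' per-stage counts. A rerun with the same configuration (including seed)
#' reproduces every output byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return A result bundle (list) with elements `selection` (per-stage
#'   counts), `harmonized`, `estimates`, `estimates_table`,
#'   `heterogeneity`, `pleiotropy`, `leave_one_out`, `forest`, `funnel`,
#'   `strength` (per-SNP F/r2 plus totals), `power`, and `manifest`.
#' @export
run_mr_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  exposure <- load_if_path(config$exposure, read_summary_table)
  outcome <- load_if_path(config$outcome, read_summary_table,
                          trait_type = "binary")
  ld <- load_if_path(config$ld, read_ld_table)
  excl <- load_if_path(config$exclusion_list, read_exclusion_list)

  counts <- list(input = n_snps(exposure))
  sel <- select_by_pvalue(exposure, config$selection$p_threshold)
  counts$p_screen <- n_snps(sel)
  sel <- clump(sel, ld = ld, config = config$selection)
  counts$clumped <- n_snps(sel)
  sel <- exclude_snps(sel, excl)
  counts$after_exclusion <- n_snps(sel)

  harm <- harmonize_datasets(sel, outcome, ld = ld,
                             config = config$selection,
                             maf_threshold = config$maf_threshold)
  counts$harmonized <- nrow(harm$pairs)
  counts$dropped_in_harmonization <- nrow(harm$drop_log)

  estimates <- run_all_methods(harm, n_boot = config$n_boot,
                               phi = config$phi, seed = config$seed,
                               flavor = config$flavor)
  est_tab <- estimates_table(estimates)
  het <- cochran_q(harm, around = estimates$ivw)
  pleio <- egger_intercept_test(harm)
  loo <- leave_one_out(harm, flavor = config$flavor)
  forest <- single_snp_forest(harm, flavor = config$flavor)
  funnel <- funnel_data(harm)

  kept_rec <- sel$records[sel$records$rsid %in% harm$pairs$rsid, , drop = FALSE]
  kept_ds <- replace_records(sel, kept_rec)
  strength <- dataset_strengths(kept_ds)
  tve <- total_variance_explained(strength)

  r2_xz <- if (!is.null(config$power$r2_xz)) config$power$r2_xz else tve$proportion
  alpha <- if (!is.null(config$power$alpha)) config$power$alpha else 0.05
  pw <- if (!is.null(outcome$n_cases) && !is.null(outcome$n_controls)) {
    n_total <- outcome$n_cases + outcome$n_controls
    c(mr_power_binary(n_total, outcome$n_cases / n_total, r2_xz,
                      estimates$ivw$or_, alpha = alpha),
      list(n_total = n_total, r2_xz = r2_xz, odds_ratio = estimates$ivw$or_))
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("mrpipe")),
    parameters = list(
      p_threshold = config$selection$p_threshold,
      clump_r2 = config$selection$clump_r2,
      clump_window_kb = config$selection$clump_window_kb,
      proxy_min_r2 = config$selection$proxy_min_r2,
      n_boot = config$n_boot, phi = config$phi, seed = config$seed,
      flavor = config$flavor, maf_threshold = config$maf_threshold
    ),
    counts = counts,
    estimates = est_tab,
    heterogeneity = het,
    pleiotropy = pleio,
    strength = list(f_min = min(strength$f_stat), f_max = max(strength$f_stat),
                    variance_explained_pct = tve$percent),
    power = pw
  )
  bundle <- list(selection = counts, harmonized = harm,
                 estimates = estimates, estimates_table = est_tab,
                 heterogeneity = het, pleiotropy = pleio,
                 leave_one_out = loo, forest = forest, funnel = funnel,
                 strength = list(per_snp = strength, total = tve),
                 power = pw, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_tsv(sel$records, p("instruments.tsv"))
    write_tsv(harm$pairs, p("harmonized.tsv"))
    write_tsv(harm$drop_log, p("harmonization_drops.tsv"))
    write_tsv(est_tab, p("estimates.tsv"))
    write_tsv(data.frame(q = het$q, df = het$df, pvalue = het$pvalue,
                         i2 = het$i2), p("heterogeneity.tsv"))
    write_tsv(data.frame(intercept = pleio$estimate, se = pleio$se,
                         pvalue = pleio$pvalue), p("pleiotropy.tsv"))
    write_tsv(loo, p("leave_one_out.tsv"))
    write_tsv(forest, p("forest.tsv"))
    write_tsv(funnel, p("funnel.tsv"))
    write_tsv(strength, p("instrument_strength.tsv"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  bundle
}

#' Render a one-page textual summary of a pipeline run
#'
#' Produces a markdown summary (counts at each selection stage, the
#' five-method results block, heterogeneity, pleiotropy, instrument
#' strength, and power) from a result bundle or from a saved
#' `manifest.json` alone.
#'
#' @param bundle A bundle from [run_mr_pipeline()], or a path to a
#'   `manifest.json`.
#' @return A character scalar of markdown text.
#' @export
mr_report <- function(bundle) {
  m <- if (is.character(bundle)) {
    jsonlite::read_json(bundle, simplifyVector = TRUE)
  } else {
    bundle$manifest
  }
  est <- as.data.frame(m$estimates)
  lines <- c(
    "# Two-sample MR report",
    "",
    sprintf("Instruments: %d input, %d past p-screen, %d after clumping, %d after exclusions, %d harmonized (%d dropped).",
            m$counts$input, m$counts$p_screen, m$counts$clumped,
            m$counts$after_exclusion, m$counts$harmonized,
            m$counts$dropped_in_harmonization),
    "",
    "| Method | N SNPs | Beta | SE | OR (95% CI) | p |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %d | %.3f | %.3f | %.3f (%.3f-%.3f) | %.3g |",
            est$method, est$n_snp, est$beta, est$se, est$or_, est$ci_low,
            est$ci_high, est$pvalue),
    "",
    sprintf("Cochran's Q = %.3f (df %d), p = %.3f; I2 = %.1f%%.",
            m$heterogeneity$q, m$heterogeneity$df, m$heterogeneity$pvalue,
            100 * m$heterogeneity$i2),
    sprintf("MR-Egger intercept = %.4f (SE %.4f), p = %.3f.",
            m$pleiotropy$estimate, m$pleiotropy$se, m$pleiotropy$pvalue),
    sprintf("Per-SNP F statistics span %.2f-%.2f; instruments explain %.2f%% of exposure variance.",
            m$strength$f_min, m$strength$f_max,
            m$strength$variance_explained_pct)
  )
  if (!is.null(m$power)) {
    lines <- c(lines, sprintf(
      "Power to detect OR = %.3f at the observed sample size and R2: %d%%.",
      m$power$odds_ratio, m$power$percent))
  }
  paste(lines, collapse = "\n")
}
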