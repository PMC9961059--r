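#' @keywords internal
"_PACKAGE"

# Canonical column order for summary-statistic tables on disk and in memory.
SUMMARY_COLUMNS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pvalue", "n")

VALID_BASES <- c("A", "C", "G", "T")

#' Construct a GWAS summary dataset
#'
#' Bundles one trait's per-SNP association statistics (one row per biallelic
#' SNP) with trait metadata. Records are sorted by chromosome and position;
#' duplicate SNP identifiers are an error (use [validate_dataset()] to audit
#' a table before construction, or [read_summary_table()], which drops and
#' reports offending rows).
#'
#' @param records Data frame with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#'   `eaf` and `n` may be `NA`.
#' @param trait_name Trait label, e.g. `"PM2.5"`.
#' @param trait_type `"continuous"` (betas in SD units) or `"binary"`
#'   (betas on the log-odds scale).
#' @param n_cases,n_controls Optional case/control counts for binary traits.
#' @return An object of class `summary_dataset`.
#' @export
summary_dataset <- function(records, trait_name, trait_type = c("continuous", "binary"),
                            n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SUMMARY_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    for (col in missing_cols) {
      if (!col %in% c("eaf", "n")) {
        stop("records is missing mandatory column(s): ",
             paste(setdiff(missing_cols, c("eaf", "n")), collapse = ", "))
      }
      records[[col]] <- NA_real_
    }
  }
  records <- records[, SUMMARY_COLUMNS]
  if (anyDuplicated(records$rsid)) {
    stop("duplicate rsid(s): ",
         paste(unique(records$rsid[duplicated(records$rsid)]), collapse = ", "))
  }
  records <- sort_records(records)
  structure(
    list(trait_name = trait_name, trait_type = trait_type, records = records,
         n_cases = n_cases, n_controls = n_controls),
    class = "summary_dataset"
  )
}

# Order by chromosome (numeric-aware: 1..22 before X/Y/MT) then position.
sort_records <- function(records) {
  chrom_num <- suppressWarnings(as.numeric(records$chrom))
  chrom_key <- ifelse(is.na(chrom_num), Inf, chrom_num)
  ord <- order(chrom_key, as.character(records$chrom), records$pos)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s), %d SNPs\n",
              x$trait_name, x$trait_type, nrow(x$records)))
  if (x$trait_type == "binary" && !is.null(x$n_cases)) {
    cat(sprintf("  cases/controls: %s / %s\n", x$n_cases, x$n_controls))
  }
  invisible(x)
}

#' Number of SNP records in a summary dataset
#' @param dataset A `summary_dataset`.
#' @return Integer record count.
#' @export
n_snps <- function(dataset) nrow(dataset$records)

#' Read a delimited GWAS summary-statistics table
#'
#' Reads a delimited text file with a header, maps source columns onto the
#' canonical summary-statistic fields, coerces and validates each row, and
#' returns a [summary_dataset()]. Rows violating record invariants (invalid
#' or multi-base alleles, non-positive SE, p outside (0,1], frequency outside
#' (0,1), unparseable numbers, duplicate rsid) are dropped and tallied in the
#' attached drop report; missing mandatory columns are an error.
#'
#' @param path File path of a delimited text table with header.
#' @param column_map Named character vector mapping canonical field names
#'   (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pvalue`, `n`) to source column names. Defaults to the identity
#'   mapping for the canonical header.
#' @param trait_name,trait_type,n_cases,n_controls Trait metadata passed to
#'   [summary_dataset()].
#' @param sep Field separator (default tab).
#' @return A `summary_dataset` with attribute `"drop_report"`: a data frame
#'   of (reason, n) counting dropped rows.
#' @export
read_summary_table <- function(path, column_map = NULL, trait_name = "trait",
                               trait_type = "continuous",
                               n_cases = NULL, n_controls = NULL, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (is.null(column_map)) {
    column_map <- stats::setNames(SUMMARY_COLUMNS, SUMMARY_COLUMNS)
  }
  mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  for (field in mandatory) {
    src <- column_map[[field]]
    if (is.null(src) || !src %in% names(raw)) {
      stop("mandatory column for field '", field, "' not found in ", path)
    }
  }
  get_col <- function(field, default = NA_character_) {
    src <- column_map[[field]]
    if (!is.null(src) && src %in% names(raw)) raw[[src]] else rep(default, nrow(raw))
  }
  tab <- data.frame(
    rsid = get_col("rsid"),
    chrom = get_col("chrom", "0"),
    pos = suppressWarnings(as.numeric(get_col("pos", "0"))),
    effect_allele = toupper(trimws(get_col("effect_allele"))),
    other_allele = toupper(trimws(get_col("other_allele"))),
    eaf = suppressWarnings(as.numeric(get_col("eaf"))),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    pvalue = suppressWarnings(as.numeric(get_col("pvalue"))),
    n = suppressWarnings(as.numeric(get_col("n"))),
    stringsAsFactors = FALSE
  )
  # 'NA' strings in optional cells become NA silently; mandatory numerics
  # that fail to parse drop the row.
  drop_reason <- rep(NA_character_, nrow(tab))
  mark <- function(cond, reason) {
    cond[is.na(cond)] <- FALSE
    drop_reason[is.na(drop_reason) & cond] <<- reason
  }
  mark(is.na(tab$beta) | is.na(tab$se), "unparseable_numeric")
  mark(!tab$effect_allele %in% VALID_BASES | !tab$other_allele %in% VALID_BASES,
       "invalid_allele")
  mark(tab$effect_allele == tab$other_allele, "identical_alleles")
  mark(tab$se <= 0, "nonpositive_se")
  mark(!is.na(tab$pvalue) & (tab$pvalue <= 0 | tab$pvalue > 1), "invalid_pvalue")
  mark(!is.na(tab$eaf) & (tab$eaf <= 0 | tab$eaf >= 1), "invalid_eaf")
  mark(is.na(tab$pos), "unparseable_numeric")
  mark(duplicated(tab$rsid), "duplicate_rsid")

  kept <- tab[is.na(drop_reason), , drop = FALSE]
  dropped <- drop_reason[!is.na(drop_reason)]
  report <- if (length(dropped) > 0) {
    as.data.frame(table(reason = dropped), responseName = "n",
                  stringsAsFactors = FALSE)
  } else {
    data.frame(reason = character(0), n = integer(0))
  }
  ds <- summary_dataset(kept, trait_name = trait_name, trait_type = trait_type,
                        n_cases = n_cases, n_controls = n_controls)
  attr(ds, "drop_report") <- report
  ds
}

#' Write a summary dataset as a canonical TSV
#'
#' Writes the canonical tab-separated table (header `rsid chrom pos
#' effect_allele other_allele eaf beta se pvalue n`). Numeric fields are
#' printed at full double precision so that [read_summary_table()] on the
#' file reproduces the dataset exactly.
#'
#' @param dataset A `summary_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(dataset, path) {
  rec <- dataset$records
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(
    rsid = rec$rsid, chrom = as.character(rec$chrom), pos = fmt(rec$pos),
    effect_allele = rec$effect_allele, other_allele = rec$other_allele,
    eaf = fmt(rec$eaf), beta = fmt(rec$beta), se = fmt(rec$se),
    pvalue = fmt(rec$pvalue), n = fmt(rec$n),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write summary table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Audit a summary dataset against its invariants
#'
#' A pure reporting operation: never mutates the data. Lists duplicate
#' identifiers, per-row invariant violations (alleles, SE, p-value,
#' frequency), and the fraction of missing `eaf` / `n`.
#'
#' @param dataset A `summary_dataset` (or a bare records data frame).
#' @return A list with `duplicates` (character), `violations` (data frame of
#'   rsid/field/problem), `frac_missing_eaf`, `frac_missing_n`, and logical
#'   `clean`.
#' @export
validate_dataset <- function(dataset) {
  rec <- if (inherits(dataset, "summary_dataset")) dataset$records else
    as.data.frame(dataset, stringsAsFactors = FALSE)
  dup <- unique(rec$rsid[duplicated(rec$rsid)])
  v <- list()
  flag <- function(cond, field, problem) {
    cond[is.na(cond)] <- FALSE
    if (any(cond)) {
      v[[length(v) + 1]] <<- data.frame(rsid = rec$rsid[cond], field = field,
                                        problem = problem,
                                        stringsAsFactors = FALSE)
    }
  }
  flag(!rec$effect_allele %in% VALID_BASES, "effect_allele", "not a single base")
  flag(!rec$other_allele %in% VALID_BASES, "other_allele", "not a single base")
  flag(rec$effect_allele == rec$other_allele, "other_allele",
       "identical to effect allele")
  flag(rec$se <= 0, "se", "not strictly positive")
  flag(!is.na(rec$pvalue) & (rec$pvalue <= 0 | rec$pvalue > 1), "pvalue",
       "outside (0, 1]")
  flag(!is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1), "eaf", "outside (0, 1)")
  violations <- if (length(v) > 0) do.call(rbind, v) else
    data.frame(rsid = character(0), field = character(0), problem = character(0))
  list(
    duplicates = dup,
    violations = violations,
    frac_missing_eaf = mean(is.na(rec$eaf)),
    frac_missing_n = mean(is.na(rec$n)),
    clean = length(dup) == 0 && nrow(violations) == 0
  )
}

#' Pairwise LD lookup table
#'
#' Stores r-squared between SNP pairs under unordered keys. Absent pairs are
#' treated as r-squared 0; the self-pair is always 1.
#'
#' @param snp_a,snp_b Character vectors of SNP identifiers.
#' @param r2 Numeric r-squared values in \[0, 1\].
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(snp_a = character(0), snp_b = character(0),
                     r2 = numeric(0)) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_a) == length(r2))
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) stop("r2 must lie in [0, 1]")
  key <- ld_key(snp_a, snp_b)
  # later entries win on duplicate keys
  map <- stats::setNames(r2, key)
  map <- map[!duplicated(names(map), fromLast = TRUE)]
  structure(list(map = map), class = "ld_table")
}

ld_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("<ld_table> %d pairs\n", length(x$map)))
  invisible(x)
}

#' Look up pairwise r-squared
#'
#' @param ld An `ld_table` (or `NULL`, meaning no LD information).
#' @param a,b SNP identifiers (vectorised, recycled).
#' @return Numeric vector of r-squared; 0 where unrecorded, 1 on self-pairs.
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- ifelse(a == b, 1, 0)
  if (!is.null(ld)) {
    hit <- unname(ld$map[ld_key(a, b)])
    out <- ifelse(a != b & !is.na(hit), hit, out)
  }
  out
}

#' Read an LD table from a 3-column TSV
#'
#' Expected header: `snp_a`, `snp_b`, `r2`.
#'
#' @param path File path.
#' @return An `ld_table`.
#' @export
read_ld_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ld_table(tab$snp_a, tab$snp_b, as.numeric(tab$r2))
}

#' Read an SNP exclusion list (one rsid per line)
#'
#' @param path File path.
#' @return Character vector of rsids.
#' @export
read_exclusion_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}
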