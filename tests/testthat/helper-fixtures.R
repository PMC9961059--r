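# Small deterministic fixtures built in code.

# A records data frame with n well-formed SNPs on distinct chromosomes.
make_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    rsid = sprintf("rs%04d", seq_len(n)),
    chrom = as.character(((seq_len(n) - 1) %% 22) + 1),
    pos = 1e6 + 1e5 * seq_len(n),
    effect_allele = sample(c("A", "C", "G"), n, replace = TRUE),
    other_allele = rep("T", n),
    eaf = runif(n, 0.05, 0.45),
    beta = rnorm(n, 0, 0.02),
    se = runif(n, 0.001, 0.01),
    pvalue = runif(n, 1e-12, 0.9),
    n = rep(10000, n),
    stringsAsFactors = FALSE
  )
}

make_dataset <- function(n, seed = 1, ...) {
  rec <- make_records(n, seed)
  rec$other_allele <- ifelse(rec$effect_allele == "A", "G", "T")  # never palindromic
  summary_dataset(rec, trait_name = "fixture", ...)
}

# Independent greedy clumping reference: re-checks all kept pairs directly.
brute_clump <- function(rec, ld, r2_thr, window_kb) {
  ord <- order(rec$pvalue, rec$pos, rec$rsid)
  kept <- character(0)
  for (i in ord) {
    conflict <- FALSE
    for (k in kept) {
      krow <- rec[rec$rsid == k, ]
      if (krow$chrom == rec$chrom[i] &&
          abs(krow$pos - rec$pos[i]) <= window_kb * 1000 &&
          ld_r2(ld, k, rec$rsid[i]) > r2_thr) conflict <- TRUE
    }
    if (!conflict) kept <- c(kept, rec$rsid[i])
  }
  kept
}

# Exact unweighted/weighted KDE on an arbitrary grid (independent of the
# package's screened evaluation).
exact_kde <- function(x, b, w, h) {
  wn <- w / sum(w)
  vapply(x, function(xi) sum(wn * dnorm((xi - b) / h)) / h, numeric(1))
}
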