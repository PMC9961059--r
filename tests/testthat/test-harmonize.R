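test_that("palindrome detection: exactly the 4 complementary ordered pairs", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ea = bases, oa = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$oa, ]
  hits <- mapply(is_palindromic, pairs$ea, pairs$oa)
  expect_equal(sum(hits), 4)
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
})

rec_row <- function(rsid = "rs1", ea = "A", oa = "G", eaf = 0.2, beta = 0.1,
                    se = 0.01) {
  list(rsid = rsid, chrom = "1", pos = 100, effect_allele = ea,
       other_allele = oa, eaf = eaf, beta = beta, se = se, pvalue = 1e-8,
       n = 1000)
}

test_that("pair harmonization covers identical, swapped, complemented and mismatched alleles", {
  # identical coding: effects copied
  h <- harmonize_pair(rec_row(), rec_row(beta = 0.2))
  expect_equal(h$pair$gamma, 0.1)
  expect_equal(h$pair$Gamma, 0.2)
  expect_false(h$pair$flipped)

  # swapped coding: outcome beta negated, frequency mirrored
  h2 <- harmonize_pair(rec_row(), rec_row(ea = "G", oa = "A", beta = 0.2, eaf = 0.8))
  expect_equal(h2$pair$Gamma, -0.2)
  expect_equal(h2$pair$eaf_outcome, 0.2)
  expect_true(h2$pair$flipped)

  # opposite-strand coding (A/G vs T/C): matches after complementing
  h3 <- harmonize_pair(rec_row(), rec_row(ea = "T", oa = "C", beta = 0.2))
  expect_equal(h3$pair$Gamma, 0.2)
  expect_false(h3$pair$flipped)
  # complement + swap
  h4 <- harmonize_pair(rec_row(), rec_row(ea = "C", oa = "T", beta = 0.2, eaf = 0.8))
  expect_equal(h4$pair$Gamma, -0.2)
  expect_true(h4$pair$flipped)

  # irreconcilable alleles
  h5 <- harmonize_pair(rec_row(), rec_row(ea = "C", oa = "A"))
  expect_equal(h5$drop_reason, "allele_mismatch")

  # exposure orientation is never changed
  expect_equal(h2$pair$gamma, 0.1)
  expect_error(harmonize_pair(rec_row("rs1"), rec_row("rs2")), "rsid mismatch")
})

test_that("palindromic pairs follow the frequency rule with a 0.3 MAF cutoff", {
  # clear frequencies on the same side: kept without flip
  h <- harmonize_pair(rec_row(ea = "A", oa = "T", eaf = 0.1),
                      rec_row(ea = "A", oa = "T", eaf = 0.12, beta = 0.2))
  expect_equal(h$pair$Gamma, 0.2)
  expect_false(h$pair$flipped)

  # opposite sides of 0.5: outcome beta negated
  h2 <- harmonize_pair(rec_row(ea = "A", oa = "T", eaf = 0.1),
                       rec_row(ea = "A", oa = "T", eaf = 0.9, beta = 0.2))
  expect_equal(h2$pair$Gamma, -0.2)
  expect_true(h2$pair$flipped)

  # intermediate frequency in either study: ambiguous, dropped
  h3 <- harmonize_pair(rec_row(ea = "A", oa = "T", eaf = 0.45),
                       rec_row(ea = "A", oa = "T", eaf = 0.45))
  expect_equal(h3$drop_reason, "ambiguous_palindrome")
  h4 <- harmonize_pair(rec_row(ea = "C", oa = "G", eaf = 0.1),
                       rec_row(ea = "C", oa = "G", eaf = 0.35))
  expect_equal(h4$drop_reason, "ambiguous_palindrome")

  # missing frequency on a palindrome: conservative drop
  h5 <- harmonize_pair(rec_row(ea = "A", oa = "T", eaf = NA),
                       rec_row(ea = "A", oa = "T", eaf = 0.1))
  expect_equal(h5$drop_reason, "ambiguous_palindrome")

  # boundary: MAF exactly at the threshold is ambiguous
  h6 <- harmonize_pair(rec_row(ea = "A", oa = "T", eaf = 0.3),
                       rec_row(ea = "A", oa = "T", eaf = 0.1))
  expect_equal(h6$drop_reason, "ambiguous_palindrome")
})

test_that("dataset harmonization accounts for every input SNP exactly once", {
  exp <- make_dataset(3)
  out <- exp
  out$records$beta <- rnorm(3)
  h <- harmonize_datasets(exp, out)
  expect_equal(nrow(h$pairs), 3)
  expect_equal(nrow(h$drop_log), 0)

  out2 <- exp
  out2$records <- out2$records[-2, ]
  h2 <- harmonize_datasets(exp, out2)
  expect_equal(nrow(h2$pairs), 2)
  expect_equal(h2$drop_log$reason, "absent_from_outcome")
  expect_equal(nrow(h2$pairs) + nrow(h2$drop_log), n_snps(exp))

  out3 <- exp
  out3$records <- out3$records[0, ]
  expect_error(harmonize_datasets(exp, out3), "no SNP could be harmonized")
})

test_that("planted swaps and palindromes in simulated data are resolved per-case", {
  cfg <- simulation_config(n_snps = 100, palindromic_fraction = 0.2,
                           swap_fraction = 0.3, seed = 17)
  sim <- simulate_two_sample(cfg)
  h <- harmonize_datasets(sim$exposure, sim$outcome)
  truth <- sim$truth$snps

  # oracle: palindromic SNPs with MAF >= 0.3 in either study are ambiguous
  out_eaf <- sim$outcome$records$eaf[match(truth$rsid, sim$outcome$records$rsid)]
  out_maf <- pmin(out_eaf, 1 - out_eaf)
  ambiguous <- truth$palindromic & (truth$maf >= 0.3 | out_maf >= 0.3)
  expect_setequal(h$drop_log$rsid[h$drop_log$reason == "ambiguous_palindrome"],
                  truth$rsid[ambiguous])
  expect_setequal(h$pairs$rsid, truth$rsid[!ambiguous])

  # non-palindromic SNPs are flagged flipped iff their coding was swapped
  nonpal <- h$pairs[!h$pairs$palindromic, ]
  expect_equal(nonpal$flipped,
               truth$swapped[match(nonpal$rsid, truth$rsid)])

  # harmonized outcome effects match the generating orientation
  m <- match(h$pairs$rsid, truth$rsid)
  resid <- (h$pairs$Gamma - truth$Gamma_true[m]) / truth$se_Gamma[m]
  expect_lt(max(abs(resid)), 5)  # standardized residuals are ordinary noise

  expect_equal(nrow(h$pairs) + nrow(h$drop_log), 100)
})

test_that("harmonization is invariant to wholesale outcome allele recoding", {
  cfg <- simulation_config(n_snps = 40, palindromic_fraction = 0.1,
                           swap_fraction = 0, seed = 23)
  sim <- simulate_two_sample(cfg)
  h1 <- harmonize_datasets(sim$exposure, sim$outcome)

  recoded <- sim$outcome
  rec <- recoded$records
  tmp <- rec$effect_allele
  rec$effect_allele <- rec$other_allele
  rec$other_allele <- tmp
  rec$beta <- -rec$beta
  rec$eaf <- 1 - rec$eaf
  recoded$records <- rec
  h2 <- harmonize_datasets(sim$exposure, recoded)

  expect_equal(h1$pairs$gamma, h2$pairs$gamma)
  expect_equal(h1$pairs$Gamma, h2$pairs$Gamma)
  expect_equal(h1$pairs$rsid, h2$pairs$rsid)
})

test_that("harmonizing an already-harmonized dataset changes nothing", {
  cfg <- simulation_config(n_snps = 30, palindromic_fraction = 0.1,
                           swap_fraction = 0.2, seed = 29)
  sim <- simulate_two_sample(cfg)
  h1 <- harmonize_datasets(sim$exposure, sim$outcome)

  # rebuild an outcome dataset from the harmonized pairs, on the exposure's
  # allele coding, and harmonize again
  xrec <- sim$exposure$records
  m <- match(h1$pairs$rsid, xrec$rsid)
  aligned <- summary_dataset(
    data.frame(rsid = h1$pairs$rsid, chrom = xrec$chrom[m], pos = xrec$pos[m],
               effect_allele = xrec$effect_allele[m],
               other_allele = xrec$other_allele[m],
               eaf = h1$pairs$eaf_outcome, beta = h1$pairs$Gamma,
               se = h1$pairs$se_Gamma, pvalue = 0.5, n = NA,
               stringsAsFactors = FALSE),
    trait_name = "aligned", trait_type = "binary")
  h2 <- harmonize_datasets(sim$exposure, aligned)
  m2 <- match(h1$pairs$rsid, h2$pairs$rsid)
  expect_equal(h2$pairs$Gamma[m2], h1$pairs$Gamma)
  expect_true(all(!h2$pairs$flipped[m2]))
})

test_that("proxy SNPs fill in outcome gaps when an LD table allows", {
  cfg <- simulation_config(n_snps = 12, palindromic_fraction = 0,
                           swap_fraction = 0, missing_outcome_fraction = 0,
                           seed = 41,
                           ld_block_spec = list(list(size = 3, r2 = 0.95)))
  sim <- simulate_two_sample(cfg)
  # drop the first block member from the outcome: its block-mates are proxies
  gone <- sim$truth$snps$rsid[sim$truth$snps$block == 1][1]
  sim$outcome$records <- sim$outcome$records[sim$outcome$records$rsid != gone, ]
  h <- harmonize_datasets(sim$exposure, sim$outcome, ld = sim$ld)
  expect_true(gone %in% h$pairs$rsid)
  used <- h$pairs$proxy_used[h$pairs$rsid == gone]
  expect_true(used %in% sim$truth$snps$rsid[sim$truth$snps$block == 1])

  # without the LD table the SNP is dropped as absent
  h2 <- harmonize_datasets(sim$exposure, sim$outcome)
  expect_equal(h2$drop_log$rsid, gone)
})
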