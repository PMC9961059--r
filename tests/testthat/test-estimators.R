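test_that("Wald ratios follow the first-order definitions", {
  h <- harmonized_data(gamma = c(0.1, 0.2, -0.05), se_gamma = rep(0.01, 3),
                       Gamma = c(0.05, 0, 0.02), se_Gamma = c(0.01, 0.02, 0.01))
  r <- wald_ratios(h)
  expect_equal(r$b, c(0.5, 0, -0.4))
  expect_equal(r$s, c(0.1, 0.1, 0.2))
  expect_equal(r$w, 1 / r$s^2)

  set.seed(2)
  g <- rnorm(10, 0.1, 0.02); G <- rnorm(10); sG <- runif(10, 0.01, 0.1)
  h2 <- harmonized_data(g, rep(0.01, 10), G, sG)
  r2 <- wald_ratios(h2)
  expect_equal(r2$b, G / g)
  expect_equal(r2$s, sG / abs(g))

  bad <- harmonized_data(c(0.1, 1), c(0.01, 0.01), c(1, 1), c(0.1, 0.1))
  bad$pairs$gamma[2] <- 0
  expect_error(wald_ratios(bad), "snp_2")
})

test_that("odds-ratio transform is exact and symmetric at the null", {
  o <- to_odds_ratio(0, 0.1)
  expect_equal(o$or_, 1)
  expect_equal(o$ci_low * o$ci_high, 1)  # symmetric about 1 on the log scale
  o2 <- to_odds_ratio(0.5, 0.2, level = 0.9)
  expect_equal(o2$or_, exp(0.5))
  expect_equal(o2$ci_low, exp(0.5 - qnorm(0.95) * 0.2))
})

test_that("IVW equals the common ratio in homogeneous data with fixed-effect SE", {
  # two identical SNPs: slope is their shared Wald ratio
  h <- harmonized_data(c(0.1, 0.1), c(0.01, 0.01), c(0.05, 0.05), c(0.01, 0.01))
  e <- ivw(h)
  expect_equal(e$beta, 0.5)

  # all ratios equal: exact fit, sigma = 0, SE floored at fixed-effect
  g <- c(0.1, 0.2, 0.3); G <- 0.7 * g
  h2 <- harmonized_data(g, rep(0.01, 3), G, c(0.01, 0.02, 0.015))
  e2 <- ivw(h2)
  expect_equal(e2$beta, 0.7)
  expect_equal(e2$extras$sigma, 0)
  w <- c(0.01, 0.02, 0.015)^-2
  expect_equal(e2$se, sqrt(1 / sum(w * g^2)))
  expect_equal(e2$or_, exp(e2$beta))

  expect_error(ivw(harmonized_data(0.1, 0.01, 0.1, 0.01)), "at least 2")
})

test_that("IVW is invariant to SNP permutation and consistent outcome rescaling", {
  set.seed(5)
  h <- harmonized_data(rnorm(12, 0.1, 0.03), runif(12, 0.005, 0.02),
                       rnorm(12, 0.05, 0.03), runif(12, 0.005, 0.02))
  e <- ivw(h)
  perm <- h
  perm$pairs <- perm$pairs[sample(12), ]
  ep <- ivw(perm)
  expect_equal(ep$beta, e$beta)
  expect_equal(ep$se, e$se)

  scaled <- h
  scaled$pairs$Gamma <- h$pairs$Gamma * 3
  scaled$pairs$se_Gamma <- h$pairs$se_Gamma * 3
  es <- ivw(scaled)
  expect_equal(es$beta, 3 * e$beta)
  expect_equal(es$se, 3 * e$se)
})

test_that("Egger recovers exact-fit slopes and planted intercepts", {
  g <- seq(0.05, 0.3, length.out = 6)
  h <- harmonized_data(g, rep(0.01, 6), 0.5 * g, runif(6, 0.01, 0.03))
  e <- egger(h)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$extras$intercept$estimate, 0, tolerance = 1e-10)

  h2 <- harmonized_data(g, rep(0.01, 6), 0.02 + 0.5 * g, runif(6, 0.01, 0.03))
  e2 <- egger(h2)
  expect_equal(e2$beta, 0.5, tolerance = 1e-10)
  expect_equal(e2$extras$intercept$estimate, 0.02, tolerance = 1e-10)
  expect_equal(e2$extras$intercept$df, 4)

  expect_error(egger(harmonized_data(c(0.1, 0.2), c(0.01, 0.01),
                                     c(0.1, 0.2), c(0.01, 0.01))), "at least 3")
})

test_that("Egger with its intercept forced to zero is IVW (internal consistency)", {
  set.seed(9)
  g <- abs(rnorm(15, 0.1, 0.05)) + 0.01
  h <- harmonized_data(g, rep(0.01, 15), rnorm(15, 0.05, 0.04),
                       runif(15, 0.01, 0.05))
  w <- h$pairs$se_Gamma^-2
  slope0 <- sum(w * g * h$pairs$Gamma) / sum(w * g^2)
  expect_equal(ivw(h)$beta, slope0)
})

test_that("weighted median interpolates the mid-cumulative weight function", {
  h <- harmonized_data(c(0.1, 0.1, 0.1), rep(0.01, 3), c(0.1, 0.2, 0.3),
                       rep(0.01, 3))
  wm <- weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(wm$beta, 2)  # equal weights: plain median of {1,2,3}

  # a dominant SNP flanked by symmetric weights sits exactly at p = 0.5
  b <- c(1, 2, 3); w <- c(0.2, 0.6, 0.2)
  expect_equal(mrpipe:::weighted_median_point(b, w), 2)

  # brute-force oracle for the interpolation on 5 unequal weights
  set.seed(4)
  b5 <- sort(rnorm(5)); w5 <- runif(5)
  oracle <- local({
    wn <- w5 / sum(w5)
    p <- cumsum(wn) - wn / 2
    f <- approxfun(p, b5, rule = 2)
    f(0.5)
  })
  expect_equal(mrpipe:::weighted_median_point(b5, w5), oracle)
})

test_that("mode estimators find the dominant cluster, not the mean", {
  # degenerate cluster: all ratios equal
  h <- harmonized_data(rep(0.1, 4), rep(0.01, 4), rep(0.07, 4), rep(0.01, 4))
  m <- mode_estimate(h, n_boot = 10, seed = 1)
  expect_equal(m$beta, 0.7)
  expect_equal(m$se, 0)

  # majority cluster at 0.5 with two far outliers
  set.seed(8)
  b <- c(rnorm(8, 0.5, 0.02), 3, 3.05)
  g <- rep(0.1, 10)
  h2 <- harmonized_data(g, rep(0.01, 10), b * g, rep(0.01, 10))
  m2 <- mode_estimate(h2, weighted = FALSE, n_boot = 10, seed = 1)
  expect_lt(abs(m2$beta - 0.5), 0.1)
  expect_gt(mean(wald_ratios(h2)$b), 0.9)  # the mean is pulled away
})

test_that("mode argmax agrees with an exhaustive 10x-finer grid scan", {
  set.seed(12)
  for (rep in 1:5) {
    J <- 20
    b <- rnorm(J, 0.5, 0.3)
    w <- runif(J)
    h <- mrpipe:::mode_bandwidth(b, 1)
    got <- mrpipe:::mode_point(b, w, h)
    fine <- seq(min(b) - 2 * h, max(b) + 2 * h, length.out = 100000)
    oracle <- fine[which.max(exact_kde(fine, b, w, h))]
    coarse_step <- (diff(range(b)) + 4 * h) / 9999
    expect_lt(abs(got - oracle), coarse_step)
  }
})

test_that("all five methods run, agree on degenerate data, and are seed-deterministic", {
  sim <- simulate_two_sample(simulation_config(n_snps = 30, seed = 77))
  h <- harmonize_datasets(sim$exposure, sim$outcome)
  est <- run_all_methods(h, n_boot = 100, seed = 5)
  expect_named(est, c("ivw", "egger", "weighted_median", "weighted_mode",
                      "simple_mode"))
  tab <- estimates_table(est)
  expect_equal(tab$method, c("IVW", "MR-Egger", "Weighted median",
                             "Weighted mode", "Simple mode"))
  expect_true(all(tab$n_snp == nrow(h$pairs)))
  expect_equal(tab$or_, exp(tab$beta))

  est2 <- run_all_methods(h, n_boot = 100, seed = 5)
  expect_identical(estimates_table(est2), tab)  # bootstrap SEs included

  # identical ratios: every method returns the common ratio
  hd <- harmonized_data(c(0.1, 0.2, 0.4), rep(0.01, 3),
                        0.6 * c(0.1, 0.2, 0.4), rep(0.01, 3))
  estd <- run_all_methods(hd, n_boot = 20, seed = 2)
  for (e in estd) expect_equal(e$beta, 0.6, tolerance = 1e-6)
})

test_that("weighted median breakdown: a bounded minority cannot drag the estimate out", {
  # equal weights, 5 SNPs: corrupting any 2 (40% of weight) keeps the
  # estimate inside the valid ratios' range, whatever the corruption
  base <- c(0.4, 0.45, 0.5, 0.55, 0.6)
  w <- rep(0.2, 5)
  for (bad in combn(5, 2, simplify = FALSE)) {
    for (val in c(-1e6, -10, 10, 1e6)) {
      b <- base
      b[bad] <- val
      est <- mrpipe:::weighted_median_point(b, w)
      expect_gte(est, min(base[-bad]))
      expect_lte(est, max(base[-bad]))
    }
  }
  # single corrupted SNP under unequal weights below 50%
  w2 <- c(0.45, 0.2, 0.15, 0.1, 0.1)
  for (bad in 1:5) {
    if (w2[bad] >= 0.5) next
    b <- base
    b[bad] <- 1e6
    est <- mrpipe:::weighted_median_point(b, w2)
    expect_lte(est, max(base[-bad]))
  }
})

test_that("directional pleiotropy biases IVW but not the Egger slope (InSIDE)", {
  res <- t(sapply(1:60, function(s) {
    cfg <- simulation_config(n_snps = 60, seed = 1000 + s,
                             invalid_fraction = 1, pleiotropy_mean = 0.01,
                             pleiotropy_sd = 0.004)
    sim <- simulate_two_sample(cfg)
    h <- harmonize_datasets(sim$exposure, sim$outcome)
    c(ivw = ivw(h)$beta, egger = egger(h)$beta,
      intercept = egger(h)$extras$intercept$estimate)
  }))
  bias_ivw <- mean(res[, "ivw"]) - 0.551
  bias_egger <- mean(res[, "egger"]) - 0.551
  expect_gt(bias_ivw, 0.05)                 # direct effects push IVW upward
  expect_lt(abs(bias_egger), abs(bias_ivw) / 2)
  # intercept recovery is approximate here: sign-unstable weak instruments
  # shave the oriented pleiotropy mean slightly downward
  expect_lt(abs(mean(res[, "intercept"]) - 0.01), 0.003)
})
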