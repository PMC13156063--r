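test_that("lilliefors screens normal vs heavy-tailed samples", {
  set.seed(41)
  norm_p <- replicate(40, lilliefors(rnorm(44))$p)
  expect_gt(mean(norm_p >= 0.05), 0.85)     # near-nominal type I
  lnorm_p <- replicate(40, lilliefors(exp(rnorm(44, sd = 1.2)))$p)
  expect_gt(mean(lnorm_p < 0.05), 0.9)      # strong skew is caught
  expect_error(lilliefors(1:3), "n >= 4")
})

test_that("normality_route follows the screen/transform/fallback ladder", {
  set.seed(42)
  r1 <- normality_route(rnorm(44), rnorm(44, 1))
  expect_equal(r1$test, "t")
  # lognormal data are rescued by the log transform
  rescued <- replicate(20, {
    r <- normality_route(exp(rnorm(44)), exp(rnorm(44, 0.5)))
    r$test == "t" && r$log_transform
  })
  expect_gt(mean(rescued), 0.7)
  # negative values block the transform -> mann_whitney
  set.seed(43)
  a <- c(exp(rnorm(40, sd = 1.5)) * sample(c(-1, 1), 40, TRUE))
  b <- rnorm(40)
  r3 <- normality_route(a, b)
  if (lilliefors(a)$p < 0.05) expect_equal(r3$test, "mann_whitney")
})

test_that("BH adjustment matches the worked examples and the oracle", {
  r1 <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_equal(sum(r1$reject), 4)
  r2 <- fdr_bh(c(0.02, 0.05, 0.9), q = 0.05)
  expect_equal(sum(r2$reject), 0)
  expect_equal(fdr_bh(0.04, 0.05)$reject, TRUE)
  expect_equal(fdr_bh(numeric(0))$p_adj, numeric(0))
  set.seed(44)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    mine <- fdr_bh(p, q = 0.05)
    expect_equal(mine$reject, bh_reject_oracle(p, 0.05))
    expect_equal(mine$p_adj, p.adjust(p, "BH"))   # cross-check vs stats
    # adjusted p monotone in the raw-p order
    o <- order(p)
    expect_true(all(diff(mine$p_adj[o]) >= -1e-15))
  }
})

test_that("cohens_d closed forms and degenerate input", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(45)
  a <- rnorm(2000, 1); b <- rnorm(2000, 0)
  expect_equal(cohens_d(a, b), 1, tolerance = 0.1)
  expect_warning(d <- cohens_d(rep(1, 5), rep(1, 5)), "undefined")
  expect_true(is.na(d))
})

test_that("cohens_d recovers a planted effect within sampling bounds", {
  set.seed(46)
  hits <- mean(replicate(50, {
    d <- cohens_d(rnorm(44, 0.9), rnorm(44))
    d >= 0.5 && d <= 1.3
  }))
  expect_gte(hits, 0.9)
})

test_that("group_compare_table routes, tests, corrects per family", {
  set.seed(47)
  n <- 20
  mk <- function(fam, feat, a, b) {
    data.frame(subject = c(paste0("a", 1:n), paste0("b", 1:n)),
               group = rep(c("ASD-like", "TD-like"), each = n),
               family = fam, feature = feat, value = c(a, b))
  }
  feats <- rbind(
    mk("lzc", "alpha_mean", rnorm(n, 0.5, 0.05), rnorm(n, 0.62, 0.05)),
    mk("lzc", "beta_mean", rnorm(n), rnorm(n)),
    mk("power", "occ_alpha", rnorm(n, 1), rnorm(n, 1)),
    mk("power", "const", rep(1, n), rep(1, n)))
  out <- group_compare_table(feats, "ASD-like", "TD-like")
  expect_equal(nrow(out), 3)                      # constant skipped
  expect_equal(attr(out, "skipped"), "power/const")
  row <- out[out$feature == "alpha_mean", ]
  expect_true(row$reject)
  expect_lt(row$cohens_d, 0)                      # ASD minus TD negative
  expect_true(all(out$p_fdr >= out$p_raw - 1e-15))
})
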