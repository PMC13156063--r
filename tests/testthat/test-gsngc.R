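test_that("symbolize reproduces the hand-computed ordinal patterns", {
  s <- symbolize(c(4, 7, 9, 10, 6, 11, 3), m = 3, tau = 1)
  expect_equal(nrow(s$patterns), 5)
  expect_equal(s$patterns,
               rbind(c(0, 1, 2), c(0, 1, 2), c(2, 0, 1),
                     c(1, 0, 2), c(2, 0, 1)))
  inc <- symbolize(1:50, m = 4, tau = 2)
  expect_true(all(inc$symbols == 0))
  expect_true(all(apply(inc$patterns, 1, identical, y = c(0L, 1L, 2L, 3L))))
  set.seed(1)
  rnd <- symbolize(rnorm(500), m = 4, tau = 2)
  expect_equal(nrow(rnd$patterns), 500 - 3 * 2)
  expect_true(all(rnd$symbols >= 0 & rnd$symbols < factorial(4)))
  expect_error(symbolize(1:5, m = 4, tau = 2), "too short")
})

test_that("IAAFT surrogates preserve amplitudes exactly and spectra closely", {
  set.seed(12)
  for (seed in 1:5) {
    x <- as.numeric(arima.sim(list(ar = 0.8), 2000))
    su <- iaaft_surrogate(x, n_surr = 4, seed = seed)
    for (k in 1:4)
      expect_identical(sort(su[, k]), sort(x))
    p0 <- welch_psd(x, fs = 100)$psd
    pc <- cor(as.numeric(p0), as.numeric(welch_psd(su[, 1], fs = 100)$psd))
    expect_gt(pc, 0.95)
  }
  x <- rnorm(500)
  expect_identical(iaaft_surrogate(x, 3, seed = 5),
                   iaaft_surrogate(x, 3, seed = 5))
  expect_error(iaaft_surrogate(rnorm(10)), ">= 64")
})

test_that("Wilcoxon gate is exact in the untied case", {
  # all 20 differences positive: exact one-sided p = 2^-20
  g <- surrogate_gate(1, 1 - seq(0.01, 0.2, by = 0.01))
  expect_equal(g$p, 2^-20)
  expect_equal(g$gated, 1)
  # symmetric differences: p around 0.5, gate closed
  d <- c(seq(0.01, 0.10, by = 0.01), -seq(0.01, 0.10, by = 0.01))
  g2 <- surrogate_gate(0.5, 0.5 - d)
  expect_gt(g2$p, 0.3)
  expect_equal(g2$gated, 0)
  # original below every surrogate: closed
  g3 <- surrogate_gate(0.1, 0.1 + seq(0.01, 0.2, by = 0.01))
  expect_equal(g3$gated, 0)
  # gate never increases the value
  expect_true(g$gated %in% c(0, g$gc_original))
})

test_that("kernel GC is positive for a lag copy and calibrated under null", {
  set.seed(31)
  x <- rnorm(1500)
  y <- c(rep(0, 2), x[1:1498])          # y is x delayed by 2
  gc_copy <- kernel_gc(symbolize(x), symbolize(y))$gc
  expect_gt(gc_copy, 0)
  null_gc <- vapply(1:20, function(s) {
    set.seed(100 + s)
    kernel_gc(symbolize(rnorm(2000)), symbolize(rnorm(2000)))$gc
  }, numeric(1))
  expect_lt(median(null_gc), 0.02)
  expect_error(kernel_gc(symbolize(rnorm(100)), symbolize(rnorm(90))),
               "equal length")
})

test_that("direction recovery on quadratic coupling", {
  cp <- coupling_spec("x", "y", lag = 2, strength = 0.8, form = "quadratic")
  fwd <- 0; rev_ <- 0
  for (s in 1:6) {
    pr <- make_coupled_pair(4000, cp, noise_sd = 1, seed = s)
    fwd <- fwd + (gsngc_pair(pr$x, pr$y, seed = s)$gated > 0)
    rev_ <- rev_ + (gsngc_pair(pr$y, pr$x, seed = s + 100)$gated > 0)
  }
  expect_gte(fwd, 5)
  expect_lte(rev_, 1)
})

test_that("connectivity returns gated per-band matrices with zero diagonal", {
  out <- generate_subject(subject_spec(
    oscillations = list(oscillation_spec(6, 2, rep(1, 8))),
    duration = 10, fs = 250, seed = 3))
  bank <- bandpass_bank(out$recording, list(theta = c(4, 8)))
  cm <- connectivity(bank, n_surr = 5, seed = 1, max_train = 80)
  M <- cm$matrices$theta
  expect_equal(dim(M), c(8, 8))
  expect_equal(diag(M), setNames(rep(0, 8), nf_channels()))
  expect_true(all(M >= 0))
  short <- bandpass_bank(recording(matrix(rnorm(8 * 100), 8), fs = 250),
                         list(theta = c(4, 8)))
  expect_error(connectivity(short), "too short")
})
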