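test_that("binarize_median follows the strictly-greater tie rule", {
  expect_equal(binarize_median(c(1, 3, 2, 5, 4)), c(0L, 0L, 0L, 1L, 1L))
  ramp <- seq_len(100)
  expect_equal(sum(binarize_median(ramp)), 50)
  expect_equal(binarize_median(rep(2, 10)), rep(0L, 10))
  expect_error(binarize_median(3), "length")
})

test_that("binarization is invariant under strictly monotone transforms", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(200)
    b <- binarize_median(x)
    expect_identical(binarize_median(exp(x)), b)
    expect_identical(binarize_median(x^3 + 2 * x), b)
    expect_identical(binarize_median(atan(x) * 5 + 1), b)
  }
})

test_that("lz76_count matches hand parses", {
  expect_equal(lz76_count(rep(0, 10)), 2)
  expect_equal(lz76_count(rep(c(0, 1), 5)), 3)
  expect_equal(lz76_count(c(1)), 1)
  expect_error(lz76_count(c(0, 2)), "binary")
})

test_that("lz76_count equals the brute-force parser on short strings", {
  for (len in c(1, 2, 3, 5, 8, 10)) {
    for (bits in all_bitstrings(len)) {
      expect_equal(lz76_count(bits), lz76_oracle(bits),
                   info = paste(bits, collapse = ""))
    }
  }
})

test_that("lz76_count equals the brute-force parser on random length-64", {
  set.seed(7)
  for (i in 1:200) {
    bits <- rbinom(64, 1, runif(1, 0.2, 0.8))
    expect_equal(lz76_count(bits), lz76_oracle(bits))
  }
})

test_that("normalized LZC discriminates regular from random sequences", {
  set.seed(21)
  rand <- lzc_normalized(rbinom(4000, 1, 0.5))
  period <- lzc_normalized(rep(c(0, 1, 1, 0), 1000))
  expect_lt(period, rand)
  expect_lte(lzc_normalized(rep(0L, 1e4)), 0.01)
})

test_that("lzc_features has the contracted shape and is deterministic", {
  out <- generate_subject(subject_spec(
    oscillations = list(oscillation_spec(10, 2, rep(2, 8))),
    duration = 12, fs = 250, seed = 5))
  rec <- out$recording
  f1 <- lzc_features(rec)
  f2 <- lzc_features(rec)
  expect_identical(f1, f2)
  expect_setequal(unique(f1$band), c("broadband", "delta", "theta",
                                     "alpha", "beta"))
  expect_equal(nrow(f1), 5 * 8)
  expect_equal(nrow(attr(f1, "global")), 5)
  expect_true(all(f1$lzc > 0))
  expect_error(lzc_features(recording(matrix(rnorm(16), 2), fs = 250)),
               "epoch")
})
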