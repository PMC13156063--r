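test_that("generate_subject shape, determinism and validation", {
  spec <- subject_spec(oscillations = list(oscillation_spec(10, 2, rep(1, 8))),
                       duration = 60, fs = 250, seed = 42)
  out1 <- generate_subject(spec)
  out2 <- generate_subject(spec)
  expect_equal(dim(out1$recording$data), c(8, 15000))
  expect_identical(out1$recording$data, out2$recording$data)
  expect_error(subject_spec(duration = -1), "positive")
  expect_error(subject_spec(fs = 50), ">= 100")
  expect_error(subject_spec(duration = 1.003, fs = 250), "integer sample")
  expect_error(oscillation_spec(-1, 2, rep(1, 8)), "peak_freq")
  expect_error(oscillation_spec(10, 2, rep(0, 8)), "at least one")
  expect_error(coupling_spec("a", "a", 1, 1), "differ")
  expect_error(subject_spec(couplings = list(coupling_spec("zz", "F3", 2, 1))),
               "unknown channel")
})

test_that("planted peaks are recovered by Welch peak-picking within 0.5 Hz", {
  # property: spectral fidelity at SNR >= 3 over 10 random specs
  set.seed(77)
  for (i in 1:10) {
    f0 <- runif(1, 5, 30)
    spec <- subject_spec(oscillations = list(
      oscillation_spec(f0, runif(1, 1, 3), rep(3, 8))),
      noise_gain = 1, duration = 40, fs = 250, seed = 1000 + i)
    rec <- generate_subject(spec)$recording
    w <- welch_psd(rec, seg_len = 1000)
    sel <- w$freq >= 2 & w$freq <= 45
    psd <- w$psd[1, sel]; fr <- w$freq[sel]
    # half-maximum centroid: argmax alone wanders on a wide noisy carrier
    top <- psd >= 0.5 * max(psd)
    peak <- sum(fr[top] * psd[top]) / sum(psd[top])
    expect_lt(abs(peak - f0), 0.5)
  }
})

test_that("generate_cohort is balanced with per-subject ground truth", {
  ch <- generate_cohort(2, base_seed = 3, duration = 8)
  expect_length(ch$recordings, 4)
  expect_equal(sum(ch$truth$subjects$group == "ASD-like"), 2)
  expect_equal(sum(ch$truth$subjects$group == "TD-like"), 2)
  expect_equal(ch$truth$subjects$seed, 3 + 1:4)
  # wider planted theta interval in the ASD-like group, from ground truth
  ch20 <- generate_cohort(20, base_seed = 1, duration = 8)
  b <- ch20$truth$bands
  theta <- b[b$peak > 4 & b$peak < 8, ]
  width <- aggregate(fwhm ~ group, theta, mean)
  expect_gt(width$fwhm[width$group == "ASD-like"],
            width$fwhm[width$group == "TD-like"])
})

test_that("custom preset with zero effects plants nothing", {
  ch <- generate_cohort(2, preset = "custom", base_seed = 1, duration = 8)
  expect_true(all(ch$truth$directions$asd_vs_td == "null"))
  ch2 <- generate_cohort(2, preset = "paper_like", base_seed = 1,
                         duration = 8)
  expect_false(any(ch2$truth$directions$asd_vs_td == "null"))
})

test_that("make_coupled_pair plants a lagged (possibly nonlinear) drive", {
  cp <- coupling_spec("x", "y", lag = 2, strength = 0.8, form = "quadratic")
  pr <- make_coupled_pair(4000, cp, noise_sd = 1, seed = 9)
  pr2 <- make_coupled_pair(4000, cp, noise_sd = 1, seed = 9)
  expect_identical(pr, pr2)
  x2 <- pr$x^2
  cc <- function(lag) cor(pr$y[(1 + lag):4000], x2[1:(4000 - lag)])
  expect_gt(cc(2), cc(0))
  # zero strength -> independence (correlation near 0)
  pr0 <- make_coupled_pair(4000, coupling_spec("x", "y", 2, 0), seed = 9)
  expect_lt(abs(cor(pr0$x, pr0$y)), 0.05)
  expect_error(make_coupled_pair(15, cp), "exceed")
})
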