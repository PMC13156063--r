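test_that("clean_mean_covariance keeps clean epochs and drops outliers", {
  set.seed(5)
  rec <- recording(matrix(rnorm(4 * 4000), 4), fs = 100,
                   labels = paste0("c", 1:4))
  ep <- epoch_recording(rec, 2)
  cv <- clean_mean_covariance(ep)
  expect_equal(length(attr(cv, "retained")), n_ep <- dim(ep$epochs)[1])
  # identical epochs: all retained, mean equals each epoch covariance
  one <- matrix(rnorm(4 * 200), 4)
  recI <- recording(one[, c(rep(seq_len(200), 10))], fs = 100,
                    labels = paste0("c", 1:4))
  epI <- epoch_recording(recI, 2)
  cvI <- clean_mean_covariance(epI)
  x <- epI$epochs[1, , ]
  expect_equal(unclass(cvI), tcrossprod(x - rowMeans(x)) / (ncol(x) - 1),
               ignore_attr = TRUE)
  # one epoch scaled x100 is rejected
  big <- rec
  big$data[, 1:200] <- big$data[, 1:200] * 100
  epB <- epoch_recording(big, 2)
  cvB <- clean_mean_covariance(epB)
  expect_false(1 %in% attr(cvB, "retained"))
  expect_lte(length(attr(cvB, "retained")), dim(epB$epochs)[1])
  expect_error(clean_mean_covariance(epoch_recording(
    recording(matrix(rnorm(4 * 300), 4), fs = 50,
              labels = paste0("c", 1:4)), 2)), ">= 4 epochs")
})

test_that("GED solutions are real, R-orthogonal and scale invariant", {
  out <- two_rhythm_subject(1, dur = 20)
  rec <- out$recording
  sol <- ged_at_frequency(rec, 10)
  expect_true(all(is.finite(sol$values)))
  expect_true(is.numeric(sol$values))          # real by construction
  # R-orthogonality: W' R W diagonal
  ep <- epoch_recording(rec, 2)
  R <- neurofuse:::regularize_cov(clean_mean_covariance(ep), 0.01)
  M <- t(sol$vectors) %*% R %*% sol$vectors
  offd <- max(abs(M[!diag(8)])) / max(abs(diag(M)))
  expect_lt(offd, 1e-6)
  # identity case: same covariance on both sides -> eigenvalues all 1
  solI <- neurofuse:::ged_solve(R, R)
  expect_equal(solI$values, rep(1, 8), tolerance = 1e-8)
  # planted 10 Hz rhythm beats 20 Hz
  s10 <- ged_at_frequency(rec, 10)$values[1]
  s20 <- ged_at_frequency(rec, 20)$values[1]
  expect_gt(s10, s20)
  # scale invariance of lambda and boundaries
  rec2 <- rec; rec2$data <- rec2$data * 7.3
  sw1 <- ged_sweep(rec, 2, 20, 1)
  sw2 <- ged_sweep(rec2, 2, 20, 1)
  expect_equal(sw1$lambda_max, sw2$lambda_max, tolerance = 1e-8)
})

test_that("ged_sweep grid arithmetic and flat noise spectrum", {
  out <- two_rhythm_subject(2, dur = 20)
  sw <- ged_sweep(out$recording, 2, 45, 0.5)
  expect_length(sw$grid, 87)
  expect_error(ged_sweep(out$recording, 0, 45), "within")
  # flatness is assessed at constant narrowband FWHM: under the default
  # fwhm = max(1, 0.1 f) rule, lambda scales with the filter width even for
  # white noise, by construction
  set.seed(8)
  noise <- recording(matrix(rnorm(8 * 15000), 8), fs = 250)
  swn <- ged_sweep(noise, 2, 40, 2, fwhm_fun = function(f) 2)
  expect_lt(max(swn$lambda_max) / min(swn$lambda_max), 2)
})

test_that("similarity matrix is a squared correlation with unit diagonal", {
  out <- two_rhythm_subject(3, dur = 20)
  sw <- ged_sweep(out$recording, 2, 20, 1)
  sim <- similarity_matrix(sw)
  expect_equal(diag(sim), rep(1, length(sw$grid)))
  expect_equal(sim, t(sim))
  expect_true(all(sim >= 0 & sim <= 1 + 1e-12))
  # identical eigenvectors -> 1; orthogonal zero-mean -> ~0
  swf <- sw
  swf$vectors <- cbind(c(1, -1, 1, -1, 0, 0, 0, 0),
                       c(1, -1, 1, -1, 0, 0, 0, 0),
                       c(1, 1, -1, -1, 0, 0, 0, 0))
  swf$grid <- 1:3
  simf <- similarity_matrix(swf)
  expect_equal(simf[1, 2], 1)
  expect_lt(simf[1, 3], 0.1)
})

test_that("cluster_bands handles degenerate similarity structures", {
  grid <- seq(2, 13, by = 0.5)
  sw <- structure(list(grid = grid,
                       lambda_max = rep(1, length(grid)),
                       vectors = matrix(1, 8, length(grid)),
                       labels = paste0("c", 1:8), subject = "s"),
                  class = "nf_ged_sweep")
  # block-diagonal similarity: [2,8] vs (8,13]
  blockA <- grid <= 8
  v1 <- c(1, 2, -1, 0.5, 0, 1, -2, 0.3)
  v2 <- c(-1, 0.2, 2, -0.5, 1, 0, 1, -1)
  sw$vectors <- sapply(blockA, function(a) if (a) v1 else v2)
  bounds <- cluster_bands(sw)
  expect_equal(nrow(bounds$intervals), 2)
  expect_equal(bounds$intervals$lo, c(2, 8.5))
  expect_equal(bounds$intervals$hi, c(8, 13))
  # all-similar -> single interval spanning the grid
  sw$vectors <- matrix(rep(v1, length(grid)), 8)
  b1 <- cluster_bands(sw)
  expect_equal(nrow(b1$intervals), 1)
  expect_equal(c(b1$intervals$lo, b1$intervals$hi), range(grid))
})

test_that("canonical assignment merges, maps and flags missing bands", {
  mk <- function(iv) {
    structure(list(intervals = iv, grid = seq(2, 45, 0.5),
                   method = "dbscan", flagged = FALSE, subject = "s"),
              class = "nf_band_boundaries")
  }
  b <- assign_canonical(mk(data.frame(lo = 4.2, hi = 7.6, cluster = 1)))
  th <- b$canonical[b$canonical$band == "theta", ]
  expect_true(th$assigned)
  expect_equal(c(th$lo, th$hi), c(4.2, 7.6))
  b2 <- assign_canonical(mk(data.frame(lo = 35, hi = 40, cluster = 1)))
  expect_false(any(b2$canonical$assigned))
  b3 <- assign_canonical(mk(data.frame(lo = numeric(), hi = numeric(),
                                       cluster = integer())))
  expect_false(any(b3$canonical$assigned))
  # two intervals in one canonical range merge to their envelope
  b4 <- assign_canonical(mk(data.frame(lo = c(8.5, 11), hi = c(10, 12.5),
                                       cluster = 1:2)))
  al <- b4$canonical[b4$canonical$band == "alpha", ]
  expect_equal(c(al$lo, al$hi), c(8.5, 12.5))
})

test_that("individualized band power behaves physically", {
  rec <- tone_recording(10, fs = 250, dur = 20, nch = 8, noise = 0.01)
  rec$labels <- nf_channels()
  bounds <- structure(list(
    intervals = data.frame(lo = c(8, 13), hi = c(13, 30), cluster = 1:2),
    grid = seq(2, 45, 0.5), method = "dbscan", flagged = FALSE,
    subject = "s"), class = "nf_band_boundaries")
  bounds <- assign_canonical(bounds)
  pw <- individualized_band_power(rec, bounds)
  alpha <- pw$power[pw$band == "alpha"]
  beta <- pw$power[pw$band == "beta"]
  expect_true(all(alpha / beta > 10))
  expect_true(all(is.na(pw$power[pw$band == "delta"])))
  # doubling the amplitude quadruples band power
  rec2 <- rec; rec2$data <- rec2$data * 2
  pw2 <- individualized_band_power(rec2, bounds)
  expect_equal(pw2$power[pw2$band == "alpha"], 4 * alpha, tolerance = 1e-6)
})

test_that("dbscan and trough methods agree on well-separated bands", {
  hits <- 0
  for (seed in 1:3) {
    out <- two_rhythm_subject(seed)
    sw <- ged_sweep(out$recording)
    cd <- assign_canonical(cluster_bands(sw, method = "dbscan"))
    ct <- assign_canonical(cluster_bands(sw, method = "trough"))
    same <- identical(cd$canonical$assigned[2:3], c(TRUE, TRUE)) &&
      identical(ct$canonical$assigned[2:3], c(TRUE, TRUE))
    hits <- hits + same
  }
  expect_gte(hits, 2)
})
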