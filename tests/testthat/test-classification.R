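fake_features <- function(n_per_group, sep = 3, seed = 1, p = 6) {
  set.seed(seed)
  n <- 2 * n_per_group
  g <- rep(c("ASD-like", "TD-like"), each = n_per_group)
  X <- matrix(rnorm(n * p), n)
  X[g == "ASD-like", 1:2] <- X[g == "ASD-like", 1:2] + sep
  cn <- c(paste0("T_f", 1:2), paste0("F_f", 1:2), paste0("S_f", 1:2))
  colnames(X) <- cn
  df <- data.frame(subject = sprintf("s%02d", 1:n), group = g, X,
                   check.names = FALSE)
  attr(df, "block") <- setNames(substr(cn, 1, 1), cn)
  df
}

test_that("SVM separates trivially separable clusters", {
  df <- fake_features(20, sep = 4)
  X <- scale(as.matrix(df[, -(1:2)]))
  fit <- svm_rbf(X, df$group, positive = "ASD-like")
  expect_equal(mean(predict(fit, X) == df$group), 1)
  expect_length(predict(fit, X, type = "decision"), 40)
})

test_that("cv_evaluate achieves near-perfect accuracy on separated data", {
  df <- fake_features(15, sep = 8)
  res <- cv_evaluate(df, reps = 2, folds = 5, seed = 3)
  expect_gte(res$summary$mean[res$summary$metric == "accuracy"], 0.99)
  expect_true(all(res$summary$mean >= 0 & res$summary$mean <= 1))
})

test_that("cv folds never leak subjects and results are reproducible", {
  df <- fake_features(12, sep = 1)
  r1 <- cv_evaluate(df, reps = 2, folds = 4, seed = 7)
  r2 <- cv_evaluate(df, reps = 2, folds = 4, seed = 7)
  expect_identical(r1$per_rep, r2$per_rep)
  preds <- r1$predictions
  for (r in unique(preds$rep)) {
    pr <- preds[preds$rep == r, ]
    expect_equal(sort(pr$subject), sort(df$subject))  # test sets partition
  }
  r3 <- cv_evaluate(df, reps = 2, folds = 4, seed = 8)
  expect_false(identical(r1$per_rep, r3$per_rep))
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(9)
  accs <- vapply(1:8, function(s) {
    df <- fake_features(20, sep = 4, seed = s)
    df$group <- sample(df$group)
    cv_evaluate(df, reps = 1, folds = 5, seed = s)$summary$mean[1]
  }, numeric(1))
  expect_true(mean(accs) > 0.3 && mean(accs) < 0.7)
})

test_that("ablation covers the five standard block sets with shared seeds", {
  df <- fake_features(12, sep = 2)
  ab <- ablation(df, reps = 1, folds = 4, seed = 5)
  expect_equal(ab$table$combination, c("T", "F", "S", "T+F", "T+F+S"))
  expect_equal(nrow(ab$table), 5)
  expect_true(all(c("accuracy", "sensitivity", "specificity", "f1",
                    "auc") %in% names(ab$table)))
})

test_that("demographics baseline is at chance when group-independent", {
  set.seed(10)
  n <- 40
  labels <- rep(c("ASD-like", "TD-like"), each = n / 2)
  res <- baseline_demographics(rnorm(n, 5.5), rbinom(n, 1, 0.8), labels,
                               reps = 2, folds = 5, seed = 2)
  acc <- res$summary$mean[res$summary$metric == "accuracy"]
  expect_true(acc > 0.2 && acc < 0.8)
  expect_equal(res$summary$metric,
               c("accuracy", "sensitivity", "specificity", "f1", "auc"))
  # perfectly separated ages classify perfectly
  res2 <- baseline_demographics(c(rnorm(20, 10), rnorm(20, 2)),
                                rbinom(n, 1, 0.5), labels,
                                reps = 1, folds = 4, seed = 2)
  expect_gte(res2$summary$mean[1], 0.95)
})

test_that("assemble_features builds the 416-column fused table", {
  bands <- names(canonical_bands())
  chans <- nf_channels()
  subs <- data.frame(subject = c("s1", "s2"),
                     group = c("ASD-like", "TD-like"))
  lzc <- expand.grid(subject = subs$subject,
                     band = c("broadband", bands), channel = chans,
                     stringsAsFactors = FALSE)
  lzc$lzc <- runif(nrow(lzc))
  pw <- expand.grid(subject = subs$subject, band = bands, channel = chans,
                    stringsAsFactors = FALSE)
  pw$power <- runif(nrow(pw))
  mkconn <- function(seed) {
    mats <- lapply(seq_along(bands), function(b) {
      M <- random_graph8(seed + b)       # symmetric is fine here
      dimnames(M) <- list(chans, chans)
      M
    })
    names(mats) <- bands
    structure(list(matrices = mats, labels = chans),
              class = "nf_connectivity")
  }
  conn <- list(s1 = mkconn(1), s2 = mkconn(10))
  nodal <- expand.grid(subject = subs$subject, band = bands,
                       metric = c("cc", "cpl", "ge", "le"), channel = chans,
                       stringsAsFactors = FALSE)
  nodal$value <- runif(nrow(nodal))
  ft <- assemble_features(lzc, pw, conn, nodal, subs)
  expect_equal(ncol(ft) - 2, 416)
  blk <- attr(ft, "block")
  expect_equal(unname(table(blk)[c("T", "F", "S")]),
               c(32L, 32L, 352L), ignore_attr = TRUE)
  # row order follows the subject table even if inputs are shuffled
  ft2 <- assemble_features(lzc[sample(nrow(lzc)), ], pw, conn, nodal, subs)
  expect_equal(ft, ft2, ignore_attr = TRUE)
  # missing block errors with subject and block named
  expect_error(assemble_features(lzc, pw, conn["s1"], nodal, subs),
               "missing connectivity block for subject s2")
  conn_bad <- conn
  conn_bad$s2$matrices$beta <- NULL
  expect_error(assemble_features(lzc, pw, conn_bad, nodal, subs),
               "missing beta connectivity")
})
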