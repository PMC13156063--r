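#' Assemble the fused per-subject feature table
#'
#' Blocks: T (temporal) = per-band per-channel LZC (4 x 8 = 32); F
#' (frequency) = per-band per-channel individualized power (4 x 8 = 32); S
#' (spatial) = directed gated connectivity entries (8 x 7 x 4 = 224) plus
#' nodal graph metrics (8 nodes x 4 metrics x 4 bands = 128).  416 feature
#' columns in total for the standard montage; epoch-level quantities are
#' already averaged per subject upstream.
#'
#' @param lzc long LZC table (subject, band, channel, lzc), canonical bands.
#' @param powers long power table (subject, band, channel, power).
#' @param conn named list (by subject) of `nf_connectivity` objects.
#' @param nodal long nodal metric table (subject, band, metric, channel,
#'   value) from [metric_table()].
#' @param subjects data.frame with `subject`, `group` (and optionally
#'   demographics) defining row order and labels.
#' @return Wide data.frame: `subject`, `group`, then feature columns;
#'   per-column block provenance in attribute `"block"`.
#' @export
assemble_features <- function(lzc, powers, conn, nodal, subjects) {
  bands <- names(canonical_bands())
  subj <- subjects$subject
  grab <- function(df, value_col, keys, sub, block, allow_na = FALSE) {
    # keys: data.frame of column-defining ids in fixed order
    v <- numeric(nrow(keys))
    for (i in seq_len(nrow(keys))) {
      sel <- df$subject == sub
      for (k in names(keys)) sel <- sel & df[[k]] == keys[[k]][i]
      hit <- df[[value_col]][sel]
      if (length(hit) != 1 || (!allow_na && !is.finite(hit)))
        stop("missing ", block, " feature for subject ", sub, ": ",
             paste(unlist(keys[i, ]), collapse = "/"))
      v[i] <- hit
    }
    v
  }
  channels <- conn[[subj[1]]]$labels %||% unique(lzc$channel)
  keyTF <- expand.grid(band = bands, channel = channels,
                       stringsAsFactors = FALSE)
  rows <- lapply(subj, function(sub) {
    tblock <- grab(lzc[lzc$band != "broadband", ], "lzc", keyTF, sub, "T")
    fblock <- grab(powers, "power", keyTF, sub, "F")
    cm <- conn[[sub]]
    if (is.null(cm)) stop("missing connectivity block for subject ", sub)
    sblock1 <- unlist(lapply(bands, function(bn) {
      M <- cm$matrices[[bn]]
      if (is.null(M)) stop("subject ", sub, " missing ", bn, " connectivity")
      M[row(M) != col(M)]
    }))
    keyS2 <- expand.grid(band = bands, metric = c("cc", "cpl", "ge", "le"),
                         channel = channels, stringsAsFactors = FALSE)
    # undefined nodal metrics (e.g. CPL of an edgeless band graph)
    # propagate as NA here and are imputed at the classifier boundary
    sblock2 <- grab(nodal, "value", keyS2, sub, "S", allow_na = TRUE)
    c(tblock, fblock, sblock1, sblock2)
  })
  X <- do.call(rbind, rows)
  cn <- c(paste0("T_lzc_", keyTF$band, "_", keyTF$channel),
          paste0("F_pow_", keyTF$band, "_", keyTF$channel),
          unlist(lapply(bands, function(bn) {
            idx <- expand.grid(i = channels, j = channels)
            idx <- idx[idx$i != idx$j, ]
            paste0("S_conn_", bn, "_", idx$i, "_to_", idx$j)
          })),
          {
            keyS2 <- expand.grid(band = bands,
                                 metric = c("cc", "cpl", "ge", "le"),
                                 channel = channels, stringsAsFactors = FALSE)
            paste0("S_node_", keyS2$band, "_", keyS2$metric, "_",
                   keyS2$channel)
          })
  colnames(X) <- cn
  out <- data.frame(subject = subj, group = subjects$group, X,
                    check.names = FALSE)
  attr(out, "block") <- setNames(substr(cn, 1, 1), cn)
  out
}

feature_columns <- function(features, blocks) {
  blk <- attr(features, "block")
  if (is.null(blk)) {
    cn <- setdiff(names(features), c("subject", "group"))
    blk <- setNames(substr(cn, 1, 1), cn)
  }
  names(blk)[blk %in% blocks]
}

# NA-safe CPL handling: replace non-finite values by the column mean over
# finite entries, or 0 when a column has none (e.g. CPL of bands whose
# gated graphs are empty for every subject)
impute_columns <- function(X) {
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) {
      fill <- if (all(bad)) 0 else mean(X[!bad, j])
      X[bad, j] <- fill
    }
  }
  X
}

stratified_folds <- function(groups, folds) {
  f <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- sample(which(groups == g))
    f[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  f
}

binary_metrics <- function(truth, pred, scores, positive) {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  auc <- if (length(pos) && length(neg))
    (mean(outer(pos, neg, `>`)) + 0.5 * mean(outer(pos, neg, `==`)))
  else NA_real_
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = rec,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
    auc = auc)
}

#' Subject-level repeated cross-validated SVM evaluation
#'
#' Per repetition: stratified subject-level k-fold split; per fold: z-score
#' standardization fit on the training subjects only, RBF-SVM (fixed C,
#' `1/n_features` kernel width) trained and the held-out subjects predicted.
#' Fold metrics are pooled within each repetition; the summary is the
#' across-repetition mean with a t-based 95% CI.  Train/test subject
#' disjointness is asserted in every fold.
#'
#' @param features wide table from [assemble_features()] (or any data.frame
#'   with `subject`, `group` and numeric feature columns).
#' @param blocks feature blocks to use, subset of `c("T", "F", "S")`.
#' @param reps repetitions (default 5).
#' @param folds folds (default 10).
#' @param C SVM penalty (default 1).
#' @param seed RNG seed controlling fold assignment.
#' @param positive positive-class label (default `"ASD-like"` when present).
#' @return An `nf_cv_result`: `summary` (metric, mean, ci_lo, ci_hi),
#'   `per_rep` matrix, per-fold `predictions`, and the config snapshot.
#' @export
cv_evaluate <- function(features, blocks = c("T", "F", "S"), reps = 5,
                        folds = 10, C = 1, seed = 1, positive = NULL) {
  cols <- feature_columns(features, blocks)
  if (!length(cols)) stop("no feature columns for blocks ",
                          paste(blocks, collapse = "+"))
  groups <- as.character(features$group)
  if (is.null(positive))
    positive <- if ("ASD-like" %in% groups) "ASD-like" else sort(unique(groups))[2]
  if (min(table(groups)) < folds)
    stop("need >= ", folds, " subjects per class for ", folds, "-fold CV")
  X <- impute_columns(as.matrix(features[, cols, drop = FALSE]))
  per_rep <- matrix(NA_real_, reps, 5,
                    dimnames = list(NULL, c("accuracy", "sensitivity",
                                            "specificity", "f1", "auc")))
  preds_all <- list()
  for (r in seq_len(reps)) {
    fold_id <- with_seed(child_seed(seed, r), stratified_folds(groups, folds))
    truth <- character(0); pred <- character(0); score <- numeric(0)
    for (k in seq_len(folds)) {
      te <- which(fold_id == k)
      tr <- which(fold_id != k)
      stopifnot(length(intersect(features$subject[tr],
                                 features$subject[te])) == 0)
      if (length(unique(groups[tr])) < 2) stop("class absent in training fold")
      mu <- colMeans(X[tr, , drop = FALSE])
      sg <- apply(X[tr, , drop = FALSE], 2, sd)
      sg[sg == 0] <- 1
      Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, `/`)
      Zte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sg, `/`)
      fit <- svm_rbf(Ztr, groups[tr], C = C, positive = positive)
      pred <- c(pred, predict(fit, Zte))
      score <- c(score, predict(fit, Zte, type = "decision"))
      truth <- c(truth, groups[te])
      preds_all[[length(preds_all) + 1]] <-
        data.frame(rep = r, fold = k, subject = features$subject[te],
                   truth = groups[te],
                   pred = predict(fit, Zte),
                   score = predict(fit, Zte, type = "decision"))
    }
    per_rep[r, ] <- binary_metrics(truth, pred, score, positive)
  }
  summarize <- function(v) {
    m <- mean(v)
    if (length(v) > 1 && sd(v) > 0) {
      half <- qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v))
      c(mean = m, ci_lo = m - half, ci_hi = m + half)
    } else c(mean = m, ci_lo = m, ci_hi = m)
  }
  summ <- t(apply(per_rep, 2, summarize))
  structure(list(summary = data.frame(metric = rownames(summ), summ,
                                      row.names = NULL),
                 per_rep = per_rep,
                 predictions = do.call(rbind, preds_all),
                 config = list(blocks = blocks, reps = reps, folds = folds,
                               C = C, kernel = "rbf",
                               gamma = "1/n_features", seed = seed,
                               positive = positive,
                               n_features = length(cols))),
            class = "nf_cv_result")
}

#' @export
print.nf_cv_result <- function(x, ...) {
  cat(sprintf("<nf_cv_result> blocks %s | %dx%d-fold CV | C = %g\n",
              paste(x$config$blocks, collapse = "+"), x$config$reps,
              x$config$folds, x$config$C))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f [%.3f, %.3f]\n", s$metric[i], s$mean[i],
                s$ci_lo[i], s$ci_hi[i]))
  invisible(x)
}

#' Feature-block ablation
#'
#' [cv_evaluate()] for each block combination (default the five standard
#' sets T, F, S, T+F, T+F+S) under shared seeds, summarized in one table.
#'
#' @param features as in [cv_evaluate()].
#' @param block_sets named list of block subsets.
#' @inheritParams cv_evaluate
#' @return `list(table, results)`: comparison data.frame (combination x
#'   metric means) and the full per-combination `nf_cv_result`s.
#' @export
ablation <- function(features,
                     block_sets = list(T = "T", F = "F", S = "S",
                                       `T+F` = c("T", "F"),
                                       `T+F+S` = c("T", "F", "S")),
                     reps = 5, folds = 10, C = 1, seed = 1) {
  results <- lapply(block_sets, function(b)
    cv_evaluate(features, blocks = b, reps = reps, folds = folds, C = C,
                seed = seed))
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    s <- results[[nm]]$summary
    data.frame(combination = nm,
               setNames(as.list(s$mean), s$metric))
  }))
  list(table = tab, results = results)
}

#' Demographics-only baseline classifier
#'
#' The same CV protocol on an age + sex table only; group-independent
#' demographics should perform at chance.
#'
#' @param age,sex numeric vectors, one entry per subject.
#' @param labels group label per subject.
#' @param subject optional subject ids.
#' @inheritParams cv_evaluate
#' @return An `nf_cv_result`.
#' @export
baseline_demographics <- function(age, sex, labels, subject = NULL,
                                  reps = 5, folds = 10, C = 1, seed = 1) {
  if (is.null(subject)) subject <- sprintf("sub-%03d", seq_along(age))
  df <- data.frame(subject = subject, group = labels,
                   T_age = age, T_sex = as.numeric(sex),
                   check.names = FALSE)
  attr(df, "block") <- c(T_age = "T", T_sex = "T")
  cv_evaluate(df, blocks = "T", reps = reps, folds = folds, C = C,
              seed = seed)
}
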