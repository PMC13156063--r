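# Soft-margin SVM with RBF kernel, trained by sequential minimal
# optimization (SMO).  Deliberately small: fixed C, no shrinking, no caching
# beyond the full kernel matrix -- training sets here are tens of subjects.
# Deterministic: systematic first-choice loop, max-|E1 - E2| second choice.

rbf_kernel_matrix <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

#' Train an RBF-kernel support vector classifier
#'
#' Dual soft-margin SVM solved by SMO.  Defaults follow the fixed protocol
#' used throughout the package: `C = 1` and the `1/n_features` kernel-width
#' heuristic on standardized inputs; no hyperparameter search.
#'
#' @param X numeric matrix, rows = observations (standardized columns).
#' @param y labels coercible to two classes; internally mapped to -1/+1
#'   (positive class = the last factor level, see `positive`).
#' @param C soft-margin penalty.
#' @param gamma RBF width; default `1 / ncol(X)`.
#' @param positive which label is the positive class (+1); default the
#'   second sorted unique label.
#' @param tol KKT violation tolerance.
#' @param max_passes sweeps over the data without any update before stopping.
#' @return An `nf_svm` model.
#' @export
svm_rbf <- function(X, y, C = 1, gamma = NULL, positive = NULL,
                    tol = 1e-3, max_passes = 200) {
  X <- as.matrix(X)
  labs <- sort(unique(as.character(y)))
  if (length(labs) != 2) stop("need exactly two classes")
  if (is.null(positive)) positive <- labs[2]
  yy <- ifelse(as.character(y) == positive, 1, -1)
  n <- nrow(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  K <- rbf_kernel_matrix(X, X, gamma)
  alpha <- numeric(n)
  b <- 0
  fcache <- function() as.numeric(K %*% (alpha * yy)) + b
  passes <- 0
  sweeps <- 0
  while (passes < 2 && sweeps < max_passes) {
    sweeps <- sweeps + 1
    changed <- 0
    E <- fcache() - yy
    for (i in seq_len(n)) {
      Ei <- E[i]
      if ((yy[i] * Ei < -tol && alpha[i] < C) ||
          (yy[i] * Ei > tol && alpha[i] > 0)) {
        j <- which.max(abs(E - Ei))
        if (j == i) next
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (yy[i] != yy[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - yy[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + yy[i] * yy[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - yy[i] * (ai - ai_old) * K[i, i] -
          yy[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - yy[i] * (ai - ai_old) * K[i, j] -
          yy[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1
             else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        E <- fcache() - yy
        changed <- changed + 1
      }
    }
    passes <- if (changed == 0) passes + 1 else 0
  }
  sv <- which(alpha > 1e-8)
  structure(list(X_sv = X[sv, , drop = FALSE], alpha_y = (alpha * yy)[sv],
                 b = b, gamma = gamma, C = C, positive = positive,
                 negative = setdiff(labs, positive)),
            class = "nf_svm")
}

#' @export
predict.nf_svm <- function(object, newdata, type = c("class", "decision"),
                           ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  f <- if (nrow(object$X_sv) == 0) rep(object$b, nrow(newdata)) else
    as.numeric(rbf_kernel_matrix(newdata, object$X_sv, object$gamma) %*%
                 object$alpha_y) + object$b
  if (type == "decision") return(f)
  ifelse(f >= 0, object$positive, object$negative)
}
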