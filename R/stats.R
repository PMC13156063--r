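#' Lilliefors test of normality
#'
#' Kolmogorov-Smirnov test against a normal with mean and SD estimated from
#' the sample, with the Dallal-Wilkinson p-value approximation (accurate in
#' the small-p region that decides routing at alpha = 0.05; values outside
#' [0, 1] are clamped).
#'
#' @param x numeric sample, n >= 4.
#' @return `list(statistic, p)`.
#' @export
lilliefors <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  s <- stats::sd(x)
  if (s == 0) return(list(statistic = 1, p = 0))
  z <- stats::pnorm((x - mean(x)) / s)
  i <- seq_len(n)
  D <- max(pmax(i / n - z, z - (i - 1) / n))
  # Dallal & Wilkinson (1986) approximation
  if (n > 100) {
    Dd <- D * (n / 100)^0.49
    nd <- 100
  } else {
    Dd <- D
    nd <- n
  }
  p <- exp(-7.01256 * Dd^2 * (nd + 2.78019) +
             2.99587 * Dd * sqrt(nd + 2.78019) - 0.122119 +
             0.974598 / sqrt(nd) + 1.67997 / nd)
  list(statistic = D, p = min(max(p, 0), 1))
}

#' Choose the two-group test by normality screening
#'
#' Lilliefors-corrected KS per group at `alpha`; if either group is
#' non-normal and all values are positive, both groups are log-transformed
#' and retested; if normality still fails (or the transform is blocked by
#' non-positive values) the route is Mann-Whitney, otherwise the t-test.
#'
#' @param a,b numeric samples (>= 4 each).
#' @param alpha normality screening level.
#' @return `list(test = "t"|"mann_whitney", log_transform = logical)`.
#' @export
normality_route <- function(a, b, alpha = 0.05) {
  normal <- function(x) lilliefors(x)$p >= alpha
  if (normal(a) && normal(b))
    return(list(test = "t", log_transform = FALSE))
  if (all(a > 0) && all(b > 0) && normal(log(a)) && normal(log(b)))
    return(list(test = "t", log_transform = TRUE))
  list(test = "mann_whitney", log_transform = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up procedure: adjusted p-values are the running minima of
#' `p_(i) * m / i` from the largest rank down; rejections at level `q` are
#' `p_adj <= q`.
#'
#' @param p vector of p-values.
#' @param q FDR level for the rejection mask.
#' @return `list(p_adj, reject)`; empty input gives empty output.
#' @export
fdr_bh <- function(p, q = 0.05) {
  m <- length(p)
  if (!m) return(list(p_adj = numeric(0), reject = logical(0)))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(p[o] * m / (m:1)))[ro]
  list(p_adj = adj, reject = adj <= q)
}

#' Cohen's d
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled` with the
#' pooled SD using n-1 weights.
#'
#' @param a,b numeric samples (>= 2 each).
#' @return d, or `NA` with a warning when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("need n >= 2 per group")
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 <= 0) {
    warning("zero pooled SD; d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Two-group comparison over a feature table
#'
#' Per feature: normality routing ([normality_route()]), Welch t-test or
#' Mann-Whitney, Cohen's d on the untransformed values (sign = group A minus
#' group B); BH correction applied within each feature family.  Constant
#' features are skipped (logged in the `skipped` attribute).
#'
#' @param features long data.frame with columns `subject`, `group`,
#'   `family`, `feature`, `value`.
#' @param group_a,group_b the two group labels; defaults to sorted unique
#'   order (A = first).
#' @param q FDR level.
#' @param global_fdr correct across all families jointly instead of within
#'   family.
#' @return Data.frame (family, feature, test, log_transform, statistic,
#'   p_raw, p_fdr, reject, cohens_d, mean_a, mean_b, sd_a, sd_b, n_a, n_b).
#' @export
group_compare_table <- function(features, group_a = NULL, group_b = NULL,
                                q = 0.05, global_fdr = FALSE) {
  stopifnot(all(c("subject", "group", "family", "feature", "value") %in%
                  names(features)))
  gs <- sort(unique(features$group))
  if (length(gs) != 2 && (is.null(group_a) || is.null(group_b)))
    stop("need exactly two groups")
  if (is.null(group_a)) group_a <- gs[1]
  if (is.null(group_b)) group_b <- gs[2]
  keys <- unique(features[, c("family", "feature")])
  skipped <- character(0)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- features$family == keys$family[i] & features$feature == keys$feature[i]
    a <- features$value[sel & features$group == group_a]
    b <- features$value[sel & features$group == group_b]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 4 || length(b) < 4 || (sd(a) == 0 && sd(b) == 0)) {
      skipped <<- c(skipped, paste0(keys$family[i], "/", keys$feature[i]))
      return(NULL)
    }
    route <- normality_route(a, b)
    ta <- if (route$log_transform) log(a) else a
    tb <- if (route$log_transform) log(b) else b
    if (route$test == "t") {
      tt <- t.test(ta, tb, var.equal = FALSE)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      wt <- suppressWarnings(wilcox.test(ta, tb))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(family = keys$family[i], feature = keys$feature[i],
               test = route$test, log_transform = route$log_transform,
               statistic = stat, p_raw = p,
               cohens_d = suppressWarnings(cohens_d(a, b)),
               mean_a = mean(a), mean_b = mean(b),
               sd_a = sd(a), sd_b = sd(b),
               n_a = length(a), n_b = length(b))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    out <- data.frame()
  } else if (global_fdr) {
    adj <- fdr_bh(out$p_raw, q)
    out$p_fdr <- adj$p_adj; out$reject <- adj$reject
  } else {
    out$p_fdr <- NA_real_; out$reject <- NA
    for (fam in unique(out$family)) {
      sel <- out$family == fam
      adj <- fdr_bh(out$p_raw[sel], q)
      out$p_fdr[sel] <- adj$p_adj
      out$reject[sel] <- adj$reject
    }
  }
  attr(out, "skipped") <- skipped
  attr(out, "groups") <- c(a = group_a, b = group_b)
  out
}
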