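#' Outlier-cleaned mean epoch covariance
#'
#' Per-epoch channel covariances are compared to their grand mean by
#' Frobenius (Euclidean) distance; distances are z-scored and epochs with
#' |z| > 3 dropped before the mean is recomputed over the survivors.
#'
#' @param epochs an [epoch_recording()] result with >= 4 epochs.
#' @param z_max rejection threshold in SD units.
#' @return Channels x channels covariance matrix; retained epoch indices in
#'   attribute `"retained"`.
#' @export
clean_mean_covariance <- function(epochs, z_max = 3) {
  stopifnot(inherits(epochs, "nf_epochs"))
  ne <- n_epochs(epochs)
  if (ne < 4) stop("need >= 4 epochs for outlier-cleaned covariance")
  covs <- lapply(seq_len(ne), function(i) {
    x <- epochs$epochs[i, , , drop = TRUE]
    x <- x - rowMeans(x)
    tcrossprod(x) / (ncol(x) - 1)
  })
  grand <- Reduce(`+`, covs) / ne
  d <- vapply(covs, function(cm) sqrt(sum((cm - grand)^2)), numeric(1))
  z <- if (stats::sd(d) > 0) (d - mean(d)) / stats::sd(d) else rep(0, ne)
  keep <- which(abs(z) <= z_max)
  stopifnot(length(keep) >= 1)   # |z|>3 cannot reject all of >= 4 epochs
  out <- Reduce(`+`, covs[keep]) / length(keep)
  attr(out, "retained") <- keep
  out
}

# shrinkage-regularized broadband (reference) covariance
regularize_cov <- function(R, gamma = 0.01) {
  (1 - gamma) * R + gamma * mean(diag(R)) * diag(nrow(R))
}

# generalized symmetric-definite eigenproblem S W = R W Lambda via Cholesky;
# eigenvalues are real by construction, eigenvectors returned R-orthogonal.
ged_solve <- function(S, R) {
  L <- chol(R)                       # R = L' L (upper triangular L)
  Li <- backsolve(L, diag(nrow(R)))  # inv(L)
  M <- t(Li) %*% S %*% Li
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  W <- Li %*% e$vectors
  # sign convention: largest-|component| positive
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  list(values = e$values, vectors = W)
}

#' Generalized eigendecomposition at one target frequency
#'
#' The recording is narrowband filtered with a Gaussian spectral filter at
#' `f` (FWHM defaulting to `max(1, 0.1 f)` Hz); the narrowband covariance S
#' and the shrinkage-regularized broadband covariance R (both outlier-cleaned
#' over 2-s epochs) define the generalized eigenproblem `S W = R W Lambda`
#' whose leading eigenvector is the spatial filter maximizing the
#' narrowband-to-broadband variance ratio (Rayleigh quotient).
#'
#' @param rec an [recording()].
#' @param f target frequency in Hz.
#' @param fwhm narrowband filter FWHM in Hz.
#' @param shrinkage shrinkage fraction for R regularization.
#' @param epoch_len covariance epoch length in seconds.
#' @param R_cov optional precomputed regularized broadband covariance.
#' @return `list(values, vectors, f)`: eigenvalues (descending, real) and
#'   R-orthogonal eigenvectors (channels x channels), sign-fixed.
#' @export
ged_at_frequency <- function(rec, f, fwhm = max(1, 0.1 * f),
                             shrinkage = 0.01, epoch_len = 2, R_cov = NULL) {
  validate_recording(rec)
  if (f <= 0 || f >= rec$fs / 2) stop("f must lie in (0, fs/2)")
  if (is.null(R_cov)) {
    R <- clean_mean_covariance(epoch_recording(rec, epoch_len))
    R_cov <- regularize_cov(R, shrinkage)
  }
  nb <- rec
  nb$data <- t(apply(rec$data, 1, gaussian_narrowband, fs = rec$fs,
                     f = f, fwhm = fwhm))
  S <- clean_mean_covariance(epoch_recording(nb, epoch_len))
  sol <- ged_solve(S, R_cov)
  c(sol, list(f = f))
}

#' Sweep the GED over a frequency grid
#'
#' @param rec an [recording()].
#' @param f_lo,f_hi grid limits in Hz (defaults 2-45; must lie in
#'   `(0, fs/2)`).
#' @param step grid step in Hz.
#' @param fwhm_fun function of f giving the narrowband FWHM.
#' @param shrinkage,epoch_len as in [ged_at_frequency()].
#' @return An `nf_ged_sweep`: `grid` (Hz), `lambda_max`, `vectors`
#'   (channels x n_freq leading eigenvectors).
#' @export
ged_sweep <- function(rec, f_lo = 2, f_hi = 45, step = 0.5,
                      fwhm_fun = function(f) max(1, 0.1 * f),
                      shrinkage = 0.01, epoch_len = 2) {
  validate_recording(rec)
  if (f_lo <= 0 || f_hi >= rec$fs / 2 || f_hi < f_lo)
    stop("frequency grid must lie within (0, fs/2)")
  grid <- seq(f_lo, f_hi, by = step)
  if (!length(grid)) stop("empty frequency grid")
  R <- clean_mean_covariance(epoch_recording(rec, epoch_len))
  R_cov <- regularize_cov(R, shrinkage)
  lam <- numeric(length(grid))
  vecs <- matrix(0, n_channels(rec), length(grid))
  for (i in seq_along(grid)) {
    sol <- ged_at_frequency(rec, grid[i], fwhm = fwhm_fun(grid[i]),
                            epoch_len = epoch_len, R_cov = R_cov)
    lam[i] <- sol$values[1]
    vecs[, i] <- sol$vectors[, 1]
  }
  structure(list(grid = grid, lambda_max = lam, vectors = vecs,
                 labels = rec$labels,
                 subject = rec$meta$subject %||% "subject"),
            class = "nf_ged_sweep")
}

#' Eigenvector similarity across frequencies
#'
#' Entry (i, j) is the squared Pearson correlation between the leading
#' eigenvectors at grid frequencies i and j; symmetric with unit diagonal.
#' A zero-variance eigenvector yields similarity 0 off-diagonal.
#'
#' @param sweep an [ged_sweep()] result.
#' @return n_freq x n_freq similarity matrix.
#' @export
similarity_matrix <- function(sweep) {
  stopifnot(inherits(sweep, "nf_ged_sweep"))
  V <- sweep$vectors
  if (ncol(V) < 2) stop("need >= 2 frequencies")
  sds <- apply(V, 2, stats::sd)
  ok <- sds > 0
  sim <- matrix(0, ncol(V), ncol(V))
  if (any(ok)) sim[ok, ok] <- cor(V[, ok, drop = FALSE])^2
  diag(sim) <- 1
  sim
}

# minimal DBSCAN on a precomputed distance matrix
dbscan_dist <- function(D, eps, min_pts) {
  n <- nrow(D)
  labels <- rep(0L, n)      # 0 = unassigned/noise
  visited <- rep(FALSE, n)
  cl <- 0L
  neighbors <- function(i) which(D[i, ] <= eps)
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbors(i)
    if (length(nb) < min_pts) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbors(j)
        if (length(nbj) >= min_pts) queue <- union(queue, setdiff(nbj, j))
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

# split cluster labels into frequency-contiguous runs, drop short runs
contiguous_runs <- function(labels, min_len) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values != 0L & r$lengths >= min_len)
  lapply(idx, function(i) starts[i]:ends[i])
}

#' Detect individualized band boundaries from a GED sweep
#'
#' `dbscan`: frequencies are clustered on the distance `1 - similarity` with
#' minPts = 3, scanning epsilon over a grid and keeping the solution with the
#' most clusters; clusters are restricted to frequency-contiguous runs, each
#' reported as the interval `[min f, max f]`.  `trough`: the lambda_max(f)
#' spectrum is smoothed (5-point moving average); peaks with prominence of at
#' least 10% of its range delimit bands at the minima between adjacent peaks.
#' If nothing is found, a single flagged interval spanning the grid is
#' returned.
#'
#' @param sweep an [ged_sweep()] result.
#' @param method `"dbscan"` (default) or `"trough"`.
#' @param min_pts DBSCAN minimum neighborhood size.
#' @param eps_grid epsilons scanned for DBSCAN.
#' @return An `nf_band_boundaries`: `intervals` data.frame (lo, hi, cluster),
#'   the grid, method, and `flagged` when detection fell back.
#' @export
cluster_bands <- function(sweep, method = c("dbscan", "trough"),
                          min_pts = 3, eps_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(inherits(sweep, "nf_ged_sweep"))
  method <- match.arg(method)
  grid <- sweep$grid
  flagged <- FALSE
  if (method == "dbscan") {
    sim <- similarity_matrix(sweep)
    D <- 1 - sim
    best <- NULL
    for (eps in eps_grid) {
      labels <- dbscan_dist(D, eps, min_pts)
      runs <- contiguous_runs(labels, min_pts)
      if (length(runs) >= 1 &&
          (is.null(best) || length(runs) > length(best)))
        best <- runs
    }
    runs <- best
  } else {
    lam <- moving_average(sweep$lambda_max, 5)
    pk <- find_peaks(lam, prominence = 0.1 * diff(range(lam)))
    if (length(pk) >= 1) {
      # troughs between adjacent peaks bound the clusters; each band
      # extends from its peak to the half-prominence level (or the trough)
      cuts <- integer(0)
      if (length(pk) > 1)
        for (i in seq_len(length(pk) - 1)) {
          seg <- pk[i]:pk[i + 1]
          cuts <- c(cuts, seg[which.min(lam[seg])])
        }
      lims <- c(1, cuts, length(grid))
      runs <- lapply(seq_along(pk), function(i) {
        lo_lim <- lims[i]; hi_lim <- lims[i + 1]
        thr <- lam[pk[i]] - 0.5 * (lam[pk[i]] - min(lam))
        lo <- pk[i]; while (lo > lo_lim && lam[lo - 1] >= thr) lo <- lo - 1
        hi <- pk[i]; while (hi < hi_lim && lam[hi + 1] >= thr) hi <- hi + 1
        lo:hi
      })
    } else runs <- NULL
  }
  if (is.null(runs) || !length(runs)) {
    runs <- list(seq_along(grid))
    flagged <- TRUE
  }
  iv <- do.call(rbind, lapply(seq_along(runs), function(k)
    data.frame(lo = grid[min(runs[[k]])], hi = grid[max(runs[[k]])],
               cluster = k)))
  iv <- iv[order(iv$lo), , drop = FALSE]
  iv$cluster <- seq_len(nrow(iv))
  structure(list(intervals = iv, grid = grid, method = method,
                 flagged = flagged, subject = sweep$subject),
            class = "nf_band_boundaries")
}

# local maxima with a simple prominence rule
find_peaks <- function(x, prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  keep <- vapply(cand, function(i) {
    left <- min(x[1:i]); right <- min(x[i:n])
    (x[i] - max(left, right)) >= prominence
  }, logical(1))
  cand[keep]
}

#' Assign detected intervals to canonical band names
#'
#' Each interval goes to the canonical band containing its midpoint
#' (delta < 4, theta 4-8, alpha 8-13, beta 13-30 Hz); several intervals in
#' one canonical range merge to their envelope `[min lo, max hi]`; bands with
#' no interval are reported unassigned (NA limits).
#'
#' @param bounds an [cluster_bands()] result.
#' @return The same object with a `canonical` data.frame
#'   (band, lo, hi, assigned).
#' @export
assign_canonical <- function(bounds) {
  stopifnot(inherits(bounds, "nf_band_boundaries"))
  ranges <- list(delta = c(-Inf, 4), theta = c(4, 8), alpha = c(8, 13),
                 beta = c(13, 30))
  iv <- bounds$intervals
  mid <- (iv$lo + iv$hi) / 2
  canon <- do.call(rbind, lapply(names(ranges), function(bn) {
    r <- ranges[[bn]]
    hit <- which(mid >= r[1] & mid < r[2])
    if (length(hit))
      data.frame(band = bn, lo = min(iv$lo[hit]), hi = max(iv$hi[hit]),
                 assigned = TRUE)
    else data.frame(band = bn, lo = NA_real_, hi = NA_real_, assigned = FALSE)
  }))
  bounds$canonical <- canon
  bounds
}

#' Individualized band power from detected boundaries
#'
#' Welch PSD per channel; a band's power is the mean density over the
#' subject's own interval for that band (units signal^2/Hz).  Unassigned
#' bands yield NA, not zero.
#'
#' @param rec an [recording()].
#' @param bounds an [assign_canonical()] result.
#' @param seg_len,overlap Welch parameters, see [welch_psd()].
#' @return Long data.frame (subject, band, channel, power, lo, hi).
#' @export
individualized_band_power <- function(rec, bounds, seg_len = NULL,
                                      overlap = 0.5) {
  stopifnot(inherits(bounds, "nf_band_boundaries"))
  if (is.null(bounds$canonical))
    stop("bounds lack canonical assignment; call assign_canonical() first")
  w <- welch_psd(rec, seg_len = seg_len, overlap = overlap)
  subject <- rec$meta$subject %||% "subject"
  do.call(rbind, lapply(seq_len(nrow(bounds$canonical)), function(i) {
    b <- bounds$canonical[i, ]
    p <- if (b$assigned) {
      sel <- w$freq >= b$lo & w$freq <= b$hi
      if (any(sel)) rowMeans(w$psd[, sel, drop = FALSE]) else NA_real_
    } else rep(NA_real_, n_channels(rec))
    data.frame(subject = subject, band = b$band, channel = rec$labels,
               power = p, lo = b$lo, hi = b$hi, row.names = NULL)
  }))
}

#' Individualized frequency-band detection (gedBounds), end to end
#'
#' Convenience wrapper: [ged_sweep()] then [cluster_bands()] then
#' [assign_canonical()].
#'
#' @inheritParams ged_sweep
#' @inheritParams cluster_bands
#' @return An `nf_band_boundaries` with canonical assignment.
#' @export
gedbounds <- function(rec, f_lo = 2, f_hi = 45, step = 0.5,
                      method = c("dbscan", "trough"), ...) {
  sweep <- ged_sweep(rec, f_lo = f_lo, f_hi = f_hi, step = step, ...)
  assign_canonical(cluster_bands(sweep, method = method))
}

#' Across-subject boundary statistics
#'
#' Mean and SD of per-subject assigned interval endpoints, per canonical
#' band and group: the cohort-level summary of individualized boundaries.
#'
#' @param bounds_list list of `nf_band_boundaries` with canonical assignment.
#' @param groups optional group label per subject.
#' @return Data.frame (group, band, n, lo_mean, lo_sd, hi_mean, hi_sd).
#' @export
boundary_stats <- function(bounds_list, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(bounds_list))
  rows <- do.call(rbind, lapply(seq_along(bounds_list), function(i) {
    cbind(group = groups[i], bounds_list[[i]]$canonical)
  }))
  rows <- rows[rows$assigned, ]
  out <- aggregate(cbind(lo, hi) ~ group + band, rows,
                   function(v) c(mean = mean(v), sd = stats::sd(v)))
  data.frame(group = out$group, band = out$band,
             lo_mean = out$lo[, "mean"], lo_sd = out$lo[, "sd"],
             hi_mean = out$hi[, "mean"], hi_sd = out$hi[, "sd"])
}
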