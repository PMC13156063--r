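# Independent brute-force oracles.  These deliberately share no code with
# the implementations they check.

# Exhaustive-history LZ76 parse by direct substring search: starting a new
# phrase at j, extend r until s[j..r] is no longer a substring of
# s[1..r-1]; an exhausted (still reproducible) tail still counts one phrase.
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  c <- 0L
  j <- 1L
  while (j <= n) {
    r <- j
    repeat {
      w <- substr(s, j, r)
      hist <- substr(s, 1, r - 1)
      if (!grepl(w, hist, fixed = TRUE)) break      # phrase ends at r
      if (r == n) break                             # reproducible tail
      r <- r + 1L
    }
    c <- c + 1L
    j <- r + 1L
  }
  c
}

# all binary vectors of length len, as a list
all_bitstrings <- function(len) {
  lapply(0:(2^len - 1), function(v)
    as.integer(intToBits(v))[seq_len(len)])
}

# Floyd-Warshall all-pairs shortest paths on a distance matrix with Inf for
# missing edges and zero diagonal
floyd_warshall <- function(D) {
  n <- nrow(D)
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# graph metrics from first principles via Floyd-Warshall (weighted mode,
# weights assumed already symmetric, normalized, zero diagonal)
graph_metrics_oracle <- function(A) {
  n <- nrow(A)
  D0 <- ifelse(A > 0, 1 / A, Inf)
  diag(D0) <- 0
  D <- floyd_warshall(D0)
  off <- !diag(n)
  fin <- is.finite(D) & off
  cpl <- if (any(fin)) mean(D[fin]) else NA_real_
  E <- 1 / D; diag(E) <- 0; E[!is.finite(E)] <- 0
  ge <- sum(E) / (n * (n - 1))
  k <- rowSums(A > 0)
  W <- A^(1 / 3)
  t_i <- diag(W %*% W %*% W) / 2
  cc_i <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  le_i <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- A[nb, nb, drop = FALSE]
    Ds0 <- ifelse(sub > 0, 1 / sub, Inf)
    diag(Ds0) <- 0
    Ds <- floyd_warshall(Ds0)
    Es <- 1 / Ds; diag(Es) <- 0; Es[!is.finite(Es)] <- 0
    sum(Es) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  list(cc = mean(cc_i), cpl = cpl, ge = ge, le = mean(le_i),
       cc_i = cc_i, le_i = le_i)
}

# Benjamini-Hochberg rejections straight from the step-up definition
bh_reject_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

random_graph8 <- function(seed, density = 0.4) {
  set.seed(seed)
  A <- matrix(0, 8, 8)
  up <- upper.tri(A)
  w <- runif(sum(up))
  w[runif(sum(up)) > density] <- 0
  A[up] <- w
  A <- A + t(A)
  A
}
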