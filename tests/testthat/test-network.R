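binary_graph <- function(edges, n) {
  A <- matrix(0, n, n)
  for (e in edges) { A[e[1], e[2]] <- 1; A[e[2], e[1]] <- 1 }
  to_graph(A, mode = "binary")
}

test_that("to_graph symmetrizes, validates and thresholds", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- 2                      # w_ij = 2, w_ji = 0 -> symmetrized 1
  g <- to_graph(W, normalize = FALSE)
  expect_equal(g$adj[1, 2], 1)
  expect_equal(g$dist[1, 2], 1)
  expect_true(is.infinite(g$dist[1, 3]))
  sym <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(to_graph(sym, normalize = FALSE)$adj, sym)
  expect_error(to_graph(matrix(c(0, -1, -1, 0), 2)), "negative")
  expect_error(to_graph(diag(2)), "diagonal")
  z <- to_graph(matrix(0, 4, 4))
  expect_equal(global_efficiency(z)$global, 0)
})

test_that("hand-computed metric values on canonical small graphs", {
  K4 <- binary_graph(list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4),
                          c(3, 4)), 4)
  expect_equal(clustering_coefficient(K4)$global, 1)
  expect_equal(characteristic_path_length(K4)$global, 1)
  expect_equal(global_efficiency(K4)$global, 1)
  expect_equal(local_efficiency(K4)$global, 1)

  star <- binary_graph(list(c(1, 2), c(1, 3), c(1, 4)), 4)
  expect_equal(clustering_coefficient(star)$global, 0)
  expect_equal(characteristic_path_length(star)$global, 1.5)
  expect_equal(global_efficiency(star)$global, 0.75)
  expect_equal(local_efficiency(star)$global, 0)

  path3 <- binary_graph(list(c(1, 2), c(2, 3)), 3)
  expect_equal(characteristic_path_length(path3)$global, 4 / 3)

  tri_pend <- binary_graph(list(c(1, 2), c(1, 3), c(2, 3), c(3, 4)), 4)
  cc <- clustering_coefficient(tri_pend)
  expect_equal(unname(cc$nodal), c(1, 1, 1 / 3, 0))
})

test_that("weighted metrics match the Floyd-Warshall oracle", {
  for (seed in 1:20) {
    A <- random_graph8(seed)
    if (max(A) > 0) A <- A / max(A)
    g <- to_graph(A)
    ora <- graph_metrics_oracle(A)
    expect_equal(clustering_coefficient(g)$global, ora$cc,
                 tolerance = 1e-10)
    expect_equal(characteristic_path_length(g)$global, ora$cpl,
                 tolerance = 1e-10)
    expect_equal(global_efficiency(g)$global, ora$ge, tolerance = 1e-10)
    expect_equal(local_efficiency(g)$global, ora$le, tolerance = 1e-10)
  }
})

test_that("GE monotonicity and scale behavior", {
  A <- random_graph8(99, density = 0.3)
  g0 <- global_efficiency(to_graph(A, normalize = FALSE))$global
  B <- A
  empty <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
  B[empty[1, 1], empty[1, 2]] <- B[empty[1, 2], empty[1, 1]] <- 0.5
  g1 <- global_efficiency(to_graph(B, normalize = FALSE))$global
  expect_gte(g1, g0)
  # multiplying weights by c multiplies GE by c under d = 1/w
  gc_ <- global_efficiency(to_graph(3 * A, normalize = FALSE))$global
  expect_equal(gc_, 3 * g0, tolerance = 1e-10)
  # which is why to_graph normalizes by default:
  expect_equal(global_efficiency(to_graph(3 * A))$global,
               global_efficiency(to_graph(A))$global)
})

test_that("metric_table emits long global and nodal tables, NA propagates", {
  mk_conn <- function(seed) {
    mats <- lapply(1:4, function(b) {
      A <- random_graph8(seed * 10 + b)
      dimnames(A) <- list(nf_channels(), nf_channels())
      A
    })
    names(mats) <- names(canonical_bands())
    structure(list(matrices = mats, labels = nf_channels()),
              class = "nf_connectivity")
  }
  tabs <- metric_table(list(s1 = mk_conn(1), s2 = mk_conn(2)))
  expect_equal(nrow(tabs$global), 2 * 4 * 4)
  expect_equal(nrow(tabs$nodal), 2 * 4 * 4 * 8)
  # permuting node order leaves global metrics unchanged
  cn <- mk_conn(3)
  perm <- sample(8)
  cnp <- cn
  cnp$matrices <- lapply(cn$matrices, function(M) M[perm, perm])
  t1 <- metric_table(list(a = cn))$global
  t2 <- metric_table(list(a = cnp))$global
  expect_equal(t1$value, t2$value, tolerance = 1e-12)
})
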