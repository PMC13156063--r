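#' Build a brain graph from a directed connectivity matrix
#'
#' The directed gated matrix is symmetrized by averaging
#' `(w_ij + w_ji) / 2`; weights are normalized by the matrix maximum (so
#' metrics are scale-free under `d = 1/w`); distances are `1/w` for positive
#' weights, `Inf` otherwise.  Binary mode thresholds at `w > 0`.
#'
#' @param conn square nonnegative matrix with zero diagonal (one band slice
#'   of an `nf_connectivity`), or an `nf_connectivity` plus `band`.
#' @param mode `"weighted"` or `"binary"`.
#' @param band band name when `conn` is an `nf_connectivity`.
#' @param normalize divide weights by the maximum (weighted mode).
#' @return An `nf_graph`: `adj`, `dist`, `mode`, `labels`.
#' @export
to_graph <- function(conn, mode = c("weighted", "binary"), band = NULL,
                     normalize = TRUE) {
  mode <- match.arg(mode)
  if (inherits(conn, "nf_connectivity")) {
    stopifnot(!is.null(band))
    W <- conn$matrices[[band]]
  } else W <- as.matrix(conn)
  if (nrow(W) != ncol(W)) stop("connectivity matrix must be square")
  if (any(W < 0)) stop("negative connectivity weights")
  if (any(diag(W) != 0)) stop("diagonal must be zero")
  A <- (W + t(W)) / 2
  if (mode == "binary") {
    A <- (A > 0) * 1
  } else if (normalize && max(A) > 0) {
    A <- A / max(A)
  }
  D <- ifelse(A > 0, 1 / A, Inf)
  diag(D) <- 0
  labels <- rownames(W) %||% paste0("n", seq_len(nrow(W)))
  structure(list(adj = A, dist = D, mode = mode, labels = labels),
            class = "nf_graph")
}

graph_shortest_paths <- function(g) {
  # Dijkstra all-pairs on the 1/w distance matrix via igraph
  A <- g$adj
  ig <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected",
                                            diag = FALSE)
  el <- igraph::as_edgelist(ig, names = FALSE)   # weights aligned to edges
  w <- 1 / A[el]
  igraph::distances(ig, weights = w, algorithm = "dijkstra")
}

#' Clustering coefficient
#'
#' Binary: node value `2 e_i / (k_i (k_i - 1))` (0 for degree < 2); weighted:
#' geometric-mean triangle intensity (Onnela) on max-normalized weights.
#' The global value is the node mean.
#'
#' @param g an [to_graph()] result with >= 3 nodes.
#' @return `list(global, nodal)`.
#' @export
clustering_coefficient <- function(g) {
  A <- g$adj
  N <- nrow(A)
  if (N < 3) stop("need >= 3 nodes")
  k <- rowSums(A > 0)
  if (g$mode == "binary") {
    B <- (A > 0) * 1
    t_i <- diag(B %*% B %*% B) / 2
    nodal <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  } else {
    Wc <- A^(1 / 3)
    t_i <- diag(Wc %*% Wc %*% Wc) / 2
    nodal <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  }
  list(global = mean(nodal), nodal = setNames(nodal, g$labels))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered pairs with finite distance
#' (Dijkstra on `d = 1/w`); the number of unreachable pairs is reported.
#'
#' @param g an [to_graph()] result with >= 2 nodes.
#' @return `list(global, nodal, n_unreachable)`; `global` is `NA` (flagged)
#'   when no finite pair exists; `nodal` is each node's mean finite distance
#'   to the others.
#' @export
characteristic_path_length <- function(g) {
  D <- graph_shortest_paths(g)
  off <- !diag(nrow(D))
  finite <- is.finite(D) & off
  n_unreach <- sum(off & !is.finite(D))
  global <- if (any(finite)) mean(D[finite]) else NA_real_
  nodal <- vapply(seq_len(nrow(D)), function(i) {
    di <- D[i, -i]
    if (any(is.finite(di))) mean(di[is.finite(di)]) else NA_real_
  }, numeric(1))
  list(global = global, nodal = setNames(nodal, g$labels),
       n_unreachable = n_unreach)
}

#' Global efficiency
#'
#' Mean over ordered pairs of `1/d_ij` with `1/Inf = 0`; nodal efficiency is
#' the row mean.
#'
#' @param g an [to_graph()] result with >= 2 nodes.
#' @return `list(global, nodal)`.
#' @export
global_efficiency <- function(g) {
  D <- graph_shortest_paths(g)
  E <- 1 / D
  diag(E) <- 0
  E[!is.finite(E)] <- 0
  N <- nrow(D)
  list(global = sum(E) / (N * (N - 1)),
       nodal = setNames(rowSums(E) / (N - 1), g$labels))
}

#' Local efficiency
#'
#' Node value: the global efficiency of the subgraph induced on the node's
#' neighbors, using paths within that subgraph (0 for degree < 2); the
#' global value is the node mean.
#'
#' @param g an [to_graph()] result with >= 3 nodes.
#' @return `list(global, nodal)`.
#' @export
local_efficiency <- function(g) {
  A <- g$adj
  N <- nrow(A)
  if (N < 3) stop("need >= 3 nodes")
  nodal <- vapply(seq_len(N), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- structure(list(adj = A[nb, nb, drop = FALSE], mode = g$mode,
                          labels = g$labels[nb]), class = "nf_graph")
    global_efficiency(sub)$global
  }, numeric(1))
  list(global = mean(nodal), nodal = setNames(nodal, g$labels))
}

#' All graph metrics for a set of connectivity matrices
#'
#' @param conn_list named list (by subject) of `nf_connectivity` objects.
#' @param mode `"weighted"` or `"binary"`.
#' @return `list(global, nodal)` long data.frames:
#'   (subject, band, metric, value) and
#'   (subject, band, metric, channel, value).  Undefined CPL propagates as
#'   `NA`.
#' @export
metric_table <- function(conn_list, mode = "weighted") {
  glob <- list(); nod <- list()
  for (sub in names(conn_list)) {
    conn <- conn_list[[sub]]
    for (band in names(conn$matrices)) {
      g <- to_graph(conn, mode = mode, band = band)
      res <- list(cc = clustering_coefficient(g),
                  cpl = characteristic_path_length(g),
                  ge = global_efficiency(g),
                  le = local_efficiency(g))
      for (mn in names(res)) {
        glob[[length(glob) + 1]] <- data.frame(
          subject = sub, band = band, metric = mn, value = res[[mn]]$global)
        nod[[length(nod) + 1]] <- data.frame(
          subject = sub, band = band, metric = mn,
          channel = names(res[[mn]]$nodal), value = unname(res[[mn]]$nodal))
      }
    }
  }
  list(global = do.call(rbind, glob), nodal = do.call(rbind, nod))
}
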