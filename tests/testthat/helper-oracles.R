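# Independent brute-force oracles for the topological measures, plus small
# utilities shared across tests. Everything here is deliberately naive
# (path enumeration, power iteration, dense scans) and independent of the
# package's implementation paths.

adjacency_of <- function(g) {
  n <- length(g$atomic_numbers)
  A <- matrix(0, n, n)
  und <- undirected_edges(g)
  if (nrow(und)) { A[und] <- 1; A[und[, 2:1, drop = FALSE]] <- 1 }
  A
}

# all-pairs shortest path distances by BFS on the adjacency matrix
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] > 0)) if (D[s, w] > d) { D[s, w] <- d; nxt <- c(nxt, w) }
      }
      frontier <- unique(nxt)
    }
  }
  D
}

# number of shortest paths between every pair (for betweenness)
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n); diag(S) <- 1
  ord <- order(D)  # fill in increasing distance
  for (idx in ord) {
    i <- (idx - 1) %% n + 1; j <- (idx - 1) %/% n + 1
    if (i == j || !is.finite(D[i, j]) || D[i, j] == 0) next
    # predecessors of j on shortest i->j paths
    pred <- which(A[, j] > 0 & D[i, ] == D[i, j] - 1)
    S[i, j] <- sum(S[i, pred])
  }
  S
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A); S <- oracle_path_counts(A, D)
  b <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (s == v || t == v || !is.finite(D[s, t])) next
    if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
        D[s, v] + D[v, t] == D[s, t]) {
      b[v] <- b[v] + S[s, v] * S[v, t] / S[s, t]
    }
  }
  b
}

oracle_edge_betweenness <- function(A, edges) {
  n <- nrow(A)
  D <- oracle_distances(A); S <- oracle_path_counts(A, D)
  vapply(seq_len(nrow(edges)), function(k) {
    u <- edges[k, 1]; v <- edges[k, 2]
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || !is.finite(D[s, t])) next
      # paths through edge u-v in either orientation
      cnt <- 0
      if (is.finite(D[s, u]) && is.finite(D[v, t]) &&
          D[s, u] + 1 + D[v, t] == D[s, t]) cnt <- cnt + S[s, u] * S[v, t]
      if (is.finite(D[s, v]) && is.finite(D[u, t]) &&
          D[s, v] + 1 + D[u, t] == D[s, t]) cnt <- cnt + S[s, v] * S[u, t]
      tot <- tot + cnt / S[s, t]
    }
    tot
  }, 1.0)
}

oracle_closeness <- function(A) {
  D <- oracle_distances(A)
  vapply(seq_len(nrow(A)), function(v) {
    d <- D[v, -v]; d <- d[is.finite(d)]
    if (!length(d)) NA_real_ else 1 / sum(d)
  }, 1.0)
}

oracle_harmonic <- function(A) {
  D <- oracle_distances(A)
  vapply(seq_len(nrow(A)), function(v) {
    d <- D[v, -v]
    sum(1 / d[is.finite(d) & d > 0])
  }, 1.0)
}

oracle_eccentricity <- function(A) {
  D <- oracle_distances(A)
  apply(D, 1, function(d) max(d[is.finite(d)]))
}

oracle_eigenvector <- function(A, iters = 100000, tol = 1e-15) {
  # shifted power iteration (A + I keeps the spectrum positive, so the
  # iteration converges on bipartite graphs too; eigenvectors are unchanged)
  M <- A + diag(nrow(A))
  x <- rep(1, nrow(A))
  for (i in seq_len(iters)) {
    y <- M %*% x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) break
    x <- as.numeric(y)
  }
  x / max(x)
}

oracle_pagerank <- function(A, d = 0.85, iters = 20000, tol = 1e-14) {
  n <- nrow(A)
  deg <- rowSums(A)
  p <- rep(1 / n, n)
  for (i in seq_len(iters)) {
    contrib <- numeric(n)
    for (v in seq_len(n)) {
      if (deg[v] > 0) contrib <- contrib + p[v] * A[v, ] / deg[v]
      else contrib <- contrib + p[v] / n   # dangling: uniform
    }
    p2 <- (1 - d) / n + d * contrib
    if (max(abs(p2 - p)) < tol) { p <- p2; break }
    p <- p2
  }
  p
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, 1.0)
}

oracle_kcore <- function(A) {
  n <- nrow(A)
  alive <- rep(TRUE, n)
  core <- integer(n)
  k <- 0
  while (any(alive)) {
    repeat {
      degs <- rowSums(A[, alive, drop = FALSE])
      victims <- which(alive & degs <= k)
      if (!length(victims)) break
      core[victims] <- k
      alive[victims] <- FALSE
    }
    k <- k + 1
  }
  core
}

# random connected graph on n nodes (spanning tree + extra edges)
random_connected_graph <- function(n, extra = n) {
  ei <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), 1L))
  all_pairs <- t(combn(n, 2))
  key <- paste(pmin(ei[, 1], ei[, 2]), pmax(ei[, 1], ei[, 2]))
  cand <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% key, , drop = FALSE]
  if (nrow(cand) && extra > 0) {
    take <- sample.int(nrow(cand), min(extra, nrow(cand)))
    ei <- rbind(ei, cand[take, , drop = FALSE])
  }
  atom_graph(rep(6L, n), edge_index = ei, graph_id = "rnd")
}

# exhaustive list of connected graphs on n labeled nodes (small n only)
all_connected_graphs <- function(n) {
  pairs <- t(combn(n, 2))
  m <- nrow(pairs)
  out <- list()
  for (code in seq_len(2^m - 1)) {
    sel <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1)))
    ei <- pairs[sel, , drop = FALSE]
    g <- atom_graph(rep(6L, n), edge_index = ei, graph_id = paste0("e", code))
    A <- adjacency_of(g)
    if (all(is.finite(oracle_distances(A)))) out[[length(out) + 1]] <- g
  }
  out
}

random_rigid_motion <- function() {
  M <- matrix(stats::rnorm(9), 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 5))
}

apply_motion <- function(coords, mo) {
  sweep(coords %*% t(mo$R), 2, -mo$t, "-")
}

# central finite-difference gradient of f wrt params[[name]][i, j]
fd_grad <- function(f, params, name, i, j, eps = 1e-6) {
  p1 <- params; p1[[name]][i, j] <- p1[[name]][i, j] + eps
  p2 <- params; p2[[name]][i, j] <- p2[[name]][i, j] - eps
  (f(p1) - f(p2)) / (2 * eps)
}

# small prepared synthetic dataset shared by model-level tests
make_test_prep <- function(n_graphs = 24, target = "local", seed = 7,
                           atoms = c(6, 10), tasks = NULL, noise_sd = 0) {
  spec <- gen_spec(n_graphs = n_graphs, atoms_range = atoms, target = target,
                   seed = seed, noise_sd = noise_sd)
  graphs <- gen_dataset(spec)
  if (is.null(tasks)) {
    type <- if (target == "motif_class") "multiclass"
            else if (target == "multilabel") "multilabel" else "regression"
    level <- if (target == "node_charge") "node" else "graph"
    n_out <- if (target == "motif_class") 4 else if (target == "multilabel") 4 else 1
    tasks <- list(task_spec(target, level = level, type = type, n_out = n_out))
  }
  prepare_dataset(graphs, tasks, d_l = 2, r_c = 2.0, seed = seed)
}
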