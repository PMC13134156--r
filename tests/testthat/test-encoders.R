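k3 <- atom_graph(c(6, 6, 6), edge_index = rbind(c(1, 2), c(1, 3), c(2, 3)))
p3 <- atom_graph(c(6, 6, 6), edge_index = rbind(c(1, 2), c(2, 3)))

test_that("chemical descriptors are a 15-column deterministic lookup", {
  m <- chemical_descriptors(c(6, 6))
  expect_equal(dim(m), c(2, 15))
  expect_identical(m[1, ], m[2, ])
  # spot values from the embedded table
  expect_equal(unname(m[1, "en_pauling"]), 2.55)
  expect_equal(unname(chemical_descriptors(8)[1, "period"]), 2)
  expect_equal(unname(chemical_descriptors(1)[1, "valence_electrons"]), 1)
  expect_error(chemical_descriptors(90), "90")
  expect_error(chemical_descriptors(0), "outside")
})

test_that("element table covers Z = 1..86 with NA markers for missing values", {
  tab <- element_table()
  expect_equal(tab$z, 1:86)
  expect_true(is.na(tab$electron_affinity[tab$symbol == "Ne"]))
  # light main-group elements are complete (generator palette depends on it)
  pal <- chemical_descriptors(c(1, 6, 7, 8))
  expect_true(all(is.finite(pal)))
})

test_that("node topological encodings match closed forms on tiny graphs", {
  m <- node_topological_encodings(k3)
  expect_equal(dim(m), c(3, 9))
  expect_equal(unname(m[, "clustering"]), rep(1, 3))
  expect_equal(unname(m[, "degree"]), rep(2, 3))
  mp <- node_topological_encodings(p3)
  expect_equal(unname(mp[, "degree"]), c(1, 2, 1))
  expect_equal(unname(mp[, "eccentricity"]), c(2, 1, 2))
  expect_equal(unname(mp[, "kcore"]), rep(1, 3))
  iso <- node_topological_encodings(atom_graph(6))
  expect_equal(unname(iso[1, "clustering"]), 0)
  expect_equal(unname(iso[1, "degree"]), 0)
  expect_equal(unname(iso[1, "pagerank"]), 1)
})

test_that("edge topological encodings match closed forms on K3 and a single edge", {
  m <- edge_topological_encodings(k3, directed_rows = FALSE)
  expect_equal(dim(m), c(3, 4))
  expect_equal(unname(m[, "jaccard"]), rep(1 / 3, 3))
  expect_equal(unname(m[, "pref_attachment"]), rep(4, 3))
  expect_equal(unname(m[, "adamic_adar"]), rep(1 / log(2), 3))
  single <- atom_graph(c(6, 6), edge_index = rbind(c(1, 2)))
  ms <- edge_topological_encodings(single, directed_rows = FALSE)
  expect_equal(unname(ms[1, "jaccard"]), 0)
  expect_equal(unname(ms[1, "pref_attachment"]), 1)
  # directed rows mirror the undirected values
  md <- edge_topological_encodings(k3)
  expect_equal(nrow(md), 6)
  expect_equal(md[1:3, ], md[4:6, ])
})

test_that("all nine node and four edge measures match brute-force oracles", {
  set.seed(101)
  graphs <- c(all_connected_graphs(4),
              all_connected_graphs(5)[sample.int(728, 120)],
              lapply(1:25, function(i) random_connected_graph(sample(6:8, 1))))
  for (g in graphs) {
    A <- adjacency_of(g)
    m <- node_topological_encodings(g)
    expect_equal(unname(m[, "degree"]), rowSums(A))
    expect_equal(unname(m[, "closeness"]), oracle_closeness(A), tolerance = 1e-10)
    expect_equal(unname(m[, "betweenness"]), oracle_betweenness(A), tolerance = 1e-9)
    expect_equal(unname(m[, "eigenvector"]), oracle_eigenvector(A), tolerance = 1e-6)
    expect_equal(unname(m[, "pagerank"]), oracle_pagerank(A), tolerance = 1e-9)
    expect_equal(unname(m[, "clustering"]), oracle_clustering(A), tolerance = 1e-10)
    expect_equal(unname(m[, "kcore"]), oracle_kcore(A))
    expect_equal(unname(m[, "harmonic"]), oracle_harmonic(A), tolerance = 1e-10)
    expect_equal(unname(m[, "eccentricity"]), oracle_eccentricity(A))
    und <- undirected_edges(g)
    e <- edge_topological_encodings(g, directed_rows = FALSE)
    expect_equal(unname(e[, "edge_betweenness"]), oracle_edge_betweenness(A, und),
                 tolerance = 1e-9)
    deg <- rowSums(A)
    for (i in seq_len(nrow(und))) {
      u <- und[i, 1]; v <- und[i, 2]
      nu <- which(A[u, ] > 0); nv <- which(A[v, ] > 0)
      common <- intersect(nu, nv)
      expect_equal(unname(e[i, "jaccard"]),
                   length(common) / length(union(nu, nv)))
      expect_equal(unname(e[i, "adamic_adar"]),
                   if (length(common)) sum(1 / log(deg[common])) else 0)
      expect_equal(unname(e[i, "pref_attachment"]), deg[u] * deg[v])
    }
  }
})

test_that("Laplacian PE returns orthonormal nonzero eigenpairs, P3 spectrum {0,1,3}", {
  V <- laplacian_pe(p3, 2)
  lam <- attr(V, "eigenvalues")
  expect_equal(lam, c(1, 3), tolerance = 1e-10)
  A <- adjacency_of(p3)
  L <- diag(rowSums(A)) - A
  for (j in 1:2) {
    expect_lt(max(abs(L %*% V[, j] - lam[j] * V[, j])), 1e-8)
    # Rayleigh quotient matches the reported eigenvalue
    expect_equal(as.numeric(t(V[, j]) %*% L %*% V[, j]), lam[j],
                 tolerance = 1e-8)
  }
  expect_equal(crossprod(V), diag(2), tolerance = 1e-8)
  # K2 has spectrum {0, 2}: only one nonzero eigenpair
  k2 <- atom_graph(c(6, 6), edge_index = rbind(c(1, 2)))
  expect_identical(laplacian_pe(k2, 2), "insufficient")
  expect_equal(attr(laplacian_pe(k2, 1), "eigenvalues"), 2, tolerance = 1e-10)
})

test_that("LPE sign fixing is deterministic and columns orthonormal on random graphs", {
  set.seed(77)
  for (i in 1:10) {
    g <- random_connected_graph(sample(5:9, 1))
    V1 <- laplacian_pe(g, 3)
    V2 <- laplacian_pe(g, 3)
    expect_identical(V1, V2)
    expect_equal(crossprod(V1), diag(3), tolerance = 1e-8)
    expect_true(all(apply(V1, 2, function(v) v[which.max(abs(v))] > 0)))
  }
})

test_that("near-zero Laplacian eigenvalue count equals component count", {
  set.seed(31)
  for (i in 1:8) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    g1 <- random_connected_graph(n1); g2 <- random_connected_graph(n2)
    ei <- rbind(undirected_edges(g1), undirected_edges(g2) + n1)
    g <- atom_graph(rep(6, n1 + n2), edge_index = ei)
    A <- adjacency_of(g)
    L <- diag(rowSums(A)) - A
    lam <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(lam) < 1e-8 * max(lam)), 2)
  }
})

test_that("standardizer gives zero mean / unit variance and flags constants", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  st <- fit_standardizer(x)
  expect_true(st$constant[["b"]])
  z <- apply_standardizer(x, st)
  expect_equal(mean(z[, 1]), 0, tolerance = 1e-6)
  expect_equal(stats::var(z[, 1]), 1, tolerance = 1e-6)
  expect_equal(z[, 2], rep(0, 3), ignore_attr = TRUE)
  # train-fitted stats applied to shifted data preserve the shift (no refit)
  val <- cbind(a = c(11, 12, 13), b = c(5, 5, 5))
  zv <- apply_standardizer(val, st)
  expect_equal(mean(zv[, 1]), 10, tolerance = 1e-6)
  expect_error(fit_standardizer(x[0, , drop = FALSE]), "empty")
})

test_that("filter_invalid discards insufficient-LPE and non-finite-CE graphs", {
  set.seed(15)
  good <- lapply(1:9, function(i) random_connected_graph(6))
  k2 <- atom_graph(c(6, 6), edge_index = rbind(c(1, 2)), graph_id = "k2")
  out <- filter_invalid(c(good, list(k2)), d_l = 2)
  expect_length(out$graphs, 9)
  expect_equal(out$discard_log$reason, "insufficient LPE")
  expect_equal(out$discard_log$id, "k2")
  # helium has no tabulated electron affinity -> non-finite CE
  he <- atom_graph(c(2, 2, 2), edge_index = rbind(c(1, 2), c(2, 3), c(1, 3)),
                   graph_id = "he3")
  out2 <- filter_invalid(c(good[1:3], list(he)), d_l = 2)
  expect_length(out2$graphs, 3)
  expect_equal(out2$discard_log$reason, "non-finite CE")
  # all-finite batch is the identity
  out3 <- filter_invalid(good, d_l = 2)
  expect_length(out3$graphs, 9)
  expect_equal(nrow(out3$discard_log), 0)
})

test_that("encodings are permutation-equivariant", {
  set.seed(202)
  for (rep in 1:6) {
    g <- random_connected_graph(8)
    perm <- sample(8)
    und <- undirected_edges(g)
    gp <- atom_graph(rep(6L, 8),
                     edge_index = cbind(perm[und[, 1]], perm[und[, 2]]))
    P1 <- node_topological_encodings(g)
    P2 <- node_topological_encodings(gp)
    expect_equal(P2[perm, ], P1, tolerance = 1e-9)
    L1 <- laplacian_pe(g, 2); L2 <- laplacian_pe(gp, 2)
    lam <- attr(L1, "eigenvalues")
    expect_equal(lam, attr(L2, "eigenvalues"), tolerance = 1e-9)
    # eigenvector rows permute (up to sign) when the eigenvalues are simple
    V3 <- laplacian_pe(g, 3)
    gap_next <- if (identical(V3, "insufficient")) Inf else
      attr(V3, "eigenvalues")[3] - lam[2]
    if (min(diff(c(0, lam))) > 1e-6 && gap_next > 1e-6) {
      expect_equal(abs(L2[perm, ]), abs(L1), tolerance = 1e-7,
                   ignore_attr = TRUE)
    }
    # edge encodings re-align under the same node relabeling
    E1 <- edge_topological_encodings(g, directed_rows = FALSE)
    E2 <- edge_topological_encodings(gp, directed_rows = FALSE)
    und2 <- undirected_edges(gp)
    key1 <- paste(pmin(perm[und[, 1]], perm[und[, 2]]),
                  pmax(perm[und[, 1]], perm[und[, 2]]))
    key2 <- paste(und2[, 1], und2[, 2])
    expect_equal(E2[match(key1, key2), ], E1, tolerance = 1e-9)
  }
})
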