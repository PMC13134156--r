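test_that("mpnn layer: empty neighborhoods, hand-computed messages, attention normalization", {
  H <- rbind(c(1, 2), c(3, 4))
  # no edges: zero aggregate transformed by the update alone
  out <- mpnn_layer(H, matrix(integer(0), 0, 2), aggregator = "sum",
                    update = function(agg, h) agg + h)
  expect_equal(out, H)
  # 2-node path, phi = identity, update returns the aggregate:
  # each node receives exactly the other's row
  ei <- rbind(c(1, 2), c(2, 1))
  out <- mpnn_layer(H, ei, aggregator = "sum")
  expect_equal(out, H[c(2, 1), ])
  # neighbor-attention weights over each neighborhood sum to 1
  set.seed(8)
  g <- random_connected_graph(7)
  Hg <- matrix(rnorm(7 * 3), 7, 3)
  ei <- g$edge_index
  rcv <- ei[, 1]
  s <- rowSums(cbind(Hg[rcv, ], Hg[ei[, 2], ]))
  w <- exp(s - ave(s, rcv, FUN = max))
  w <- w / ave(w, rcv, FUN = sum)
  expect_equal(as.numeric(tapply(w, rcv, sum)), rep(1, 7), tolerance = 1e-12)
  # mean aggregator averages neighbor rows
  out <- mpnn_layer(Hg, ei, aggregator = "mean")
  v <- which(ei[, 1] == 1)
  expect_equal(out[1, ], colMeans(Hg[ei[v, 2], , drop = FALSE]))
})

test_that("geometric features: right angles, collinearity, rigid-motion invariance", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  ei <- rbind(c(1, 2), c(1, 3), c(2, 1), c(3, 1))
  geom <- geometric_features(coords, ei)
  expect_equal(geom$r, c(1, 1, 1, 1))
  # the two angles at node 1 are both pi/2
  ang1 <- geom$theta[geom$theta_edge %in% c(1, 2)]
  expect_equal(ang1, rep(pi / 2, 2))
  # collinear neighbors give 0 or pi
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0))
  eic <- rbind(c(1, 2), c(1, 3), c(2, 1), c(3, 1))
  gc <- geometric_features(col, eic)
  expect_equal(sort(unique(round(gc$theta[gc$theta_edge %in% 1:2], 10))), pi)
  set.seed(12)
  for (i in 1:20) {
    mo <- random_rigid_motion()
    g2 <- geometric_features(apply_motion(coords, mo), ei)
    expect_equal(g2$r, geom$r, tolerance = 1e-9)
    expect_equal(g2$theta, geom$theta, tolerance = 1e-9)
  }
  expect_error(geometric_features(rbind(c(0, 0, 0), c(0, 0, 0)),
                                  rbind(c(1, 2))), "coincident")
  expect_error(geometric_features(NULL, ei), "2D path")
})

test_that("geometric edge embedding: empty angular sums, linearity in the angular term", {
  set.seed(13)
  W_r <- matrix(rnorm(16 * 4), 16, 4)
  W_a <- matrix(rnorm(8 * 4), 8, 4)
  # degree-1 receiver: embedding is the radial term exactly
  coords <- rbind(c(0, 0, 0), c(1.3, 0, 0))
  ei <- rbind(c(1, 2), c(2, 1))
  geom <- geometric_features(coords, ei)
  e <- geometric_edge_embedding(geom, W_r, W_a, r_c = 2)
  expect_equal(e, rbf_expand(geom$r, 2, 16) %*% W_r)
  # zeroed angular weights: depends on r only
  coords3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  ei3 <- rbind(c(1, 2), c(1, 3), c(2, 1), c(3, 1))
  g3 <- geometric_features(coords3, ei3)
  e0 <- geometric_edge_embedding(g3, W_r, W_a * 0, r_c = 2)
  expect_equal(e0, rbf_expand(g3$r, 2, 16) %*% W_r)
  # doubling the neighbors at the same angle doubles the angular term
  e1 <- geometric_edge_embedding(g3, W_r * 0, W_a, r_c = 2)
  coords4 <- rbind(coords3, c(0, -1, 0))  # second neighbor of 1 at 90 deg to edge (1,2)
  ei4 <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 1), c(3, 1), c(4, 1))
  g4 <- geometric_features(coords4, ei4)
  e2 <- geometric_edge_embedding(g4, W_r * 0, W_a, r_c = 2)
  expect_equal(e2[1, ], 2 * e1[1, ], tolerance = 1e-10)
})

test_that("multi-head attention is row-stochastic within graphs and blocks across them", {
  set.seed(14)
  d <- 8; B <- 2
  W_Q <- matrix(rnorm(d * d), d); W_K <- matrix(rnorm(d * d), d)
  W_V <- matrix(rnorm(d * d), d); W_O <- matrix(rnorm(d * d), d)
  # single node: weight 1 on itself, output = v W_O on that row
  H1 <- matrix(rnorm(d), 1, d)
  out1 <- multi_head_attention(H1, 1L, W_Q, W_K, W_V, W_O, B)
  expect_equal(out1$attn[[1]][1, 1], 1)
  expect_equal(out1$H, (H1 %*% W_V) %*% W_O)
  # identical rows: uniform attention 1/N
  H <- matrix(rep(rnorm(d), each = 4), 4, d)
  outu <- multi_head_attention(H, rep(1L, 4), W_Q, W_K, W_V, W_O, B)
  for (b in 1:B) expect_equal(outu$attn[[b]],
                              matrix(1 / 4, 4, 4), tolerance = 1e-12)
  # two graphs in a batch: zero mass across the boundary, rows sum to 1
  Hb <- matrix(rnorm(6 * d), 6, d)
  mem <- c(1L, 1L, 1L, 2L, 2L, 2L)
  outb <- multi_head_attention(Hb, mem, W_Q, W_K, W_V, W_O, B)
  for (b in 1:B) {
    P <- outb$attn[[b]]
    expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-6)
    expect_true(all(P >= 0))
    expect_equal(P[1:3, 4:6], matrix(0, 3, 3))
    expect_equal(P[4:6, 1:3], matrix(0, 3, 3))
  }
  expect_error(multi_head_attention(Hb, mem, W_Q, W_K, W_V, W_O, 3),
               "divide")
})

test_that("gps layer fuses branches additively with the documented degenerate limits", {
  set.seed(15)
  X <- matrix(rnorm(12), 4, 3)
  mlp <- function(x) tanh(x %*% diag(3) + 0.5)
  mp <- function(X, E, ei) list(X = X * 2, E = E)
  at0 <- function(X) X * 0
  atY <- function(X) X * 2
  ei <- rbind(c(1, 2), c(2, 1))
  # attention zeroed: pure-local limit
  expect_equal(gps_layer(X, NULL, ei, mp, at0, mlp)$X, mlp(2 * X))
  # mpnn zeroed: pure-global limit
  mp0 <- function(X, E, ei) list(X = X * 0, E = E)
  expect_equal(gps_layer(X, NULL, ei, mp0, atY, mlp)$X, mlp(2 * X))
  # both branches equal Y: MLP(2Y)
  expect_equal(gps_layer(X, NULL, ei, mp, atY, mlp)$X, mlp(4 * X))
  bad <- function(X) X[, 1, drop = FALSE]
  expect_error(gps_layer(X, NULL, ei, mp, bad, mlp), "width mismatch")
})

test_that("pooling reduces permutation-invariantly in every mode", {
  set.seed(16)
  H <- matrix(rnorm(15), 5, 3)
  one <- matrix(rnorm(3), 1, 3)
  for (mode in c("min", "max", "sum", "mean")) {
    expect_equal(pool(one, 1L, mode), one)
    perm <- sample(5)
    expect_equal(pool(H[perm, ], rep(1L, 5), mode), pool(H, rep(1L, 5), mode))
  }
  expect_equal(pool(rbind(H[1, ], H[1, ]), c(1L, 1L), "sum"),
               matrix(2 * H[1, ], 1))
  mem <- c(1L, 1L, 2L, 2L, 2L)
  ps <- pool(H, mem, "mean")
  expect_equal(ps[2, ], colMeans(H[3:5, ]))
  expect_error(pool(H[0, , drop = FALSE]), "empty")
})

test_that("assembled layers are permutation-equivariant and pooled outputs invariant", {
  prep <- make_test_prep(n_graphs = 8, target = "local", seed = 31)
  cfg <- model_config(scheme = "S4", mpnn_type = "edgecond-sum",
                      num_conv_layers = 1, hidden_dim = 8, edge_embed_dim = 4,
                      global_attn_heads = 2, has_pos = TRUE, lpe_dim = 2,
                      r_c = 2.0)
  set.seed(3)
  m <- assemble(cfg, prep$meta)
  fwd <- getFromNamespace("model_forward", "molgps")
  i <- prep$split$train[1]
  b <- make_batch(prep, i, cfg)
  fw <- fwd(m, b)
  h <- getFromNamespace("ag_value", "molgps")(fw$tape, fw$h)
  set.seed(4)
  perm <- sample(b$n_nodes)      # row r of the permuted batch is old node perm[r]
  pos <- integer(b$n_nodes); pos[perm] <- seq_len(b$n_nodes)
  bp <- b
  bp$X <- b$X[perm, , drop = FALSE]
  bp$Znode <- b$Znode[perm, , drop = FALSE]
  bp$edge_index <- cbind(pos[b$edge_index[, 1]], pos[b$edge_index[, 2]])
  fwp <- fwd(m, bp)
  hp <- getFromNamespace("ag_value", "molgps")(fwp$tape, fwp$h)
  expect_equal(hp, h[perm, ], tolerance = 1e-9)
  expect_equal(fwp$preds[[1]], fw$preds[[1]], tolerance = 1e-9)
})

test_that("receptive field: K-layer MPNN is blind beyond K hops, 1-layer GPS is not", {
  # 12-node path graph
  n <- 12
  ei <- cbind(1:(n - 1), 2:n)
  coords <- cbind(seq(0, by = 1.4, length.out = n), 0, 0)
  g <- atom_graph(rep(6L, n), coords = coords, edge_index = ei,
                  targets = list(y = 1))
  graphs <- c(list(g), lapply(1:5, function(i) {
    gi <- g; gi$graph_id <- paste0("f", i); gi
  }))
  tasks <- list(task_spec("y"))
  prep <- prepare_dataset(graphs, tasks, d_l = 2, r_c = 2.0,
                          split = list(train = 1:4, val = 5L, test = 6L))
  fwd <- getFromNamespace("model_forward", "molgps")
  val <- getFromNamespace("ag_value", "molgps")
  probe <- function(cfg, K) {
    set.seed(9)
    m <- assemble(cfg, prep$meta)
    b <- make_batch(prep, 1L, cfg)
    h0 <- val(fwd(m, b)$tape, fwd(m, b)$h)
    # perturb the raw features of node 12 (far end of the path)
    b2 <- b
    b2$X[n, ] <- b2$X[n, ] + 10
    if (!is.null(b2$Znode)) b2$Znode[n, 1] <- b2$Znode[n, 1] + 10
    h1 <- val(fwd(m, b2)$tape, fwd(m, b2)$h)
    abs(h1[1, ] - h0[1, ])  # effect at node 1, distance 11 > K
  }
  cfg_mpnn <- model_config(scheme = "S1", mpnn_type = "edgecond-sum",
                           num_conv_layers = 3, hidden_dim = 6,
                           has_pos = TRUE, lpe_dim = 2, r_c = 2.0)
  expect_equal(max(probe(cfg_mpnn, 3)), 0)
  cfg_gps <- model_config(scheme = "S3", mpnn_type = "edgecond-sum",
                          num_conv_layers = 1, hidden_dim = 8,
                          edge_embed_dim = 4, global_attn_heads = 2,
                          has_pos = TRUE, lpe_dim = 2, r_c = 2.0)
  expect_gt(max(probe(cfg_gps, 1)), 1e-8)
})

test_that("gps with zeroed attention value/output weights equals the MPNN+MLP composition", {
  prep <- make_test_prep(n_graphs = 8, target = "local", seed = 41)
  cfg <- model_config(scheme = "S3", mpnn_type = "edgecond-sum",
                      num_conv_layers = 2, hidden_dim = 6, edge_embed_dim = 3,
                      global_attn_heads = 2, has_pos = TRUE, lpe_dim = 2,
                      r_c = 2.0)
  set.seed(6)
  m <- assemble(cfg, prep$meta)
  for (k in 1:2) {
    m$params[[sprintf("L%d.W_V", k)]][] <- 0
    m$params[[sprintf("L%d.W_O", k)]][] <- 0
  }
  b <- make_batch(prep, prep$split$train[1:2], cfg)
  fwd <- getFromNamespace("model_forward", "molgps")
  val <- getFromNamespace("ag_value", "molgps")
  fw <- fwd(m, b)
  h_gps <- val(fw$tape, fw$h)
  # manual MPNN + MLP composition with the same parameters (matrix algebra)
  relu <- function(x) pmax(x, 0)
  H <- b$Znode %*% m$params$W_node
  E <- b$Zedge %*% m$params$W_edge
  for (k in 1:2) {
    pre <- sprintf("L%d.", k)
    msg <- (H %*% m$params[[paste0(pre, "W_phi")]])[b$edge_index[, 2], ] +
      E %*% m$params[[paste0(pre, "W_e")]]
    agg <- rowsum(msg, b$edge_index[, 1])
    full <- matrix(0, nrow(H), ncol(msg)); full[as.integer(rownames(agg)), ] <- agg
    Hm <- relu(sweep(cbind(H, full) %*% m$params[[paste0(pre, "W_u")]], 2,
                     as.numeric(m$params[[paste0(pre, "b_u")]]), "+"))
    hid <- relu(sweep(Hm %*% m$params[[paste0(pre, "mlp.W1")]], 2,
                      as.numeric(m$params[[paste0(pre, "mlp.b1")]]), "+"))
    H <- sweep(hid %*% m$params[[paste0(pre, "mlp.W2")]], 2,
               as.numeric(m$params[[paste0(pre, "mlp.b2")]]), "+")
  }
  expect_identical(h_gps, H)
})

test_that("geometric-path predictions are invariant under rigid motions", {
  spec <- gen_spec(n_graphs = 8, atoms_range = c(6, 9), target = "local",
                   seed = 51)
  graphs <- gen_dataset(spec)
  tasks <- list(task_spec("local"))
  prep <- prepare_dataset(graphs, tasks, d_l = 2, r_c = 2.0, seed = 5)
  cfg <- model_config(scheme = "S1", mpnn_type = "geometric-mpnn",
                      num_conv_layers = 2, hidden_dim = 6,
                      has_pos = TRUE, lpe_dim = 2, r_c = 2.0)
  set.seed(7)
  m <- assemble(cfg, prep$meta)
  base <- predict_batch(m, make_batch(prep, 1:3, cfg))$preds[[1]]
  set.seed(8)
  for (i in 1:20) {
    mo <- random_rigid_motion()
    graphs2 <- lapply(graphs, function(g) {
      g$coords <- apply_motion(g$coords, mo); g
    })
    prep2 <- prepare_dataset(graphs2, tasks, d_l = 2, r_c = 2.0, seed = 5)
    got <- predict_batch(m, make_batch(prep2, 1:3, cfg))$preds[[1]]
    expect_equal(got, base, tolerance = 1e-5)
  }
})
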