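# Learnable building blocks: generic MPNN layer, geometric features and the
# geometric MPNN layer, within-graph multi-head global attention, the GPS
# fusion layer, and pooling. Each block has a plain-matrix functional form
# (exported, used directly and in tests) and a tape form (ag_*_fwd, used by
# assembled models for training).

# ---- generic MPNN ----------------------------------------------------------

segment_reduce <- function(x, groups, ngroups, mode) {
  out <- matrix(0, ngroups, ncol(x))
  if (nrow(x) == 0) return(out)
  if (mode == "sum" || mode == "mean") {
    s <- rowsum(x, group = groups)
    out[as.integer(rownames(s)), ] <- s
    if (mode == "mean") {
      cnt <- tabulate(groups, nbins = ngroups)
      out <- out / pmax(cnt, 1)
    }
  } else {
    f <- if (mode == "max") max else min
    for (k in unique(groups)) out[k, ] <- apply(x[groups == k, , drop = FALSE], 2, f)
  }
  out
}

#' Generic message-passing layer
#'
#' One MPNN layer: messages \code{phi(h_v)} (optionally edge-conditioned) are
#' aggregated over each node's neighborhood and combined with the previous
#' state by the update function \code{update(agg, h)}. Edge row \code{i} of
#' \code{edge_index} carries a message \code{receiver <- source} with the
#' receiver in column 1. Isolated nodes receive a zero aggregate.
#'
#' @param H N x d node state.
#' @param edge_index directed edge matrix (receiver, source), both directions
#'   of each undirected edge present.
#' @param E optional per-edge feature matrix (rows aligned with
#'   \code{edge_index}); added to messages through \code{edge_map}.
#' @param aggregator one of \code{"sum"}, \code{"mean"}, \code{"max"},
#'   \code{"attention"} (softmax-normalized neighbor attention).
#' @param phi message transform, a function of the source rows (default
#'   identity).
#' @param update node update \code{function(agg, h)} (default returns the
#'   aggregate).
#' @param edge_map function of \code{E} rows added to messages (default 0).
#' @param att_score for \code{aggregator = "attention"}: function of the
#'   matrix \code{[h_receiver || h_source]} returning one score per edge.
#' @return updated node state H'.
#' @export
mpnn_layer <- function(H, edge_index, E = NULL,
                       aggregator = c("sum", "mean", "max", "attention"),
                       phi = identity, update = function(agg, h) agg,
                       edge_map = NULL, att_score = NULL) {
  aggregator <- match.arg(aggregator)
  n <- nrow(H)
  if (nrow(edge_index) == 0) {
    agg <- matrix(0, n, ncol(phi(H)))
    return(update(agg, H))
  }
  rcv <- edge_index[, 1]; src <- edge_index[, 2]
  msg <- phi(H)[src, , drop = FALSE]
  if (!is.null(E) && !is.null(edge_map)) {
    em <- edge_map(E)
    if (ncol(em) != ncol(msg)) stop("edge map width mismatch")
    msg <- msg + em
  }
  if (aggregator == "attention") {
    if (is.null(att_score))
      att_score <- function(hh) rowSums(hh)  # default additive score
    s <- att_score(cbind(H[rcv, , drop = FALSE], H[src, , drop = FALSE]))
    s <- s - ave(s, rcv, FUN = max)
    w <- exp(s) / ave(exp(s), rcv, FUN = sum)
    agg <- segment_reduce(msg * w, rcv, n, "sum")
  } else {
    agg <- segment_reduce(msg, rcv, n, aggregator)
  }
  update(agg, H)
}

# ---- geometric features ----------------------------------------------------

#' Interatomic distances and bond angles
#'
#' For each directed edge \code{(u, v)} (receiver u in column 1), the
#' Euclidean distance \code{r_uv} and the angles at u between \code{r_v - r_u}
#' and \code{r_w - r_u} for every other neighbor w of u. Both quantities are
#' invariant under rigid motions of the coordinates.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param edge_index directed edge matrix.
#' @return list with \code{r} (distance per edge row), \code{theta} (angle
#'   vector, radians in \code{[0, pi]}), and \code{theta_edge} (edge row each
#'   angle belongs to).
#' @export
geometric_features <- function(coords, edge_index) {
  if (is.null(coords)) stop("geometric features require coordinates; use the 2D path for graphs without them")
  m <- nrow(edge_index)
  diff <- coords[edge_index[, 2], , drop = FALSE] -
    coords[edge_index[, 1], , drop = FALSE]
  r <- sqrt(rowSums(diff^2))
  if (any(r == 0)) stop("coincident atoms on an edge make the graph invalid")
  # neighbors of each receiver
  nbrs <- split(seq_len(m), edge_index[, 1])
  theta <- numeric(0); theta_edge <- integer(0)
  for (rows in nbrs) {
    if (length(rows) < 2) next
    for (i in rows) {
      others <- setdiff(rows, i)
      a <- diff[i, ] / r[i]
      cosang <- (diff[others, , drop = FALSE] %*% a) / r[others]
      theta <- c(theta, acos(pmin(1, pmax(-1, cosang))))
      theta_edge <- c(theta_edge, rep(i, length(others)))
    }
  }
  list(r = r, theta = theta, theta_edge = theta_edge, n_edges = m)
}

#' Radial basis expansion of distances
#'
#' Gaussian RBF grid: centers uniform on \code{[0, r_c]}, width equal to the
#' spacing.
#' @param r distance vector.
#' @param r_c radius cutoff.
#' @param n_rbf number of Gaussians.
#' @return |r| x n_rbf matrix.
#' @export
rbf_expand <- function(r, r_c = 5.0, n_rbf = 16) {
  centers <- seq(0, r_c, length.out = n_rbf)
  width <- centers[2] - centers[1]
  exp(-((outer(r, centers, "-")) / width)^2)
}

#' Cosine basis expansion of angles
#'
#' Features \code{cos(n * theta)} for \code{n = 0..n_cos - 1}.
#' @param theta angle vector (radians).
#' @param n_cos number of harmonics.
#' @return |theta| x n_cos matrix.
#' @export
cos_expand <- function(theta, n_cos = 8) {
  outer(theta, seq_len(n_cos) - 1, function(t, n) cos(n * t))
}

#' Geometric edge embedding
#'
#' \code{e_uv = phi_l(r_uv) + sum_w phi_a(theta_uvw)}: a learnable linear map
#' over the radial basis plus the sum of learnable linear maps over the
#' angular basis of all triplet angles at the receiver. Edges whose receiver
#' has a single neighbor get a zero angular sum.
#'
#' @param geom output of \code{\link{geometric_features}}.
#' @param W_r n_rbf x d radial weights.
#' @param W_a n_cos x d angular weights.
#' @param r_c radius cutoff for the RBF grid.
#' @return |edges| x d matrix.
#' @export
geometric_edge_embedding <- function(geom, W_r, W_a, r_c = 5.0) {
  rad <- rbf_expand(geom$r, r_c, nrow(W_r)) %*% W_r
  if (length(geom$theta)) {
    ang <- cos_expand(geom$theta, nrow(W_a)) %*% W_a
    rad <- rad + segment_reduce(ang, geom$theta_edge, geom$n_edges, "sum")
  }
  rad
}

#' Geometric message-passing layer
#'
#' Messages \code{xi(h_u, h_v, e_uv)} with a one-hidden-layer MLP \code{xi}
#' over the concatenation, summed over neighbors, followed by an MLP update.
#' Only distances and angles enter, so the output is invariant under rigid
#' motions and permutation-equivariant.
#'
#' @param H node state.
#' @param ebar geometric edge embedding (from
#'   \code{\link{geometric_edge_embedding}}).
#' @param edge_index directed edge matrix (receiver first).
#' @param weights list with \code{W_xi}, \code{b_xi} (message MLP) and
#'   \code{W_u}, \code{b_u} (update MLP over \code{[h || agg]}).
#' @return updated node state.
#' @export
geometric_mpnn_layer <- function(H, ebar, edge_index, weights) {
  n <- nrow(H)
  rcv <- edge_index[, 1]; src <- edge_index[, 2]
  Zm <- cbind(H[rcv, , drop = FALSE], H[src, , drop = FALSE], ebar)
  msg <- pmax(sweep(Zm %*% weights$W_xi, 2, as.numeric(weights$b_xi), "+"), 0)
  agg <- segment_reduce(msg, rcv, n, "sum")
  Zu <- cbind(H, agg)
  pmax(sweep(Zu %*% weights$W_u, 2, as.numeric(weights$b_u), "+"), 0)
}

# ---- global attention ------------------------------------------------------

#' Block mask for within-graph attention
#'
#' Additive mask: 0 where two nodes belong to the same graph, a large
#' negative constant across graph boundaries, so softmax places no attention
#' mass outside each graph block.
#' @param membership integer vector mapping node to graph.
#' @return N x N matrix.
#' @export
attention_mask <- function(membership) {
  same <- outer(membership, membership, "==")
  ifelse(same, 0, -1e30)
}

#' Multi-head global self-attention within graphs
#'
#' Scaled dot-product attention (per-head width \code{d / B}), computed
#' strictly within each graph of a batch via a block mask; heads are
#' concatenated and projected by \code{W_O}. Per-row attention weights over
#' same-graph nodes sum to 1.
#'
#' @param H N x d_in node state.
#' @param membership node-to-graph index vector.
#' @param W_Q,W_K,W_V d_in x d projection weights (columns split across
#'   heads).
#' @param W_O d x d output projection.
#' @param B number of heads; must divide d.
#' @return list with \code{H} (N x d output) and \code{attn} (list of per-head
#'   N x N row-stochastic matrices within blocks).
#' @export
multi_head_attention <- function(H, membership, W_Q, W_K, W_V, W_O, B) {
  d <- ncol(W_Q)
  if (d %% B != 0) stop("head count must divide the hidden width")
  dh <- d %/% B
  mask <- attention_mask(membership)
  Q <- H %*% W_Q; K <- H %*% W_K; V <- H %*% W_V
  outs <- vector("list", B); attn <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- ((b - 1) * dh + 1):(b * dh)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh) + mask
    S <- S - apply(S, 1, max)
    P <- exp(S) / rowSums(exp(S))
    attn[[b]] <- P
    outs[[b]] <- P %*% V[, cols, drop = FALSE]
  }
  list(H = do.call(cbind, outs) %*% W_O, attn = attn)
}

# ---- GPS fusion ------------------------------------------------------------

#' GPS fusion layer
#'
#' Hybrid local/global layer: the node update is an MLP of the elementwise
#' sum of the MPNN branch and the global-attention branch; the edge state is
#' updated by the GNN branch only.
#'
#' @param X node state.
#' @param E edge state (passed to and possibly updated by
#'   \code{mpnn_block}).
#' @param edge_index directed edge matrix.
#' @param mpnn_block \code{function(X, E, edge_index)} returning
#'   \code{list(X, E)}.
#' @param attn_block \code{function(X)} returning the global branch output.
#' @param mlp_block \code{function(X)} applied to the branch sum.
#' @return list with updated \code{X} and \code{E}.
#' @export
gps_layer <- function(X, E, edge_index, mpnn_block, attn_block, mlp_block) {
  loc <- mpnn_block(X, E, edge_index)
  glob <- attn_block(X)
  if (!all(dim(loc$X) == dim(glob))) stop("branch width mismatch in GPS layer")
  list(X = mlp_block(loc$X + glob), E = loc$E)
}

# ---- pooling ---------------------------------------------------------------

#' Graph-level pooling
#'
#' Permutation-invariant reduction of node states over each graph.
#' @param H N x d node state.
#' @param membership node-to-graph index (defaults to a single graph).
#' @param mode one of \code{"sum"}, \code{"mean"}, \code{"max"},
#'   \code{"min"}.
#' @return n_graphs x d matrix.
#' @export
pool <- function(H, membership = rep(1L, nrow(H)),
                 mode = c("mean", "sum", "max", "min")) {
  mode <- match.arg(mode)
  if (nrow(H) == 0) stop("cannot pool an empty graph")
  segment_reduce(H, membership, max(membership), mode)
}

# ---- tape (trainable) forms -----------------------------------------------

# Edge-conditioned MPNN layer on the tape.
# params: W_phi (d_in x d), b_phi, W_e (f x d or NULL), W_u (d_in+d x d), b_u
# plus GRU variant (W_z, W_r, W_h + biases) when update == "gru".
ag_mpnn_fwd <- function(tp, h, batch, pw, aggregator = "sum",
                        update = "mlp", e_node = NULL) {
  rcv <- batch$edge_index[, 1]; src <- batch$edge_index[, 2]
  n <- batch$n_nodes
  phi <- ag_matmul(tp, h, pw$W_phi)
  msg <- ag_gather_rows(tp, phi, src)
  if (!is.null(e_node) && !is.null(pw$W_e)) {
    msg <- ag_add(tp, msg, ag_matmul(tp, e_node, pw$W_e))
  }
  if (aggregator == "attention") {
    hr <- ag_gather_rows(tp, h, rcv)
    hs <- ag_gather_rows(tp, h, src)
    sc <- ag_matmul(tp, ag_cbind(tp, list(hr, hs)), pw$W_att)  # |E| x 1
    # per-receiver softmax; subtract a detached running max for stability
    scv <- ag_value(tp, sc)
    shift <- stats::ave(scv[, 1], rcv, FUN = max)
    e <- ag_exp(tp, ag_add(tp, sc, ag_input(tp, matrix(-shift, ncol = 1))))
    den <- ag_scatter_sum(tp, e, rcv, n)
    w <- ag_div(tp, e, ag_gather_rows(tp, den, rcv))
    wmat <- ag_matmul(tp, w, ag_input(tp, matrix(1, 1, ncol(ag_value(tp, msg)))))
    agg <- ag_scatter_sum(tp, ag_hadamard(tp, msg, wmat), rcv, n)
  } else {
    agg <- switch(aggregator,
      sum = ag_scatter_sum(tp, msg, rcv, n),
      mean = ag_scatter_mean(tp, msg, rcv, n),
      max = ag_scatter_extreme(tp, msg, rcv, n, "max"))
  }
  z <- ag_cbind(tp, list(h, agg))
  if (update == "gru") {
    zg <- ag_sigmoid(tp, ag_add_bias(tp, ag_matmul(tp, z, pw$W_z), pw$b_z))
    ht <- ag_tanh(tp, ag_add_bias(tp, ag_matmul(tp, z, pw$W_h), pw$b_h))
    hproj <- ag_matmul(tp, h, pw$W_p)
    one <- ag_input(tp, matrix(1, batch$n_nodes, ncol(ag_value(tp, zg))))
    ag_add(tp, ag_hadamard(tp, ag_sub(tp, one, zg), hproj),
           ag_hadamard(tp, zg, ht))
  } else {
    ag_relu(tp, ag_add_bias(tp, ag_matmul(tp, z, pw$W_u), pw$b_u))
  }
}

# Geometric MPNN layer on the tape; batch carries precomputed RBF/cos bases.
ag_geom_mpnn_fwd <- function(tp, h, batch, pw) {
  rcv <- batch$edge_index[, 1]; src <- batch$edge_index[, 2]
  ebar <- ag_matmul(tp, ag_input(tp, batch$rbf), pw$W_r)
  if (nrow(batch$cosb) > 0) {
    ang <- ag_matmul(tp, ag_input(tp, batch$cosb), pw$W_a)
    ebar <- ag_add(tp, ebar,
                   ag_scatter_sum(tp, ang, batch$theta_edge, nrow(batch$edge_index)))
  }
  hr <- ag_gather_rows(tp, h, rcv)
  hs <- ag_gather_rows(tp, h, src)
  zm <- ag_cbind(tp, list(hr, hs, ebar))
  msg <- ag_relu(tp, ag_add_bias(tp, ag_matmul(tp, zm, pw$W_xi), pw$b_xi))
  agg <- ag_scatter_sum(tp, msg, rcv, batch$n_nodes)
  zu <- ag_cbind(tp, list(h, agg))
  ag_relu(tp, ag_add_bias(tp, ag_matmul(tp, zu, pw$W_u), pw$b_u))
}

# A @ t(B)
ag_matmul_bt <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ag_node(tp, tcrossprod(A, B), c(a, b),
          function(g) list(g %*% B, crossprod(g, A)))
}

ag_gather_cols <- function(tp, a, cols) {
  force(a)
  A <- tp$vals[[a]]
  ag_node(tp, A[, cols, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    out[, cols] <- g
    list(out)
  })
}

# Multi-head attention on the tape; pw entries are tape node ids, mask is a
# plain additive matrix from attention_mask().
ag_mha_fwd <- function(tp, h, batch, pw, B, d) {
  dh <- d %/% B
  Q <- ag_matmul(tp, h, pw$W_Q)
  K <- ag_matmul(tp, h, pw$W_K)
  V <- ag_matmul(tp, h, pw$W_V)
  outs <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- ((b - 1) * dh + 1):(b * dh)
    S <- ag_scale(tp, ag_matmul_bt(tp, ag_gather_cols(tp, Q, cols),
                                   ag_gather_cols(tp, K, cols)), 1 / sqrt(dh))
    P <- ag_softmax_rows(tp, S, batch$mask)
    outs[[b]] <- ag_matmul(tp, P, ag_gather_cols(tp, V, cols))
  }
  ag_matmul(tp, ag_cbind(tp, outs), pw$W_O)
}

# Two-layer MLP (relu hidden, linear out) on the tape.
ag_mlp_fwd <- function(tp, x, W1, b1, W2, b2) {
  hid <- ag_relu(tp, ag_add_bias(tp, ag_matmul(tp, x, W1), b1))
  ag_add_bias(tp, ag_matmul(tp, hid, W2), b2)
}
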