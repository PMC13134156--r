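# Tape-based reverse-mode automatic differentiation over dense matrices.
# Every learnable module in the package (embeddings, MPNN/GPS layers, heads)
# builds its forward pass on a fresh tape per batch; ag_backward() walks the
# tape in reverse creation order (creation order is topological) and
# accumulates gradients into parameter leaves.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$parents <- list()
  tp$bw <- list()
  tp$n <- 0L
  tp
}

ag_node <- function(tp, value, parents = integer(0), bw = NULL) {
  tp$n <- tp$n + 1L
  id <- tp$n
  tp$vals[[id]] <- value
  tp$parents[[id]] <- as.integer(parents)
  tp$bw[[id]] <- if (is.null(bw)) list(NULL) else bw
  id
}

#' @noRd
ag_input <- function(tp, x) ag_node(tp, as.matrix(x))

ag_value <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

ag_matmul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ag_node(tp, A %*% B, c(a, b),
          function(g) list(g %*% t(B), crossprod(A, g)))
}

ag_add <- function(tp, a, b) {
  force(a); force(b)
  ag_node(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b),
          function(g) list(g, g))
}

ag_sub <- function(tp, a, b) {
  force(a); force(b)
  ag_node(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b),
          function(g) list(g, -g))
}

ag_hadamard <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ag_node(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

ag_scale <- function(tp, a, s) {
  force(a)
  ag_node(tp, tp$vals[[a]] * s, a, function(g) list(g * s))
}

# broadcast a 1 x d bias row over all rows of a
ag_add_bias <- function(tp, a, bias) {
  force(a); force(bias)
  A <- tp$vals[[a]]; B <- tp$vals[[bias]]
  ag_node(tp, sweep(A, 2, as.numeric(B), "+"), c(a, bias),
          function(g) list(g, matrix(colSums(g), 1)))
}

ag_relu <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  ag_node(tp, pmax(A, 0), a, function(g) list(g * (A > 0)))
}

ag_tanh <- function(tp, a) {
  force(a)
  V <- tanh(tp$vals[[a]])
  ag_node(tp, V, a, function(g) list(g * (1 - V^2)))
}

ag_sigmoid <- function(tp, a) {
  force(a)
  V <- 1 / (1 + exp(-tp$vals[[a]]))
  ag_node(tp, V, a, function(g) list(g * V * (1 - V)))
}

ag_exp <- function(tp, a) {
  force(a)
  V <- exp(tp$vals[[a]])
  ag_node(tp, V, a, function(g) list(g * V))
}

ag_div <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ag_node(tp, A / B, c(a, b),
          function(g) list(g / B, -g * A / B^2))
}

ag_cbind <- function(tp, ids) {
  force(ids)
  mats <- lapply(ids, function(i) tp$vals[[i]])
  widths <- vapply(mats, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(tp, do.call(cbind, mats), ids, function(g) {
    lapply(seq_along(ids), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

# gather rows: out[i, ] = x[idx[i], ]
ag_gather_rows <- function(tp, a, idx) {
  force(a)
  A <- tp$vals[[a]]
  nr <- nrow(A)
  ag_node(tp, A[idx, , drop = FALSE], a, function(g) {
    gs <- rowsum(g, group = idx)
    out <- matrix(0, nr, ncol(g))
    out[as.integer(rownames(gs)), ] <- gs
    list(out)
  })
}

# segment sum: out[k, ] = sum of rows of x with groups == k, k in 1..ngroups
ag_scatter_sum <- function(tp, a, groups, ngroups) {
  force(a)
  A <- tp$vals[[a]]
  val <- matrix(0, ngroups, ncol(A))
  if (nrow(A) > 0) {
    gs <- rowsum(A, group = groups)
    val[as.integer(rownames(gs)), ] <- gs
  }
  ag_node(tp, val, a, function(g) list(g[groups, , drop = FALSE]))
}

ag_scatter_mean <- function(tp, a, groups, ngroups) {
  force(a)
  cnt <- tabulate(groups, nbins = ngroups)
  s <- ag_scatter_sum(tp, a, groups, ngroups)
  ag_node(tp, tp$vals[[s]] / pmax(cnt, 1), s,
          function(g) list(g / pmax(cnt, 1)))
}

# segment max/min with gradient routed to the argmax/argmin row per column
ag_scatter_extreme <- function(tp, a, groups, ngroups, which = c("max", "min")) {
  force(a)
  which <- match.arg(which)
  A <- tp$vals[[a]]
  f <- if (which == "max") max else min
  val <- matrix(0, ngroups, ncol(A))
  arg <- matrix(NA_integer_, ngroups, ncol(A))
  for (k in seq_len(ngroups)) {
    rows <- which(groups == k)
    if (length(rows) == 0) next
    for (j in seq_len(ncol(A))) {
      v <- A[rows, j]
      i <- if (which == "max") which.max(v) else which.min(v)
      val[k, j] <- v[i]
      arg[k, j] <- rows[i]
    }
  }
  ag_node(tp, val, a, function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    for (k in seq_len(ngroups)) for (j in seq_len(ncol(A))) {
      if (!is.na(arg[k, j])) out[arg[k, j], j] <- out[arg[k, j], j] + g[k, j]
    }
    list(out)
  })
}

# row-wise softmax with an additive constant mask (0 for allowed, -Inf-like
# for masked entries); used for within-graph attention in batches
ag_softmax_rows <- function(tp, a, mask = NULL) {
  force(a)
  A <- tp$vals[[a]]
  if (!is.null(mask)) A <- A + mask
  A <- A - apply(A, 1, max)
  E <- exp(A)
  P <- E / rowSums(E)
  ag_node(tp, P, a, function(g) {
    list(P * (g - rowSums(g * P)))
  })
}

ag_sum <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  ag_node(tp, matrix(sum(A), 1, 1), a,
          function(g) list(matrix(g[1, 1], nrow(A), ncol(A))))
}

ag_mse_loss <- function(tp, pred, target) {
  force(pred)
  P <- tp$vals[[pred]]; Tt <- as.matrix(target)
  n <- length(P)
  ag_node(tp, matrix(mean((P - Tt)^2), 1, 1), pred,
          function(g) list(g[1, 1] * 2 * (P - Tt) / n))
}

# softmax cross-entropy over rows; y is a 1-based class index vector
ag_ce_loss <- function(tp, logits, y) {
  force(logits)
  Z <- tp$vals[[logits]]
  Zs <- Z - apply(Z, 1, max)
  lse <- log(rowSums(exp(Zs))) + apply(Z, 1, max)
  n <- nrow(Z)
  loss <- mean(lse - Z[cbind(seq_len(n), y)])
  P <- exp(Z - lse)
  ag_node(tp, matrix(loss, 1, 1), logits, function(g) {
    G <- P
    G[cbind(seq_len(n), y)] <- G[cbind(seq_len(n), y)] - 1
    list(g[1, 1] * G / n)
  })
}

# per-label binary cross-entropy with a 0/1 missing-label mask
ag_bce_masked_loss <- function(tp, logits, targets, mask) {
  force(logits)
  Z <- tp$vals[[logits]]; Tt <- as.matrix(targets); M <- as.matrix(mask)
  m <- max(sum(M), 1)
  # numerically stable softplus
  sp <- pmax(Z, 0) + log1p(exp(-abs(Z)))
  loss <- sum(M * (sp - Tt * Z)) / m
  S <- 1 / (1 + exp(-Z))
  ag_node(tp, matrix(loss, 1, 1), logits,
          function(g) list(g[1, 1] * M * (S - Tt) / m))
}

# Reverse pass from the node `loss`; returns per-node gradient list.
ag_backward <- function(tp, loss) {
  grads <- vector("list", tp$n)
  grads[[loss]] <- matrix(1, 1, 1)
  for (id in seq(loss, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    bw <- tp$bw[[id]]
    if (is.function(bw)) {
      pg <- bw(g)
      ps <- tp$parents[[id]]
      for (k in seq_along(ps)) {
        p <- ps[k]
        grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
      }
    }
  }
  grads
}

# ---- parameter store and optimizer ----------------------------------------

#' Initialize a weight matrix
#'
#' Uniform on \code{[-1, 1] / sqrt(fan_in)}; deterministic under the caller's
#' RNG state.
#' @noRd
ag_init_weight <- function(fan_in, fan_out) {
  s <- 1 / sqrt(max(fan_in, 1))
  matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

adam_state <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, st) {
  st$t <- st$t + 1L
  for (k in seq_along(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    st$m[[k]] <- st$beta1 * st$m[[k]] + (1 - st$beta1) * g
    st$v[[k]] <- st$beta2 * st$v[[k]] + (1 - st$beta2) * g^2
    mhat <- st$m[[k]] / (1 - st$beta1^st$t)
    vhat <- st$v[[k]] / (1 - st$beta2^st$t)
    params[[k]] <- params[[k]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  list(params = params, state = st)
}
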