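# Scheme-specific model assembly, multitask heads, losses and metrics.

#' Task specification
#'
#' @param name task name (must match a target name on the graphs).
#' @param level \code{"graph"} or \code{"node"}.
#' @param type \code{"regression"}, \code{"multiclass"} or
#'   \code{"multilabel"}.
#' @param n_out output width (1 for scalar regression; number of classes /
#'   labels otherwise).
#' @param weight positive loss weight.
#' @return a \code{task_spec} list.
#' @export
task_spec <- function(name, level = c("graph", "node"),
                      type = c("regression", "multiclass", "multilabel"),
                      n_out = 1, weight = 1) {
  level <- match.arg(level); type <- match.arg(type)
  stopifnot(weight > 0, n_out >= 1)
  structure(list(name = name, level = level, type = type,
                 n_out = as.integer(n_out), weight = weight),
            class = "task_spec")
}

#' Model configuration
#'
#' Scheme flags and architecture hyperparameters. The scheme is determined
#' by (and must agree with) the two switches: S1 = attention off/encoders
#' off, S2 = off/on, S3 = on/off, S4 = on/on. When attention is on the head
#' count must divide the hidden width.
#'
#' @param scheme \code{"S1".."S4"}; inferred from the flags when missing.
#' @param mpnn_type one of \code{"edgecond-sum"}, \code{"edgecond-mean"},
#'   \code{"edgecond-max"}, \code{"neighbor-attention"},
#'   \code{"geometric-mpnn"}.
#' @param num_conv_layers number of MPNN (S1/S2) or GPS (S3/S4) layers.
#' @param hidden_dim node hidden width d_h.
#' @param edge_embed_dim edge embed width; 0 selects the raw-edge
#'   (equivariance-preserving) path.
#' @param global_attn_heads head count B; 0 iff attention is off.
#' @param global_attn_engine,use_encodings the two switches.
#' @param has_pos whether 3D coordinates are available.
#' @param pooling graph pooling mode.
#' @param update node update function family (\code{"mlp"} or \code{"gru"}).
#' @param lpe_dim LPE dimensionality d_l.
#' @param r_c radius cutoff (Angstrom) for geometric bases.
#' @param lr learning rate.
#' @return a validated \code{model_config}.
#' @export
model_config <- function(scheme = NULL, mpnn_type = "edgecond-sum",
                         num_conv_layers = 2, hidden_dim = 16,
                         edge_embed_dim = 0, global_attn_heads = 0,
                         global_attn_engine = NULL, use_encodings = NULL,
                         has_pos = FALSE, pooling = "mean", update = "mlp",
                         lpe_dim = 2, r_c = 5.0, lr = 1e-3) {
  if (is.null(scheme)) {
    stopifnot(!is.null(global_attn_engine), !is.null(use_encodings))
    scheme <- paste0("S", 1 + use_encodings + 2 * global_attn_engine)
  }
  flags <- scheme_channels(scheme)
  if (!is.null(global_attn_engine) &&
      global_attn_engine != flags$global_attn_engine)
    stop("scheme and global_attn_engine flag disagree")
  if (!is.null(use_encodings) && use_encodings != flags$use_encodings)
    stop("scheme and use_encodings flag disagree")
  attn <- flags$global_attn_engine
  if (attn && global_attn_heads < 1)
    stop("attention-on schemes need global_attn_heads >= 1")
  if (!attn && global_attn_heads != 0)
    stop("global_attn_heads must be 0 when attention is off")
  if (attn && hidden_dim %% global_attn_heads != 0)
    stop("hidden_dim must be divisible by global_attn_heads")
  if (mpnn_type == "geometric-mpnn" && !has_pos)
    stop("geometric-mpnn requires coordinates (has_pos = TRUE)")
  stopifnot(num_conv_layers >= 1, hidden_dim >= 1, edge_embed_dim >= 0)
  structure(list(scheme = scheme, mpnn_type = mpnn_type,
                 num_conv_layers = as.integer(num_conv_layers),
                 hidden_dim = as.integer(hidden_dim),
                 edge_embed_dim = as.integer(edge_embed_dim),
                 global_attn_heads = as.integer(global_attn_heads),
                 global_attn_engine = attn,
                 use_encodings = flags$use_encodings,
                 has_pos = has_pos, pooling = pooling, update = update,
                 lpe_dim = as.integer(lpe_dim), r_c = r_c, lr = lr),
            class = "model_config")
}

N_RBF <- 16L
N_COS <- 8L

node_input_width <- function(config, meta) {
  ch <- scheme_channels(config$scheme)$node
  w <- c(X = meta$p, L = config$lpe_dim, P = 9L, C = 15L)
  sum(w[ch])
}

edge_input_width <- function(config, meta) {
  if (config$scheme == "S1") return(meta$f)
  if (config$edge_embed_dim == 0) return(meta$f)  # raw pass-through
  if (config$use_encodings) meta$f + 4L else meta$f + config$lpe_dim
}

# width of the edge features the conv layers actually see
edge_feature_width <- function(config, meta) {
  if (config$scheme == "S1" || config$edge_embed_dim == 0) meta$f
  else config$edge_embed_dim
}

mpnn_param_shapes <- function(prefix, din, d, edge_w, config) {
  sh <- list()
  if (config$mpnn_type == "geometric-mpnn") {
    sh[[paste0(prefix, "W_r")]] <- c(N_RBF, d)
    sh[[paste0(prefix, "W_a")]] <- c(N_COS, d)
    sh[[paste0(prefix, "W_xi")]] <- c(2 * din + d, d)
    sh[[paste0(prefix, "b_xi")]] <- c(1, d)
    sh[[paste0(prefix, "W_u")]] <- c(din + d, d)
    sh[[paste0(prefix, "b_u")]] <- c(1, d)
  } else {
    sh[[paste0(prefix, "W_phi")]] <- c(din, d)
    if (edge_w > 0) sh[[paste0(prefix, "W_e")]] <- c(edge_w, d)
    if (config$mpnn_type == "neighbor-attention")
      sh[[paste0(prefix, "W_att")]] <- c(2 * din, 1)
    if (config$update == "gru") {
      sh[[paste0(prefix, "W_z")]] <- c(din + d, d)
      sh[[paste0(prefix, "b_z")]] <- c(1, d)
      sh[[paste0(prefix, "W_h")]] <- c(din + d, d)
      sh[[paste0(prefix, "b_h")]] <- c(1, d)
      sh[[paste0(prefix, "W_p")]] <- c(din, d)
    } else {
      sh[[paste0(prefix, "W_u")]] <- c(din + d, d)
      sh[[paste0(prefix, "b_u")]] <- c(1, d)
    }
  }
  sh
}

#' Assemble a model from a configuration
#'
#' Creates the full parameter set for the configured scheme: fusion
#' embeddings, a stack of MPNN (S1/S2) or GPS (S3/S4) layers, and one
#' decoder head per task on the shared trunk. Weights are initialized
#' uniformly scaled by the inverse square root of the input width under the
#' current RNG state.
#'
#' @param config a \code{\link{model_config}}.
#' @param meta list with \code{p} (raw node feature width), \code{f} (raw
#'   edge feature width, 0 if none) and \code{tasks} (list of
#'   \code{\link{task_spec}}).
#' @return a \code{molgps_model}: \code{config}, \code{meta}, named
#'   parameter list \code{params}.
#' @export
assemble <- function(config, meta) {
  stopifnot(inherits(config, "model_config"), length(meta$tasks) >= 1)
  d <- config$hidden_dim
  shapes <- list()
  if (config$scheme != "S1")
    shapes$W_node <- c(node_input_width(config, meta), d)
  if (config$scheme != "S1" && config$edge_embed_dim > 0)
    shapes$W_edge <- c(edge_input_width(config, meta), config$edge_embed_dim)
  edge_w <- edge_feature_width(config, meta)
  din <- if (config$scheme == "S1") meta$p else d
  gps <- config$global_attn_engine
  for (k in seq_len(config$num_conv_layers)) {
    pre <- sprintf("L%d.", k)
    shapes <- c(shapes, mpnn_param_shapes(pre, din, d, edge_w, config))
    if (gps) {
      shapes[[paste0(pre, "W_Q")]] <- c(din, d)
      shapes[[paste0(pre, "W_K")]] <- c(din, d)
      shapes[[paste0(pre, "W_V")]] <- c(din, d)
      shapes[[paste0(pre, "W_O")]] <- c(d, d)
      shapes[[paste0(pre, "mlp.W1")]] <- c(d, d)
      shapes[[paste0(pre, "mlp.b1")]] <- c(1, d)
      shapes[[paste0(pre, "mlp.W2")]] <- c(d, d)
      shapes[[paste0(pre, "mlp.b2")]] <- c(1, d)
    }
    din <- d
  }
  for (t in meta$tasks) {
    pre <- sprintf("head.%s.", t$name)
    shapes[[paste0(pre, "W1")]] <- c(d, d)
    shapes[[paste0(pre, "b1")]] <- c(1, d)
    shapes[[paste0(pre, "W2")]] <- c(d, t$n_out)
    shapes[[paste0(pre, "b2")]] <- c(1, t$n_out)
  }
  params <- lapply(shapes, function(s) ag_init_weight(s[1], s[2]))
  structure(list(config = config, meta = meta, params = params),
            class = "molgps_model")
}

#' Total trainable parameter count
#' @param model a \code{molgps_model}.
#' @return integer.
#' @export
param_count <- function(model) sum(vapply(model$params, length, 1L))

#' @export
print.molgps_model <- function(x, ...) {
  cat(sprintf("<molgps_model %s %s: %d conv layers, d_h=%d, %d heads, %d parameters>\n",
              x$config$scheme, x$config$mpnn_type, x$config$num_conv_layers,
              x$config$hidden_dim, x$config$global_attn_heads, param_count(x)))
  invisible(x)
}

# ---- forward pass ----------------------------------------------------------

# batch: list(n_nodes, n_graphs, membership, edge_index, mask, X, Znode,
#             Zedge, E_raw, rbf, cosb, theta_edge, targets)
model_forward <- function(model, batch, params = model$params) {
  cfg <- model$config
  tp <- ag_tape()
  pid <- lapply(params, function(p) ag_input(tp, p))
  # node input
  h <- if (cfg$scheme == "S1") ag_input(tp, batch$X)
       else ag_matmul(tp, ag_input(tp, batch$Znode), pid$W_node)
  # edge features seen by the conv layers
  e <- NULL
  if (nrow(batch$edge_index) > 0) {
    if (cfg$scheme != "S1" && cfg$edge_embed_dim > 0)
      e <- ag_matmul(tp, ag_input(tp, batch$Zedge), pid$W_edge)
    else if (!is.null(batch$E_raw) && ncol(batch$E_raw) > 0)
      e <- ag_input(tp, batch$E_raw)
  }
  agg <- switch(cfg$mpnn_type,
                "edgecond-sum" = "sum", "edgecond-mean" = "mean",
                "edgecond-max" = "max", "neighbor-attention" = "attention",
                "geometric-mpnn" = "sum")
  layer_pid <- function(k) {
    pre <- sprintf("L%d.", k)
    nm <- names(pid)[startsWith(names(pid), pre)]
    out <- pid[nm]
    names(out) <- substring(nm, nchar(pre) + 1)
    out
  }
  for (k in seq_len(cfg$num_conv_layers)) {
    pw <- layer_pid(k)
    local_out <- if (cfg$mpnn_type == "geometric-mpnn")
      ag_geom_mpnn_fwd(tp, h, batch, pw)
    else
      ag_mpnn_fwd(tp, h, batch, pw, aggregator = agg,
                  update = cfg$update, e_node = e)
    if (cfg$global_attn_engine) {
      glob <- ag_mha_fwd(tp, h, batch, pw, cfg$global_attn_heads,
                         cfg$hidden_dim)
      s <- ag_add(tp, local_out, glob)
      h <- ag_mlp_fwd(tp, s, pw$mlp.W1, pw$mlp.b1, pw$mlp.W2, pw$mlp.b2)
    } else {
      h <- local_out
    }
  }
  pooled <- NULL
  preds <- list(); losses <- list()
  total <- NULL
  for (t in model$meta$tasks) {
    pre <- sprintf("head.%s.", t$name)
    src <- if (t$level == "graph") {
      if (is.null(pooled)) {
        pooled <- switch(cfg$pooling,
          sum = ag_scatter_sum(tp, h, batch$membership, batch$n_graphs),
          mean = ag_scatter_mean(tp, h, batch$membership, batch$n_graphs),
          max = ag_scatter_extreme(tp, h, batch$membership, batch$n_graphs, "max"),
          min = ag_scatter_extreme(tp, h, batch$membership, batch$n_graphs, "min"))
      }
      pooled
    } else h
    out <- ag_mlp_fwd(tp, src, pid[[paste0(pre, "W1")]], pid[[paste0(pre, "b1")]],
                      pid[[paste0(pre, "W2")]], pid[[paste0(pre, "b2")]])
    preds[[t$name]] <- ag_value(tp, out)
    y <- batch$targets[[t$name]]
    lt <- switch(t$type,
      regression = ag_mse_loss(tp, out, y),
      multiclass = ag_ce_loss(tp, out, as.integer(y)),
      multilabel = ag_bce_masked_loss(tp, out, ifelse(is.na(y), 0, y),
                                      1 - is.na(y)))
    losses[[t$name]] <- ag_value(tp, lt)[1, 1]
    wl <- ag_scale(tp, lt, t$weight)
    total <- if (is.null(total)) wl else ag_add(tp, total, wl)
  }
  list(tape = tp, pid = pid, h = h, loss = total,
       loss_value = ag_value(tp, total)[1, 1],
       task_losses = unlist(losses), preds = preds)
}

model_gradients <- function(fw) {
  grads <- ag_backward(fw$tape, fw$loss)
  out <- lapply(fw$pid, function(id) grads[[id]])
  out
}

#' Run a model on a batch and return predictions
#'
#' Forward pass without gradient bookkeeping beyond the tape build; returns
#' per-task predictions and losses.
#' @param model a \code{molgps_model}.
#' @param batch a batch from \code{\link{make_batch}}.
#' @return list with \code{preds}, \code{task_losses}, \code{loss}.
#' @export
predict_batch <- function(model, batch) {
  fw <- model_forward(model, batch)
  list(preds = fw$preds, task_losses = fw$task_losses, loss = fw$loss_value)
}

#' Weighted multitask loss
#'
#' \code{sum(w_t * loss_t)}; a single task reduces to that loss times its
#' weight.
#' @param losses numeric vector of per-task losses.
#' @param weights positive weights aligned with \code{losses}.
#' @return scalar.
#' @export
multitask_loss <- function(losses, weights = rep(1, length(losses))) {
  stopifnot(length(losses) == length(weights), all(weights > 0))
  sum(losses * weights)
}

# ---- metrics ---------------------------------------------------------------

#' Average precision for one label
#'
#' Positions with \code{NA} truth are excluded. AP is the mean of
#' precision-at-k over the positive positions of the score-sorted list.
#' @param scores numeric scores.
#' @param labels 0/1 truth, \code{NA} for missing.
#' @return AP in [0, 1], or \code{NA} if no positives.
#' @export
average_precision <- function(scores, labels) {
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  npos <- sum(labels == 1)
  if (npos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  cum <- cumsum(lab)
  prec_at_pos <- cum[lab == 1] / which(lab == 1)
  mean(prec_at_pos)
}

#' Task metrics
#'
#' Regression: MSE, MAE and Pearson r (NA when either side has zero
#' variance). Multiclass: top-1 accuracy from logits. Multilabel: mean
#' average precision over labels, missing labels excluded per label.
#'
#' @param pred prediction matrix (regression values or logits/scores).
#' @param truth truth vector/matrix; multilabel truth may contain \code{NA}.
#' @param kind \code{"regression"}, \code{"multiclass"} or
#'   \code{"multilabel"}.
#' @return named numeric vector of scores.
#' @export
eval_metrics <- function(pred, truth, kind) {
  if (kind == "regression") {
    p <- as.numeric(pred); y <- as.numeric(truth)
    r <- if (length(p) < 2 || stats::sd(p) == 0 || stats::sd(y) == 0)
      NA_real_ else stats::cor(p, y)
    c(mse = mean((p - y)^2), mae = mean(abs(p - y)), pearson_r = r)
  } else if (kind == "multiclass") {
    cls <- max.col(as.matrix(pred), ties.method = "first")
    c(accuracy = mean(cls == as.integer(truth)))
  } else if (kind == "multilabel") {
    pred <- as.matrix(pred); truth <- as.matrix(truth)
    aps <- vapply(seq_len(ncol(truth)), function(j)
      average_precision(pred[, j], truth[, j]), numeric(1))
    c(map = mean(aps, na.rm = TRUE))
  } else stop("unknown metric kind")
}
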