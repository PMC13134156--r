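# Dataset preparation, batching, the training loop with early stopping and
# checkpointing, and conditional random hyperparameter search.

#' Prepare a dataset for training
#'
#' Computes encoding bundles, discards invalid samples, splits 80/10/10 (or
#' uses a supplied split), fits all standardizers on the training split and
#' applies them unchanged to validation/test, and standardizes regression
#' targets with train-fitted statistics. When coordinates are present and no
#' raw edge features exist, the interatomic distance is attached as the sole
#' continuous edge attribute.
#'
#' @param graphs list of \code{atom_graph}.
#' @param tasks list of \code{\link{task_spec}}.
#' @param d_l LPE dimensionality.
#' @param r_c radius cutoff used for the geometric bases (Angstrom).
#' @param split optional list of train/val/test indices into the retained
#'   graphs.
#' @param seed seed for the split.
#' @return a \code{molgps_dataset}: per-graph standardized channels, split,
#'   standardizers, discard log, and meta (widths).
#' @export
prepare_dataset <- function(graphs, tasks, d_l = 2, r_c = 5.0, split = NULL,
                            seed = 1L) {
  flt <- filter_invalid(graphs, d_l = d_l)
  graphs <- flt$graphs; bundles <- flt$bundles
  n <- length(graphs)
  if (n < 3) stop("fewer than 3 valid graphs after filtering")
  if (is.null(split)) split <- make_split(n, seed = seed)
  per <- lapply(seq_len(n), function(i) {
    g <- graphs[[i]]; b <- bundles[[i]]
    X <- if (!is.null(g$node_features)) g$node_features else
      matrix(as.numeric(g$atomic_numbers), ncol = 1)
    E <- g$edge_features
    if (is.null(E) && !is.null(g$coords) && nrow(g$edge_index) > 0) {
      dvec <- sqrt(rowSums((g$coords[g$edge_index[, 1], , drop = FALSE] -
                            g$coords[g$edge_index[, 2], , drop = FALSE])^2))
      E <- matrix(dvec, ncol = 1)
    }
    geom <- if (!is.null(g$coords) && nrow(g$edge_index) > 0)
      geometric_features(g$coords, g$edge_index) else NULL
    list(g = g, X = X, E = E, C = b$C, P = b$P, G = b$G, L = b$L,
         edge_index = g$edge_index, n = n_atoms(g), geom = geom)
  })
  tr <- split$train
  fit_block <- function(field) {
    rows <- do.call(rbind, lapply(per[tr], `[[`, field))
    if (is.null(rows) || nrow(rows) == 0) return(NULL)
    fit_standardizer(rows)
  }
  stz <- list(X = fit_block("X"), C = fit_block("C"), P = fit_block("P"),
              L = fit_block("L"), G = fit_block("G"), E = fit_block("E"))
  for (i in seq_len(n)) {
    for (f in c("X", "C", "P", "L", "G", "E")) {
      if (!is.null(stz[[f]]) && !is.null(per[[i]][[f]]) &&
          nrow(per[[i]][[f]]) > 0)
        per[[i]][[f]] <- apply_standardizer(per[[i]][[f]], stz[[f]])
    }
  }
  # targets: standardize regression tasks on train statistics
  target_stats <- list()
  targets <- list()
  for (t in tasks) {
    vals <- lapply(per, function(p) as.numeric(p$g$targets[[t$name]]))
    if (any(vapply(vals, length, 1L) == 0))
      stop(sprintf("target '%s' missing on some graphs", t$name))
    if (t$type == "regression") {
      pool <- unlist(vals[tr])
      st <- list(mean = mean(pool), sd = max(stats::sd(pool), 1e-12))
      target_stats[[t$name]] <- st
      vals <- lapply(vals, function(v) (v - st$mean) / st$sd)
    }
    targets[[t$name]] <- vals
  }
  structure(list(per = per, split = split, tasks = tasks, targets = targets,
                 target_stats = target_stats, standardizers = stz,
                 discard_log = flt$discard_log, d_l = d_l, r_c = r_c,
                 meta = list(p = ncol(per[[1]]$X),
                             f = if (is.null(per[[1]]$E)) 0L else
                               ncol(per[[1]]$E),
                             tasks = tasks)),
            class = "molgps_dataset")
}

#' Build a training batch from prepared graphs
#'
#' Concatenates the selected graphs into one block batch: node channels
#' row-stacked, edge indices offset, an additive block mask for within-graph
#' attention, and geometric bases when the backbone needs them.
#'
#' @param prep a \code{molgps_dataset}.
#' @param idx indices of the graphs to batch.
#' @param config a \code{\link{model_config}}.
#' @return a batch list consumed by the model forward pass.
#' @export
make_batch <- function(prep, idx, config) {
  per <- prep$per[idx]
  ns <- vapply(per, `[[`, 1L, "n")
  offs <- cumsum(c(0L, ns[-length(ns)]))
  membership <- rep(seq_along(per), ns)
  ei <- do.call(rbind, lapply(seq_along(per), function(i)
    per[[i]]$edge_index + offs[i]))
  if (is.null(ei)) ei <- matrix(integer(0), 0, 2)
  stackf <- function(f) {
    rows <- lapply(per, `[[`, f)
    if (any(vapply(rows, is.null, TRUE))) return(NULL)
    do.call(rbind, rows)
  }
  X <- stackf("X"); L <- stackf("L"); P <- stackf("P"); C <- stackf("C")
  E <- stackf("E"); G <- stackf("G")
  ch <- scheme_channels(config$scheme)
  Znode <- if (config$scheme == "S1") NULL else
    do.call(cbind, Filter(Negate(is.null),
                          list(X = X, L = L, P = P, C = C)[ch$node]))
  Zedge <- NULL
  if (config$scheme != "S1" && config$edge_embed_dim > 0 && nrow(ei) > 0) {
    Zedge <- if (config$use_encodings)
      do.call(cbind, Filter(Negate(is.null), list(E = E, G = G)))
    else
      do.call(cbind, Filter(Negate(is.null),
                            list(E = E, Ldiff = lpe_edge_diff(L, ei))))
  }
  batch <- list(n_nodes = sum(ns), n_graphs = length(per),
                membership = membership, edge_index = ei,
                X = X, Znode = Znode, Zedge = Zedge, E_raw = E,
                mask = if (config$global_attn_engine)
                  attention_mask(membership) else NULL)
  if (config$mpnn_type == "geometric-mpnn") {
    r <- unlist(lapply(per, function(p) p$geom$r))
    eoffs <- cumsum(c(0L, vapply(per, function(p) nrow(p$edge_index), 1L)))
    theta <- unlist(lapply(per, function(p) p$geom$theta))
    tedge <- unlist(lapply(seq_along(per), function(i)
      per[[i]]$geom$theta_edge + eoffs[i]))
    batch$rbf <- rbf_expand(r, prep$r_c, N_RBF)
    batch$cosb <- if (length(theta)) cos_expand(theta, N_COS) else
      matrix(numeric(0), 0, N_COS)
    batch$theta_edge <- if (length(tedge)) tedge else integer(0)
  }
  batch$targets <- lapply(stats::setNames(prep$tasks,
                                          vapply(prep$tasks, `[[`, "", "name")),
                          function(t) {
    vals <- prep$targets[[t$name]][idx]
    if (t$level == "node") matrix(unlist(vals), ncol = 1)
    else if (t$type == "multilabel") do.call(rbind, vals)
    else if (t$type == "multiclass") as.integer(unlist(vals))
    else matrix(unlist(vals), ncol = 1)
  })
  batch
}

split_batches <- function(prep, idx, config, batch_size) {
  groups <- split(idx, ceiling(seq_along(idx) / batch_size))
  lapply(groups, function(ix) make_batch(prep, ix, config))
}

#' Train a model with early stopping and checkpointing
#'
#' Minimizes the weighted multitask training loss with Adam. Training stops
#' at epoch \code{e <= epochs} once \code{patience} consecutive epochs fail
#' to improve the best validation loss. Parameters are checkpointed every
#' epoch; the best epoch's checkpoint is flagged and reloaded into the
#' returned record.
#'
#' @param model a \code{molgps_model} (from \code{\link{assemble}}).
#' @param prep a \code{molgps_dataset}.
#' @param epochs maximum epochs T.
#' @param patience early-stopping patience p.
#' @param batch_size graphs per batch.
#' @param seed RNG seed (batch order and any stochastic ops).
#' @param checkpoint_dir directory for per-epoch checkpoints (default a
#'   temporary directory).
#' @param verbose print per-epoch losses.
#' @return a \code{trial_record}: config, per-epoch \code{train_loss} and
#'   \code{val_loss}, \code{best_epoch}, \code{best_val},
#'   \code{checkpoint} path of the best epoch, and the best \code{params}.
#' @export
train_model <- function(model, prep, epochs = 100, patience = 20,
                        batch_size = 32, seed = 1L,
                        checkpoint_dir = tempfile("ckpt"), verbose = FALSE) {
  stopifnot(epochs >= 1, patience >= 1)
  dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  cfg <- model$config
  tr_idx <- sample(prep$split$train)
  tb <- split_batches(prep, tr_idx, cfg, batch_size)
  vb <- split_batches(prep, prep$split$val, cfg, batch_size)
  params <- model$params
  opt <- adam_state(params, lr = cfg$lr)
  train_curve <- numeric(0); val_curve <- numeric(0)
  best_val <- Inf; best_epoch <- 0L; stall <- 0L
  best_file <- NULL
  for (ep in seq_len(epochs)) {
    ep_loss <- 0
    for (b in tb) {
      fw <- model_forward(model, b, params)
      if (!is.finite(fw$loss_value))
        stop(sprintf("non-finite training loss at epoch %d; trial aborted", ep))
      g <- model_gradients(fw)
      st <- adam_step(params, g, opt)
      params <- st$params; opt <- st$state
      ep_loss <- ep_loss + fw$loss_value * b$n_graphs
    }
    train_curve[ep] <- ep_loss / length(prep$split$train)
    vl <- 0
    for (b in vb) vl <- vl + model_forward(model, b, params)$loss_value * b$n_graphs
    val_curve[ep] <- vl / length(prep$split$val)
    ck <- file.path(checkpoint_dir, sprintf("epoch_%04d.rds", ep))
    saveRDS(list(epoch = ep, params = params, val_loss = val_curve[ep],
                 config = cfg), ck)
    if (verbose)
      message(sprintf("epoch %d train %.6f val %.6f", ep, train_curve[ep],
                      val_curve[ep]))
    if (val_curve[ep] < best_val) {
      best_val <- val_curve[ep]; best_epoch <- ep; best_file <- ck; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  best <- readRDS(best_file)
  structure(list(config = cfg, train_loss = train_curve, val_loss = val_curve,
                 best_epoch = best_epoch, best_val = best_val,
                 checkpoint = best_file, params = best$params, seed = seed),
            class = "trial_record")
}

#' Evaluate a trained model on a split
#'
#' Test metrics are computed on the held-out split only (and exactly once
#' per final model in the retraining protocol).
#' @param model a \code{molgps_model}.
#' @param params parameter list (e.g. a trial record's best parameters).
#' @param prep a \code{molgps_dataset}.
#' @param split one of \code{"train"}, \code{"val"}, \code{"test"}.
#' @param batch_size graphs per batch.
#' @return named list of metric vectors per task, plus \code{loss}.
#' @export
evaluate_model <- function(model, params, prep, split = "test",
                           batch_size = 32) {
  idx <- prep$split[[split]]
  bs <- split_batches(prep, idx, model$config, batch_size)
  preds <- list(); loss <- 0
  for (b in bs) {
    fw <- model_forward(model, b, params)
    loss <- loss + fw$loss_value * b$n_graphs
    for (nm in names(fw$preds))
      preds[[nm]] <- rbind(preds[[nm]], fw$preds[[nm]])
  }
  out <- list(loss = loss / length(idx))
  for (t in prep$tasks) {
    truth <- prep$targets[[t$name]][idx]
    y <- if (t$type == "multilabel") do.call(rbind, truth) else
      unlist(truth)
    out[[t$name]] <- eval_metrics(preds[[t$name]], y, t$type)
  }
  out
}

# ---- conditional hyperparameter search space -------------------------------

#' The conditional hyperparameter search space
#'
#' Grids conditioned on coordinate availability, the attention switch and
#' the encoder switch. With attention on, every hidden width in the grid is
#' a multiple of 8 = lcm(2, 4, 8), so any sampled (hidden_dim, heads) pair
#' satisfies the divisibility constraint by construction.
#'
#' @return nested list of grids.
#' @export
search_space <- function() {
  list(
    attn_off = list(
      num_conv_layers = 1:6,
      global_attn_heads = 0L,
      hidden_dim = list(enc_off = 4:32, enc_on = 16:64),
      edge_embed_dim = list(enc_off = 0L, enc_on = c(0L, 4:12))),
    attn_on = list(
      num_conv_layers = 1:3,
      global_attn_heads = c(2L, 4L, 8L),
      hidden_dim = list(enc_off = c(8L, 16L, 24L, 32L, 40L, 48L),
                        enc_on = c(16L, 24L, 32L, 40L, 48L, 56L, 64L)),
      edge_embed_dim = list(enc_off = c(0L, 4L, 5L, 6L, 8L, 9L, 10L, 11L, 12L),
                            enc_on = c(0L, 4:12))),
    mpnn_type = list(
      pos = c("geometric-mpnn", "edgecond-sum", "edgecond-mean",
              "neighbor-attention"),
      no_pos = c("edgecond-sum", "edgecond-mean", "edgecond-max",
                 "neighbor-attention")),
    lr = c(1e-2, 3e-3, 1e-3, 3e-4))
}

#' Sample a model configuration from the conditional space
#'
#' Uniform draws from the grids selected by the three condition flags; uses
#' the current RNG state.
#' @param has_pos,global_attn_engine,use_encodings condition flags.
#' @param lpe_dim,r_c,pooling passed through to the config.
#' @return a \code{\link{model_config}}.
#' @export
sample_config <- function(has_pos = FALSE, global_attn_engine = FALSE,
                          use_encodings = FALSE, lpe_dim = 2, r_c = 5.0,
                          pooling = "mean") {
  sp <- search_space()
  br <- if (global_attn_engine) sp$attn_on else sp$attn_off
  enc <- if (use_encodings) "enc_on" else "enc_off"
  pick <- function(v) v[sample.int(length(v), 1)]
  hidden <- pick(br$hidden_dim[[enc]])
  heads <- if (global_attn_engine) pick(br$global_attn_heads) else 0L
  if (heads > 0 && hidden %% heads != 0)
    stop("sampled configuration violates the divisibility constraint")
  model_config(
    mpnn_type = pick(sp$mpnn_type[[if (has_pos) "pos" else "no_pos"]]),
    num_conv_layers = pick(br$num_conv_layers),
    hidden_dim = hidden,
    edge_embed_dim = pick(br$edge_embed_dim[[enc]]),
    global_attn_heads = heads,
    global_attn_engine = global_attn_engine,
    use_encodings = use_encodings,
    has_pos = has_pos, lpe_dim = lpe_dim, r_c = r_c, pooling = pooling,
    lr = pick(sp$lr))
}

#' Random hyperparameter search
#'
#' Samples \code{n_trials} configurations from the conditional space, trains
#' each for up to \code{epochs} epochs, and returns the trial minimizing the
#' best validation loss (ties resolved to the earliest trial) together with
#' a leaderboard sorted ascending and the total epoch-unit cost.
#'
#' @param prep a \code{molgps_dataset}.
#' @param has_pos,global_attn_engine,use_encodings condition flags.
#' @param n_trials number of sampled configurations.
#' @param epochs per-trial training budget T.
#' @param patience early-stopping patience.
#' @param batch_size graphs per batch.
#' @param seed master seed; trial t uses \code{seed + t}.
#' @param verbose print progress.
#' @return list with \code{best} (the winning trial record),
#'   \code{leaderboard} (data.frame), \code{trials}, and
#'   \code{cost_epoch_units}.
#' @export
run_hpo <- function(prep, has_pos = FALSE, global_attn_engine = FALSE,
                    use_encodings = FALSE, n_trials = 5, epochs = 30,
                    patience = 10, batch_size = 32, seed = 1L,
                    verbose = FALSE) {
  stopifnot(n_trials >= 1)
  trials <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    set.seed(seed + t)
    cfg <- sample_config(has_pos, global_attn_engine, use_encodings,
                         lpe_dim = prep$d_l, r_c = prep$r_c)
    model <- assemble(cfg, prep$meta)
    trials[[t]] <- tryCatch(
      train_model(model, prep, epochs = epochs, patience = patience,
                  batch_size = batch_size, seed = seed + t),
      error = function(e) {
        if (verbose) message(sprintf("trial %d failed: %s", t,
                                     conditionMessage(e)))
        NULL
      })
    if (verbose && !is.null(trials[[t]]))
      message(sprintf("trial %d: best val %.6f", t, trials[[t]]$best_val))
  }
  ok <- !vapply(trials, is.null, TRUE)
  if (!any(ok)) stop("all HPO trials failed")
  vals <- vapply(trials, function(tr) if (is.null(tr)) Inf else tr$best_val,
                 1.0)
  best_i <- which.min(vals)              # which.min takes the earliest tie
  lb <- data.frame(trial = which(ok),
                   val_loss = vals[ok],
                   hidden_dim = vapply(trials[ok], function(tr)
                     tr$config$hidden_dim, 1L),
                   num_conv_layers = vapply(trials[ok], function(tr)
                     tr$config$num_conv_layers, 1L),
                   mpnn_type = vapply(trials[ok], function(tr)
                     tr$config$mpnn_type, ""))
  lb <- lb[order(lb$val_loss), ]
  list(best = trials[[best_i]], best_trial = best_i, leaderboard = lb,
       trials = trials,
       cost_epoch_units = n_trials * epochs)
}

#' Retrain the selected configuration for an extended budget
#'
#' Fresh initialization with the winning configuration \code{h*}, an
#' extended budget \code{T' > T} with early stopping, and a single final
#' evaluation on the held-out test split.
#'
#' @param config the winning \code{model_config}.
#' @param prep a \code{molgps_dataset}.
#' @param epochs extended budget T'.
#' @param patience early-stopping patience.
#' @param batch_size graphs per batch.
#' @param seed RNG seed for the fresh initialization.
#' @return list with the final \code{model}, \code{record}, and
#'   \code{test_metrics}.
#' @export
retrain <- function(config, prep, epochs = 200, patience = 30,
                    batch_size = 32, seed = 1L) {
  set.seed(seed)
  model <- assemble(config, prep$meta)
  rec <- train_model(model, prep, epochs = epochs, patience = patience,
                     batch_size = batch_size, seed = seed)
  test <- evaluate_model(model, rec$params, prep, "test", batch_size)
  list(model = model, record = rec, test_metrics = test)
}
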