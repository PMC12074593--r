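#' Training configuration
#'
#' @param epochs number of full-batch epochs (>= 1).
#' @param learning_rate Adam step size.
#' @param seed RNG seed governing initialisation and oversampling.
#' @param oversample an [oversample_config()], or `NULL` to train on the
#'   raw imbalanced graph.
#' @param loss a [focal_loss_config()].
#' @param threshold decision threshold on the positive-class probability
#'   (prediction is positive when `prob >= threshold`).
#' @param sage_dims,mlp_dims hidden widths of the network (see
#'   [sage_mlp()]).
#' @param aggregation `"sum"` or `"mean"` neighbour aggregation.
#' @param weight_decay decoupled L2 penalty applied to the weight
#'   matrices at each step (biases exempt); 0 disables.
#' @param dropout train-time dropout rate in \[0, 1) applied to every
#'   hidden activation (inverted dropout; evaluation passes are
#'   deterministic).
#' @param batch_fraction fraction of training nodes whose loss drives each
#'   update step (a fresh random subset per epoch). Values below 1 inject
#'   the gradient noise of minibatch stochastic training while keeping
#'   one cheap full-graph pass per step; 1 = deterministic full-batch.
#' @param val_fraction fraction of training nodes held out (stratified by
#'   class, before any oversampling) to monitor held-out ranking during
#'   training; the returned model is the checkpoint with the best
#'   validation AUC. 0 disables early checkpoint selection and returns
#'   the final-epoch weights.
#' @param val_every how often (in epochs) the validation AUC is measured
#'   with an evaluation-mode forward pass.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, learning_rate = 0.01, seed = 1L,
                         oversample = oversample_config(),
                         loss = focal_loss_config(), threshold = 0.5,
                         sage_dims = c(256L, 256L), mlp_dims = c(128L, 64L),
                         aggregation = "sum", weight_decay = 0,
                         dropout = 0.2, batch_fraction = 0.25,
                         val_fraction = 0.15, val_every = 5L) {
  assert_that(is.numeric(epochs) && epochs >= 1, "epochs must be >= 1")
  assert_that(is.numeric(threshold) && threshold > 0 && threshold < 1,
              "threshold must be in (0, 1)")
  assert_that(is.numeric(weight_decay) && weight_decay >= 0,
              "weight_decay must be >= 0")
  assert_that(is.numeric(dropout) && dropout >= 0 && dropout < 1,
              "dropout must be in [0, 1)")
  assert_that(is.numeric(batch_fraction) && batch_fraction > 0 &&
                batch_fraction <= 1, "batch_fraction must be in (0, 1]")
  assert_that(is.numeric(val_fraction) && val_fraction >= 0 &&
                val_fraction < 0.5, "val_fraction must be in [0, 0.5)")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), oversample = oversample,
                 loss = loss, threshold = threshold,
                 sage_dims = as.integer(sage_dims),
                 mlp_dims = as.integer(mlp_dims), aggregation = aggregation,
                 weight_decay = weight_decay, dropout = dropout,
                 batch_fraction = batch_fraction,
                 val_fraction = val_fraction,
                 val_every = as.integer(val_every)),
            class = "train_config")
}

# Adam state and update for a nested parameter list
adam_init <- function(params) rapply(params, function(p) p * 0, how = "replace")

adam_step <- function(params, grads, m, v, t, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  # recurse over the nested parameter structure by position, so named and
  # unnamed sub-lists (e.g. the list of SAGE layers) are treated alike
  step_rec <- function(p, g, m_, v_) {
    if (is.list(p)) {
      # match by name where names exist (construction order may differ
      # between the parameter and gradient lists), by position otherwise
      keys <- if (!is.null(names(p)) && all(nzchar(names(p)))) names(p)
              else seq_along(p)
      parts <- lapply(keys, function(i)
        step_rec(p[[i]], g[[i]], m_[[i]], v_[[i]]))
      reassemble <- function(field) {
        out <- lapply(parts, `[[`, field)
        names(out) <- names(p)
        out
      }
      return(list(p = reassemble("p"), m = reassemble("m"),
                  v = reassemble("v")))
    }
    m_ <- beta1 * m_ + (1 - beta1) * g
    v_ <- beta2 * v_ + (1 - beta2) * g^2
    mh <- m_ / (1 - beta1^t)
    vh <- v_ / (1 - beta2^t)
    # decoupled weight decay on matrices only (biases are vectors)
    wd <- if (is.matrix(p)) weight_decay else 0
    list(p = p - lr * (mh / (sqrt(vh) + eps) + wd * p), m = m_, v = v_)
  }
  r <- step_rec(params, grads, m, v)
  list(params = r$p, m = r$m, v = r$v)
}

#' Train the SAGE+MLP classifier on one or more protein graphs
#'
#' Batches the graphs into a disjoint union, optionally rebalances the
#' minority class with graph-aware SMOTE, then minimises the mean focal
#' loss over the training nodes (real and synthetic) by full-batch Adam.
#' Deterministic given the seed.
#'
#' @param graphs a [protein_graph()] or list of them.
#' @param cfg a [train_config()].
#' @return A `bindgraph_fit`: the trained [sage_mlp()] model plus the
#'   per-epoch loss history, the configuration, and the augmented
#'   training-graph summary.
#' @export
train <- function(graphs, cfg = train_config()) {
  if (inherits(graphs, "protein_graph")) graphs <- list(graphs)
  assert_that(length(graphs) >= 1L, "need at least one training graph")
  batched <- if (length(graphs) == 1L) graphs[[1L]] else batch_graphs(graphs)
  tr_labels <- batched$labels[batched$train_mask]
  if (length(unique(tr_labels)) < 2L)
    stop_bindgraph("training labels contain a single class",
                   "bindgraph_degenerate_error")

  # stratified validation split for checkpoint selection, carved out of
  # the training mask before oversampling so no validation information
  # reaches the synthetic nodes
  val_ids <- integer(0)
  vf <- cfg$val_fraction %||% 0
  if (vf > 0) {
    tr_ids <- which(batched$train_mask)
    pos <- tr_ids[batched$labels[tr_ids] == 1L]
    neg <- tr_ids[batched$labels[tr_ids] == 0L]
    if (length(pos) >= 2L && length(neg) >= 2L) {
      val_ids <- with_local_seed(cfg$seed + 13L, c(
        sample(pos, min(max(1L, round(vf * length(pos))), length(pos) - 1L)),
        sample(neg, min(max(1L, round(vf * length(neg))), length(neg) - 1L))))
      batched$train_mask[val_ids] <- FALSE
    }
  }

  g_train <- if (is.null(cfg$oversample)) batched else {
    os <- cfg$oversample
    os$seed <- cfg$seed + os$seed  # tie oversampling stream to the run seed
    oversample(batched, os)
  }

  model <- sage_mlp(input_dim = ncol(g_train$features),
                    sage_dims = cfg$sage_dims, mlp_dims = cfg$mlp_dims,
                    leaky_slope = 0.01, aggregation = cfg$aggregation,
                    seed = cfg$seed)
  S <- aggregation_operator(g_train, model$aggregation)
  mask <- g_train$train_mask
  params <- list(sage = model$sage, mlp = model$mlp)
  m_st <- adam_init(params); v_st <- adam_init(params)
  history <- numeric(cfg$epochs)

  bf <- cfg$batch_fraction %||% 1
  mask_ids <- which(mask)
  val_every <- cfg$val_every %||% 5L
  best <- list(auc = -Inf, params = NULL, epoch = NA_integer_)
  val_history <- data.frame(epoch = integer(0), auc = numeric(0))
  with_local_seed(cfg$seed + 7L, {  # dropout / batch subsampling stream
    for (ep in seq_len(cfg$epochs)) {
      model$sage <- params$sage; model$mlp <- params$mlp
      cache <- model_forward_cache(model, g_train$features, S,
                                   dropout = cfg$dropout %||% 0)
      p_pos <- cache$P[, 2L]
      history[[ep]] <- focal_loss(p_pos[mask], g_train$labels[mask], cfg$loss)
      step_mask <- mask
      if (bf < 1) {
        sub <- mask_ids[stats::runif(length(mask_ids)) < bf]
        if (length(sub) == 0L) sub <- sample(mask_ids, 1L)
        step_mask <- rep(FALSE, length(mask))
        step_mask[sub] <- TRUE
      }
      grads <- model_backward(model, g_train, S, cache, cfg$loss, step_mask)
      st <- adam_step(params, grads, m_st, v_st, ep, cfg$learning_rate,
                      weight_decay = cfg$weight_decay %||% 0)
      params <- st$params; m_st <- st$m; v_st <- st$v
      if (length(val_ids) > 0L &&
          (ep %% val_every == 0L || ep == cfg$epochs)) {
        model$sage <- params$sage; model$mlp <- params$mlp
        P_eval <- model_forward_cache(model, g_train$features, S)$P
        v_auc <- auc_score(P_eval[val_ids, 2L], g_train$labels[val_ids])
        val_history <- rbind(val_history, data.frame(epoch = ep, auc = v_auc))
        if (v_auc > best$auc) best <- list(auc = v_auc, params = params,
                                           epoch = ep)
      }
    }
  })
  if (!is.null(best$params)) params <- best$params
  model$sage <- params$sage; model$mlp <- params$mlp

  structure(list(model = model, loss_history = history,
                 val_history = val_history,
                 best_epoch = best$epoch, config = cfg,
                 n_train_nodes = sum(mask),
                 n_synthetic = if (inherits(g_train, "augmented_graph"))
                   nrow(g_train$provenance) else 0L),
            class = "bindgraph_fit")
}

#' @export
print.bindgraph_fit <- function(x, ...) {
  cat(sprintf(
    "<bindgraph_fit> %d epochs, final loss %.5f (%d train nodes, %d synthetic)\n",
    length(x$loss_history), x$loss_history[[length(x$loss_history)]],
    x$n_train_nodes, x$n_synthetic))
  invisible(x)
}

#' Per-residue binding probabilities for new graphs
#'
#' @param object a `bindgraph_fit`.
#' @param graphs a [protein_graph()] or list of them.
#' @param ... unused.
#' @return Data frame with columns `chain_id`, `residue_index`,
#'   `prob_binding`, one row per residue.
#' @export
predict.bindgraph_fit <- function(object, graphs, ...) {
  if (inherits(graphs, "protein_graph")) graphs <- list(graphs)
  do.call(rbind, lapply(graphs, function(g) {
    P <- model_forward(g, object$model)
    data.frame(chain_id = rep(g$chain_id[[1L]], nrow(P)),
               residue_index = g$node_ids,
               prob_binding = P[, 2L])
  }))
}

#' Evaluate a fitted model on held-out graphs
#'
#' Pools the residues of all supplied graphs (dataset-level reporting, not
#' per-chain averaging) and computes the confusion-matrix metrics at the
#' decision threshold plus the threshold-free rank AUC. Synthetic nodes
#' are never part of the supplied evaluation graphs, so they cannot
#' contribute.
#'
#' @param fit a `bindgraph_fit`.
#' @param graphs held-out [protein_graph()]s.
#' @param threshold decision threshold; defaults to the training config's.
#' @return A `metrics_report` (see [compute_metrics()]).
#' @export
evaluate <- function(fit, graphs, threshold = fit$config$threshold) {
  if (inherits(graphs, "protein_graph")) graphs <- list(graphs)
  assert_that(!any(vapply(graphs, inherits, logical(1), "augmented_graph")),
              "evaluation graphs must not contain synthetic nodes")
  p <- unlist(lapply(graphs, function(g) model_forward(g, fit$model)[, 2L]))
  y <- unlist(lapply(graphs, `[[`, "labels"))
  cc <- confusion_counts(p, y, threshold)
  rep <- compute_metrics(cc[["TP"]], cc[["FP"]], cc[["TN"]], cc[["FN"]])
  rep$AUC <- auc_score(p, y)
  rep$threshold <- threshold
  rep
}

#' Save a fitted model checkpoint
#'
#' Writes the weights as a single RDS file and a human-readable DCF
#' manifest (`<path>.manifest`) recording all hyperparameters and the RNG
#' seed, sufficient to reproduce the run.
#'
#' @param fit a `bindgraph_fit`.
#' @param path checkpoint file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  cfg <- fit$config
  manifest <- data.frame(
    package_version = as.character(utils::packageVersion("bindgraph")),
    epochs = cfg$epochs, learning_rate = cfg$learning_rate, seed = cfg$seed,
    threshold = cfg$threshold,
    sage_dims = paste(cfg$sage_dims, collapse = ","),
    mlp_dims = paste(cfg$mlp_dims, collapse = ","),
    aggregation = cfg$aggregation,
    focal_alpha = cfg$loss$alpha, focal_gamma = cfg$loss$gamma,
    oversample = !is.null(cfg$oversample),
    target_ratio = if (is.null(cfg$oversample)) NA else cfg$oversample$target_ratio,
    k_neighbors = if (is.null(cfg$oversample)) NA else cfg$oversample$k_neighbors,
    edge_strategy = if (is.null(cfg$oversample)) NA else cfg$oversample$edge_strategy)
  write.dcf(manifest, paste0(path, ".manifest"))
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file path.
#' @return The `bindgraph_fit`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop_bindgraph(sprintf("checkpoint not found: %s", path),
                   "bindgraph_io_error")
  readRDS(path)
}
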