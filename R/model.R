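#' Focal-loss configuration
#'
#' Focal loss down-weights easy examples: `L = -alpha * (1 - p_t)^gamma *
#' log(p_t)`, where `p_t` is the predicted probability of the true class.
#' With `gamma = 0, alpha = 1` it reduces to plain cross-entropy.
#'
#' @param alpha class-balance weight in (0, 1].
#' @param gamma focusing exponent, >= 0.
#' @return A `focal_loss_config` list.
#' @export
focal_loss_config <- function(alpha = 0.25, gamma = 2) {
  assert_that(is.numeric(alpha) && alpha > 0 && alpha <= 1,
              "alpha must be in (0, 1]")
  assert_that(is.numeric(gamma) && gamma >= 0, "gamma must be >= 0")
  structure(list(alpha = alpha, gamma = gamma), class = "focal_loss_config")
}

#' Focal loss for binary node classification
#'
#' `p_t` is `p_pos` for positive nodes and `1 - p_pos` for negative nodes;
#' the log is guarded by clamping `p_t` at 1e-12, where the raw formula is
#' undefined.
#'
#' @param p_pos predicted positive-class probabilities in \[0, 1\].
#' @param y true labels in \{0, 1\}.
#' @param cfg a [focal_loss_config()].
#' @param reduce `"mean"` for the batch loss, `"none"` for per-node values.
#' @return Non-negative loss (scalar or vector).
#' @export
focal_loss <- function(p_pos, y, cfg = focal_loss_config(),
                       reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  assert_that(length(p_pos) == length(y), "p_pos and y differ in length",
              "bindgraph_shape_error")
  assert_that(all(p_pos >= 0 & p_pos <= 1), "probabilities must lie in [0, 1]")
  assert_that(all(y %in% c(0L, 1L)), "labels must be 0 or 1",
              "bindgraph_label_error")
  p_t <- ifelse(y == 1L, p_pos, 1 - p_pos)
  p_t <- pmax(p_t, 1e-12)
  l <- -cfg$alpha * (1 - p_t)^cfg$gamma * log(p_t)
  if (reduce == "mean") mean(l) else l
}

leaky_relu <- function(z, slope = 0.01) ifelse(z > 0, z, slope * z)

softmax_rows <- function(Z) {
  Z <- Z - Z[cbind(seq_len(nrow(Z)), max.col(Z, "first"))]  # stabilised
  E <- exp(Z)
  E / rowSums(E)
}

# Glorot-uniform weight matrix (n_in x n_out)
glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), nrow = n_in, ncol = n_out)
}

#' SAGE layer parameters
#'
#' One neighbour-aggregation layer: each node's own feature vector `h_i`
#' is concatenated with the aggregate `n_i` of its neighbours' features
#' (sum by default), linearly mapped and passed through ReLU:
#' `h_i' = ReLU(W [h_i, n_i] + b)`.
#'
#' @param d_in,d_out input and output widths.
#' @return List with `W` (`2*d_in x d_out`) and `b` (length `d_out`).
#' @export
sage_layer_params <- function(d_in, d_out) {
  list(W = glorot(2L * d_in, d_out), b = rep(0, d_out))
}

#' MLP head parameters
#'
#' Input layer, two LeakyReLU hidden layers, and a softmax output layer
#' over `K` classes.
#'
#' @param d_in input width; `h1,h2` hidden widths; `K` number of classes.
#' @return List of weight matrices and bias vectors `W1,b1,W2,b2,Wout,bout`.
#' @export
mlp_params <- function(d_in, h1, h2, K = 2L) {
  list(W1 = glorot(d_in, h1), b1 = rep(0, h1),
       W2 = glorot(h1, h2),   b2 = rep(0, h2),
       Wout = glorot(h2, K),  bout = rep(0, K))
}

#' Initialise a SAGE+MLP node classifier
#'
#' Stacked SAGE neighbour-aggregation layers feeding a two-hidden-layer
#' MLP with softmax output. Hidden widths and the aggregation rule (sum by
#' default, printed-formula style; mean available) are configurable.
#'
#' @param input_dim node-feature dimension D.
#' @param sage_dims widths of the SAGE layers (default `c(256, 256)`).
#' @param mlp_dims widths of the two MLP hidden layers (default
#'   `c(128, 64)`).
#' @param n_classes number of output classes (2).
#' @param leaky_slope negative slope of the hidden LeakyReLU (0.01).
#' @param aggregation `"sum"` or `"mean"` neighbour aggregation.
#' @param seed RNG seed for the Glorot initialisation.
#' @return An object of class `sage_mlp`.
#' @export
sage_mlp <- function(input_dim, sage_dims = c(256L, 256L),
                     mlp_dims = c(128L, 64L), n_classes = 2L,
                     leaky_slope = 0.01, aggregation = c("sum", "mean"),
                     seed = 1L) {
  aggregation <- match.arg(aggregation)
  assert_that(n_classes >= 2L, "n_classes must be >= 2")
  with_local_seed(seed, {
    dims <- c(input_dim, sage_dims)
    sage <- lapply(seq_along(sage_dims), function(l)
      sage_layer_params(dims[[l]], dims[[l + 1L]]))
    mlp <- mlp_params(dims[[length(dims)]], mlp_dims[[1L]], mlp_dims[[2L]],
                      n_classes)
    structure(list(sage = sage, mlp = mlp, input_dim = as.integer(input_dim),
                   sage_dims = as.integer(sage_dims),
                   mlp_dims = as.integer(mlp_dims),
                   n_classes = as.integer(n_classes),
                   leaky_slope = leaky_slope, aggregation = aggregation,
                   seed = as.integer(seed)),
              class = "sage_mlp")
  })
}

# Aggregation operator: sparse matrix S with n_i = (S H)_i.
#
# For an augmented graph the operator is direction-aware and interpolated:
# base residues aggregate only over base edges (their representations are
# then identical with and without the synthetic nodes, so what is learned
# on the augmented training graph transfers unchanged to evaluation
# graphs), while each synthetic node's incoming row is the convex
# combination (1-lambda) * row(source) + lambda * row(neighbour) of its
# interpolation endpoints' rows. A synthetic node's layer input is thereby
# the same interpolation in aggregate space as in feature space at every
# layer, which keeps synthetic nodes distributionally indistinguishable
# from real minority nodes and closes the train/test shift that symmetric
# wiring of synthetic edges would introduce.
aggregation_operator <- function(graph, aggregation = "sum") {
  if (inherits(graph, "augmented_graph") && nrow(graph$provenance) > 0L) {
    nb <- nrow(graph$base$features)
    n <- nrow(graph$features)
    A <- graph_adjacency(graph$base)
    if (aggregation == "mean") {
      deg <- Matrix::rowSums(A)
      A <- Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0)) %*% A
    }
    prov <- graph$provenance
    Wsyn <- (1 - prov$lambda) * A[prov$source_id, , drop = FALSE] +
      prov$lambda * A[prov$neighbor_id, , drop = FALSE]
    zero_tr <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                    dims = c(nb, n - nb))
    zero_br <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                    dims = c(n - nb, n - nb))
    return(Matrix::drop0(rbind(cbind(A, zero_tr), cbind(Wsyn, zero_br))))
  }
  A <- graph_adjacency(graph)
  if (aggregation == "mean") {
    deg <- Matrix::rowSums(A)
    A <- Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0)) %*% A
  }
  Matrix::drop0(A)
}

#' One SAGE forward pass over a node-feature matrix
#'
#' For every node i: `n_i` = aggregate of neighbour rows (sum by default;
#' the zero vector for isolated nodes), `h_i' = [h_i, n_i]`, output row
#' `ReLU(W' h_i' + b)`.
#'
#' @param H numeric n x d matrix of node features.
#' @param edges two-column undirected edge matrix (1-based).
#' @param params a [sage_layer_params()] list.
#' @param aggregation `"sum"` or `"mean"`.
#' @return n x d_out matrix of updated node features.
#' @export
sage_forward <- function(H, edges, params, aggregation = "sum") {
  H <- as.matrix(H)
  assert_that(all(is.finite(H)), "H must be finite")
  assert_that(2L * ncol(H) == nrow(params$W),
              sprintf("W expects concatenated width %d, got feature width %d",
                      nrow(params$W), ncol(H)), "bindgraph_shape_error")
  g <- protein_graph(features = H, edges = edges,
                     labels = rep(0L, nrow(H)))
  S <- aggregation_operator(g, aggregation)
  N <- as.matrix(S %*% H)
  Z <- cbind(H, N) %*% params$W +
    matrix(params$b, nrow(H), length(params$b), byrow = TRUE)
  pmax(Z, 0)
}

#' MLP head forward pass for a single feature vector
#'
#' Two LeakyReLU hidden layers followed by a softmax output layer; the
#' result is a probability distribution over the classes.
#'
#' @param x numeric input vector.
#' @param params a [mlp_params()] list.
#' @param leaky_slope negative slope of the LeakyReLU.
#' @return Probability vector of length K (positive, sums to 1).
#' @export
mlp_forward <- function(x, params, leaky_slope = 0.01) {
  assert_that(length(x) == nrow(params$W1), "input width mismatch",
              "bindgraph_shape_error")
  a1 <- leaky_relu(drop(x %*% params$W1) + params$b1, leaky_slope)
  a2 <- leaky_relu(drop(a1 %*% params$W2) + params$b2, leaky_slope)
  zout <- drop(a2 %*% params$Wout) + params$bout
  drop(softmax_rows(matrix(zout, nrow = 1L)))
}

# Full forward pass with caches for backpropagation. `dropout` > 0
# activates inverted dropout (training mode) after every SAGE ReLU and
# after each MLP hidden activation; masks are kept in the cache so the
# backward pass gates the same units. Raw input features are not dropped:
# they are low-dimensional and dense, and deleting them removes signal
# rather than co-adaptation. dropout = 0 (evaluation) is deterministic.
model_forward_cache <- function(model, features, S, dropout = 0) {
  drop_gate <- function(X) {
    if (dropout <= 0) return(list(X = X, M = NULL))
    M <- matrix(stats::runif(length(X)) >= dropout, nrow(X), ncol(X))
    list(X = X * M / (1 - dropout), M = M)
  }
  H <- as.matrix(features)
  sage_cache <- vector("list", length(model$sage))
  for (l in seq_along(model$sage)) {
    p <- model$sage[[l]]
    N <- as.matrix(S %*% H)
    Hc <- cbind(H, N)
    Z <- Hc %*% p$W + matrix(p$b, nrow(H), length(p$b), byrow = TRUE)
    gl <- drop_gate(pmax(Z, 0))
    sage_cache[[l]] <- list(Hc = Hc, Z = Z, M = gl$M)
    H <- gl$X
  }
  m <- model$mlp
  s <- model$leaky_slope
  Z1 <- H %*% m$W1 + matrix(m$b1, nrow(H), length(m$b1), byrow = TRUE)
  g1 <- drop_gate(leaky_relu(Z1, s))
  Z2 <- g1$X %*% m$W2 + matrix(m$b2, nrow(H), length(m$b2), byrow = TRUE)
  g2 <- drop_gate(leaky_relu(Z2, s))
  Zout <- g2$X %*% m$Wout + matrix(m$bout, nrow(H), length(m$bout), byrow = TRUE)
  P <- softmax_rows(Zout)
  list(P = P, H_sage = H, Z1 = Z1, A1 = g1$X, Z2 = Z2, A2 = g2$X,
       M1 = g1$M, M2 = g2$M, sage_cache = sage_cache, dropout = dropout)
}

#' Per-node class probabilities of a graph
#'
#' Runs the stacked SAGE layers and the MLP head over every node
#' (including synthetic nodes when the graph is augmented).
#'
#' @param graph a [protein_graph()] or `augmented_graph`.
#' @param model a [sage_mlp()].
#' @return n x K matrix of probabilities; each row sums to 1. Column 2 is
#'   the positive (binding) class for the binary case.
#' @export
model_forward <- function(graph, model) {
  assert_that(ncol(graph$features) == model$input_dim,
              sprintf("graph features have width %d but model expects %d",
                      ncol(graph$features), model$input_dim),
              "bindgraph_shape_error")
  S <- aggregation_operator(graph, model$aggregation)
  model_forward_cache(model, graph$features, S)$P
}

# Backward pass of mean focal loss over masked nodes wrt all parameters.
# Returns gradients in the same nested shape as the model parameters.
model_backward <- function(model, graph, S, cache, loss_cfg, mask) {
  P <- cache$P
  n <- nrow(P)
  y <- graph$labels
  idx_t <- cbind(seq_len(n), y + 1L)       # true-class column per node
  p_t <- pmax(P[idx_t], 1e-12)
  a <- loss_cfg$alpha; g <- loss_cfg$gamma
  # dL/dp_t for L = -a (1-p)^g log p; 1-p_t clamped so the g-1 power is
  # finite as p_t -> 1
  omp <- pmax(1 - p_t, 1e-12)
  dLdp <- a * g * omp^(g - 1) * log(p_t) - a * omp^g / p_t
  if (g == 0) dLdp <- -a / p_t
  w <- as.numeric(mask) / sum(mask)        # mean over masked nodes
  # softmax jacobian: dL/dz_k = dLdp * p_t * (delta_kt - p_k)
  Gz <- -P * (dLdp * p_t * w)
  Gz[idx_t] <- Gz[idx_t] + dLdp * p_t * w

  m <- model$mlp; s <- model$leaky_slope
  dr <- cache$dropout %||% 0
  gate <- function(dX, M) if (is.null(M)) dX else dX * M / (1 - dr)
  grads <- list(mlp = list(), sage = vector("list", length(model$sage)))
  grads$mlp$Wout <- t(cache$A2) %*% Gz
  grads$mlp$bout <- colSums(Gz)
  dA2 <- gate(Gz %*% t(m$Wout), cache$M2)
  dZ2 <- dA2 * ifelse(cache$Z2 > 0, 1, s)
  grads$mlp$W2 <- t(cache$A1) %*% dZ2
  grads$mlp$b2 <- colSums(dZ2)
  dA1 <- gate(dZ2 %*% t(m$W2), cache$M1)
  dZ1 <- dA1 * ifelse(cache$Z1 > 0, 1, s)
  grads$mlp$W1 <- t(cache$H_sage) %*% dZ1
  grads$mlp$b1 <- colSums(dZ1)
  dH <- dZ1 %*% t(m$W1)

  St <- Matrix::t(S)
  for (l in rev(seq_along(model$sage))) {
    cc <- cache$sage_cache[[l]]
    p <- model$sage[[l]]
    dZ <- gate(dH, cc$M) * (cc$Z > 0)
    grads$sage[[l]] <- list(W = t(cc$Hc) %*% dZ, b = colSums(dZ))
    dHc <- dZ %*% t(p$W)
    d_in <- ncol(cc$Hc) / 2L
    dH <- dHc[, seq_len(d_in), drop = FALSE] +
      as.matrix(St %*% dHc[, d_in + seq_len(d_in), drop = FALSE])
  }
  grads
}
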