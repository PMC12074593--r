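# independent per-node oracle for one SAGE layer: explicit loops, no
# matrix algebra shared with the implementation
sage_oracle <- function(H, edges, params, aggregation = "sum") {
  n <- nrow(H)
  out <- matrix(0, n, length(params$b))
  for (i in seq_len(n)) {
    nb <- c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])
    n_i <- rep(0, ncol(H))
    for (j in nb) n_i <- n_i + H[j, ]
    if (aggregation == "mean" && length(nb) > 0) n_i <- n_i / length(nb)
    z <- as.numeric(c(H[i, ], n_i) %*% params$W) + params$b
    out[i, ] <- pmax(z, 0)
  }
  out
}

test_that("an isolated node aggregates the zero vector", {
  h <- matrix(c(0.5, 1.2, 0.3), 1, 3)
  params <- list(W = diag(6), b = rep(0, 6))
  out <- sage_forward(h, NULL, params)
  expect_equal(as.numeric(out), c(0.5, 1.2, 0.3, 0, 0, 0))
})

test_that("neighbour features sum into the aggregate channel", {
  H <- rbind(c(0, 0), c(1, 0), c(0, 1))
  edges <- rbind(c(1L, 2L), c(1L, 3L))
  # W reads out only the aggregate half of the concatenation
  params <- list(W = rbind(matrix(0, 2, 2), diag(2)), b = c(0, 0))
  out <- sage_forward(H, edges, params)
  expect_equal(out[1L, ], c(1, 1))   # n_1 = h_2 + h_3
  expect_equal(out[2L, ], c(0, 0))   # n_2 = h_1 = (0,0)
})

test_that("a path graph matches hand arithmetic through the layer", {
  H <- rbind(c(1, 0), c(0, 1), c(1, 1), c(2, 0))
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  set.seed(2)
  params <- list(W = matrix(rnorm(4 * 3), 4, 3), b = c(0.1, -0.2, 0))
  expect_equal(sage_forward(H, edges, params),
               sage_oracle(H, edges, params))
})

test_that("sage layers agree with the per-node loop oracle on random graphs", {
  for (s in 1:10) {
    g <- random_graph(n = 5L + (s %% 15L), d = 3L, n_pos = 2L, seed = s)
    set.seed(s + 100)
    params <- list(W = matrix(rnorm(6 * 4), 6, 4), b = rnorm(4))
    for (agg in c("sum", "mean")) {
      expect_equal(sage_forward(g$features, g$edges, params, agg),
                   sage_oracle(g$features, g$edges, params, agg),
                   tolerance = 1e-12)
    }
  }
})

test_that("the MLP head returns a probability distribution", {
  set.seed(1)
  params <- mlp_params(4L, 3L, 3L)
  for (i in 1:20) {
    p <- mlp_forward(rnorm(4), params)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p > 0))
  }
  expect_error(mlp_forward(rnorm(5), params), class = "bindgraph_shape_error")
})

test_that("symmetric logits give the uniform distribution", {
  params <- list(W1 = matrix(0, 2, 3), b1 = rep(0, 3),
                 W2 = matrix(0, 3, 3), b2 = rep(0, 3),
                 Wout = matrix(0, 3, 2), bout = c(0, 0))
  expect_equal(mlp_forward(c(1, 2), params), c(0.5, 0.5))
})

test_that("the MLP matches a direct evaluation of its defining formulas", {
  params <- list(W1 = rbind(c(1, -1), c(0.5, 2)), b1 = c(0.1, -0.1),
                 W2 = rbind(c(2, 0), c(-1, 1)), b2 = c(0, 0.2),
                 Wout = rbind(c(1, -1), c(0.5, 0.5)), bout = c(0, 0))
  x <- c(0.3, -0.7)
  lrelu <- function(z) ifelse(z > 0, z, 0.01 * z)
  a1 <- lrelu(as.numeric(x %*% params$W1) + params$b1)
  a2 <- lrelu(as.numeric(a1 %*% params$W2) + params$b2)
  z <- as.numeric(a2 %*% params$Wout) + params$bout
  expect_equal(mlp_forward(x, params), exp(z) / sum(exp(z)),
               tolerance = 1e-12)
})

test_that("focal loss reduces to cross-entropy at gamma 0, alpha 1", {
  p_grid <- seq(0.05, 0.95, by = 0.05)
  ce_cfg <- focal_loss_config(alpha = 1, gamma = 0)
  expect_equal(focal_loss(p_grid, rep(1L, length(p_grid)), ce_cfg,
                          reduce = "none"),
               -log(p_grid), tolerance = 1e-12)
  expect_equal(focal_loss(p_grid, rep(0L, length(p_grid)), ce_cfg,
                          reduce = "none"),
               -log(1 - p_grid), tolerance = 1e-12)
})

test_that("focal loss is zero at certainty and matches the hand-computed point", {
  expect_equal(focal_loss(1, 1L, focal_loss_config(0.25, 2)), 0)
  expect_equal(focal_loss(0, 0L, focal_loss_config(0.25, 2)), 0)
  # alpha 0.25, gamma 2, p_t = 0.5: 0.25 * 0.25 * (-log 0.5)
  expect_equal(focal_loss(0.5, 1L, focal_loss_config(0.25, 2)),
               0.25 * 0.25 * log(2), tolerance = 1e-6)
  expect_equal(focal_loss(0.5, 1L, focal_loss_config(0.25, 2)), 0.0433217,
               tolerance = 1e-6)
})

test_that("focal loss is non-negative and strictly decreasing in p_t", {
  for (cfg in list(focal_loss_config(0.25, 2), focal_loss_config(1, 0),
                   focal_loss_config(0.5, 1))) {
    p <- seq(0.01, 0.99, by = 0.01)
    l <- focal_loss(p, rep(1L, length(p)), cfg, reduce = "none")
    expect_true(all(l >= 0))
    expect_true(all(diff(l) < 0))
  }
  expect_error(focal_loss(1.2, 1L, focal_loss_config()), "\\[0, 1\\]")
})

test_that("model forward yields one probability row per node", {
  g1 <- protein_graph(matrix(rnorm(3), 1, 3), NULL, 1L)
  m <- sage_mlp(3L, sage_dims = c(4L), mlp_dims = c(4L, 3L), seed = 1L)
  P <- model_forward(g1, m)
  expect_equal(dim(P), c(1L, 2L))
  expect_equal(rowSums(P), 1, tolerance = 1e-9)

  g <- random_graph(n = 15L, d = 3L, seed = 2L)
  P2 <- model_forward(g, m)
  expect_equal(nrow(P2), 15L)
  expect_equal(unname(rowSums(P2)), rep(1, 15L), tolerance = 1e-9)
})

test_that("all-zero features with zero biases predict the uniform distribution", {
  g <- random_graph(n = 8L, d = 3L, seed = 3L)
  g$features[] <- 0
  m <- sage_mlp(3L, sage_dims = c(4L), mlp_dims = c(4L, 3L), seed = 1L)
  P <- model_forward(g, m)
  expect_equal(P, matrix(0.5, 8L, 2L), tolerance = 1e-12)
})

test_that("node relabelling permutes the output rows identically", {
  g <- random_graph(n = 12L, d = 3L, n_pos = 3L, seed = 4L)
  m <- sage_mlp(3L, sage_dims = c(5L, 4L), mlp_dims = c(4L, 3L), seed = 2L)
  P <- model_forward(g, m)
  set.seed(9)
  perm <- sample.int(12L)
  inv <- order(perm)
  g2 <- protein_graph(g$features[perm, ], cbind(inv[g$edges[, 1]],
                                                inv[g$edges[, 2]]),
                      g$labels[perm])
  expect_equal(model_forward(g2, m), P[perm, ], tolerance = 1e-10)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(1)
  g <- random_graph(n = 10L, d = 4L, n_pos = 4L, seed = 5L)
  model <- sage_mlp(4L, sage_dims = c(5L), mlp_dims = c(4L, 3L), seed = 3L)
  S <- bindgraph:::aggregation_operator(g, "sum")
  loss_cfg <- focal_loss_config(0.7, 2)
  mask <- rep(TRUE, 10L)
  lossfun <- function(m) {
    cache <- bindgraph:::model_forward_cache(m, g$features, S)
    focal_loss(cache$P[, 2L][mask], g$labels[mask], loss_cfg)
  }
  cache <- bindgraph:::model_forward_cache(model, g$features, S)
  gr <- bindgraph:::model_backward(model, g, S, cache, loss_cfg, mask)
  eps <- 1e-6
  numgrad <- function(get, set) {
    W <- get(model)
    out <- W * 0
    for (i in seq_along(W)) {
      up <- set(model, `[<-`(W, i, W[i] + eps))
      dn <- set(model, `[<-`(W, i, W[i] - eps))
      out[i] <- (lossfun(up) - lossfun(dn)) / (2 * eps)
    }
    out
  }
  expect_equal(numgrad(function(m) m$sage[[1]]$W,
                       function(m, v) { m$sage[[1]]$W <- v; m }),
               unname(gr$sage[[1]]$W), tolerance = 1e-6)
  expect_equal(numgrad(function(m) m$mlp$W2,
                       function(m, v) { m$mlp$W2 <- v; m }),
               unname(gr$mlp$W2), tolerance = 1e-6)
  expect_equal(numgrad(function(m) m$mlp$bout,
                       function(m, v) { m$mlp$bout <- v; m }),
               unname(gr$mlp$bout), tolerance = 1e-6)
})

test_that("feature width mismatches are rejected", {
  g <- random_graph(n = 5L, d = 3L, seed = 1L)
  m <- sage_mlp(4L, sage_dims = c(4L), mlp_dims = c(3L, 3L), seed = 1L)
  expect_error(model_forward(g, m), class = "bindgraph_shape_error")
})
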