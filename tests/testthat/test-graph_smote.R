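test_that("the rarer training class is identified by counting, not assumption", {
  g <- protein_graph(matrix(0, 5, 2), NULL, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(identify_minority_nodes(g), 1L)

  # majority-positive graph: minority is the negative class
  g2 <- protein_graph(matrix(0, 5, 2), NULL, c(1L, 1L, 1L, 1L, 0L))
  expect_equal(identify_minority_nodes(g2), 5L)

  # exact tie: nothing to oversample
  g3 <- protein_graph(matrix(0, 6, 2), NULL, rep(c(0L, 1L), 3))
  expect_length(identify_minority_nodes(g3), 0L)

  g4 <- protein_graph(matrix(0, 4, 2), NULL, rep(0L, 4))
  expect_error(identify_minority_nodes(g4),
               class = "bindgraph_degenerate_error")
})

test_that("a Table-1-like imbalance marks the binding class as minority", {
  labels <- rep(c(1L, 0L), c(50L, 954L))  # ~4.98% positives
  g <- protein_graph(matrix(0, length(labels), 2), NULL, labels)
  mins <- identify_minority_nodes(g)
  expect_true(all(g$labels[mins] == 1L))
  expect_length(mins, 50L)
})

test_that("nearest minority neighbours rank by feature distance with id tie-break", {
  feats <- matrix(c(0, 0.1, 5, 0.5), ncol = 1L)
  g <- protein_graph(feats, NULL, c(1L, 1L, 1L, 0L))
  expect_equal(nearest_minority_neighbors(1L, g, 1L), 2L)

  # equidistant candidates: lower node id first
  feats2 <- matrix(c(0, 1, -1, 9), ncol = 1L)
  g2 <- protein_graph(feats2, NULL, c(1L, 1L, 1L, 0L))
  expect_equal(nearest_minority_neighbors(1L, g2, 2L), c(2L, 3L))

  g3 <- protein_graph(matrix(0, 3, 1), NULL, c(1L, 0L, 0L))
  expect_error(nearest_minority_neighbors(1L, g3, 1L),
               class = "bindgraph_isolation_error")
})

test_that("neighbour search matches an exhaustive distance sort on a random fixture", {
  set.seed(7)
  feats <- matrix(rnorm(50 * 4), 50, 4)
  labels <- rep(0L, 50); labels[sample.int(50, 20)] <- 1L
  g <- protein_graph(feats, NULL, labels)
  minority <- which(labels == 1L)
  for (node in minority[1:5]) {
    cand <- setdiff(minority, node)
    d <- sqrt(colSums((t(feats[cand, ]) - feats[node, ])^2))
    expected <- cand[order(d, cand)][1:5]
    expect_equal(nearest_minority_neighbors(node, g, 5L), expected)
  }
})

test_that("interpolation hits its endpoints and midpoints exactly", {
  expect_equal(synthesize_node(c(1, 2), c(3, 8), 0), c(1, 2))
  expect_equal(synthesize_node(c(1, 2), c(3, 8), 1), c(3, 8))
  expect_equal(synthesize_node(c(0, 0), c(2, 4), 0.5), c(1, 2))
  expect_error(synthesize_node(c(1, 2), c(1, 2, 3), 0.5),
               class = "bindgraph_shape_error")
  expect_error(synthesize_node(c(1, 2), c(3, 4), 1.5), "lambda")
})

test_that("edge strategies wire synthetic nodes as specified", {
  # node 1 (source) has neighbours 3 and 7
  edges <- rbind(c(1L, 3L), c(1L, 7L), c(2L, 5L))
  g <- protein_graph(matrix(rnorm(16), 8, 2), edges,
                     c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(
    bindgraph:::synthetic_edge_targets(g, 1L, 2L, "inherit-source", 5L),
    c(1L, 3L, 7L))
  # union of both endpoints' neighbourhoods plus the endpoints
  expect_equal(
    bindgraph:::synthetic_edge_targets(g, 1L, 2L, "inherit-union", 5L),
    c(1L, 2L, 3L, 5L, 7L))
  # isolated source: the single anchoring edge to the source remains
  g_iso <- protein_graph(matrix(rnorm(8), 4, 2), rbind(c(2L, 3L)),
                         c(1L, 1L, 0L, 0L))
  expect_equal(
    bindgraph:::synthetic_edge_targets(g_iso, 1L, 2L, "inherit-source", 5L),
    1L)
})

test_that("inherit-union edge count follows set arithmetic on a fixed graph", {
  # neighbourhoods N(1) = {2,3}, N(4) = {3,5}; union with endpoints
  # {1,4} gives {1,2,3,4,5}: |N1 u N4| + 2 - |{1,4} n (N1 u N4)| = 4+2-1
  edges <- rbind(c(1L, 2L), c(1L, 3L), c(4L, 3L), c(4L, 5L))
  g <- protein_graph(matrix(0, 6, 2), edges, c(1L, 0L, 0L, 1L, 0L, 0L))
  targets <- bindgraph:::synthetic_edge_targets(g, 1L, 4L, "inherit-union", 5L)
  expect_length(targets, 5L)
  expect_equal(targets, 1:5)
})

test_that("oversampling reaches the target count and records provenance", {
  set.seed(3)
  g <- protein_graph(matrix(rnorm(24), 12, 2), NULL,
                     rep(c(1L, 0L), c(2L, 10L)))
  aug <- oversample(g, oversample_config(seed = 5L))
  expect_s3_class(aug, "augmented_graph")
  expect_equal(nrow(aug$provenance), 8L)  # 10 majority - 2 minority
  expect_equal(sum(aug$labels == 1L), 10L)
  expect_true(all(aug$provenance$source_id %in% 1:2))
  expect_true(all(aug$provenance$lambda >= 0 & aug$provenance$lambda <= 1))
  # every synthetic node is anchored by at least one edge
  for (id in aug$provenance$new_id)
    expect_gte(length(bindgraph:::node_neighbors(aug, id)), 1L)
})

test_that("oversampling to the current ratio is a no-op", {
  g <- protein_graph(matrix(rnorm(24), 12, 2), NULL,
                     rep(c(1L, 0L), c(4L, 8L)))
  aug <- oversample(g, oversample_config(target_ratio = 0.5, seed = 1L))
  expect_equal(nrow(aug$provenance), 0L)
  expect_equal(aug$features, g$features)
  expect_equal(aug$labels, g$labels)
})

test_that("a tied training set oversamples to a warned no-op", {
  g <- protein_graph(matrix(rnorm(12), 6, 2), NULL, rep(c(0L, 1L), 3))
  expect_warning(aug <- oversample(g, oversample_config(seed = 1L)),
                 "no-op")
  expect_equal(nrow(aug$provenance), 0L)
})

test_that("oversampling is reproducible under a fixed seed", {
  ds <- make_synthetic_dataset(n_chains = 3L, chain_len = 60L,
                               binding_fraction = 0.08, seed = 7L)
  g <- batch_graphs(ds$train)
  a <- oversample(g, oversample_config(seed = 7L))
  b <- oversample(g, oversample_config(seed = 7L))
  expect_identical(a$features, b$features)
  expect_identical(a$edges, b$edges)
  expect_identical(a$provenance, b$provenance)
  c_ <- oversample(g, oversample_config(seed = 8L))
  expect_false(identical(a$provenance, c_$provenance))
})

test_that("the base graph is conserved bit-for-bit under augmentation", {
  ds <- make_synthetic_dataset(n_chains = 2L, chain_len = 80L,
                               binding_fraction = 0.1, seed = 2L)
  g <- batch_graphs(ds$train)
  before <- list(f = g$features, e = g$edges, l = g$labels)
  aug <- oversample(g, oversample_config(seed = 3L))
  n_base <- nrow(g$features)
  expect_identical(aug$base$features, before$f)
  expect_identical(aug$features[seq_len(n_base), ], before$f)
  expect_identical(aug$labels[seq_len(n_base)], before$l)
  base_keys <- edge_key(before$e)
  expect_true(all(base_keys %in% edge_key(aug$edges)))
  # synthetic edges all touch a synthetic node
  expect_true(all(aug$synthetic_edges[, 2L] > n_base |
                  aug$synthetic_edges[, 1L] > n_base))
})

test_that("synthetic features stay on the segment between their endpoints", {
  ds <- make_synthetic_dataset(n_chains = 2L, chain_len = 80L,
                               binding_fraction = 0.1, seed = 4L)
  g <- batch_graphs(ds$train)
  aug <- oversample(g, oversample_config(seed = 9L))
  prov <- aug$provenance
  for (m in seq_len(nrow(prov))) {
    x <- aug$features[prov$new_id[[m]], ]
    a <- g$features[prov$source_id[[m]], ]
    b <- g$features[prov$neighbor_id[[m]], ]
    expect_true(all(x >= pmin(a, b) - 1e-12 & x <= pmax(a, b) + 1e-12))
    expect_equal(x, a + prov$lambda[[m]] * (b - a), tolerance = 1e-12)
  }
})

test_that("minority balance lands within one node of the target", {
  for (s in 1:4) {
    set.seed(s)
    n <- 100L + s
    labels <- rep(0L, n); labels[sample.int(n, 7L + s)] <- 1L
    g <- protein_graph(matrix(rnorm(n * 3), n, 3), NULL, labels)
    for (ratio in c(0.5, 1.0)) {
      aug <- oversample(g, oversample_config(target_ratio = ratio, seed = s))
      n_min <- sum(aug$labels[aug$train_mask] == 1L)
      n_maj <- sum(aug$labels[aug$train_mask] == 0L)
      expect_lte(abs(n_min - ratio * n_maj), 1)
    }
  }
})

test_that("synthetic nodes live only in the training mask", {
  ds <- make_synthetic_dataset(n_chains = 2L, chain_len = 60L,
                               binding_fraction = 0.1, seed = 6L)
  g <- batch_graphs(ds$train)
  g$train_mask[1:30] <- FALSE  # held-out base nodes
  aug <- oversample(g, oversample_config(seed = 2L))
  syn <- is_synthetic_node(aug)
  expect_true(all(aug$train_mask[syn]))
  expect_identical(aug$train_mask[!syn], g$train_mask)
  # oversampling ignores held-out minority nodes as sources
  expect_true(all(g$train_mask[aug$provenance$source_id]))
  expect_true(all(g$train_mask[aug$provenance$neighbor_id]))
})

test_that("provenance exports as a readable table", {
  g <- protein_graph(matrix(rnorm(20), 10, 2), NULL,
                     rep(c(1L, 0L), c(2L, 8L)))
  aug <- oversample(g, oversample_config(seed = 1L))
  f <- withr::local_tempfile()
  write_provenance(aug, f)
  back <- read.table(f, header = TRUE)
  expect_equal(nrow(back), nrow(aug$provenance))
  expect_named(back, c("new_id", "source_id", "neighbor_id", "lambda"))
})
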