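# shared helpers for building small in-memory fixtures

# a tiny labelled chain with deterministic coordinates
toy_chain <- function(n = 5L, chain_id = "A", label = rep(0L, n)) {
  residue_chain(chain_id = chain_id, residue_index = seq_len(n),
                aa = rep("A", n),
                ca_xyz = cbind(3.8 * seq_len(n), 0, 0),
                label = label)
}

# a small random protein_graph with both classes present
random_graph <- function(n = 20L, d = 4L, n_pos = 4L, p_edge = 0.2,
                         seed = 1L) {
  set.seed(seed)
  feats <- matrix(rnorm(n * d), n, d)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  labels <- rep(0L, n)
  labels[sample.int(n, n_pos)] <- 1L
  protein_graph(feats, pairs[keep, , drop = FALSE], labels)
}

# brute-force contact edges: all-pairs O(n^2) scan, independent of
# build_contact_graph's dist()-based implementation
brute_force_edges <- function(xyz, threshold) {
  n <- nrow(xyz)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < threshold)
        out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (length(out) == 0L) matrix(integer(0), ncol = 2L) else do.call(rbind, out)
}

edge_key <- function(e) {
  if (nrow(e) == 0L) return(character(0))
  sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}
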