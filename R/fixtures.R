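#' Fixture specification for synthetic protein chains
#'
#' Describes a toy chain: length, fraction of binding residues (the
#' benchmark datasets sit in the 4-9% band), whether positives form
#' spatial patches (as real binding interfaces do) or are scattered
#' uniformly, the planted feature effect size, and the seed.
#'
#' @param n_residues chain length (>= 1).
#' @param binding_fraction fraction of residues labelled binding, in
#'   (0, 0.5); the positive count is `round(n * fraction)`.
#' @param spatial_clustering place positives as 1-2 contiguous spatial
#'   patches (`TRUE`, default) or uniformly at random.
#' @param class_shift effect size passed to the synthetic feature
#'   provider.
#' @param seed integer RNG seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 100L, binding_fraction = 0.05,
                         spatial_clustering = TRUE, class_shift = 2,
                         seed = 1L) {
  assert_that(is.numeric(n_residues) && n_residues >= 1,
              "n_residues must be >= 1")
  assert_that(binding_fraction > 0 && binding_fraction < 0.5,
              "binding_fraction must be in (0, 0.5)")
  structure(list(n_residues = as.integer(n_residues),
                 binding_fraction = binding_fraction,
                 spatial_clustering = isTRUE(spatial_clustering),
                 class_shift = class_shift, seed = as.integer(seed)),
            class = "fixture_spec")
}

# self-avoiding random walk with fixed step length and excluded volume
random_walk_coords <- function(n, step = 3.8, min_sep = 3.0,
                               max_tries = 200L) {
  xyz <- matrix(0, nrow = n, ncol = 3L)
  for (i in seq_len(n)[-1L]) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      u <- stats::rnorm(3L)
      u <- u / sqrt(sum(u^2))
      cand <- xyz[i - 1L, ] + step * u
      prev <- xyz[seq_len(i - 1L), , drop = FALSE]  # 1 .. i-1
      if (i == 2L || min(sqrt(colSums((t(prev[-nrow(prev), , drop = FALSE]) - cand)^2))) >= min_sep) {
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) xyz[i, ] <- cand  # accept the last candidate; rare
  }
  xyz
}

#' Generate a labelled toy residue chain
#'
#' Coordinates follow a self-avoiding 3-D random walk with ~3.8 Angstrom
#' steps (realistic consecutive C-alpha spacing) and a 3 Angstrom
#' excluded-volume rejection, which yields contact graphs with realistic
#' node degrees under the 8 Angstrom rule. Positives are placed either as
#' 1-2 spatially contiguous patches (seeded at random residues, grown by
#' spatial proximity) or uniformly. Pure function of the spec.
#'
#' @param spec a [fixture_spec()].
#' @param chain_id chain identifier for the result.
#' @return A labelled [residue_chain()].
#' @export
generate_toy_chain <- function(spec = fixture_spec(), chain_id = "A") {
  n <- spec$n_residues
  n_pos <- round(n * spec$binding_fraction)
  assert_that(n_pos >= 1 || spec$binding_fraction == 0,
              sprintf("binding_fraction %.3f yields zero positives at n=%d",
                      spec$binding_fraction, n))
  with_local_seed(spec$seed, {
    xyz <- random_walk_coords(n)
    aa <- sample(STANDARD_AA, n, replace = TRUE)
    label <- rep(0L, n)
    if (n_pos > 0L) {
      if (spec$spatial_clustering && n_pos >= 2L) {
        n_patches <- if (n_pos >= 4L) sample(1:2, 1L) else 1L
        sizes <- if (n_patches == 2L) {
          s1 <- ceiling(n_pos / 2); c(s1, n_pos - s1)
        } else n_pos
        pos <- integer(0)
        for (s in sizes) {
          seed_res <- sample(setdiff(seq_len(n), pos), 1L)
          d <- sqrt(colSums((t(xyz) - xyz[seed_res, ])^2))
          d[pos] <- Inf  # don't reuse residues across patches
          pos <- c(pos, order(d)[seq_len(s)])
        }
        label[pos] <- 1L
      } else {
        label[sample.int(n, n_pos)] <- 1L
      }
    }
    residue_chain(chain_id = chain_id, residue_index = seq_len(n),
                  aa = aa, ca_xyz = xyz, label = label)
  })
}

#' Write a minimal PDB file for a toy chain
#'
#' One CA ATOM record per residue, standard fixed-width PDB formatting
#' (coordinates at 3 decimals), suitable for round-tripping through
#' [read_structure()].
#'
#' @param chain a [residue_chain()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_toy_pdb <- function(chain, path) {
  assert_that(inherits(chain, "residue_chain"), "chain must be a residue_chain")
  n <- length(chain)
  assert_that(n >= 1L, "chain is empty", "bindgraph_empty_chain_error")
  aa3 <- bio3d::aa123(chain$aa)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), aa3, chain$chain_id, chain$residue_index,
    chain$ca_xyz[, 1L], chain$ca_xyz[, 2L], chain$ca_xyz[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a two-column label sidecar file for a chain
#'
#' @param chain a labelled [residue_chain()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(chain, path) {
  assert_that(!is.null(chain$label), "chain carries no labels",
              "bindgraph_label_error")
  writeLines(sprintf("%d %d", chain$residue_index, chain$label), path)
  invisible(path)
}

#' Build a ready-to-train synthetic graph dataset
#'
#' Convenience generator used by the examples and the evaluation scripts:
#' draws `n_chains` toy chains, embeds them with the synthetic feature
#' provider (planting a class signal of size `class_shift`), builds the
#' contact graphs, and splits chains into training and held-out sets.
#'
#' @param n_chains number of chains.
#' @param chain_len residues per chain.
#' @param binding_fraction fraction of binding residues per chain.
#' @param class_shift planted effect size (0 = no signal).
#' @param feature_dim synthetic feature dimension.
#' @param test_fraction fraction of chains held out.
#' @param seed integer RNG seed.
#' @return List with elements `train` and `test`, each a list of
#'   [protein_graph()]s.
#' @export
make_synthetic_dataset <- function(n_chains = 10L, chain_len = 200L,
                                   binding_fraction = 0.05, class_shift = 2,
                                   feature_dim = 32L, test_fraction = 0.3,
                                   seed = 1L) {
  n_test <- max(1L, round(n_chains * test_fraction))
  graphs <- lapply(seq_len(n_chains), function(k) {
    chain <- generate_toy_chain(
      fixture_spec(n_residues = chain_len,
                   binding_fraction = binding_fraction,
                   class_shift = class_shift, seed = seed * 1000L + k),
      chain_id = sprintf("C%02d", k))
    feats <- synthetic_features_for_labels(
      chain$label,
      provider_config(dim = feature_dim, seed = seed,  # shared signal direction
                      # per-chain noise on a stream disjoint from the
                      # geometry stream (seed * 1000 + k) used above
                      noise_seed = seed * 1000L + k + 500000L,
                      class_shift = class_shift))
    build_contact_graph(chain, feats)
  })
  list(train = graphs[seq_len(n_chains - n_test)],
       test = graphs[(n_chains - n_test + 1L):n_chains])
}

#' Emit a fixture dataset as files
#'
#' Writes one PDB, one label file, and one feature matrix (TSV) per chain
#' into a directory — the file-level entry point of the pipeline.
#'
#' @param dir output directory (created if needed).
#' @param n_chains,chain_len,binding_fraction,class_shift,feature_dim,seed
#'   as in [make_synthetic_dataset()].
#' @return Invisibly, a data frame listing the files written.
#' @export
make_fixture_files <- function(dir, n_chains = 3L, chain_len = 60L,
                               binding_fraction = 0.08, class_shift = 2,
                               feature_dim = 16L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n_chains), function(k) {
    chain <- generate_toy_chain(
      fixture_spec(n_residues = chain_len, binding_fraction = binding_fraction,
                   class_shift = class_shift, seed = seed * 1000L + k),
      chain_id = "A")
    feats <- synthetic_features_for_labels(
      chain$label, provider_config(dim = feature_dim, seed = seed,
                                   noise_seed = seed * 1000L + k + 500000L,
                                   class_shift = class_shift))
    stem <- file.path(dir, sprintf("chain%02d", k))
    write_toy_pdb(chain, paste0(stem, ".pdb"))
    write_labels(chain, paste0(stem, ".labels"))
    utils::write.table(feats, paste0(stem, ".features.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    data.frame(pdb = paste0(stem, ".pdb"), labels = paste0(stem, ".labels"),
               features = paste0(stem, ".features.tsv"))
  })
  invisible(do.call(rbind, rows))
}
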