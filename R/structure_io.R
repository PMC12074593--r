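#' Ordered residue chain with C-alpha coordinates
#'
#' Container for one protein chain as used by the contact-graph builder:
#' residue numbers, one-letter amino-acid codes, C-alpha coordinates in
#' Angstroms, and (optionally) per-residue binary binding labels.
#'
#' @param chain_id single chain identifier.
#' @param residue_index integer vector of residue numbers, strictly
#'   increasing (1-based, as in structure files).
#' @param aa character vector of one-letter amino-acid codes.
#' @param ca_xyz numeric matrix with one row per residue and columns
#'   x, y, z (Angstroms).
#' @param label optional integer vector in \{0, 1\}; 1 marks a
#'   DNA-binding residue.
#'
#' @return An object of class `residue_chain`.
#' @export
residue_chain <- function(chain_id, residue_index, aa, ca_xyz, label = NULL) {
  ca_xyz <- as.matrix(ca_xyz)
  n <- length(residue_index)
  assert_that(is.character(chain_id) && length(chain_id) == 1L,
              "chain_id must be a single string")
  assert_that(n >= 1L, "chain must contain at least one residue",
              "bindgraph_empty_chain_error")
  assert_that(length(aa) == n && nrow(ca_xyz) == n && ncol(ca_xyz) == 3L,
              "residue_index, aa and ca_xyz must agree in length",
              "bindgraph_shape_error")
  assert_that(all(diff(residue_index) > 0),
              "residue_index must be strictly increasing")
  assert_that(all(is.finite(ca_xyz)),
              "all C-alpha coordinates must be finite")
  if (!is.null(label)) {
    assert_that(length(label) == n, "label length must match residue count",
                "bindgraph_label_error")
    assert_that(all(label %in% c(0L, 1L)), "labels must be 0 or 1",
                "bindgraph_label_error")
    label <- as.integer(label)
  }
  structure(
    list(chain_id = chain_id,
         residue_index = as.integer(residue_index),
         aa = as.character(aa),
         ca_xyz = unname(ca_xyz),
         label = label),
    class = "residue_chain")
}

#' @export
print.residue_chain <- function(x, ...) {
  cat(sprintf("<residue_chain> chain %s: %d residues%s\n",
              x$chain_id, length(x$residue_index),
              if (is.null(x$label)) " (unlabelled)"
              else sprintf(", %d binding", sum(x$label))))
  invisible(x)
}

#' @export
length.residue_chain <- function(x) length(x$residue_index)

#' Read one chain of a protein structure file
#'
#' Parses a PDB or mmCIF file and extracts the ordered residues of a single
#' chain with their C-alpha coordinates. Only standard polymer residues are
#' kept (HETATM records, waters and non-standard residues are excluded).
#' Residues without a C-alpha atom cannot take part in the contact graph and
#' are dropped with a warning. Alternate locations are resolved to the
#' highest-occupancy C-alpha.
#'
#' @param path path to a `.pdb`, `.ent`, `.cif` or `.mmcif` file.
#' @param chain_id chain identifier to extract (e.g. `"A"`).
#'
#' @return A [residue_chain()] (without labels; see [attach_labels()]).
#' @seealso [build_contact_graph()], [write_toy_pdb()]
#' @export
read_structure <- function(path, chain_id) {
  assert_that(is.character(path) && length(path) == 1L,
              "path must be a single string")
  if (!file.exists(path))
    stop_bindgraph(sprintf("structure file not found: %s", path),
                   "bindgraph_io_error")
  ext <- tolower(tools::file_ext(path))
  # rm.alt = FALSE: alternate locations are resolved here by occupancy,
  # not by the reader's keep-"A" default
  pdb <- if (ext %in% c("cif", "mmcif")) {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE))
  } else {
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
  }
  atoms <- pdb$atom
  if (!chain_id %in% unique(atoms$chain))
    stop_bindgraph(sprintf("chain '%s' not present in %s (chains: %s)",
                           chain_id, basename(path),
                           paste(unique(atoms$chain), collapse = ", ")),
                   "bindgraph_lookup_error")
  atoms <- atoms[atoms$chain == chain_id & atoms$type == "ATOM", , drop = FALSE]
  # standard polymer residues only
  aa1 <- suppressWarnings(bio3d::aa321(atoms$resid))
  atoms <- atoms[aa1 %in% STANDARD_AA, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop_bindgraph(sprintf("chain '%s' has no standard residues with atoms",
                           chain_id), "bindgraph_empty_chain_error")

  resno_all <- sort(unique(atoms$resno))
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  # alternate locations: keep highest occupancy per residue (ties: first)
  if (nrow(ca) > 0L) {
    occ <- ca$o
    occ[is.na(occ)] <- 1
    ord <- order(ca$resno, -occ)
    ca <- ca[ord, , drop = FALSE]
    ca <- ca[!duplicated(ca$resno), , drop = FALSE]
    ca <- ca[order(ca$resno), , drop = FALSE]
  }
  dropped <- setdiff(resno_all, ca$resno)
  if (length(dropped) > 0L)
    warning(sprintf("chain %s: dropped %d residue(s) without a C-alpha atom (%s)",
                    chain_id, length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")),
            call. = FALSE)
  if (nrow(ca) == 0L)
    stop_bindgraph(sprintf("chain '%s' has no residues with C-alpha atoms",
                           chain_id), "bindgraph_empty_chain_error")
  residue_chain(
    chain_id = chain_id,
    residue_index = ca$resno,
    aa = as.character(suppressWarnings(bio3d::aa321(ca$resid))),
    ca_xyz = cbind(ca$x, ca$y, ca$z))
}

#' Read a residue label sidecar file
#'
#' Two formats are accepted: (a) two whitespace-separated columns
#' `residue_index label`, one residue per line; (b) a single line holding a
#' 0/1 string of length L, interpreted as labels for residues in chain
#' order.
#'
#' @param path path to the label file.
#' @return For format (a), a named integer vector of 0/1 labels with
#'   residue indices as names; for format (b), an unnamed 0/1 integer
#'   vector.
#' @export
read_labels <- function(path) {
  if (!file.exists(path))
    stop_bindgraph(sprintf("label file not found: %s", path),
                   "bindgraph_io_error")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  assert_that(length(lines) >= 1L, "label file is empty",
              "bindgraph_label_error")
  if (length(lines) == 1L && grepl("^[01]+$", lines[[1L]])) {
    return(as.integer(strsplit(lines[[1L]], "")[[1L]]))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  assert_that(all(lengths(parts) == 2L),
              "label file must have two columns (residue_index label) or a single 0/1 string",
              "bindgraph_label_error")
  idx <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  lab <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  assert_that(!anyNA(idx) && !anyNA(lab), "label file contains non-numeric entries",
              "bindgraph_label_error")
  assert_that(all(lab %in% c(0L, 1L)),
              "labels must be 0 or 1", "bindgraph_label_error")
  assert_that(!anyDuplicated(idx), "duplicate residue indices in label file",
              "bindgraph_label_error")
  stats::setNames(lab, idx)
}

#' Attach per-residue binding labels to a chain
#'
#' Every retained residue must receive a label; a missing or superfluous
#' entry is an error rather than a silent default, because a mislabelled
#' residue silently poisons training.
#'
#' @param chain a [residue_chain()].
#' @param labels either a path to a sidecar label file (see
#'   [read_labels()]), a named 0/1 vector keyed by residue index, or an
#'   unnamed 0/1 vector of length equal to the chain.
#'
#' @return The chain with `label` filled in.
#' @export
attach_labels <- function(chain, labels) {
  assert_that(inherits(chain, "residue_chain"), "chain must be a residue_chain")
  if (is.character(labels) && length(labels) == 1L) labels <- read_labels(labels)
  labels <- if (is.null(names(labels))) as.integer(labels)
            else stats::setNames(as.integer(labels), names(labels))
  assert_that(all(labels %in% c(0L, 1L)), "labels must be 0 or 1",
              "bindgraph_label_error")
  n <- length(chain)
  if (is.null(names(labels))) {
    if (length(labels) != n)
      stop_bindgraph(sprintf(
        "label vector has %d entries but chain %s has %d residues",
        length(labels), chain$chain_id, n), "bindgraph_label_error")
    chain$label <- labels
  } else {
    idx <- as.integer(names(labels))
    missing <- setdiff(chain$residue_index, idx)
    if (length(missing) > 0L)
      stop_bindgraph(sprintf(
        "no label for residue(s) %s of chain %s",
        paste(utils::head(missing, 5L), collapse = ", "), chain$chain_id),
        "bindgraph_label_error")
    chain$label <- unname(labels[match(chain$residue_index, idx)])
  }
  chain
}

#' Extract the one-letter sequence of a chain
#'
#' @param chain a [residue_chain()].
#' @return Single character string of one-letter codes.
#' @export
chain_sequence <- function(chain) {
  paste(chain$aa, collapse = "")
}
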