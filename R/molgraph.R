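# Directed molecular graphs with atom/bond feature vectors.
#
# Every chemical bond contributes two directed edges carrying identical bond
# features; nodes are ordered canonically (the molecule is canonicalized
# before graph construction) so order-sensitive downstream steps — the GRU
# readout in particular — are deterministic across SMILES spellings.

GRAPH_ELEMENTS <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")
GRAPH_CHARGES <- c(-2, -1, 0, 1, 2)
GRAPH_CHIRALITY <- c("none", "cw", "ccw", "other")
GRAPH_HYBRID <- c("sp", "sp2", "sp3")

one_hot <- function(values, levels, other_slot = TRUE) {
  k <- length(levels) + as.integer(other_slot)
  m <- matrix(0, length(values), k)
  idx <- match(values, levels)
  if (other_slot) idx[is.na(idx)] <- length(levels) + 1L
  m[cbind(seq_along(values), idx)] <- 1
  m
}

#' Feature schema of the graph representation
#'
#' Describes the fixed-length atom and bond feature vectors: block names,
#' widths, and a stable hash used to stamp model checkpoints so a model is
#' never applied to graphs built under a different featurization.
#'
#' @return a list with `atom_dim`, `bond_dim`, the block layouts and `hash`.
#' @export
feature_schema <- function() {
  atom_blocks <- c(element = length(GRAPH_ELEMENTS) + 1L, degree = 7L,
                   charge = length(GRAPH_CHARGES) + 1L,
                   chirality = length(GRAPH_CHIRALITY),
                   n_h = 6L, hybridization = length(GRAPH_HYBRID) + 1L,
                   aromatic = 1L, mass = 1L)
  bond_blocks <- c(order = 4L, conjugated = 1L, in_ring = 1L, stereo = 3L)
  schema <- list(atom_blocks = atom_blocks, bond_blocks = bond_blocks,
                 elements = GRAPH_ELEMENTS,
                 atom_dim = sum(atom_blocks), bond_dim = sum(bond_blocks))
  schema$hash <- rlang::hash(schema[c("atom_blocks", "bond_blocks", "elements")])
  schema
}

atom_feature_matrix <- function(atoms) {
  cbind(
    one_hot(atoms$element, GRAPH_ELEMENTS),
    one_hot(pmin(atoms$degree, 5L), 0:5, other_slot = TRUE),
    one_hot(atoms$charge, GRAPH_CHARGES),
    one_hot(atoms$chirality, GRAPH_CHIRALITY, other_slot = FALSE),
    one_hot(pmin(atoms$n_h, 5L), 0:4, other_slot = TRUE),
    one_hot(atoms$hybridization, GRAPH_HYBRID),
    as.numeric(atoms$aromatic),
    atoms$mass / 100
  )
}

bond_feature_vectors <- function(bonds) {
  cls <- ifelse(bonds$aromatic, "aromatic",
                c("single", "double", "triple")[pmin(bonds$order, 3L)])
  cbind(
    one_hot(cls, c("single", "double", "triple", "aromatic"),
            other_slot = FALSE),
    as.numeric(bonds$conjugated),
    as.numeric(bonds$in_ring),
    # E/Z annotations are not propagated by the parsing backend; the stereo
    # block is kept (fixed layout) with the "none" slot active
    one_hot(rep("none", nrow(bonds)), c("none", "cis", "trans"),
            other_slot = FALSE)
  )
}

#' Convert SMILES to directed molecular graphs
#'
#' Each molecule becomes a directed graph: atoms are nodes in canonical
#' order, every chemical bond emits two directed edges (forward and
#' reverse, identical bond features), and the reverse-edge map pairs them.
#'
#' @param smiles a character vector of SMILES strings.
#' @return for `mol_graphs()` a list of `mol_graph` objects; `mol_graph()`
#'   accepts a single SMILES and returns one object. A `mol_graph` carries
#'   `n_atoms`, `n_edges`, feature matrices `atom_features`
#'   (`n_atoms x atom_dim`) and `bond_features` (`n_edges x bond_dim`),
#'   integer vectors `edge_src`, `edge_dst`, `rev_edge`, and the
#'   `incoming` edge list per node.
#' @export
mol_graphs <- function(smiles) {
  can <- canonical_smiles(as.character(smiles))
  if (anyNA(can)) {
    stop_cmpnntox(paste0("unparseable SMILES: ",
                         paste(utils::head(smiles[is.na(can)], 5),
                               collapse = ", ")),
                  "cmpnntox_parse_error")
  }
  topos <- parse_molecules(can)
  lapply(seq_along(topos), function(i) graph_from_topology(topos[[i]], smiles[i]))
}

#' @rdname mol_graphs
#' @export
mol_graph <- function(smiles) {
  stopifnot(length(smiles) == 1)
  mol_graphs(smiles)[[1]]
}

graph_from_topology <- function(topo, input_smiles) {
  n <- nrow(topo$atoms)
  nb <- nrow(topo$bonds)
  # directed edges: bond k -> edges 2k-1 (a1->a2) and 2k (a2->a1)
  edge_src <- integer(0); edge_dst <- integer(0); rev_edge <- integer(0)
  bf <- matrix(0, 0, feature_schema()$bond_dim)
  if (nb > 0) {
    edge_src <- as.integer(rbind(topo$bonds$a1, topo$bonds$a2))
    edge_dst <- as.integer(rbind(topo$bonds$a2, topo$bonds$a1))
    rev_edge <- as.integer(rbind(seq_len(nb) * 2L, seq_len(nb) * 2L - 1L))
    bf1 <- bond_feature_vectors(topo$bonds)
    bf <- bf1[rep(seq_len(nb), each = 2), , drop = FALSE]
  }
  incoming <- split(seq_along(edge_dst), factor(edge_dst, levels = seq_len(n)))
  structure(list(
    smiles = input_smiles,
    canonical_smiles = topo$smiles,
    n_atoms = n, n_edges = length(edge_src),
    atoms = topo$atoms, bonds = topo$bonds,
    atom_features = atom_feature_matrix(topo$atoms),
    bond_features = bf,
    edge_src = edge_src, edge_dst = edge_dst, rev_edge = rev_edge,
    incoming = unname(incoming)
  ), class = "mol_graph")
}

#' @export
#' @method print mol_graph
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$canonical_smiles, ": ", x$n_atoms, " atoms, ",
      x$n_edges, " directed edges\n", sep = "")
  invisible(x)
}

#' Batch molecular graphs into a disjoint union
#'
#' Concatenates graphs with offset node/edge indices so a whole batch runs
#' through the network in one pass; `unbatch_graphs()` recovers the member
#' graphs exactly.
#'
#' @param graphs a non-empty list of `mol_graph` objects.
#' @return a `mol_graph_batch`: the union graph plus `n_mols`, per-node
#'   `mol_index`, and bookkeeping to invert the batching.
#' @export
batch_graphs <- function(graphs) {
  if (length(graphs) == 0) {
    stop_cmpnntox("cannot batch an empty collection", "cmpnntox_empty_error")
  }
  stopifnot(all(vapply(graphs, inherits, TRUE, "mol_graph")))
  nv <- vapply(graphs, `[[`, 0L, "n_atoms")
  ne <- vapply(graphs, `[[`, 0L, "n_edges")
  voff <- cumsum(c(0L, nv[-length(nv)]))
  eoff <- cumsum(c(0L, ne[-length(ne)]))
  edge_src <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]$edge_src + voff[i]))
  edge_dst <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]$edge_dst + voff[i]))
  rev_edge <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]$rev_edge + eoff[i]))
  batch <- structure(list(
    n_mols = length(graphs),
    n_atoms = sum(nv), n_edges = sum(ne),
    nv = nv, ne = ne, voff = voff, eoff = eoff,
    mol_index = rep(seq_along(graphs), nv),
    smiles = vapply(graphs, `[[`, "", "smiles"),
    canonical_smiles = vapply(graphs, `[[`, "", "canonical_smiles"),
    atom_features = do.call(rbind, lapply(graphs, `[[`, "atom_features")),
    bond_features = do.call(rbind, lapply(graphs, `[[`, "bond_features")),
    edge_src = as.integer(edge_src %||% integer(0)),
    edge_dst = as.integer(edge_dst %||% integer(0)),
    rev_edge = as.integer(rev_edge %||% integer(0)),
    atoms = lapply(graphs, `[[`, "atoms"),
    bonds = lapply(graphs, `[[`, "bonds")
  ), class = "mol_graph_batch")
  batch$in_slots <- incoming_slot_matrix(batch$edge_dst, batch$n_atoms)
  batch
}

# V x maxdeg matrix of incoming directed-edge ids (0 = empty slot)
incoming_slot_matrix <- function(edge_dst, n_atoms) {
  if (length(edge_dst) == 0) return(matrix(0L, n_atoms, 0))
  deg <- tabulate(edge_dst, nbins = n_atoms)
  maxdeg <- max(deg)
  m <- matrix(0L, n_atoms, maxdeg)
  ord <- order(edge_dst)
  slot <- stats::ave(edge_dst[ord], edge_dst[ord], FUN = seq_along)
  m[cbind(edge_dst[ord], slot)] <- ord
  m
}

#' @export
#' @method print mol_graph_batch
print.mol_graph_batch <- function(x, ...) {
  cat("<mol_graph_batch> ", x$n_mols, " molecules, ", x$n_atoms, " atoms, ",
      x$n_edges, " directed edges\n", sep = "")
  invisible(x)
}

#' @rdname batch_graphs
#' @param batch a `mol_graph_batch`.
#' @export
unbatch_graphs <- function(batch) {
  stopifnot(inherits(batch, "mol_graph_batch"))
  lapply(seq_len(batch$n_mols), function(i) {
    nv <- batch$nv[i]; ne <- batch$ne[i]
    vsel <- batch$voff[i] + seq_len(nv)
    esel <- batch$eoff[i] + seq_len(ne)
    edge_src <- batch$edge_src[esel] - batch$voff[i]
    edge_dst <- batch$edge_dst[esel] - batch$voff[i]
    incoming <- split(seq_along(edge_dst),
                      factor(edge_dst, levels = seq_len(nv)))
    structure(list(
      smiles = batch$smiles[i],
      canonical_smiles = batch$canonical_smiles[i],
      n_atoms = nv, n_edges = ne,
      atoms = batch$atoms[[i]], bonds = batch$bonds[[i]],
      atom_features = batch$atom_features[vsel, , drop = FALSE],
      bond_features = batch$bond_features[esel, , drop = FALSE],
      edge_src = as.integer(edge_src), edge_dst = as.integer(edge_dst),
      rev_edge = as.integer(batch$rev_edge[esel] - batch$eoff[i]),
      incoming = unname(incoming)
    ), class = "mol_graph")
  })
}
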