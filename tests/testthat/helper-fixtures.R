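# Fixtures built in code: toy residue tables with chosen geometry, random
# labeled graphs, and independent oracles (BFS distances, a naive
# quadruple-loop kernel, midrank Mann-Whitney AUC).

# A toy protein: one carbon atom per residue at the given coordinates.
# Attributes default to a constant 0.5 (already inside [0, 1]).
toy_protein <- function(coords, protein_id = "toy",
                        attrs = NULL,
                        asa_unbound = 50, asa_complex = NULL,
                        rel_acc = 30, chain = "A", aa = "A",
                        element = "C") {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (is.null(attrs)) {
    attrs <- matrix(0.5, n, 26)
  }
  colnames(attrs) <- attribute_names()
  if (is.null(asa_complex)) asa_complex <- rep(asa_unbound, n) - 0.5
  atoms <- lapply(seq_len(n), function(i) {
    tibble::tibble(name = "CA", element = element,
                   x = coords[i, 1], y = coords[i, 2], z = coords[i, 3],
                   radius = unname(default_radii()[element]))
  })
  out <- tibble::tibble(
    protein_id = protein_id,
    chain = chain,
    resnum = seq_len(n),
    icode = "",
    aa = rep_len(aa, n),
    atoms = atoms,
    asa_complex = rep_len(asa_complex, n),
    asa_unbound = rep_len(asa_unbound, n),
    rel_acc = rep_len(rel_acc, n)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(attrs))
  out$key <- residue_key(out$chain, out$resnum, out$icode)
  out
}

# n residues on a straight line, `spacing` Angstroms apart (consecutive
# carbons are in contact for spacing < 3.9).
line_protein <- function(n, spacing = 3.8, ...) {
  toy_protein(cbind(spacing * (seq_len(n) - 1), 0, 0), ...)
}

# Random Erdos-Renyi labeled graph as a patch_graph (labels in [0, 1]).
random_patch_graph <- function(n, p, d = 5) {
  labels <- matrix(runif(n * d), n, d)
  keys <- sprintf("A:%d:", seq_len(n))
  rownames(labels) <- keys
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dimnames(pairs) <- NULL
  edges <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  structure(list(keys = keys, labels = labels, edges = edges),
            class = "patch_graph")
}

# Independent BFS all-pairs distances (igraph), Inf when disconnected.
bfs_distances <- function(n, edges) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  igraph::distances(g, algorithm = "unweighted")
}

# Independent naive shortest-path kernel: explicit quadruple loop over the
# oriented edges of both shortest-path graphs, no vectorization, no reuse
# of package kernels.
naive_graph_kernel <- function(s1, s2, gamma = 72, cc = 2) {
  orient <- function(s) {
    if (nrow(s$edges) == 0) return(list())
    out <- list()
    for (i in seq_len(nrow(s$edges))) {
      a <- s$edges[i, 1]; b <- s$edges[i, 2]; w <- s$weights[i]
      out[[length(out) + 1]] <- list(from = a, to = b, w = w)
      out[[length(out) + 1]] <- list(from = b, to = a, w = w)
    }
    out
  }
  knode <- function(x, y) exp(-gamma * sum((x - y)^2))
  total <- 0
  for (e1 in orient(s1)) {
    for (e2 in orient(s2)) {
      kw <- max(0, cc - abs(e1$w - e2$w))
      total <- total + kw *
        knode(s1$labels[e1$from, ], s2$labels[e2$from, ]) *
        knode(s1$labels[e1$to, ], s2$labels[e2$to, ])
    }
  }
  total
}

# A two-node shortest-path graph with one weight-1 edge; both nodes carry
# the same label vector.
single_edge_graph <- function(label = rep(0.5, 26)) {
  labels <- rbind(label, label)
  keys <- c("A:1:", "A:2:")
  rownames(labels) <- keys
  structure(list(keys = keys, labels = labels,
                 edges = matrix(c(1L, 2L), 1), weights = 1L),
            class = "sp_graph")
}

# Midrank Mann-Whitney AUC oracle.
rank_auc <- function(scores, is_positive) {
  r <- rank(scores)
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A tiny synthetic dataset shared by classifier/evaluation tests.
small_dataset <- function(n_proteins = 4, n_residues = 40, separation = 1,
                          seed = 11) {
  generate_dataset(generator_config(
    n_proteins = n_proteins, n_residues = n_residues,
    separation = separation, seed = seed))
}

# Shortest-path graphs for n random patches (for kernel property tests).
random_sp_graphs <- function(n, nodes = 8, p = 0.4, d = 5) {
  lapply(seq_len(n), function(i) {
    shortest_path_transform(random_patch_graph(nodes, p, d))
  })
}

# Hand-written PDB text: three residues; residue 2 has a hydrogen and a
# two-conformer CB altloc (A occupancy 0.6 listed after B at 0.4).
toy_pdb_lines <- function() {
  c(
    "HEADER    TOY",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB BSER A   3       7.600   1.000   0.000  0.40  0.00           C",
    "ATOM      4  CB ASER A   3       7.600   2.000   0.000  0.60  0.00           C",
    "ATOM      5  CA  SER A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      6  H   SER A   3       7.600   0.500   0.000  1.00  0.00           H",
    "HETATM    7  O   HOH A  90      20.000  20.000  20.000  1.00  0.00           O",
    "END"
  )
}

write_toy_pdb <- function(lines = toy_pdb_lines()) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A well-formed two-residue feature table (all 26 attributes).
toy_feature_lines <- function(drop_strcn = FALSE) {
  cols <- c("protein_id", "chain", "resnum", "icode", "aa", "asa_complex",
            "asa_unbound", "rel_acc", "rasa", "ep", "entropy", "curv",
            "pocket", "strcn", paste0("pssm_", strsplit(
              "ARNDCQEGHILKMFPSTWYV", "")[[1]]))
  if (drop_strcn) cols <- setdiff(cols, "strcn")
  n_attr <- length(cols) - 8
  row_of <- function(resnum, val) {
    paste(c("toy", "A", resnum, "", "A", "40.0", "50.0", "30.0",
            rep(sprintf("%.2f", val), n_attr)), collapse = "\t")
  }
  c(paste(cols, collapse = "\t"), row_of(1, 0.25), row_of(2, 0.75))
}

write_toy_features <- function(lines = toy_feature_lines()) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
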