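# Labeled residue contact graphs and their shortest-path transform.
#
# Two residues are in contact when the closest distance between their heavy
# atoms is less than the sum of the atoms' van der Waals radii plus a 0.5 A
# pad. A patch becomes a graph with one node per residue (labeled with the
# residue's normalized attribute vector) and an edge per contacting pair;
# the shortest-path transform (Floyd-Warshall over unit edge weights)
# replaces the edge set with one weighted edge per connected node pair.

# Radius-adjusted minimum inter-residue atom distance matrix:
# D[i, j] = min over atom pairs of (euclidean distance - r_a - r_b).
# Contact iff D[i, j] < pad.
adjusted_distance_matrix <- function(residues) {
  atoms <- residues$atoms
  n <- length(atoms)
  counts <- vapply(atoms, nrow, integer(1))
  if (any(counts == 0)) {
    stop("residue without heavy atoms: ",
         residues$key[which(counts == 0)[1]], call. = FALSE)
  }
  xyz <- do.call(rbind, lapply(atoms, function(a) cbind(a$x, a$y, a$z)))
  rad <- unlist(lapply(atoms, `[[`, "radius"), use.names = FALSE)
  idx <- rep(seq_len(n), counts)
  # pairwise atom distances minus both radii
  sq <- rowSums(xyz^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  adj <- sqrt(d2) - outer(rad, rad, "+")
  # reduce atom-pair matrix to residue-pair minima
  rows <- rowsum_min(adj, idx)          # n x n_atoms
  t(rowsum_min(t(rows), idx))           # n x n
}

# min-aggregation of rows of `m` by group `idx` (no matrixStats dependency)
rowsum_min <- function(m, idx) {
  groups <- sort(unique(idx))
  out <- matrix(NA_real_, length(groups), ncol(m))
  for (g in seq_along(groups)) {
    block <- m[idx == groups[g], , drop = FALSE]
    out[g, ] <- do.call(pmin, c(asplit(block, 1), list(na.rm = FALSE)))
  }
  out
}

#' Are two residues in contact?
#'
#' True when the minimum over heavy-atom pairs of
#' (distance - radius_a - radius_b) is strictly less than `pad`.
#'
#' @param r1,r2 One-row residue tibbles (with `atoms` list-column).
#' @param pad Contact padding in Angstroms (default 0.5).
#' @return Logical scalar.
#' @export
residues_in_contact <- function(r1, r2, pad = 0.5) {
  two <- dplyr::bind_rows(r1, r2)
  adjusted_distance_matrix(two)[1, 2] < pad
}

new_patch_graph <- function(keys, labels, edges) {
  structure(list(keys = keys, labels = labels, edges = edges),
            class = "patch_graph")
}

#' Build the labeled contact graph of a patch
#'
#' One node per patch residue, labeled with the residue's normalized
#' attribute vector; an undirected edge for every contacting residue pair.
#' Contacts to residues outside the patch are ignored (induced subgraph).
#'
#' @param residues Normalized residue tibble for the protein (attributes in
#'   \[0, 1\], e.g. from [apply_normalizer()]).
#' @param patch One-row patch tibble, or a character vector of residue keys.
#' @param features Feature groups used as node labels (see
#'   [feature_columns()]); default all seven.
#' @param pad Contact padding in Angstroms.
#' @return A `patch_graph`: node keys, label matrix (nodes x attributes),
#'   and an m x 2 integer edge matrix.
#' @export
build_patch_graph <- function(residues, patch, features = "all", pad = 0.5) {
  keys <- if (is.character(patch)) patch else patch$keys[[1]]
  idx <- match(keys, residues$key)
  if (anyNA(idx)) {
    stop("patch residue(s) absent from protein: ",
         paste(head(keys[is.na(idx)], 3), collapse = ", "), call. = FALSE)
  }
  sub <- residues[idx, ]
  cols <- feature_columns(features)
  labels <- as.matrix(sub[, cols])
  rownames(labels) <- keys
  if (anyNA(labels) || any(labels < 0 | labels > 1)) {
    stop("attributes not normalized to [0, 1]; apply a fitted normalizer ",
         "before building graphs", call. = FALSE)
  }
  D <- adjusted_distance_matrix(sub)
  contact <- D < pad
  contact[lower.tri(contact, diag = TRUE)] <- FALSE
  edges <- which(contact, arr.ind = TRUE)
  dimnames(edges) <- NULL
  new_patch_graph(keys, labels, edges)
}

# Floyd-Warshall all-pairs shortest paths over unit edge weights.
# Returns the n x n distance matrix (Inf for disconnected pairs, 0 diagonal).
floyd_warshall <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (nrow(edges) > 0) {
    d[edges] <- 1
    d[edges[, 2:1, drop = FALSE]] <- 1
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    lower <- dk < d
    d[lower] <- dk[lower]
  }
  d
}

#' Shortest-path transform of a contact graph
#'
#' Same nodes as the original graph; one weighted edge per connected node
#' pair, carrying the shortest-path distance (hop count) in the original
#' graph, computed with the Floyd-Warshall algorithm over unit edge
#' weights. Pairs in different components produce no edge.
#'
#' @param g A `patch_graph` from [build_patch_graph()].
#' @return An `sp_graph`: node keys, label matrix, m x 2 edge matrix and an
#'   integer `weights` vector.
#' @export
shortest_path_transform <- function(g) {
  stopifnot(inherits(g, "patch_graph"))
  n <- length(g$keys)
  d <- floyd_warshall(n, g$edges)
  ut <- which(upper.tri(d) & is.finite(d), arr.ind = TRUE)
  dimnames(ut) <- NULL
  structure(
    list(keys = g$keys, labels = g$labels, edges = ut,
         weights = as.integer(d[ut])),
    class = "sp_graph"
  )
}

#' @export
print.patch_graph <- function(x, ...) {
  cat("<patch_graph>", length(x$keys), "nodes,", nrow(x$edges),
      "contact edges,", ncol(x$labels), "attributes\n")
  invisible(x)
}

#' @export
print.sp_graph <- function(x, ...) {
  cat("<sp_graph>", length(x$keys), "nodes,", nrow(x$edges),
      "weighted edges\n")
  invisible(x)
}

#' @export
tidy.patch_graph <- function(x, ...) {
  tibble::tibble(
    from = x$keys[x$edges[, 1]],
    to = x$keys[x$edges[, 2]],
    weight = 1L
  )
}

#' @export
tidy.sp_graph <- function(x, ...) {
  tibble::tibble(
    from = x$keys[x$edges[, 1]],
    to = x$keys[x$edges[, 2]],
    weight = x$weights
  )
}

#' Write a graph as edge-list text
#'
#' Debug dump: one `from to weight` line per edge.
#'
#' @param g A `patch_graph` or `sp_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_edgelist <- function(g, path) {
  readr::write_tsv(tidy(g), path, progress = FALSE)
  invisible(path)
}
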