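# The shortest-path graph kernel.
#
# Two patches are compared by summing, over all ordered pairs of weighted
# edges of their shortest-path graphs, the product of a Gaussian kernel on
# the two start-node labels, a Brownian-bridge kernel on the edge weights,
# and a Gaussian kernel on the two end-node labels. Undirected edges carry
# no orientation, so each edge is enumerated in both directions in both
# graphs; the resulting uniform factor of 4 (2 per graph) cancels in the
# classifier, which only compares kernel values against size-matched
# patches.

#' Kernel parameters
#'
#' `gamma` is the Gaussian node-kernel coefficient, i.e. 1/(2 delta^2) in
#' the radial-basis form exp(-gamma * ||x - y||^2); the default 72 is the
#' value at which cross-validated patch classification accuracy peaks.
#' `c` is the Brownian-bridge cutoff in hop-count units: edge-weight pairs
#' differing by `c` or more hops contribute nothing.
#'
#' @param gamma Positive node-kernel coefficient (default 72).
#' @param c Positive Brownian-bridge cutoff (default 2).
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(gamma = 72, c = 2) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 0,
            is.numeric(c), length(c) == 1, c > 0)
  structure(list(gamma = gamma, c = c), class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat("<kernel_params> gamma =", x$gamma, "(1/(2 delta^2)), c =", x$c, "\n")
  invisible(x)
}

#' Gaussian node kernel
#'
#' `exp(-gamma * ||x - y||^2)` on two node label vectors.
#'
#' @param x,y Numeric attribute vectors of equal length.
#' @param params [kernel_params()].
#' @return Similarity in (0, 1].
#' @export
node_kernel <- function(x, y, params = kernel_params()) {
  if (length(x) != length(y)) {
    stop("label vectors differ in length (", length(x), " vs ", length(y),
         ")", call. = FALSE)
  }
  exp(-params$gamma * sum((x - y)^2))
}

#' Brownian-bridge edge-weight kernel
#'
#' `max(0, c - |w1 - w2|)`: maximal (`c`) for identical shortest-path
#' lengths, zero once they differ by `c` or more hops.
#'
#' @param w1,w2 Edge weights (hop counts, >= 1).
#' @param params [kernel_params()].
#' @return Similarity in \[0, c\].
#' @export
weight_kernel <- function(w1, w2, params = kernel_params()) {
  pmax(0, params$c - abs(w1 - w2))
}

#' Edge kernel
#'
#' Product `k_node(v1, v2) * k_weight(e1, e2) * k_node(w1, w2)` for two
#' oriented edges given as `list(from = <label>, to = <label>, weight = )`.
#'
#' @param e1,e2 Oriented edges (lists with `from`, `to` label vectors and a
#'   `weight`).
#' @param params [kernel_params()].
#' @return Non-negative similarity.
#' @export
edge_kernel <- function(e1, e2, params = kernel_params()) {
  kw <- weight_kernel(e1$weight, e2$weight, params)
  if (kw == 0) return(0)
  node_kernel(e1$from, e2$from, params) * kw *
    node_kernel(e1$to, e2$to, params)
}

#' Shortest-path graph kernel between two patches
#'
#' Sums the edge kernel over all ordered pairs of weighted edges of the two
#' shortest-path graphs (each undirected edge taken in both orientations in
#' both graphs). Symmetric and non-negative.
#'
#' @param g1,g2 `sp_graph` objects from [shortest_path_transform()].
#' @param params [kernel_params()].
#' @return Non-negative kernel value; 0 (with a warning) if either graph
#'   has no weighted edges.
#' @export
graph_kernel <- function(g1, g2, params = kernel_params()) {
  stopifnot(inherits(g1, "sp_graph"), inherits(g2, "sp_graph"))
  if (ncol(g1$labels) != ncol(g2$labels)) {
    stop("graphs were labeled with different attribute sets", call. = FALSE)
  }
  m1 <- nrow(g1$edges); m2 <- nrow(g2$edges)
  if (m1 == 0 || m2 == 0) {
    warning("graph with zero weighted edges; kernel is 0", call. = FALSE)
    return(0)
  }
  # node-kernel matrix M[i, j] = exp(-gamma ||x_i - y_j||^2)
  sq1 <- rowSums(g1$labels^2)
  sq2 <- rowSums(g2$labels^2)
  d2 <- outer(sq1, sq2, "+") - 2 * tcrossprod(g1$labels, g2$labels)
  d2[d2 < 0] <- 0
  M <- exp(-params$gamma * d2)

  a <- g1$edges[, 1]; b <- g1$edges[, 2]
  u <- g2$edges[, 1]; v <- g2$edges[, 2]
  W <- pmax(0, params$c - abs(outer(g1$weights, g2$weights, "-")))
  # ordered-edge enumeration: the 4 orientation combinations collapse to
  # 2 * (M[a,u] M[b,v] + M[a,v] M[b,u])
  S <- M[a, u, drop = FALSE] * M[b, v, drop = FALSE] +
       M[a, v, drop = FALSE] * M[b, u, drop = FALSE]
  2 * sum(W * S)
}

#' Gram matrix of the graph kernel
#'
#' @param graphs List of `sp_graph` objects.
#' @param params [kernel_params()].
#' @return Symmetric numeric matrix `K[i, j] = K(graphs[[i]], graphs[[j]])`.
#' @export
kernel_matrix <- function(graphs, params = kernel_params()) {
  n <- length(graphs)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      K[i, j] <- K[j, i] <- graph_kernel(graphs[[i]], graphs[[j]], params)
    }
  }
  K
}
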