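# The voting strategy.
#
# Raw kernel values grow with graph size, so a query patch is never compared
# against patches of different sizes directly. Instead, for every training
# protein the query is compared to that protein's interface patch and its
# size-matched non-interface patch; each K(G, G_int) > K(G, G_non) win casts
# one vote for "interface". The query is predicted interface when the votes
# exceed half the training-set size (strict majority).

#' Build size-matched training pairs from a dataset
#'
#' For each training protein: the interface patch (all interface residues)
#' and one sampled contiguous non-interface patch of identical size, both as
#' shortest-path graphs labeled with the protein's normalized attributes.
#'
#' @param residues Normalized residue tibble covering >= 1 protein
#'   (`protein_id` column distinguishes them).
#' @param seed Integer seed for non-interface patch sampling; protein `i`
#'   (in `protein_id` order) uses `seed + i`.
#' @param features Feature groups for node labels (see [feature_columns()]).
#' @param pad Contact padding in Angstroms.
#' @return Tibble with columns `protein_id`, `size`, and list-columns
#'   `interface_graph`, `noninterface_graph`, `interface_keys`,
#'   `noninterface_keys`.
#' @export
training_pairs <- function(residues, seed, features = "all", pad = 0.5) {
  ids <- sort(unique(residues$protein_id))
  purrr::map_dfr(seq_along(ids), function(i) {
    prot <- dplyr::filter(residues, .data$protein_id == ids[i])
    int_patch <- extract_interface_patch(prot)
    non_patch <- sample_noninterface_patch(prot, int_patch$size,
                                           seed = seed + i, pad = pad)
    gi <- shortest_path_transform(
      build_patch_graph(prot, int_patch, features, pad))
    gn <- shortest_path_transform(
      build_patch_graph(prot, non_patch, features, pad))
    tibble::tibble(
      protein_id = ids[i],
      size = int_patch$size,
      interface_graph = list(gi),
      noninterface_graph = list(gn),
      interface_keys = int_patch$keys,
      noninterface_keys = non_patch$keys
    )
  })
}

#' Classify a query patch by size-matched voting
#'
#' Compares the query graph to each training protein's interface and
#' non-interface shortest-path graphs; a strict win
#' `K(G, G_int) > K(G, G_non)` casts one vote (ties cast none). At the
#' default threshold the label is `interface` iff votes exceed half the
#' number of training pairs.
#'
#' @param query_graph `sp_graph` of the query patch (built with the same
#'   normalizer and feature set as the training pairs).
#' @param pairs Training-pair tibble from [training_pairs()].
#' @param params [kernel_params()].
#' @return A `vote_result`: votes, total, label, and the per-pair kernel
#'   comparisons (see [tidy()]).
#' @export
vote <- function(query_graph, pairs, params = kernel_params()) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0) {
    stop("empty training set", call. = FALSE)
  }
  k_int <- purrr::map_dbl(pairs$interface_graph, graph_kernel,
                          g2 = query_graph, params = params)
  k_non <- purrr::map_dbl(pairs$noninterface_graph, graph_kernel,
                          g2 = query_graph, params = params)
  per_pair <- tibble::tibble(
    protein_id = pairs$protein_id,
    k_interface = k_int,
    k_noninterface = k_non,
    vote_interface = k_int > k_non
  )
  votes <- sum(per_pair$vote_interface)
  total <- nrow(per_pair)
  structure(
    list(votes = votes, total = total,
         label = if (votes > total / 2) "interface" else "non_interface",
         per_pair = per_pair),
    class = "vote_result"
  )
}

#' @export
print.vote_result <- function(x, ...) {
  cat("<vote_result>", x$votes, "of", x$total, "votes ->", x$label, "\n")
  invisible(x)
}

#' @export
tidy.vote_result <- function(x, ...) x$per_pair

#' @export
glance.vote_result <- function(x, ...) {
  tibble::tibble(votes = x$votes, total = x$total, label = x$label)
}

#' Apply a vote threshold
#'
#' Predicts `interface` iff `votes > threshold` (strict). The default
#' majority rule corresponds to `threshold = total / 2`.
#'
#' @param vote_result A `vote_result` from [vote()], or an integer vote
#'   count together with `total`.
#' @param threshold Numeric threshold in \[0, total\].
#' @param total Total number of training pairs (taken from `vote_result`
#'   when one is supplied).
#' @return `"interface"` or `"non_interface"`.
#' @export
classify_at_threshold <- function(vote_result, threshold, total = NULL) {
  if (inherits(vote_result, "vote_result")) {
    votes <- vote_result$votes
    total <- vote_result$total
  } else {
    votes <- vote_result
    if (is.null(total)) stop("supply `total` with a raw vote count",
                             call. = FALSE)
  }
  if (threshold < 0 || threshold > total) {
    stop("threshold must lie in [0, ", total, "]", call. = FALSE)
  }
  if (votes > threshold) "interface" else "non_interface"
}

#' Rank a protein's patches by vote count
#'
#' Scores every patch by [vote()] and sorts in decreasing vote order; ties
#' are broken by center residue key in `(chain, resnum, icode)` order, so
#' the ranking never depends on input order.
#'
#' @param patches Patch tibble (one protein; e.g. from
#'   [centered_surface_patches()]).
#' @param residues Normalized residue tibble for the same protein.
#' @param pairs Training pairs from [training_pairs()].
#' @param params [kernel_params()].
#' @param features,pad Graph construction options (must match the pairs).
#' @return The patch tibble with `votes` and `total` columns, ordered by
#'   decreasing votes.
#' @export
rank_patches <- function(patches, residues, pairs,
                         params = kernel_params(), features = "all",
                         pad = 0.5) {
  stopifnot(length(unique(patches$protein_id)) == 1)
  graphs <- purrr::map(patches$keys, function(kk) {
    shortest_path_transform(build_patch_graph(residues, kk, features, pad))
  })
  vr <- purrr::map(graphs, vote, pairs = pairs, params = params)
  out <- dplyr::mutate(
    patches,
    votes = purrr::map_int(vr, function(v) as.integer(v$votes)),
    total = purrr::map_int(vr, function(v) as.integer(v$total))
  )
  anchor <- ifelse(is.na(out$center),
                   purrr::map_chr(out$keys, 1), out$center)
  idx <- match(anchor, residues$key)
  ord <- order(-out$votes, residues$chain[idx], residues$resnum[idx],
               residues$icode[idx])
  out[ord, ]
}
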