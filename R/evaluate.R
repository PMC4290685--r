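# Evaluation protocol: protein-level leave-one-out cross-validation of
# patch classification, residue-level ROC/AUC over integer vote thresholds,
# the P_random significance of the top-ranked patch, and the top-k
# coverage/accuracy trade-off.

# Per-fold patch memberships are fixed once (per-protein derived seeds); the
# normalizer is refit per fold on the training proteins only, so held-out
# attributes are scaled by training extremes and clipped.

split_by_protein <- function(residues) {
  ids <- sort(unique(residues$protein_id))
  setNames(lapply(ids, function(id) {
    dplyr::filter(residues, .data$protein_id == id)
  }), ids)
}

# Precompute, per protein, the fold-independent pieces: interface patch
# keys and a seeded non-interface patch (topology and membership do not
# depend on the normalizer).
prepare_patch_sets <- function(proteins, seed, pad) {
  ids <- names(proteins)
  lapply(seq_along(ids), function(i) {
    prot <- proteins[[i]]
    int_patch <- extract_interface_patch(prot)
    non_patch <- sample_noninterface_patch(prot, int_patch$size,
                                           seed = seed + i, pad = pad)
    list(protein_id = ids[i], interface = int_patch$keys[[1]],
         noninterface = non_patch$keys[[1]])
  })
}

pairs_from_patch_sets <- function(proteins, patch_sets, normalizer,
                                  features, pad, exclude = NULL) {
  keep <- vapply(patch_sets, function(ps) !identical(ps$protein_id, exclude),
                 logical(1))
  purrr::map_dfr(patch_sets[keep], function(ps) {
    prot <- apply_normalizer(proteins[[ps$protein_id]], normalizer)
    gi <- shortest_path_transform(
      build_patch_graph(prot, ps$interface, features, pad))
    gn <- shortest_path_transform(
      build_patch_graph(prot, ps$noninterface, features, pad))
    tibble::tibble(protein_id = ps$protein_id,
                   size = length(ps$interface),
                   interface_graph = list(gi),
                   noninterface_graph = list(gn))
  })
}

#' Leave-one-out cross-validation of patch classification
#'
#' For each protein in turn, its interface patch and its size-matched
#' non-interface patch are classified by voting over the remaining
#' proteins' pairs (the held-out protein's own pair never votes). Reports
#' accuracy, sensitivity (interface patches recovered) and specificity
#' (non-interface patches recovered) over all 2N patches.
#'
#' @param residues Raw (unnormalized) residue tibble covering >= 3
#'   proteins.
#' @param params [kernel_params()].
#' @param seed Integer seed for non-interface patch sampling.
#' @param features Feature groups for node labels.
#' @param pad Contact padding in Angstroms.
#' @return A `loocv_result` with per-patch predictions ([tidy()]) and
#'   summary metrics ([glance()]).
#' @export
loocv_patch_classification <- function(residues, params = kernel_params(),
                                       seed = 1, features = "all",
                                       pad = 0.5) {
  proteins <- split_by_protein(residues)
  if (length(proteins) < 3) stop("need >= 3 proteins", call. = FALSE)
  patch_sets <- prepare_patch_sets(proteins, seed, pad)

  rows <- purrr::map_dfr(seq_along(proteins), function(i) {
    held_id <- names(proteins)[i]
    train <- dplyr::filter(residues, .data$protein_id != held_id)
    norm <- fit_normalizer(train)
    pairs <- pairs_from_patch_sets(proteins, patch_sets, norm,
                                   features, pad, exclude = held_id)
    held <- apply_normalizer(proteins[[held_id]], norm)
    ps <- patch_sets[[i]]
    q_int <- shortest_path_transform(
      build_patch_graph(held, ps$interface, features, pad))
    q_non <- shortest_path_transform(
      build_patch_graph(held, ps$noninterface, features, pad))
    v_int <- vote(q_int, pairs, params)
    v_non <- vote(q_non, pairs, params)
    tibble::tibble(
      protein_id = held_id,
      truth = c("interface", "non_interface"),
      votes = c(v_int$votes, v_non$votes),
      total = c(v_int$total, v_non$total),
      predicted = c(v_int$label, v_non$label)
    )
  })

  tp <- sum(rows$truth == "interface" & rows$predicted == "interface")
  tn <- sum(rows$truth == "non_interface" &
              rows$predicted == "non_interface")
  n_int <- sum(rows$truth == "interface")
  n_non <- sum(rows$truth == "non_interface")
  structure(
    list(predictions = rows,
         accuracy = (tp + tn) / nrow(rows),
         sensitivity = tp / n_int,
         specificity = tn / n_non,
         n_proteins = length(proteins)),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf(
    "<loocv_result> %d proteins, %d patches: accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
    x$n_proteins, nrow(x$predictions), x$accuracy, x$sensitivity,
    x$specificity))
  invisible(x)
}

#' @export
tidy.loocv_result <- function(x, ...) x$predictions

#' @export
glance.loocv_result <- function(x, ...) {
  tibble::tibble(n_proteins = x$n_proteins,
                 n_patches = nrow(x$predictions),
                 accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity)
}

# ROC points for integer vote scores with prediction rule v > threshold.
# Thresholds run from `total` down to 0 per the voting rule, plus the -1
# anchor (everything predicted positive) that closes the curve at (1, 1);
# without the anchor the trapezoid area would not equal the Mann-Whitney
# statistic.
roc_points <- function(scores, labels, total) {
  thresholds <- seq(total, -1)
  pos <- sum(labels)
  neg <- sum(!labels)
  purrr::map_dfr(thresholds, function(t) {
    pred <- scores > t
    tibble::tibble(
      threshold = t,
      tpr = sum(pred & labels) / pos,
      fpr = sum(pred & !labels) / neg
    )
  })
}

trapezoid_auc <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                          utils::tail(tpr[ord], -1)) / 2)
}

#' Residue-level ROC over vote thresholds
#'
#' Scores every surface residue of every protein by protein-level
#' leave-one-out voting on the patch centered at the residue (the residue
#' plus its `k` nearest surface neighbors); ground truth is the residue's
#' own interface status. One ROC point per integer threshold of the rule
#' `votes > threshold`; AUC by the trapezoid rule.
#'
#' @inheritParams loocv_patch_classification
#' @param k Neighbors per centered patch (default 5).
#' @return A `roc_result` with the per-residue scores, the ROC tibble and
#'   the AUC.
#' @export
residue_roc <- function(residues, params = kernel_params(), seed = 1,
                        k = 5, features = "all", pad = 0.5) {
  proteins <- split_by_protein(residues)
  if (length(proteins) < 3) stop("need >= 3 proteins", call. = FALSE)
  patch_sets <- prepare_patch_sets(proteins, seed, pad)

  scored <- purrr::map_dfr(seq_along(proteins), function(i) {
    held_id <- names(proteins)[i]
    train <- dplyr::filter(residues, .data$protein_id != held_id)
    norm <- fit_normalizer(train)
    pairs <- pairs_from_patch_sets(proteins, patch_sets, norm,
                                   features, pad, exclude = held_id)
    held <- apply_normalizer(proteins[[held_id]], norm)
    patches <- centered_surface_patches(held, k = k)
    ranked <- rank_patches(patches, held, pairs, params, features, pad)
    int_keys <- interface_residues(held)
    tibble::tibble(
      protein_id = held_id,
      center = ranked$center,
      votes = ranked$votes,
      total = ranked$total,
      is_interface = ranked$center %in% int_keys
    )
  })

  both <- c(any(scored$is_interface), any(!scored$is_interface))
  if (!all(both)) {
    stop("ROC undefined: ground truth has a single class", call. = FALSE)
  }
  total <- max(scored$total)
  roc <- roc_points(scored$votes, scored$is_interface, total)
  structure(
    list(scores = scored, roc = roc,
         auc = trapezoid_auc(roc$fpr, roc$tpr)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d residues, AUC %.4f\n", nrow(x$scores),
              x$auc))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$roc

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(n_residues = nrow(x$scores),
                 n_interface = sum(x$scores$is_interface), auc = x$auc)
}

patch_interface_counts <- function(patches, interface_keys) {
  purrr::map_int(patches$keys, function(kk) {
    length(intersect(kk, interface_keys))
  })
}

#' Random-patch significance of the top-ranked patch
#'
#' The probability that a randomly chosen patch of the protein contains at
#' least as many interface residues as the top-ranked patch: `N / N_all`,
#' where `N_all` is the number of patches and `N` counts patches with at
#' least as many interface residues as the top patch (inclusive, so the
#' result is always >= 1/N_all).
#'
#' @param patches Patch tibble: the full patch universe of one protein
#'   (the centered surface patches used for prediction).
#' @param interface_keys Character vector of interface residue keys.
#' @param top_patch One-row patch tibble (default: first row of `patches`,
#'   i.e. the top-ranked patch of a ranked table).
#' @return Fraction in (0, 1].
#' @export
p_random <- function(patches, interface_keys, top_patch = NULL) {
  if (!is.data.frame(patches) || nrow(patches) == 0) {
    stop("empty patch list", call. = FALSE)
  }
  if (is.null(top_patch)) top_patch <- patches[1, ]
  counts <- patch_interface_counts(patches, interface_keys)
  top_count <- patch_interface_counts(top_patch, interface_keys)[1]
  sum(counts >= top_count) / nrow(patches)
}

#' Coverage and accuracy of the union of the top-k patches
#'
#' The predicted interface is the union of the residues of the `k`
#' top-ranked patches. Coverage is TP / N_int (fraction of actual interface
#' residues recovered); accuracy is TP / N_pr (fraction of predicted
#' residues that are actually interface).
#'
#' @param ranked_patches Ranked patch tibble from [rank_patches()].
#' @param k Number of top patches to merge; may be a vector, one output
#'   row per value.
#' @param interface_keys Character vector of interface residue keys.
#' @return Tibble with columns `k`, `tp`, `n_pr`, `n_int`, `coverage`,
#'   `accuracy`.
#' @export
topk_coverage_accuracy <- function(ranked_patches, k, interface_keys) {
  stopifnot(all(k >= 1))
  if (length(interface_keys) == 0) {
    stop("coverage undefined for an empty interface set", call. = FALSE)
  }
  purrr::map_dfr(k, function(kk) {
    kk <- min(kk, nrow(ranked_patches))
    predicted <- unique(unlist(ranked_patches$keys[seq_len(kk)]))
    tp <- length(intersect(predicted, interface_keys))
    tibble::tibble(
      k = kk, tp = tp,
      n_pr = length(predicted),
      n_int = length(interface_keys),
      coverage = tp / length(interface_keys),
      accuracy = tp / length(predicted)
    )
  })
}
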