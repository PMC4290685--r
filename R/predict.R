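# End-to-end prediction: score every surface residue of a query protein
# against a training set of proteins with known interfaces.

#' Predict DNA-binding residues on a query protein
#'
#' Fits the attribute normalizer on the training proteins, builds their
#' size-matched interface/non-interface training pairs, scores every
#' centered surface patch of the query by voting, and labels patches at a
#' vote threshold.
#'
#' @param query Raw residue tibble for the query protein (structure +
#'   features; interface ground truth not required).
#' @param training Raw residue tibble for the training proteins (>= 1,
#'   each with interface residues).
#' @param params [kernel_params()].
#' @param k Neighbors per centered patch (default 5).
#' @param seed Seed for non-interface patch sampling.
#' @param threshold Vote threshold for the `predicted` label; `"auto"`
#'   (default) uses the strict majority total/2.
#' @param features Feature groups; `"auto"` selects `"pssm"` alone when the
#'   query table is in PSSM-only mode (no structural conservation), else
#'   all seven.
#' @param pad Contact padding in Angstroms.
#' @return Ranked patch tibble with `votes`, `total`, `predicted` and
#'   `rank` columns.
#' @export
predict_binding_sites <- function(query, training,
                                  params = kernel_params(), k = 5,
                                  seed = 1, threshold = "auto",
                                  features = "auto", pad = 0.5) {
  if (identical(features, "auto")) {
    features <- if (isTRUE(attr(query, "pssm_only"))) "pssm" else "all"
  }
  norm <- fit_normalizer(training, columns = feature_columns(features))
  pairs <- training_pairs(apply_normalizer(training, norm), seed = seed,
                          features = features, pad = pad)
  query_n <- apply_normalizer(query, norm)
  patches <- centered_surface_patches(query_n, k = k)
  ranked <- rank_patches(patches, query_n, pairs, params, features, pad)
  thr <- if (identical(threshold, "auto")) ranked$total[1] / 2
         else as.numeric(threshold)
  dplyr::mutate(
    ranked,
    predicted = ifelse(.data$votes > thr, "interface", "non_interface"),
    rank = dplyr::row_number()
  )
}
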