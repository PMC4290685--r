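# The size-matched voting strategy and vote-threshold classification.

# Training pairs with controlled outcomes: the interface graphs carry label
# `int_label`, the non-interface graphs `non_label`, so a query near
# `int_label` wins every comparison.
made_pairs <- function(n, int_label, non_label) {
  tibble::tibble(
    protein_id = sprintf("p%02d", seq_len(n)),
    size = 2L,
    interface_graph = replicate(n, single_edge_graph(int_label),
                                simplify = FALSE),
    noninterface_graph = replicate(n, single_edge_graph(non_label),
                                   simplify = FALSE)
  )
}

test_that("votes count strict kernel wins and the majority rule is strict", {
  near_int <- rep(0.8, 26)
  pairs <- made_pairs(5, int_label = rep(0.8, 26),
                      non_label = rep(0.2, 26))
  v <- vote(single_edge_graph(near_int), pairs)
  expect_equal(v$votes, 5)
  expect_equal(v$total, 5)
  expect_equal(v$label, "interface")
  expect_equal(tidy(v)$vote_interface, rep(TRUE, 5))

  # identical interface and non-interface graphs: K ties, no vote granted
  tie_pairs <- made_pairs(4, rep(0.5, 26), rep(0.5, 26))
  v_tie <- vote(single_edge_graph(rep(0.5, 26)), tie_pairs)
  expect_equal(v_tie$votes, 0)
  expect_equal(v_tie$label, "non_interface")

  # even |T| with votes == |T|/2 exactly: non-interface (strict v > |T|/2)
  half <- dplyr::bind_rows(made_pairs(2, rep(0.8, 26), rep(0.2, 26)),
                           made_pairs(2, rep(0.2, 26), rep(0.8, 26)))
  half$protein_id <- sprintf("p%02d", 1:4)
  v_half <- vote(single_edge_graph(rep(0.8, 26)), half)
  expect_equal(v_half$votes, 2)
  expect_equal(v_half$label, "non_interface")

  expect_error(vote(single_edge_graph(near_int), made_pairs(0, 0, 0)),
               "empty training set")
})

test_that("vote counts are invariant to training-pair order", {
  withr::local_seed(31)
  pairs <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:8),
    size = 2L,
    interface_graph = replicate(8, single_edge_graph(runif(26)),
                                simplify = FALSE),
    noninterface_graph = replicate(8, single_edge_graph(runif(26)),
                                   simplify = FALSE)
  )
  q <- single_edge_graph(runif(26))
  v1 <- vote(q, pairs)
  v2 <- vote(q, pairs[sample(8), ])
  expect_equal(v1$votes, v2$votes)
  expect_equal(v1$label, v2$label)
})

test_that("threshold classification reproduces the majority arithmetic", {
  # 146 training pairs, 74 wins: 74 > 73 so interface at the default rule
  expect_equal(classify_at_threshold(74, threshold = 146 / 2, total = 146),
               "interface")
  # exactly half the votes (73 of 146) is non-interface
  expect_equal(classify_at_threshold(73, threshold = 146 / 2, total = 146),
               "non_interface")
  expect_equal(classify_at_threshold(74, threshold = 74, total = 146),
               "non_interface")
  expect_equal(classify_at_threshold(1, threshold = 0, total = 146),
               "interface")
  expect_error(classify_at_threshold(3, threshold = 200, total = 146),
               "threshold")

  # monotone: raising the threshold can only flip interface -> non-interface
  labels <- vapply(0:10, function(t) {
    classify_at_threshold(6, threshold = t, total = 10)
  }, character(1))
  expect_false(is.unsorted(rev(labels == "interface")))
})

test_that("patch ranking is deterministic with lexicographic tie-breaks", {
  ds <- small_dataset(n_proteins = 4, n_residues = 40, seed = 19)
  train <- dplyr::filter(ds, protein_id != "synth01")
  query <- dplyr::filter(ds, protein_id == "synth01")
  norm <- fit_normalizer(train)
  pairs <- training_pairs(apply_normalizer(train, norm), seed = 7)
  query_n <- apply_normalizer(query, norm)
  patches <- centered_surface_patches(query_n, k = 3)

  ranked <- rank_patches(patches, query_n, pairs)
  expect_equal(nrow(ranked), nrow(patches))
  expect_false(is.unsorted(rev(ranked$votes)))
  # input order never affects the ranking
  ranked2 <- rank_patches(patches[rev(seq_len(nrow(patches))), ],
                          query_n, pairs)
  expect_identical(ranked$center, ranked2$center)
  # ties are ordered by residue key
  for (vv in unique(ranked$votes)) {
    centers <- ranked$center[ranked$votes == vv]
    idx <- match(centers, query_n$key)
    expect_false(is.unsorted(query_n$resnum[idx]))
  }
})
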