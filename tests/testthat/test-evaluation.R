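# Cross-validation, ROC/AUC, P_random and the top-k trade-off.

test_that("LOOCV classifies exactly 2N patches, protein order irrelevant", {
  ds <- small_dataset(n_proteins = 4, n_residues = 40, seed = 23)
  cv <- loocv_patch_classification(ds, seed = 5)
  preds <- tidy(cv)
  expect_equal(nrow(preds), 8)
  expect_equal(sum(preds$truth == "interface"), 4)
  expect_true(all(preds$total == 3))

  # shuffling protein blocks changes nothing
  ids <- unique(ds$protein_id)
  shuffled <- dplyr::bind_rows(lapply(rev(ids), function(id) {
    dplyr::filter(ds, protein_id == id)
  }))
  cv2 <- loocv_patch_classification(shuffled, seed = 5)
  expect_equal(glance(cv2), glance(cv))

  expect_error(loocv_patch_classification(
    dplyr::filter(ds, protein_id %in% ids[1:2]), seed = 5), ">= 3")
})

test_that("well-separated synthetic classes are classified at the ceiling", {
  ds <- small_dataset(n_proteins = 5, n_residues = 40, separation = 1.2,
                      seed = 29)
  cv <- loocv_patch_classification(ds, seed = 3)
  expect_equal(cv$accuracy, 1.0)
})

test_that("trapezoid AUC equals the rank-statistic oracle; degenerate scores hit 0.5/1/0", {
  roc_points <- patchkernel:::roc_points
  trapezoid_auc <- patchkernel:::trapezoid_auc
  auc_of <- function(scores, labels, total) {
    r <- roc_points(scores, labels, total)
    trapezoid_auc(r$fpr, r$tpr)
  }
  labels <- c(rep(TRUE, 6), rep(FALSE, 14))

  expect_equal(auc_of(rep(3, 20), labels, 10), 0.5)       # constant scores
  expect_equal(auc_of(ifelse(labels, 9, 2), labels, 10), 1.0)  # separating
  expect_equal(auc_of(ifelse(labels, 2, 9), labels, 10), 0.0)  # reversed

  withr::local_seed(47)
  for (i in 1:25) {
    total <- sample(5:30, 1)
    scores <- sample(0:total, 40, replace = TRUE)
    labels <- runif(40) < 0.3
    if (!any(labels) || all(labels)) next
    expect_equal(auc_of(scores, labels, total), rank_auc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("residue-level ROC agrees with the rank oracle end to end", {
  ds <- small_dataset(n_proteins = 4, n_residues = 36, seed = 41)
  rr <- residue_roc(ds, seed = 5, k = 4)
  expect_true(rr$auc >= 0 && rr$auc <= 1)
  expect_equal(rr$auc, rank_auc(rr$scores$votes, rr$scores$is_interface),
               tolerance = 1e-9)
  # one score per surface residue of every protein
  n_surface <- sum(vapply(split(ds, ds$protein_id), function(p) {
    length(surface_residues(p))
  }, numeric(1)))
  expect_equal(nrow(rr$scores), n_surface)
})

test_that("single-class ground truth is an explicit ROC error", {
  ds <- small_dataset(n_proteins = 3, n_residues = 36, seed = 43)
  # confine the interface to buried residues: every scored surface residue
  # is then ground-truth negative
  ds$asa_complex <- ifelse(ds$rel_acc <= 5,
                           ds$asa_unbound - 5, ds$asa_unbound - 0.1)
  # the tiny buried interface patches are edgeless, so the kernel's
  # zero-edge warnings fire along the way; only the final error matters here
  expect_error(suppressWarnings(residue_roc(ds, seed = 1)), "single class")
})

test_that("P_random counts patches at least as interface-rich as the top patch", {
  # 100 singleton patches over 100 residues, 5 of them interface
  keys <- sprintf("A:%d:", 1:100)
  patches <- purrr::map_dfr(keys, function(kk) {
    tibble::tibble(protein_id = "toy", center = kk, label = "unknown",
                   size = 1L, keys = list(kk))
  })
  interface <- keys[1:5]
  expect_equal(p_random(patches, interface, top_patch = patches[1, ]), 0.05)
  # a top patch with zero interface residues qualifies every patch
  expect_equal(p_random(patches, interface, top_patch = patches[50, ]), 1.0)
  # default top patch is the first row (a ranked table's top 1)
  expect_equal(p_random(patches, interface), 0.05)
  # a strictly best top patch gives 1 / N_all
  two_res <- dplyr::bind_rows(
    patches[3:10, ],
    tibble::tibble(protein_id = "toy", center = "A:1:", label = "unknown",
                   size = 2L, keys = list(c("A:1:", "A:2:"))))
  expect_equal(p_random(two_res, interface,
                        top_patch = two_res[nrow(two_res), ]),
               1 / nrow(two_res))
  expect_error(p_random(patches[0, ], interface), "empty patch list")
})

test_that("top-k union coverage/accuracy follow the set arithmetic", {
  keys <- sprintf("A:%d:", 1:40)
  interface <- keys[1:26]
  ranked <- purrr::map_dfr(1:5, function(i) {
    tibble::tibble(protein_id = "toy", center = keys[i], label = "unknown",
                   size = 6L, keys = list(keys[(6 * (i - 1) + 1):(6 * i)]))
  })
  # top patch: 6 residues, all interface, N_int = 26
  one <- topk_coverage_accuracy(ranked, 1, interface)
  expect_equal(one$coverage, 6 / 26)
  expect_equal(one$accuracy, 1.0)
  expect_equal(one$tp, 6)

  many <- topk_coverage_accuracy(ranked, 1:5, interface)
  expect_false(is.unsorted(many$coverage))       # unions only grow
  expect_false(is.unsorted(many$n_pr))
  expect_equal(many$coverage[5], 26 / 26)        # all interface covered
  expect_equal(many$accuracy[5], 26 / 30)

  expect_error(topk_coverage_accuracy(ranked, 1, character(0)),
               "empty interface")
})
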