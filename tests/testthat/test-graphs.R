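# Contact graphs and the shortest-path transform.

test_that("contact rule: closest heavy-atom gap under radii + 0.5 A, strict", {
  two_c <- function(d) toy_protein(rbind(c(0, 0, 0), c(d, 0, 0)))
  # carbon radii 1.70: cutoff 1.70 + 1.70 + 0.5 = 3.9
  expect_true(residues_in_contact(two_c(3.5)[1, ], two_c(3.5)[2, ]))
  expect_false(residues_in_contact(two_c(3.9)[1, ], two_c(3.9)[2, ]))
  expect_true(residues_in_contact(two_c(0)[1, ], two_c(0)[2, ]))
  # the minimum over atom pairs decides: add a far CB to residue 1 of a
  # non-contacting pair, bridging the gap
  prot <- two_c(6.0)
  prot$atoms[[1]] <- dplyr::bind_rows(
    prot$atoms[[1]],
    tibble::tibble(name = "CB", element = "C", x = 3.0, y = 0, z = 0,
                   radius = 1.70))
  expect_true(residues_in_contact(prot[1, ], prot[2, ]))
})

test_that("patch graphs are induced contact graphs with label checks", {
  # 3 collinear residues, consecutive spacing 3.8: path with 2 edges
  prot <- line_protein(3)
  g <- build_patch_graph(prot, prot$key)
  expect_equal(length(g$keys), 3)
  expect_equal(nrow(g$edges), 2)

  # a single residue: 1 node, 0 edges
  g1 <- build_patch_graph(prot, prot$key[1])
  expect_equal(nrow(g1$edges), 0)

  # 4 mutually touching residues: complete graph, 6 edges
  sq <- toy_protein(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0)))
  expect_equal(nrow(build_patch_graph(sq, sq$key)$edges), 6)

  # contacts to residues outside the patch are ignored
  g_sub <- build_patch_graph(prot, prot$key[c(1, 3)])
  expect_equal(nrow(g_sub$edges), 0)

  # unnormalized labels are a state error
  bad <- prot
  bad$rasa <- c(2, 0.5, 0.5)
  expect_error(build_patch_graph(bad, bad$key), "not normalized")
})

test_that("graph construction is invariant to residue input order", {
  withr::local_seed(21)
  prot <- toy_protein(matrix(rnorm(8 * 3, sd = 3), 8, 3),
                      attrs = matrix(runif(8 * 26), 8, 26))
  g <- build_patch_graph(prot, prot$key)
  perm <- sample(8)
  g2 <- build_patch_graph(prot[perm, ], prot$key)  # same key order requested
  expect_identical(g$keys, g2$keys)
  expect_identical(g$edges, g2$edges)
  expect_equal(g$labels, g2$labels)

  # permuted key order gives the same edge set up to the node relabeling
  g3 <- build_patch_graph(prot, prot$key[perm])
  edges_as_keys <- function(g) {
    e <- cbind(g$keys[g$edges[, 1]], g$keys[g$edges[, 2]])
    sorted <- t(apply(e, 1, sort))
    sorted[order(sorted[, 1], sorted[, 2]), , drop = FALSE]
  }
  expect_equal(edges_as_keys(g), edges_as_keys(g3))
})

test_that("shortest-path transform: hop counts, no cross-component edges", {
  prot <- line_protein(3)
  sp <- shortest_path_transform(build_patch_graph(prot, prot$key))
  d <- tidy(sp)
  expect_equal(d$weight[d$from == "A:1:" & d$to == "A:2:"], 1L)
  expect_equal(d$weight[d$from == "A:2:" & d$to == "A:3:"], 1L)
  expect_equal(d$weight[d$from == "A:1:" & d$to == "A:3:"], 2L)

  # two disconnected residues: zero weighted edges
  far <- toy_protein(rbind(c(0, 0, 0), c(50, 0, 0)))
  sp_far <- shortest_path_transform(build_patch_graph(far, far$key))
  expect_equal(nrow(sp_far$edges), 0)

  # K4: 6 edges, all weight 1
  sq <- toy_protein(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0)))
  sp_k4 <- shortest_path_transform(build_patch_graph(sq, sq$key))
  expect_equal(nrow(sp_k4$edges), 6)
  expect_true(all(sp_k4$weights == 1L))
})

test_that("Floyd-Warshall distances match a BFS oracle on 200 random graphs", {
  withr::local_seed(1234)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    g <- random_patch_graph(n, runif(1))  # densities across (0, 1)
    sp <- shortest_path_transform(g)
    ref <- bfs_distances(n, g$edges)

    got <- matrix(Inf, n, n)
    diag(got) <- 0
    if (nrow(sp$edges) > 0) {
      got[sp$edges] <- sp$weights
      got[sp$edges[, 2:1, drop = FALSE]] <- sp$weights
    }
    expect_identical(got, unname(ref))
  }
})

test_that("weighted edges satisfy the triangle inequality within components", {
  withr::local_seed(77)
  for (i in 1:20) {
    g <- random_patch_graph(sample(3:10, 1), runif(1, 0.2, 0.9))
    sp <- shortest_path_transform(g)
    n <- length(sp$keys)
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    if (nrow(sp$edges) > 0) {
      d[sp$edges] <- sp$weights
      d[sp$edges[, 2:1, drop = FALSE]] <- sp$weights
    }
    for (k in seq_len(n)) {
      expect_true(all(d <= outer(d[, k], d[k, ], "+") + 1e-12))
    }
  }
})
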