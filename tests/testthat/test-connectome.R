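test_that("connectome constructor enforces invariants", {
  w <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  c1 <- connectome(w)
  expect_false(c1$weighted)
  expect_false(c1$directed)

  expect_error(connectome(matrix(0, 2, 3)), "square")
  expect_error(connectome(w, labels = c("A", "A")), "unique")
  expect_error(connectome(-w), "negative")
  asym <- w; asym[1, 2] <- 0
  expect_error(connectome(asym, labels = c("A", "B")), "symmetric")
  expect_silent(connectome(asym, labels = c("A", "B"), directed = TRUE))

  selfw <- w; diag(selfw) <- 2
  expect_warning(c2 <- connectome(selfw), "self-connections")
  expect_true(all(diag(c2$weights) == 0))
})

test_that("read/write round trip is bit-exact for both formats", {
  toy <- fig1d_toy()[[1]]
  subj <- generate_subjects(random_connectome(8, 12, weighted = TRUE,
                                              seed = 3),
                            n_subjects = 1, noise_sd = 0.3, seed = 4)[[1]]
  empty <- connectome(matrix(0, 3, 3,
                             dimnames = list(c("A", "B", "C"),
                                             c("A", "B", "C"))),
                      weighted = FALSE)
  for (c0 in list(toy, subj, empty)) {
    for (fmt in c("dense", "edgelist")) {
      path <- withr::local_tempfile(fileext = ".tsv")
      write_connectome(c0, path, fmt)
      c1 <- read_connectome(path, fmt)
      expect_identical(c1$labels, c0$labels)
      expect_identical(c1$weights, c0$weights)
    }
  }
})

test_that("edge-list ingestion handles duplicates, self-pairs, ordering", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t1", "B\tA\t1"), path)
  c1 <- read_connectome(path, "edgelist")
  expect_equal(edge_count(c1), 1)
  expect_equal(c1$weights["A", "B"], 1)

  writeLines(c("A\tA\t1"), path)
  expect_error(read_connectome(path, "edgelist"), "[Ss]elf")

  writeLines(c("A\tB\t1", "B\tA\t2"), path)
  expect_error(read_connectome(path, "edgelist"), "conflicting")

  writeLines(c("A\tB\t-1"), path)
  expect_error(read_connectome(path, "edgelist"), "negative")

  # region table fixes canonical order and rejects unknown labels
  rt <- region_table(c("C", "B", "A"), c("L", "L", "R"))
  writeLines(c("A\tB\t1", "B\tC\t2"), path)
  c2 <- read_connectome(path, "edgelist", region_table = rt)
  expect_identical(c2$labels, c("C", "B", "A"))
  writeLines(c("A\tZ\t1"), path)
  expect_error(read_connectome(path, "edgelist", region_table = rt),
               "absent from region table")
})

test_that("symmetrize_binarize uses any nonzero entry and is idempotent", {
  labs <- c("A", "B", "C")
  w <- matrix(0, 3, 3, dimnames = list(labs, labs))
  w["A", "B"] <- 5          # one-way only
  w["B", "C"] <- 0.2        # weak one-way
  d <- connectome(w, directed = TRUE)
  s <- symmetrize_binarize(d)
  expect_false(s$directed)
  expect_false(s$weighted)
  expect_equal(s$weights["B", "A"], 1)
  expect_equal(s$weights["C", "B"], 1)
  expect_identical(symmetrize_binarize(s)$weights, s$weights)

  # commutes with label permutation
  g <- random_connectome(10, 20, weighted = TRUE, seed = 11)
  perm <- sample(g$labels)
  lhs <- symmetrize_binarize(permute_connectome(g, perm))
  rhs <- permute_connectome(symmetrize_binarize(g), perm)
  expect_identical(lhs$weights, rhs$weights)
})

test_that("average_subjects is the element-wise mean", {
  base <- random_connectome(6, 8, weighted = TRUE, seed = 5)
  expect_identical(average_subjects(list(base, base))$weights, base$weights)

  subj <- generate_subjects(base, n_subjects = 5, noise_sd = 0.4, seed = 6)
  avg <- average_subjects(subj)
  manual <- (subj[[1]]$weights + subj[[2]]$weights + subj[[3]]$weights +
             subj[[4]]$weights + subj[[5]]$weights) / 5
  expect_equal(avg$weights, manual, tolerance = 1e-14)

  expect_error(average_subjects(list()), "empty")
  other <- random_connectome(6, 8, weighted = TRUE, seed = 7,
                             labels = letters[1:6])
  expect_error(average_subjects(list(base, other)), "identical label")
})

test_that("threshold_to_edge_count keeps the largest weights deterministically", {
  labs <- c("A", "B", "C", "D")
  c0 <- conn_from_edges(labs, list(c("A", "B"), c("A", "C"), c("B", "C")),
                        weights = c(3, 2, 1))
  t2 <- threshold_to_edge_count(c0, 2)
  expect_equal(edge_count(t2), 2)
  expect_equal(t2$weights["A", "B"], 1)
  expect_equal(t2$weights["A", "C"], 1)
  expect_equal(t2$weights["B", "C"], 0)

  # boundary: target_L = all nonzero pairs is plain binarization
  t3 <- threshold_to_edge_count(c0, 3)
  expect_identical(t3$weights, symmetrize_binarize(c0)$weights)
  expect_error(threshold_to_edge_count(c0, 4), "exceeds")

  # tie at the cut: lexicographic (from, to) wins, stable across runs
  c1 <- conn_from_edges(labs, list(c("C", "D"), c("A", "D"), c("B", "C"),
                                   c("A", "B")),
                        weights = c(2, 1, 1, 1))
  for (i in 1:3) {
    tt <- threshold_to_edge_count(c1, 2)
    expect_equal(edge_count(tt), 2)
    expect_equal(tt$weights["C", "D"], 1)
    expect_equal(tt$weights["A", "B"], 1)  # "A","B" sorts first among ties
  }

  # exact edge count and exact density identity, ties included
  g <- random_connectome(30, 200, weighted = TRUE, seed = 8)
  g$weights[g$weights > 0] <- round(g$weights[g$weights > 0], 1)  # force ties
  g <- connectome(g$weights, weighted = TRUE)
  for (L in c(1, 50, 117)) {
    th <- threshold_to_edge_count(g, L)
    expect_equal(edge_count(th), L)
    expect_equal(density(th), L / (30 * 29 / 2))
  }
})

test_that("density matches the unordered-pair definition", {
  k4 <- conn_from_edges(LETTERS[1:4],
                        utils::combn(LETTERS[1:4], 2, simplify = FALSE))
  expect_equal(density(k4), 1)
  empty <- connectome(matrix(0, 4, 4, dimnames = list(LETTERS[1:4],
                                                      LETTERS[1:4])))
  expect_equal(density(empty), 0)
})

test_that("split_hemispheres induces within-hemisphere subnetworks", {
  rt <- synthetic_region_table(41)
  g <- random_connectome(82, 1857, seed = 9, labels = rt$label)
  halves <- split_hemispheres(g, rt)
  expect_equal(length(halves$L$labels), 41)
  expect_equal(length(halves$R$labels), 41)

  # brute-force within-hemisphere edge counts over label pairs
  hemi <- setNames(rt$hemisphere, rt$label)
  et <- which(upper.tri(g$weights) & g$weights != 0, arr.ind = TRUE)
  same <- hemi[g$labels[et[, 1]]] == hemi[g$labels[et[, 2]]]
  nL <- sum(same & hemi[g$labels[et[, 1]]] == "L")
  nR <- sum(same & hemi[g$labels[et[, 1]]] == "R")
  expect_equal(edge_count(halves$L), nL)
  expect_equal(edge_count(halves$R), nR)

  # only interhemispheric edges -> two empty subnetworks
  rt2 <- region_table(c("a", "b", "x", "y"), c("L", "L", "R", "R"))
  cross <- conn_from_edges(rt2$label, list(c("a", "x"), c("b", "y")))
  halves2 <- split_hemispheres(cross, rt2)
  expect_equal(edge_count(halves2$L), 0)
  expect_equal(edge_count(halves2$R), 0)

  expect_error(split_hemispheres(cross, region_table("a", "L")),
               "missing from region table")
})

test_that("subject_consistency measures edge persistence and weight agreement", {
  base <- random_connectome(12, 30, weighted = TRUE, seed = 10)
  same <- list(base, base, base)
  res <- subject_consistency(same, target_L = 20, m = 3)
  expect_equal(res$fraction, 1)
  expect_equal(res$pairwise_correlations, rep(1, 3))

  # two subjects with disjoint top-L supports
  labs <- letters[1:6]
  s1 <- conn_from_edges(labs, list(c("a", "b"), c("c", "d")), c(5, 4))
  s2 <- conn_from_edges(labs, list(c("a", "c"), c("b", "d")), c(5, 4))
  res2 <- subject_consistency(list(s1, s2), target_L = 2, m = 2)
  expect_equal(res2$fraction, 0)

  expect_error(subject_consistency(list(base), 5, 1), "at least 2")
  expect_error(subject_consistency(same, 5, 4), "exceeds")

  # brute-force set-intersection count on noisy subjects
  subj <- generate_subjects(base, n_subjects = 5, noise_sd = 0.5, seed = 11)
  res3 <- subject_consistency(subj, target_L = 25, m = 4)
  avg_thr <- threshold_to_edge_count(average_subjects(subj), 25)
  eav <- which(upper.tri(avg_thr$weights) & avg_thr$weights != 0)
  hits <- vapply(eav, function(e) {
    sum(vapply(subj, function(s) {
      st <- threshold_to_edge_count(s, 25)
      st$weights[e] != 0
    }, logical(1)))
  }, numeric(1))
  expect_equal(res3$fraction, mean(hits >= 4))
})
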