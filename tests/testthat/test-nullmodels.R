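test_that("degree_preserving_rewire conserves degrees and actually mixes", {
  k4 <- conn_from_edges(LETTERS[1:4],
                        utils::combn(LETTERS[1:4], 2, simplify = FALSE))
  expect_warning(r <- degree_preserving_rewire(k4, seed = 1), "complete")
  expect_identical(r$weights, k4$weights)

  g <- random_connectome(82, 1857, seed = 2)
  for (s in 1:10) {
    rg <- degree_preserving_rewire(g, seed = s)
    expect_identical(degrees(rg), degrees(g))
    expect_equal(edge_count(rg), 1857)
    # well-mixed: a large share of edges displaced
    moved <- 1857 - sum(adjacency(rg) * adjacency(g)) / 2
    expect_gt(moved, 0.2 * 1857)
  }
  expect_identical(degree_preserving_rewire(g, seed = 4)$weights,
                   degree_preserving_rewire(g, seed = 4)$weights)
})

test_that("link_weight_reshuffle conserves the weight multiset only", {
  single <- conn_from_edges(c("a", "b", "c"), list(c("a", "b")),
                            weights = 2.5)
  rs <- link_weight_reshuffle(single, seed = 3)
  expect_equal(sort(rs$weights[upper.tri(rs$weights)]),
               c(0, 0, 2.5))

  g <- random_connectome(30, 140, weighted = TRUE, seed = 4)
  wts <- sort(g$weights[upper.tri(g$weights) & g$weights != 0])
  strengths_differ <- logical(5)
  for (s in 1:5) {
    rg <- link_weight_reshuffle(g, seed = s)
    expect_identical(degrees(rg), degrees(g))
    expect_equal(sort(rg$weights[upper.tri(rg$weights) & rg$weights != 0]),
                 wts, tolerance = 1e-14)
    strengths_differ[s] <- !isTRUE(all.equal(rowSums(rg$weights),
                                             rowSums(g$weights)))
  }
  expect_true(all(strengths_differ))
})

test_that("perturb implements the two published controls", {
  g <- random_connectome(82, 1857, seed = 5)

  # exactly round(f * L) new edges, all previously absent
  ins <- perturb(g, perturbation_spec("insert_fraction", 0.10, seed = 6))
  expect_equal(edge_count(ins), 1857 + 186)
  expect_true(all(ins$weights[g$weights == 1] == 1))  # originals retained

  expect_identical(perturb(g, perturbation_spec("insert_fraction", 0))$weights,
                   g$weights)
  expect_identical(perturb(g, perturbation_spec("rewire_prob", 0))$weights,
                   g$weights)

  # rewire_prob keeps degrees and L, and retains ~ 1 - p of the edges
  retained <- vapply(1:8, function(s) {
    pg <- perturb(g, perturbation_spec("rewire_prob", 0.1, seed = s))
    expect_identical(degrees(pg), degrees(g))
    sum(adjacency(pg) * adjacency(g)) / 2 / 1857
  }, numeric(1))
  expect_lt(abs(mean(retained) - 0.9), 0.02)

  dense <- conn_from_edges(LETTERS[1:3],
                           utils::combn(LETTERS[1:3], 2, simplify = FALSE))
  expect_error(perturb(dense, perturbation_spec("insert_fraction", 5)),
               "empty positions")
  expect_error(perturbation_spec("rewire_prob", 1.5), "\\[0, 1\\]")
})

test_that("build_ensemble is seed-stable and type-checked", {
  g <- random_connectome(20, 80, seed = 7)
  expect_error(build_ensemble(g, "degree_preserving", 0, 1, "density"),
               "at least 1")
  expect_error(build_ensemble(g, "link_weight_reshuffle", 5, 1, "density"),
               "weighted")
  gw <- random_connectome(20, 80, weighted = TRUE, seed = 7)
  expect_error(build_ensemble(gw, "degree_preserving", 5, 1, "density"),
               "binary")
  expect_error(build_ensemble(g, "degree_preserving", 5, 1, "nope"),
               "unknown statistic")

  ens <- build_ensemble(g, "degree_preserving", 25, seed = 8,
                        statistic = "density")
  expect_s3_class(ens, "null_ensemble")
  expect_equal(ens$size, 25)
  expect_true(all(unlist(ens$values) == density(g)))  # conserved exactly

  e1 <- build_ensemble(g, "degree_preserving", 10, seed = 9,
                       statistic = "rcc_phi")
  e2 <- build_ensemble(g, "degree_preserving", 10, seed = 9,
                       statistic = "rcc_phi")
  expect_identical(e1$values, e2$values)

  # custom closure statistic: intersection against a fixed partner
  partner <- random_connectome(20, 80, seed = 10)
  e3 <- build_ensemble(g, "degree_preserving", 40, seed = 11,
                       statistic = function(x) {
                         intersection_ratio(x, partner)
                       })
  v <- unlist(e3$values)
  expect_true(all(v >= 0 & v <= 1))
  expect_gt(stats::sd(v), 0)
})

test_that("empirical_stats follows the (1 + count) / (1 + n) convention", {
  ens <- c(1, 2, 3)
  res <- empirical_stats(2, ens, "greater")
  expect_equal(res$z, 0)
  expect_equal(res$p, 3 / 4)
  expect_equal(empirical_stats(2.5, ens, "greater")$p, 2 / 4)
  expect_equal(empirical_stats(2.5, ens, "less")$p, 3 / 4)

  big <- seq_len(10000) / 20000          # all nulls below 0.9
  expect_equal(empirical_stats(0.9, big, "greater")$p, 1 / 10001)

  same <- rep(5, 10)
  res2 <- empirical_stats(6, same, "greater")
  expect_true(is.na(res2$z))             # zero null variance
  expect_equal(res2$p, 1 / 11)

  # p always within [1/(n+1), 1]
  for (s in 1:5) {
    nulls <- stats::rnorm(100)
    p <- empirical_stats(stats::rnorm(1), nulls, "greater")$p
    expect_gte(p, 1 / 101)
    expect_lte(p, 1)
  }
  expect_error(empirical_stats(1, numeric(0)), "empty")
})

test_that("correct_pvalues implements Bonferroni and BH step-up", {
  ps <- setNames(rep(1, 5), letters[1:5])
  expect_false(any(correct_pvalues(ps, "bonferroni")))
  expect_false(any(correct_pvalues(ps, "fdr_bh")))

  # m = 82 regions: p = 1e-4 clears 0.05 / 82, p = 1e-3 does not
  ps82 <- setNames(c(1e-4, 1e-3, rep(0.5, 80)), sprintf("r%02d", 1:82))
  sig <- correct_pvalues(ps82, "bonferroni", 0.05)
  expect_true(sig[["r01"]])
  expect_false(sig[["r02"]])

  bh <- correct_pvalues(setNames(c(0.01, 0.02, 0.03, 0.5), letters[1:4]),
                        "fdr_bh", 0.05)
  expect_identical(unname(bh), c(TRUE, TRUE, TRUE, FALSE))

  # NA excluded from m and flagged FALSE
  pna <- setNames(c(0.01, NA, 0.5), letters[1:3])
  sna <- correct_pvalues(pna, "bonferroni", 0.05)
  expect_identical(unname(sna), c(TRUE, FALSE, FALSE))

  expect_error(correct_pvalues(ps, alpha = 1.2), "alpha")
  expect_error(correct_pvalues(setNames(-0.1, "a")), "lie in")
})
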