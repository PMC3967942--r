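k4 <- conn_from_edges(LETTERS[1:4],
                      utils::combn(LETTERS[1:4], 2, simplify = FALSE))
path4 <- conn_from_edges(LETTERS[1:4],
                         list(c("A", "B"), c("B", "C"), c("C", "D")))
star5 <- conn_from_edges(c("hub", "l1", "l2", "l3", "l4"),
                         list(c("hub", "l1"), c("hub", "l2"),
                              c("hub", "l3"), c("hub", "l4")))

test_that("rcc matches subgraph-density enumeration", {
  ck4 <- rcc(k4)
  expect_equal(ck4$phi[ck4$k == 1], 1)
  expect_true(all(ck4$phi[!is.na(ck4$phi)] == 1))

  cp <- rcc(path4)
  expect_equal(cp$phi[cp$k == 1], 1)  # members {B, C}, the B-C edge present
  expect_identical(sort(attr(cp, "members")[["1"]]), c("B", "C"))
  expect_equal(max(cp$k), max(degrees(path4)) - 1)  # k >= max degree absent

  # members shrink weakly as k grows
  g <- random_connectome(25, 90, seed = 1)
  cg <- rcc(g)
  expect_true(all(diff(cg$n_gt_k) <= 0))

  for (s in 1:4) {
    h <- random_connectome(9, sample(6:24, 1), seed = 100 + s)
    ch <- rcc(h)
    oracle <- vapply(ch$k, function(k) oracle_rcc_k(h, k), numeric(1))
    expect_same_na(ch$phi, oracle)
  }
})

test_that("weighted rcc uses the globally top-ranked weight sum", {
  # club edges are exactly the globally strongest -> phi_w = 1
  labs <- letters[1:6]
  g1 <- conn_from_edges(labs, list(c("a", "b"), c("a", "c"), c("b", "c"),
                                   c("a", "d"), c("b", "e"), c("c", "f")),
                        weights = c(9, 8, 7, 1, 1, 1))
  c1 <- weighted_rcc(g1)
  expect_equal(c1$phi[c1$k == 2], 1)  # members {a,b,c}: the 9,8,7 edges

  # unit weights: numerator and denominator both equal E_>k
  g2 <- connectome(random_connectome(12, 40, seed = 2)$weights,
                   weighted = TRUE)
  c2 <- weighted_rcc(g2)
  expect_true(all(c2$phi[!is.na(c2$phi)] == 1))

  for (s in 1:4) {
    h <- random_connectome(9, 18, weighted = TRUE, seed = 110 + s)
    ch <- weighted_rcc(h)
    oracle <- vapply(ch$k, function(k) oracle_wrcc_k(h, k), numeric(1))
    expect_same_na(ch$phi, oracle, tol = 1e-12)
  }
})

test_that("rich_members uses strict degree > k", {
  expect_identical(sort(rich_members(k4, 2)), LETTERS[1:4])
  expect_identical(rich_members(k4, 3), character(0))
  expect_identical(rich_members(star5, 1), "hub")
})

test_that("normalized_rcc behaves against self and matched ensembles", {
  g <- random_connectome(30, 140, seed = 3)
  base <- rcc(g)
  # ensemble of copies of the graph itself -> phi_norm = 1 wherever defined
  self_ens <- structure(list(model_name = "degree_preserving", size = 5,
                             seed = 1,
                             values = replicate(5, base$phi,
                                                simplify = FALSE)),
                        class = "null_ensemble")
  ns <- normalized_rcc(g, ensemble = self_ens)
  expect_equal(ns$phi_norm[!is.na(ns$phi_norm)],
               rep(1, sum(!is.na(ns$phi_norm))), tolerance = 1e-12)

  # seeded runs are reproducible
  r1 <- normalized_rcc(g, n_null = 30, seed = 11)
  r2 <- normalized_rcc(g, n_null = 30, seed = 11)
  expect_identical(r1$phi_norm, r2$phi_norm)
  expect_identical(r1$p, r2$p)
})

test_that("a planted rich club is detected with phi_norm > 1 and small p", {
  # 10 "rich" regions form a clique and each links to 11 of 50 periphery
  # nodes; periphery wiring is random and sparse, so the clique's
  # interconnection density far exceeds the configuration-model expectation
  set.seed(42)
  rich <- sprintf("rich%02d", 1:10)
  peri <- sprintf("p%02d", 1:50)
  labs <- c(rich, peri)
  w <- matrix(0, 60, 60, dimnames = list(labs, labs))
  for (pr in utils::combn(rich, 2, simplify = FALSE)) {
    w[pr[1], pr[2]] <- w[pr[2], pr[1]] <- 1
  }
  for (r in rich) {
    tgt <- sample(peri, 11)
    w[r, tgt] <- 1; w[tgt, r] <- 1
  }
  pg <- igraph::sample_gnm(50, 100)
  pe <- igraph::as_edgelist(pg)
  for (q in seq_len(nrow(pe))) {
    w[peri[pe[q, 1]], peri[pe[q, 2]]] <- 1
    w[peri[pe[q, 2]], peri[pe[q, 1]]] <- 1
  }
  g <- connectome(w, weighted = FALSE)
  expect_true(all(degrees(g)[rich] == 20))
  expect_lt(max(degrees(g)[peri]), 16)

  nr <- normalized_rcc(g, n_null = 300, seed = 7)
  planted <- nr$k >= 15 & nr$k <= 19   # member set is exactly the clique
  expect_true(all(nr$phi_norm[planted] > 1))
  expect_true(all(nr$p[planted] <= 0.01))
})

test_that("overlap_test agrees with the hypergeometric null", {
  g <- random_connectome(20, 80, seed = 4)
  k <- stats::quantile(degrees(g), 0.7)
  mem <- rich_members(g, k)
  res <- overlap_test(g, g, k, k, n_draws = 500, seed = 5)
  expect_equal(res$overlap, length(mem))
  expect_lt(res$p, 0.05)

  # null mean matches m1*m2/N within Monte-Carlo error
  a <- random_connectome(82, 1857, seed = 6)
  b <- random_connectome(82, 1857, seed = 7)
  ka <- sort(degrees(a), decreasing = TRUE)[20] # ~20 members
  kb <- sort(degrees(b), decreasing = TRUE)[20]
  res2 <- overlap_test(a, b, ka, kb, n_draws = 4000, seed = 8)
  nulls <- unlist(res2$null$values)
  hyper_mean <- res2$n_a * res2$n_b / 82
  expect_lt(abs(mean(nulls) - hyper_mean),
            3 * stats::sd(nulls) / sqrt(length(nulls)))

  # planted shared membership of 14/20 is decisively significant
  build_club <- function(members, labels) {
    w <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    for (pr in utils::combn(members, 2, simplify = FALSE)) {
      w[pr[1], pr[2]] <- w[pr[2], pr[1]] <- 1
    }
    connectome(w, weighted = FALSE)
  }
  labs <- sprintf("r%02d", 1:82)
  ca <- build_club(labs[1:20], labs)
  cb <- build_club(labs[7:26], labs)   # 14 shared members
  res3 <- overlap_test(ca, cb, 15, 15, n_draws = 2000, seed = 9)
  expect_equal(res3$overlap, 14)
  expect_lt(res3$p, 0.01)

  empty <- connectome(matrix(0, 82, 82, dimnames = list(labs, labs)))
  expect_error(overlap_test(ca, empty, 15, 0), "empty")
})

test_that("rich_vs_nonrich_test attains its bounds", {
  # members hold the strictly top values -> minimum attainable p (the
  # label universe is large enough that a permutation re-drawing exactly
  # the member set is essentially impossible)
  m <- metric_vector("BC", sprintf("x%02d", 1:30),
                     c(14:10, seq(0.1, 0.9, length.out = 25)))
  res <- rich_vs_nonrich_test(m, sprintf("x%02d", 1:5), n_perm = 99,
                              seed = 10, direction = "greater")
  expect_equal(res$p, 1 / 100)

  # constant metric: every permutation ties the observed difference
  const <- metric_vector("C", letters[1:8], rep(3, 8))
  expect_equal(rich_vs_nonrich_test(const, letters[1:3], n_perm = 50,
                                    seed = 11)$p, 1)

  # direction = "less" flips the tail
  res2 <- rich_vs_nonrich_test(m, sprintf("x%02d", 1:3), n_perm = 99,
                               seed = 12, direction = "less")
  expect_equal(res2$p, 1)

  expect_error(rich_vs_nonrich_test(m, m$labels, 10), "proper subset")
  expect_error(rich_vs_nonrich_test(m, character(0), 10), "proper subset")
})
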