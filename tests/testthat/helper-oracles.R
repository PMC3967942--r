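# Brute-force set-arithmetic oracles, independent of the package's
# vectorized implementations, plus small fixture builders.

# connectome from a list of label pairs
conn_from_edges <- function(labels, edges, weights = NULL) {
  w <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    val <- if (is.null(weights)) 1 else weights[k]
    w[e[1], e[2]] <- val
    w[e[2], e[1]] <- val
  }
  connectome(w, labels = labels, directed = FALSE,
             weighted = !is.null(weights))
}

neighbors_of <- function(c, i) c$labels[c$weights[i, ] != 0]

# Jaccard of neighbor sets across two networks
oracle_hcs <- function(a, b, i) {
  ga <- neighbors_of(a, i); gb <- neighbors_of(b, i)
  u <- union(ga, gb)
  if (!length(u)) return(NA_real_)
  length(intersect(ga, gb)) / length(u)
}

# matching index by explicit set arithmetic, both endpoints excluded
oracle_mi <- function(a, i, j) {
  gi <- setdiff(neighbors_of(a, i), c(i, j))
  gj <- setdiff(neighbors_of(a, j), c(i, j))
  u <- union(gi, gj)
  if (!length(u)) return(NA_real_)
  length(intersect(gi, gj)) / length(u)
}

oracle_mi_matrix <- function(a) {
  n <- length(a$labels)
  m <- matrix(NA_real_, n, n, dimnames = list(a$labels, a$labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) m[i, j] <- oracle_mi(a, a$labels[i], a$labels[j])
  }
  m
}

# rich-club coefficient at one level by pair enumeration
oracle_rcc_k <- function(a, k) {
  d <- rowSums(a$weights != 0)
  mem <- which(d > k)
  if (length(mem) < 2) return(NA_real_)
  e <- 0
  for (p in utils::combn(mem, 2, simplify = FALSE)) {
    if (a$weights[p[1], p[2]] != 0) e <- e + 1
  }
  2 * e / (length(mem) * (length(mem) - 1))
}

# weighted rich-club coefficient at one level by explicit ranking
oracle_wrcc_k <- function(a, k) {
  d <- rowSums(a$weights != 0)
  mem <- which(d > k)
  if (length(mem) < 2) return(NA_real_)
  wsum <- 0; ecnt <- 0
  for (p in utils::combn(mem, 2, simplify = FALSE)) {
    if (a$weights[p[1], p[2]] != 0) {
      wsum <- wsum + a$weights[p[1], p[2]]
      ecnt <- ecnt + 1
    }
  }
  if (ecnt == 0) return(NA_real_)
  allw <- sort(a$weights[upper.tri(a$weights)][
    a$weights[upper.tri(a$weights)] != 0], decreasing = TRUE)
  wsum / sum(allw[seq_len(ecnt)])
}

# all 2^(n(n-1)/2) binary undirected graphs on n labeled nodes
all_graphs <- function(n) {
  npairs <- n * (n - 1) / 2
  labels <- LETTERS[seq_len(n)]
  lapply(0:(2^npairs - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(npairs)]
    w <- matrix(0, n, n, dimnames = list(labels, labels))
    w[upper.tri(w)] <- bits
    w <- w + t(w)
    connectome(w, labels = labels, directed = FALSE, weighted = FALSE)
  })
}

expect_same_na <- function(x, y, tol = 1e-12) {
  expect_identical(is.na(x), is.na(y))
  expect_equal(as.numeric(x[!is.na(x)]), as.numeric(y[!is.na(y)]),
               tolerance = tol, ignore_attr = TRUE)
}
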