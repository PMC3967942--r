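# Cross-species similarity statistics for two connectomes that share a
# parcellation: edge intersection ratio, homologue connectivity similarity
# (HCS), matching index (MI), homologue matching index similarity (HMIS),
# and their weighted variants.
#
# Conventions (documented in the methods vignette):
#  * MI excludes BOTH endpoint regions from both neighbor sets before
#    intersecting/uniting. This is the only exclusion convention that
#    reproduces the analytic toy value HMIS(A) = -0.5 on the four-node pair.
#  * Undefined values (empty union, zero variance, zero norm) are NA and are
#    propagated, never silently replaced by 0; row correlations drop NA
#    pairwise and require at least `min_pairs` valid entries.

MIN_COR_PAIRS <- 3L

#' Edge intersection ratio of two binary connectomes
#'
#' The number of edges common to both networks divided by the (shared) total
#' edge count \eqn{L}: \eqn{L_x / L \in [0, 1]}, 0 meaning disjoint edge sets
#' and 1 identical wiring.
#'
#' @param a,b binary undirected connectomes with identical labels and equal
#'   edge counts.
#' @param allow_unequal if \code{TRUE}, unequal edge counts produce a warning
#'   and the denominator is \eqn{L(a)}; otherwise they are an error.
#' @return scalar in \eqn{[0, 1]}.
#' @export
#' @examples
#' toy <- fig1d_toy()
#' intersection_ratio(toy[[1]], toy[[2]])  # 0.75
intersection_ratio <- function(a, b, allow_unequal = FALSE) {
  stopifnot_connectome(a, undirected = TRUE, binary = TRUE)
  stopifnot_connectome(b, undirected = TRUE, binary = TRUE)
  stopifnot_same_labels(a, b)
  la <- edge_count(a); lb <- edge_count(b)
  if (la != lb) {
    if (!allow_unequal) {
      stop("edge counts differ (", la, " vs ", lb,
           "); threshold to a common L or set allow_unequal = TRUE")
    }
    warning("edge counts differ; dividing the intersection by L(a) = ", la)
  }
  x <- adjacency(a) * adjacency(b)
  sum(x[upper.tri(x)]) / la
}

#' Homologue connectivity similarity (HCS)
#'
#' For each region \eqn{i}, the Jaccard similarity of its neighbor sets in
#' the two networks:
#' \eqn{HCS_i = |\Gamma_a(i) \cap \Gamma_b(i)| / |\Gamma_a(i) \cup \Gamma_b(i)|}.
#' A region isolated in both networks has an empty union and is returned as
#' \code{NA} (undefined), not 0.
#'
#' @param a,b binary undirected connectomes with identical labels.
#' @return named numeric vector in \eqn{[0, 1]} (or \code{NA}).
#' @export
#' @examples
#' toy <- fig1d_toy()
#' hcs(toy[[1]], toy[[2]])[["A"]]  # 1
hcs <- function(a, b) {
  stopifnot_connectome(a, undirected = TRUE, binary = TRUE)
  stopifnot_connectome(b, undirected = TRUE, binary = TRUE)
  stopifnot_same_labels(a, b)
  hcs_matrices(adjacency(a), adjacency(b), a$labels)
}

# matrix-level fast path shared with the null-ensemble loops
hcs_matrices <- function(A, B, labels) {
  inter <- rowSums(A * B)
  uni <- rowSums((A + B) != 0)
  out <- ifelse(uni == 0, NA_real_, inter / uni)
  setNames(as.numeric(out), labels)
}

#' Matching index matrix
#'
#' Neighborhood-overlap similarity between every pair of regions of one
#' network: \eqn{MI_{ij} = |(\Gamma(i) \cap \Gamma(j)) \setminus \{i,j\}| /
#' |(\Gamma(i) \cup \Gamma(j)) \setminus \{i,j\}|}. Both endpoint regions
#' are excluded from both neighbor sets before intersecting, so a direct
#' \eqn{i}-\eqn{j} edge does not by itself contribute similarity. The
#' diagonal is \code{NA} (self-similarity is undefined), as is any pair with
#' an empty union after the exclusion.
#'
#' @param a a binary undirected connectome.
#' @return symmetric numeric matrix with entries in \eqn{[0, 1]} or \code{NA},
#'   labeled by region.
#' @export
matching_index <- function(a) {
  stopifnot_connectome(a, undirected = TRUE, binary = TRUE)
  matching_index_matrix(adjacency(a), a$labels)
}

matching_index_matrix <- function(A, labels) {
  # Common neighbors excluding endpoints: diag(A) = 0 makes the i/j terms of
  # the inner product vanish, so A %*% A already is the excluded count.
  common <- A %*% A
  deg <- rowSums(A)
  uni <- outer(deg, deg, `+`) - common - 2 * A
  mi <- ifelse(uni == 0, NA_real_, common / uni)
  diag(mi) <- NA_real_
  dimnames(mi) <- list(labels, labels)
  mi
}

# Pearson correlation of corresponding rows of two MI-type matrices,
# diagonal excluded, NA dropped pairwise, >= min_pairs valid entries and
# nonzero variance in both rows required.
row_correlations <- function(ma, mb, labels, min_pairs = MIN_COR_PAIRS) {
  n <- nrow(ma)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    x <- ma[i, -i]; y <- mb[i, -i]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_pairs) next
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    out[i] <- stats::cor(x, y)
  }
  setNames(out, labels)
}

#' Homologue matching index similarity (HMIS)
#'
#' A "second-order" similarity: for each region \eqn{i}, the Pearson
#' correlation between row \eqn{i} of the two networks' matching-index
#' matrices (diagonal entries excluded — no self-similarity values). It asks
#' whether a region's connectivity-similarity profile with the rest of the
#' brain is preserved across the two networks. Values range over
#' \eqn{[-1, 1]}; rows with fewer than 3 valid paired entries or zero
#' variance give \code{NA}.
#'
#' @param a,b binary undirected connectomes with identical labels.
#' @return named numeric vector in \eqn{[-1, 1]} (or \code{NA}).
#' @export
#' @examples
#' toy <- fig1d_toy()
#' hmis(toy[[1]], toy[[2]])[["A"]]  # -0.5
hmis <- function(a, b) {
  stopifnot_connectome(a, undirected = TRUE, binary = TRUE)
  stopifnot_connectome(b, undirected = TRUE, binary = TRUE)
  stopifnot_same_labels(a, b)
  row_correlations(matching_index_matrix(adjacency(a), a$labels),
                   matching_index_matrix(adjacency(b), b$labels),
                   a$labels)
}

#' Weighted matching index matrix (cosine similarity of weight rows)
#'
#' Weighted analogue of \code{\link{matching_index}}: entry \eqn{(i, j)} is
#' the cosine similarity of weight rows \eqn{i} and \eqn{j}, after zeroing
#' positions \eqn{i} and \eqn{j} in both rows (the mirror of the binary
#' endpoint exclusion). Values lie in \eqn{[0, 1]} for nonnegative weights;
#' a zero row after exclusion gives \code{NA}.
#'
#' @param a an undirected weighted connectome with nonnegative weights.
#' @return symmetric labeled numeric matrix, diagonal \code{NA}.
#' @export
weighted_matching_index <- function(a) {
  stopifnot_connectome(a, undirected = TRUE)
  weighted_matching_index_matrix(a$weights, a$labels)
}

weighted_matching_index_matrix <- function(W, labels) {
  # with diag(W) = 0, (W %*% W)[i,j] is already the dot product of rows i
  # and j with positions i and j excluded; the norms only need the (i,j)
  # entry removed.
  S <- W %*% W
  r2 <- rowSums(W^2)
  ni2 <- outer(r2, rep(1, length(r2))) - W^2  # ||row_i without pos j||^2
  denom2 <- ni2 * t(ni2)
  mi <- ifelse(denom2 == 0, NA_real_, S / sqrt(denom2))
  diag(mi) <- NA_real_
  dimnames(mi) <- list(labels, labels)
  mi
}

#' Weighted homologue matching index similarity
#'
#' As \code{\link{hmis}}, but correlating rows of the two
#' \code{\link{weighted_matching_index}} matrices. With unit weights it
#' reduces to a monotone analogue of the binary HMIS (identical on the toy
#' pair). Restricted to within-network weight structure, so it remains valid
#' when the two networks' weight scales are not directly comparable.
#'
#' @param a,b undirected weighted connectomes with identical labels.
#' @return named numeric vector in \eqn{[-1, 1]} (or \code{NA}).
#' @export
weighted_hmis <- function(a, b) {
  stopifnot_connectome(a, undirected = TRUE)
  stopifnot_connectome(b, undirected = TRUE)
  stopifnot_same_labels(a, b)
  row_correlations(weighted_matching_index_matrix(a$weights, a$labels),
                   weighted_matching_index_matrix(b$weights, b$labels),
                   a$labels)
}
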