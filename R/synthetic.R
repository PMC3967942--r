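# Synthetic test worlds: the four-node toy pair, random connectomes, paired
# binary connectomes with planted edge overlap / preserved / rewired
# regions, and multi-subject weighted matrices. Everything is reproducible
# from a single integer seed, so the whole pipeline runs with no downloads.

#' Four-node toy connectome pair
#'
#' Two hypothetical four-region "brains", each with 4 connections, that
#' dissociate first-order and second-order connectivity similarity: region A
#' is connected to B, C and D in both networks (neighbor-set Jaccard
#' \code{\link{hcs}} = 1), yet the single rewired connection (B-C in network
#' 1 becomes C-D in network 2) flips A's connectivity-similarity profile
#' (\code{\link{hmis}} = -0.5).
#'
#' @return list of two binary undirected connectomes with labels
#'   \code{A, B, C, D}; network 1 has edges \{A-B, A-C, A-D, B-C\}, network
#'   2 has edges \{A-B, A-C, A-D, C-D\}.
#' @export
#' @examples
#' toy <- fig1d_toy()
#' hcs(toy[[1]], toy[[2]])[["A"]]   # 1
#' hmis(toy[[1]], toy[[2]])[["A"]]  # -0.5
fig1d_toy <- function() {
  labs <- c("A", "B", "C", "D")
  mk <- function(edges, tag) {
    w <- matrix(0, 4, 4, dimnames = list(labs, labs))
    for (e in edges) {
      w[e[1], e[2]] <- 1; w[e[2], e[1]] <- 1
    }
    connectome(w, labels = labs, directed = FALSE, weighted = FALSE,
               species_tag = tag)
  }
  list(
    mk(list(c("A", "B"), c("A", "C"), c("A", "D"), c("B", "C")), "toy1"),
    mk(list(c("A", "B"), c("A", "C"), c("A", "D"), c("C", "D")), "toy2")
  )
}

#' Synthetic region table
#'
#' Labels \code{R01.L ... Rnn.L, R01.R ... Rnn.R} with lobe classes cycled
#' over the cortical lobes; mirrors an n-regions-per-hemisphere bilateral
#' parcellation.
#'
#' @param n_per_hemisphere regions per hemisphere (default 41, i.e. 82
#'   regions in total).
#' @return a \code{\link{region_table}}.
#' @export
synthetic_region_table <- function(n_per_hemisphere = 41) {
  lobes <- c("frontal", "temporal", "parietal", "occipital", "limbic",
             "insular")
  base <- sprintf("R%02d", seq_len(n_per_hemisphere))
  region_table(
    label = c(paste0(base, ".L"), paste0(base, ".R")),
    hemisphere = rep(c("L", "R"), each = n_per_hemisphere),
    lobe_class = rep(rep_len(lobes, n_per_hemisphere), 2))
}

#' Random connectome
#'
#' A uniform G(n, L) random graph; weighted variants draw edge weights from
#' a log-normal distribution (meanlog 0, sdlog 1), a common shape for
#' tractography-derived connection weights.
#'
#' @param n_regions number of regions.
#' @param n_edges number of edges.
#' @param weighted logical.
#' @param seed integer seed.
#' @param labels optional label vector (default \code{R01 ...}).
#' @param species_tag dataset tag.
#' @return an undirected connectome.
#' @export
random_connectome <- function(n_regions, n_edges, weighted = FALSE,
                              seed = NULL, labels = NULL, species_tag = "") {
  npairs <- n_regions * (n_regions - 1) / 2
  if (n_edges > npairs) stop("n_edges exceeds the number of region pairs")
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(n_regions))
  with_seed(seed, {
    w <- matrix(0, n_regions, n_regions, dimnames = list(labels, labels))
    sel <- sample.int(npairs, n_edges)
    ut <- which(upper.tri(w))
    w[ut[sel]] <- if (weighted) stats::rlnorm(n_edges) else 1
    w <- w + t(w)
    connectome(w, labels = labels, directed = FALSE, weighted = weighted,
               species_tag = species_tag)
  })
}

#' Specification for a planted connectome pair
#'
#' Describes two binary undirected connectomes with identical labels and
#' edge count, a planted fraction of shared edges, a set of regions whose
#' neighborhoods are forced identical across the pair ("preserved"), and a
#' set whose neighborhoods are maximally scrambled subject to degree
#' constraints ("rewired").
#'
#' @param n_regions number of regions.
#' @param n_edges edge count L of both networks.
#' @param edge_overlap planted fraction of shared edges in \eqn{[0, 1]}.
#' @param preserved_regions labels (or indices into \code{labels}) of
#'   preserved regions.
#' @param rewired_regions labels (or indices) of rewired regions; disjoint
#'   from the preserved set.
#' @param seed integer seed.
#' @param labels optional label vector (default from
#'   \code{\link{synthetic_region_table}} when \code{n_regions} is even,
#'   else \code{R01 ...}).
#' @return object of class \code{"planted_pair_spec"}.
#' @export
planted_pair_spec <- function(n_regions, n_edges, edge_overlap,
                              preserved_regions = character(),
                              rewired_regions = character(),
                              seed = 1, labels = NULL) {
  if (is.null(labels)) {
    labels <- if (n_regions %% 2 == 0) {
      synthetic_region_table(n_regions / 2)$label
    } else sprintf("R%02d", seq_len(n_regions))
  }
  if (length(labels) != n_regions) stop("labels length must equal n_regions")
  as_labels <- function(x) {
    if (is.numeric(x)) labels[x] else as.character(x)
  }
  preserved_regions <- as_labels(preserved_regions)
  rewired_regions <- as_labels(rewired_regions)
  if (!all(c(preserved_regions, rewired_regions) %in% labels)) {
    stop("preserved/rewired regions must be among the labels")
  }
  if (length(intersect(preserved_regions, rewired_regions))) {
    stop("preserved and rewired region sets must be disjoint")
  }
  npairs <- n_regions * (n_regions - 1) / 2
  if (n_edges > npairs) stop("n_edges exceeds the number of region pairs")
  if (edge_overlap < 0 || edge_overlap > 1) {
    stop("edge_overlap must lie in [0, 1]")
  }
  structure(list(n_regions = n_regions, n_edges = n_edges,
                 edge_overlap = edge_overlap,
                 preserved_regions = preserved_regions,
                 rewired_regions = rewired_regions,
                 seed = seed, labels = labels),
            class = "planted_pair_spec")
}

#' Generate a planted connectome pair
#'
#' Construction: network A is uniform G(n, L); network B starts as a copy.
#' Rewired regions are scrambled by degree-preserving double-edge swaps
#' confined to their incident edges (never touching preserved regions), then
#' additional shared edges are exchanged for pairs absent from both networks
#' until the shared edge count equals \code{round(edge_overlap * L)} (the
#' exchange step does not touch preserved- or rewired-incident pairs).
#' Both networks keep exactly L edges; preserved regions keep identical
#' neighborhoods (so their \code{\link{hcs}} is exactly 1); the realized
#' overlap is within 2 edges of the planted value, or an infeasibility
#' error is raised.
#'
#' @param spec a \code{\link{planted_pair_spec}}.
#' @return list of two binary undirected connectomes (\code{a}, \code{b}).
#' @export
generate_planted_pair <- function(spec) {
  if (!inherits(spec, "planted_pair_spec")) {
    stop("spec must be a planted_pair_spec")
  }
  n <- spec$n_regions; L <- spec$n_edges; labels <- spec$labels
  target <- round(spec$edge_overlap * L)
  pres_idx <- match(spec$preserved_regions, labels)
  rew_idx <- match(spec$rewired_regions, labels)
  with_seed(spec$seed, {
    A <- matrix(0L, n, n)
    ut <- which(upper.tri(A))
    A[ut[sample.int(length(ut), L)]] <- 1L
    A <- A + t(A)
    B <- A
    shared <- L
    is_pres <- seq_len(n) %in% pres_idx

    # -- targeted scrambling of rewired regions (degree-preserving) --------
    for (r in rew_idx) {
      for (round_i in 1:4) {
        orig_nb <- which(A[r, ] == 1 & B[r, ] == 1 & !is_pres)
        if (!length(orig_nb)) break
        for (x in sample(orig_nb)) {
          if (B[r, x] == 0) next
          eb <- which(upper.tri(B) & B == 1)
          cand <- eb[sample.int(length(eb), min(30, length(eb)))]
          done <- FALSE
          for (e in cand) {
            u <- (e - 1) %% n + 1; v <- (e - 1) %/% n + 1
            if (any(c(u, v) %in% c(r, x)) || is_pres[u] || is_pres[v]) next
            # re-pair (r,x),(u,v) -> (r,v),(u,x)
            if (B[r, v] == 1 || B[u, x] == 1) {
              tmp <- u; u <- v; v <- tmp   # try other orientation
              if (B[r, v] == 1 || B[u, x] == 1) next
            }
            delta <- -(A[r, x] == 1) - (A[u, v] == 1) +
              (A[r, v] == 1) + (A[u, x] == 1)
            if (shared + delta < target) next
            B[r, x] <- B[x, r] <- 0L
            B[u, v] <- B[v, u] <- 0L
            B[r, v] <- B[v, r] <- 1L
            B[u, x] <- B[x, u] <- 1L
            shared <- shared + delta
            done <- TRUE
            break
          }
          if (!done) next
        }
      }
    }

    # -- generic overlap adjustment (edge count preserved) -----------------
    if (shared > target) {
      n_ops <- shared - target
      touched <- is_pres | seq_len(n) %in% rew_idx
      pair_free <- outer(!touched, !touched, `&`)
      removable <- which(upper.tri(B) & B == 1 & A == 1 & pair_free)
      insertable <- which(upper.tri(B) & B == 0 & A == 0 & pair_free)
      if (length(removable) < n_ops || length(insertable) < n_ops) {
        stop("infeasible planted-pair spec: overlap/rewiring constraints ",
             "cannot be met at this density")
      }
      rem <- sample(removable, n_ops)
      ins <- sample(insertable, n_ops)
      B[rem] <- 0L
      B[ins] <- 1L
      B[lower.tri(B)] <- 0L   # upper triangle is authoritative; re-mirror
      B <- B + t(B)
      shared <- target
    }
    if (abs(shared - target) > 2) {
      stop("infeasible planted-pair spec: realized overlap ", shared,
           " misses the planted ", target, " by more than 2 edges")
    }
    a <- connectome(A, labels = labels, directed = FALSE, weighted = FALSE,
                    species_tag = "planted_a")
    b <- connectome(B, labels = labels, directed = FALSE, weighted = FALSE,
                    species_tag = "planted_b")
    list(a = a, b = b)
  })
}

#' Generate per-subject weighted connectomes
#'
#' Each subject equals the base connectome plus independent symmetric
#' Gaussian noise (applied to every off-diagonal pair, then clipped at
#' zero), emulating inter-subject variability of tractography weight
#' matrices around a shared backbone. The default noise level
#' (\code{noise_sd = 0.7} against the log-normal weights of
#' \code{\link{random_connectome}}) puts pairwise inter-subject weight
#' correlations in the mid-0.8s, the regime reported for real
#' tractography cohorts.
#'
#' @param base undirected weighted connectome.
#' @param n_subjects number of subjects (default 5).
#' @param noise_sd standard deviation of the additive noise (>= 0).
#' @param seed integer seed.
#' @return list of weighted undirected connectomes.
#' @export
generate_subjects <- function(base, n_subjects = 5, noise_sd = 0.7,
                              seed = NULL) {
  stopifnot_connectome(base, undirected = TRUE)
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  n <- length(base$labels)
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      e <- matrix(0, n, n)
      e[upper.tri(e)] <- stats::rnorm(n * (n - 1) / 2, sd = noise_sd)
      e <- e + t(e)
      w <- pmax(base$weights + e, 0)
      diag(w) <- 0
      connectome(w, labels = base$labels, directed = FALSE, weighted = TRUE,
                 species_tag = sprintf("subject%02d", s))
    })
  })
}
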