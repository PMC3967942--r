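# Null-network generation, robustness perturbations, and the empirical
# statistics (z, p, multiple-testing correction) shared by all analyses.

# lightweight constructor for hot loops; callers guarantee validity
new_connectome_unsafe <- function(w, labels, directed, weighted, tag) {
  dimnames(w) <- list(labels, labels)
  structure(list(labels = labels, weights = w, directed = directed,
                 weighted = weighted, species_tag = tag),
            class = "connectome")
}

rewired_adjacency <- function(g, niter) {
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = niter))
  igraph::as_adjacency_matrix(g2, sparse = FALSE)
}

#' Degree-preserving rewiring (double-edge swaps)
#'
#' Randomizes the topology of a binary undirected connectome while
#' conserving every region's degree exactly, via repeated double-edge swaps
#' (no self-loops or multi-edges are ever created). The default of 10
#' attempted swaps per edge is a standard mixing heuristic.
#'
#' @param c binary undirected connectome.
#' @param n_swap_per_edge attempted swaps per edge; the total number of
#'   attempts is \code{round(n_swap_per_edge * L)}.
#' @param seed integer seed (optional; uses the current RNG stream if
#'   \code{NULL}).
#' @return a rewired binary undirected connectome with the same degree
#'   sequence.
#' @export
degree_preserving_rewire <- function(c, n_swap_per_edge = 10, seed = NULL) {
  stopifnot_connectome(c, undirected = TRUE, binary = TRUE)
  L <- edge_count(c)
  n <- length(c$labels)
  if (L == 0 || L == n * (n - 1) / 2) {
    warning("graph is empty or complete; no feasible swap, returning a copy")
    return(c)
  }
  with_seed(seed, {
    a <- rewired_adjacency(as_igraph(c), niter = max(1L, round(n_swap_per_edge * L)))
    new_connectome_unsafe(a, c$labels, FALSE, FALSE, c$species_tag)
  })
}

#' Link-and-weight reshuffle null model for weighted networks
#'
#' Rewires the binary support degree-preservingly, then randomly permutes
#' the multiset of edge weights over the new edges. The weight multiset is
#' conserved exactly; the strength (weighted degree) sequence generally is
#' not.
#'
#' @param c undirected weighted connectome.
#' @param seed integer seed (optional).
#' @param n_swap_per_edge attempted swaps per edge for the topology step.
#' @return a reshuffled undirected weighted connectome.
#' @export
link_weight_reshuffle <- function(c, seed = NULL, n_swap_per_edge = 10) {
  stopifnot_connectome(c, undirected = TRUE, weighted = TRUE)
  L <- edge_count(c)
  n <- length(c$labels)
  if (L == 0) {
    warning("empty graph; returning a copy")
    return(c)
  }
  with_seed(seed, {
    if (L == n * (n - 1) / 2) {
      warning("complete graph; topology fixed, reshuffling weights only")
      a <- adjacency(c)
    } else {
      a <- rewired_adjacency(as_igraph(symmetrize_binarize(c)),
                             niter = max(1L, round(n_swap_per_edge * L)))
    }
    reshuffle_weights_on(a, c)
  })
}

# place c's weight multiset, randomly permuted, onto support matrix `a`
reshuffle_weights_on <- function(a, c) {
  wts <- c$weights[upper.tri(c$weights)]
  wts <- wts[wts != 0]
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  perm <- sample.int(length(wts))
  w <- matrix(0, nrow(a), ncol(a))
  w[idx] <- wts[perm]
  w <- w + t(w)
  new_connectome_unsafe(w, c$labels, FALSE, TRUE, c$species_tag)
}

#' Perturbation specification
#'
#' Describes a robustness perturbation: \code{"rewire_prob"} (each edge
#' enters a degree-preserving double-edge swap with the given probability)
#' or \code{"insert_fraction"} (a fraction of L new edges inserted uniformly
#' into empty positions, emulating the appearance of previously absent
#' connections).
#'
#' @param kind \code{"rewire_prob"} or \code{"insert_fraction"}.
#' @param parameter probability in \eqn{[0,1]} (rewire) or nonnegative
#'   fraction (insert).
#' @param seed integer seed.
#' @return object of class \code{"perturbation_spec"}.
#' @export
perturbation_spec <- function(kind = c("rewire_prob", "insert_fraction"),
                              parameter, seed = NULL) {
  kind <- match.arg(kind)
  parameter <- as.numeric(parameter)
  if (kind == "rewire_prob" && (parameter < 0 || parameter > 1)) {
    stop("rewire_prob must lie in [0, 1]")
  }
  if (kind == "insert_fraction" && parameter < 0) {
    stop("insert_fraction must be nonnegative")
  }
  structure(list(kind = kind, parameter = parameter, seed = seed),
            class = "perturbation_spec")
}

#' Apply a robustness perturbation to a connectome
#'
#' \code{rewire_prob}: every edge is considered once in random order and
#' enters the swap pool with the given probability; pooled edges are paired
#' and double-edge-swapped where feasible, so the degree sequence and edge
#' count are preserved. \code{insert_fraction}: exactly
#' \code{round(fraction * L)} new edges are added uniformly at random in
#' empty positions; degrees are not preserved and the density rises
#' accordingly.
#'
#' @param c binary undirected connectome.
#' @param spec a \code{\link{perturbation_spec}}.
#' @return the perturbed connectome.
#' @export
perturb <- function(c, spec) {
  stopifnot_connectome(c, undirected = TRUE, binary = TRUE)
  if (!inherits(spec, "perturbation_spec")) {
    stop("spec must be a perturbation_spec")
  }
  with_seed(spec$seed, {
    if (spec$kind == "rewire_prob") {
      perturb_rewire(c, spec$parameter)
    } else {
      perturb_insert(c, spec$parameter)
    }
  })
}

perturb_rewire <- function(c, prob) {
  if (prob == 0) return(c)
  a <- adjacency(c)
  et <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  L <- nrow(et)
  if (L < 2) return(c)
  # every edge is considered once; with probability `prob` it enters the
  # swap pool; pooled edges are then paired with a feasible ("eligible")
  # partner from the pool, so ~prob*L edges end up displaced.
  pool <- which(stats::runif(L) < prob)
  pool <- pool[sample.int(length(pool))]
  while (length(pool) >= 2) {
    q1 <- pool[1]
    pool <- pool[-1]
    e1 <- et[q1, ]
    swapped_with <- NA_integer_
    for (idx in seq_along(pool)) {
      q2 <- pool[idx]
      e2 <- et[q2, ]
      if (anyDuplicated(c(e1, e2))) next
      ok <- FALSE
      for (o in sample(1:2)) {   # the two possible re-pairings
        if (o == 1) {
          new1 <- c(e1[1], e2[1]); new2 <- c(e1[2], e2[2])
        } else {
          new1 <- c(e1[1], e2[2]); new2 <- c(e1[2], e2[1])
        }
        if (a[new1[1], new1[2]] == 0 && a[new2[1], new2[2]] == 0) {
          a[e1[1], e1[2]] <- a[e1[2], e1[1]] <- 0
          a[e2[1], e2[2]] <- a[e2[2], e2[1]] <- 0
          a[new1[1], new1[2]] <- a[new1[2], new1[1]] <- 1
          a[new2[1], new2[2]] <- a[new2[2], new2[1]] <- 1
          ok <- TRUE
          break
        }
      }
      if (ok) {
        swapped_with <- idx
        break
      }
    }
    if (!is.na(swapped_with)) pool <- pool[-swapped_with]
  }
  new_connectome_unsafe(a, c$labels, FALSE, FALSE, c$species_tag)
}

perturb_insert <- function(c, fraction) {
  a <- adjacency(c)
  L <- sum(a[upper.tri(a)])
  n_add <- round(fraction * L)
  if (n_add == 0) return(c)
  empty <- which(upper.tri(a) & a == 0)
  if (length(empty) < n_add) {
    stop("not enough empty positions to insert ", n_add, " edges")
  }
  add <- sample(empty, n_add)
  a[add] <- 1
  a <- pmax(a, t(a))  # mirror inserted upper-triangle entries
  new_connectome_unsafe(a, c$labels, FALSE, FALSE, c$species_tag)
}

#' Build a null ensemble of statistic values
#'
#' Generates \code{n} independent null networks from the requested model and
#' evaluates a statistic on each. Nulls match the observed network in node
#' count, edge count and degree distribution (degree-preserving model for
#' binary networks; link-and-weight reshuffle for weighted ones). Graphs are
#' not retained, only the statistic values, plus the seed for replay.
#'
#' @param c the observed connectome.
#' @param model_name \code{"degree_preserving"} or
#'   \code{"link_weight_reshuffle"}.
#' @param n ensemble size (>= 1).
#' @param seed integer seed.
#' @param statistic a function taking a connectome and returning a numeric
#'   scalar or vector, or one of the registered names \code{"density"},
#'   \code{"rcc_phi"}, \code{"weighted_rcc_phi"}.
#' @param n_swap_per_edge mixing parameter passed to the rewiring step.
#' @return object of class \code{"null_ensemble"}: a list with
#'   \code{model_name}, \code{size}, \code{seed} and \code{values} (a list
#'   of statistic outcomes).
#' @export
build_ensemble <- function(c, model_name = c("degree_preserving",
                                             "link_weight_reshuffle"),
                           n, seed = NULL, statistic,
                           n_swap_per_edge = 10) {
  model_name <- match.arg(model_name)
  stopifnot_connectome(c, undirected = TRUE)
  if (n < 1) stop("ensemble size must be at least 1")
  if (model_name == "degree_preserving" && c$weighted) {
    stop("degree_preserving model requires a binary connectome")
  }
  if (model_name == "link_weight_reshuffle" && !c$weighted) {
    stop("link_weight_reshuffle model requires a weighted connectome")
  }
  stat_fun <- resolve_statistic(statistic)
  L <- edge_count(c)
  niter <- max(1L, round(n_swap_per_edge * L))
  g <- as_igraph(if (c$weighted) symmetrize_binarize(c) else c)
  values <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- rewired_adjacency(g, niter)
      nc <- if (model_name == "degree_preserving") {
        new_connectome_unsafe(a, c$labels, FALSE, FALSE, c$species_tag)
      } else {
        reshuffle_weights_on(a, c)
      }
      stat_fun(nc)
    })
  })
  structure(list(model_name = model_name, size = n, seed = seed,
                 values = values),
            class = "null_ensemble")
}

resolve_statistic <- function(statistic) {
  if (is.function(statistic)) return(statistic)
  switch(as.character(statistic),
         density = function(c) density(c),
         rcc_phi = function(c) rcc(c)$phi,
         weighted_rcc_phi = function(c) weighted_rcc(c)$phi,
         stop("unknown statistic: ", statistic))
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble %s: n = %d, seed = %s>\n", x$model_name,
              x$size, x$seed %||% "NULL"))
  invisible(x)
}

ensemble_matrix <- function(ensemble) {
  vals <- if (inherits(ensemble, "null_ensemble")) ensemble$values
          else ensemble
  if (is.numeric(vals)) vals <- as.list(vals)
  do.call(rbind, lapply(vals, as.numeric))
}

#' Empirical z-score and p-value against a null ensemble
#'
#' \eqn{z = (obs - mean_{null}) / sd_{null}} (sample SD; \code{NA} when the
#' null SD is zero) and the empirical tail probability
#' \eqn{p = (1 + \#\{null\ at\ least\ as\ extreme\}) / (1 + n)}. The +1
#' convention keeps p strictly positive; with \eqn{n = 10000} nulls the
#' smallest attainable p is about 1e-4.
#'
#' @param observed observed scalar statistic.
#' @param ensemble a \code{"null_ensemble"} of scalars, or a numeric vector
#'   of null values.
#' @param side \code{"greater"} (observed large under the alternative) or
#'   \code{"less"}.
#' @return list with \code{z}, \code{p}, \code{null_mean}, \code{null_std},
#'   \code{n}.
#' @export
empirical_stats <- function(observed, ensemble, side = c("greater", "less")) {
  side <- match.arg(side)
  vals <- if (inherits(ensemble, "null_ensemble")) {
    unlist(ensemble$values)
  } else as.numeric(ensemble)
  if (!length(vals)) stop("empty null ensemble")
  m <- mean(vals); s <- stats::sd(vals)
  z <- if (is.na(s) || s == 0) NA_real_ else (observed - m) / s
  extreme <- if (side == "greater") sum(vals >= observed)
             else sum(vals <= observed)
  p <- (1 + extreme) / (1 + length(vals))
  list(z = z, p = p, null_mean = m, null_std = s, n = length(vals))
}

# vectorized form: obs is a vector, nulls a matrix with one row per draw
empirical_stats_vec <- function(obs, null_matrix, side = "greater") {
  m <- colMeans(null_matrix, na.rm = TRUE)
  s <- apply(null_matrix, 2, stats::sd, na.rm = TRUE)
  z <- ifelse(is.na(s) | s == 0, NA_real_, (obs - m) / s)
  nn <- colSums(!is.na(null_matrix))
  cmp <- if (side == "greater") {
    sweep(null_matrix, 2, obs, `>=`)
  } else {
    sweep(null_matrix, 2, obs, `<=`)
  }
  extreme <- colSums(cmp, na.rm = TRUE)
  p <- ifelse(is.na(obs), NA_real_, (1 + extreme) / (1 + nn))
  list(z = z, p = p, null_mean = m, null_std = s, n = nn)
}

#' Multiple-testing correction for region-wise p-values
#'
#' Bonferroni: significant iff \eqn{p < \alpha / m}, with \eqn{m} the number
#' of defined (non-\code{NA}) tests. Benjamini-Hochberg
#' (\code{"fdr_bh"}): step-up control of the false discovery rate at level
#' \eqn{\alpha}. \code{NA} p-values are excluded from \eqn{m} and flagged
#' \code{FALSE}.
#'
#' @param ps named numeric vector of p-values in \eqn{(0, 1]}.
#' @param method \code{"bonferroni"} or \code{"fdr_bh"}.
#' @param alpha significance level in \eqn{(0, 1)}.
#' @return named logical vector of significance flags.
#' @export
correct_pvalues <- function(ps, method = c("bonferroni", "fdr_bh"),
                            alpha = 0.05) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  p <- as.numeric(ps)
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  sig <- rep(FALSE, length(p))
  m <- sum(ok)
  if (m > 0) {
    if (method == "bonferroni") {
      sig[ok] <- p[ok] < alpha / m
    } else {
      sig[ok] <- stats::p.adjust(p[ok], method = "BH") <= alpha
    }
  }
  setNames(sig, names(ps))
}
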