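# Binary, normalized and weighted rich-club analysis; member extraction;
# cross-network overlap permutation test; rich vs non-rich metric contrasts.

#' Rich-club member regions at level k
#'
#' Regions with degree strictly greater than \code{k} (degree taken on the
#' binary support for weighted connectomes).
#'
#' @param c an undirected connectome.
#' @param k degree level.
#' @return character vector of labels.
#' @export
rich_members <- function(c, k) {
  stopifnot_connectome(c, undirected = TRUE)
  d <- rowSums(adjacency(c))
  c$labels[d > k]
}

rich_club_curve <- function(df, members, weighted = FALSE) {
  structure(df, members = members, weighted = weighted,
            class = c("rich_club_curve", "data.frame"))
}

#' @export
print.rich_club_curve <- function(x, ...) {
  cat(sprintf("<rich_club_curve%s: k = %d..%d>\n",
              if (isTRUE(attr(x, "weighted"))) " (weighted)" else "",
              min(x$k), max(x$k)))
  print(as.data.frame(x))
  invisible(x)
}

#' Binary rich-club coefficient curve
#'
#' For each degree level \eqn{k} from 0 to (max degree - 1):
#' \eqn{\phi(k) = 2 E_{>k} / (N_{>k} (N_{>k} - 1))}, the density of the
#' subgraph induced by the regions with degree strictly greater than
#' \eqn{k}. Undefined (\code{NA}) when fewer than two such regions remain.
#'
#' @param c binary undirected connectome.
#' @return a \code{"rich_club_curve"} data frame with columns \code{k},
#'   \code{n_gt_k}, \code{e_gt_k}, \code{phi}; the per-level member sets are
#'   in \code{attr(, "members")}.
#' @export
rcc <- function(c) {
  stopifnot_connectome(c, undirected = TRUE, binary = TRUE)
  A <- adjacency(c)
  d <- rowSums(A)
  ks <- 0:max(1, max(d)) - 1L
  ks <- ks[ks >= 0]
  members <- list()
  out <- data.frame(k = ks, n_gt_k = NA_integer_, e_gt_k = NA_integer_,
                    phi = NA_real_)
  for (r in seq_along(ks)) {
    k <- ks[r]
    sel <- d > k
    members[[as.character(k)]] <- c$labels[sel]
    nk <- sum(sel)
    out$n_gt_k[r] <- nk
    if (nk >= 2) {
      sub <- A[sel, sel, drop = FALSE]
      ek <- sum(sub) / 2
      out$e_gt_k[r] <- ek
      out$phi[r] <- 2 * ek / (nk * (nk - 1))
    } else {
      out$e_gt_k[r] <- if (nk >= 1) 0L else NA_integer_
    }
  }
  rich_club_curve(out, members, weighted = FALSE)
}

#' Weighted rich-club coefficient curve
#'
#' \eqn{\phi_w(k) = W_{>k} / \sum_{l=1}^{E_{>k}} w^{rank}_l}: the total
#' weight among regions of degree (on the binary support) strictly greater
#' than \eqn{k}, divided by the sum of the \eqn{E_{>k}} largest edge weights
#' anywhere in the network. Equals 1 when the club's edges are exactly the
#' globally strongest ones; undefined (\code{NA}) when \eqn{E_{>k} = 0}.
#'
#' @param c undirected weighted connectome.
#' @return a \code{"rich_club_curve"} with columns \code{k}, \code{n_gt_k},
#'   \code{e_gt_k}, \code{w_gt_k}, \code{phi}.
#' @export
weighted_rcc <- function(c) {
  stopifnot_connectome(c, undirected = TRUE, weighted = TRUE)
  W <- c$weights
  A <- adjacency(c)
  d <- rowSums(A)
  wts_sorted <- sort(W[upper.tri(W) & W != 0], decreasing = TRUE)
  cum <- cumsum(wts_sorted)
  ks <- 0:max(1, max(d)) - 1L
  ks <- ks[ks >= 0]
  members <- list()
  out <- data.frame(k = ks, n_gt_k = NA_integer_, e_gt_k = NA_integer_,
                    w_gt_k = NA_real_, phi = NA_real_)
  for (r in seq_along(ks)) {
    k <- ks[r]
    sel <- d > k
    members[[as.character(k)]] <- c$labels[sel]
    nk <- sum(sel)
    out$n_gt_k[r] <- nk
    if (nk >= 2) {
      subA <- A[sel, sel, drop = FALSE]
      subW <- W[sel, sel, drop = FALSE]
      ek <- sum(subA) / 2
      out$e_gt_k[r] <- ek
      out$w_gt_k[r] <- sum(subW) / 2
      if (ek > 0) out$phi[r] <- (sum(subW) / 2) / cum[ek]
    } else {
      out$e_gt_k[r] <- if (nk >= 1) 0L else NA_integer_
    }
  }
  rich_club_curve(out, members, weighted = TRUE)
}

#' Normalized rich-club curve against a null ensemble
#'
#' Divides the observed rich-club coefficient by the mean coefficient of
#' degree-matched null networks, \eqn{\phi_{norm}(k) = \phi(k) /
#' \langle\phi_{null}(k)\rangle}, and attaches a per-level one-sided
#' empirical p-value. Values above 1 over a range of \eqn{k} indicate a
#' rich-club organization beyond what density and degree sequence explain.
#'
#' @param c an undirected connectome (binary or weighted).
#' @param ensemble optional pre-built \code{\link{build_ensemble}} result
#'   with statistic \code{"rcc_phi"} (binary) or \code{"weighted_rcc_phi"}
#'   (weighted). Built internally when \code{NULL}.
#' @param n_null ensemble size when building internally (default 1000).
#' @param seed seed for the internal ensemble.
#' @param n_swap_per_edge mixing parameter for the rewiring step.
#' @return the \code{\link{rcc}} / \code{\link{weighted_rcc}} curve with
#'   added columns \code{null_mean}, \code{null_std}, \code{phi_norm},
#'   \code{p}, plus attributes \code{model_name} and \code{n_null}.
#' @export
normalized_rcc <- function(c, ensemble = NULL, n_null = 1000, seed = NULL,
                           n_swap_per_edge = 10) {
  stopifnot_connectome(c, undirected = TRUE)
  curve <- if (c$weighted) weighted_rcc(c) else rcc(c)
  if (is.null(ensemble)) {
    ensemble <- build_ensemble(
      c,
      model_name = if (c$weighted) "link_weight_reshuffle"
                   else "degree_preserving",
      n = n_null, seed = seed,
      statistic = if (c$weighted) "weighted_rcc_phi" else "rcc_phi",
      n_swap_per_edge = n_swap_per_edge)
  }
  nm <- ensemble_matrix(ensemble)
  if (ncol(nm) != nrow(curve)) {
    stop("ensemble statistic length does not match the rich-club k grid")
  }
  st <- empirical_stats_vec(curve$phi, nm, side = "greater")
  curve$null_mean <- st$null_mean
  curve$null_std <- st$null_std
  curve$phi_norm <- ifelse(is.na(st$null_mean) | st$null_mean == 0,
                           NA_real_, curve$phi / st$null_mean)
  curve$p <- st$p
  attr(curve, "model_name") <- if (inherits(ensemble, "null_ensemble")) {
    ensemble$model_name
  } else NA_character_
  attr(curve, "n_null") <- nrow(nm)
  curve
}

#' Peak of a normalized rich-club curve
#'
#' The level \eqn{k} maximizing \eqn{\phi_{norm}} among levels with at least
#' \code{min_members} member regions and a defined null mean; used to pick
#' the reporting cutoff for member extraction.
#'
#' @param curve a normalized rich-club curve.
#' @param min_members minimum club size considered (default 3).
#' @return list with \code{k}, \code{phi_norm} and \code{members} at the
#'   peak, or \code{NULL} if no level qualifies.
#' @export
rich_club_peak <- function(curve, min_members = 3) {
  ok <- !is.na(curve$phi_norm) & curve$n_gt_k >= min_members
  if (!any(ok)) return(NULL)
  idx <- which(ok)[which.max(curve$phi_norm[ok])]
  k <- curve$k[idx]
  list(k = k, phi_norm = curve$phi_norm[idx],
       members = attr(curve, "members")[[as.character(k)]])
}

#' Permutation test for cross-network rich-club overlap
#'
#' Observed statistic: the size of the intersection of the two networks'
#' rich-club member sets at levels \code{k_a} and \code{k_b}. Null: the same
#' two set sizes drawn uniformly without replacement from the label
#' universe, independently for each network, \code{n_draws} times; the
#' one-sided empirical probability of a null overlap at least as large is
#' reported. (The null overlap is hypergeometric; the Monte-Carlo draw
#' mirrors the published procedure.)
#'
#' @param a,b undirected connectomes over the same label universe.
#' @param k_a,k_b rich-club levels for \code{a} and \code{b}.
#' @param n_draws number of null draws (default 10000).
#' @param seed integer seed.
#' @return list with \code{overlap}, \code{p}, \code{n_a}, \code{n_b} and
#'   \code{null} (a \code{"null_ensemble"} of model \code{"region_draw"}).
#' @export
overlap_test <- function(a, b, k_a, k_b, n_draws = 10000, seed = NULL) {
  stopifnot_connectome(a, undirected = TRUE)
  stopifnot_connectome(b, undirected = TRUE)
  stopifnot_same_labels(a, b)
  ma <- rich_members(a, k_a); mb <- rich_members(b, k_b)
  if (!length(ma) || !length(mb)) {
    stop("rich-club member set is empty in one of the networks")
  }
  observed <- length(intersect(ma, mb))
  n <- length(a$labels)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      da <- sample.int(n, length(ma))
      db <- sample.int(n, length(mb))
      length(intersect(da, db))
    }, numeric(1))
  })
  p <- (1 + sum(nulls >= observed)) / (1 + n_draws)
  list(overlap = observed, p = p, n_a = length(ma), n_b = length(mb),
       null = structure(list(model_name = "region_draw", size = n_draws,
                             seed = seed, values = as.list(nulls)),
                        class = "null_ensemble"))
}

#' Permutation contrast of a metric between rich and non-rich regions
#'
#' Observed statistic: mean metric value of member regions minus mean of
#' non-members. Membership labels are randomly reassigned \code{n_perm}
#' times to form the null; the one-sided empirical p-value
#' \eqn{(1 + \#extreme)/(1 + n_{perm})} is returned
#' (\code{direction = "greater"}: members expected higher, e.g. centrality;
#' \code{"less"}: members expected lower, e.g. clustering).
#'
#' @param m a \code{\link{metric_vector}}.
#' @param members character vector of member labels; nonempty proper subset
#'   of \code{m$labels}.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param direction \code{"greater"} or \code{"less"}.
#' @return list with \code{statistic} (observed mean difference) and
#'   \code{p}.
#' @export
rich_vs_nonrich_test <- function(m, members, n_perm = 10000, seed = NULL,
                                 direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!all(members %in% m$labels)) stop("unknown member labels")
  n_mem <- length(unique(members))
  if (n_mem == 0 || n_mem == length(m$labels)) {
    stop("members must be a nonempty proper subset of the regions")
  }
  v <- as.numeric(m$values)
  if (anyNA(v)) stop("metric vector contains NA values")
  is_mem <- m$labels %in% members
  obs <- mean(v[is_mem]) - mean(v[!is_mem])
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample(is_mem)
      mean(v[perm]) - mean(v[!perm])
    }, numeric(1))
  })
  extreme <- if (direction == "greater") sum(nulls >= obs)
             else sum(nulls <= obs)
  list(statistic = obs, p = (1 + extreme) / (1 + n_perm))
}
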