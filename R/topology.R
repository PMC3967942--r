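# Centrality and clustering metrics (binary and weighted), cross-species
# rank correlation, and hub flagging.

#' Metric vector container
#'
#' A named per-region metric with bookkeeping used by reports and the hub
#' flagging / permutation-contrast utilities.
#'
#' @param metric_name one of \code{"degree"}, \code{"strength"}, \code{"BC"},
#'   \code{"EC"}, \code{"C"}.
#' @param labels region labels.
#' @param values numeric values, one per label.
#' @param normalized logical flag recording whether values are normalized.
#' @return object of class \code{"metric_vector"}.
#' @export
metric_vector <- function(metric_name, labels, values, normalized = FALSE) {
  metric_name <- match.arg(metric_name,
                           c("degree", "strength", "BC", "EC", "C"))
  if (length(labels) != length(values)) {
    stop("labels and values must have equal length")
  }
  structure(list(metric_name = metric_name, labels = as.character(labels),
                 values = setNames(as.numeric(values), labels),
                 normalized = isTRUE(normalized)),
            class = "metric_vector")
}

#' @export
print.metric_vector <- function(x, ...) {
  cat(sprintf("<metric_vector %s%s: %d regions>\n", x$metric_name,
              if (x$normalized) " (normalized)" else "", length(x$labels)))
  print(utils::head(x$values, 10))
  invisible(x)
}

#' @export
as.data.frame.metric_vector <- function(x, ...) {
  data.frame(label = x$labels, value = as.numeric(x$values),
             stringsAsFactors = FALSE)
}

as_igraph <- function(c) {
  mode <- if (c$directed) "directed" else "undirected"
  igraph::graph_from_adjacency_matrix(c$weights, mode = mode,
                                      weighted = if (c$weighted) TRUE else NULL,
                                      diag = FALSE)
}

#' Betweenness centrality
#'
#' Shortest-path betweenness of each region. For weighted connectomes edge
#' lengths are \code{1/weight} (stronger connections are shorter), the usual
#' convention for connectivity weights. Normalization divides by
#' \eqn{(N-1)(N-2)/2}, the maximum attainable by a star hub.
#'
#' @param c an undirected connectome.
#' @param normalized logical (default \code{FALSE}: raw path counts).
#' @return a \code{\link{metric_vector}} with \code{metric_name = "BC"}.
#' @export
betweenness_centrality <- function(c, normalized = FALSE) {
  stopifnot_connectome(c, undirected = TRUE)
  n <- length(c$labels)
  if (n < 3) {
    return(metric_vector("BC", c$labels, rep(0, n), normalized))
  }
  g <- as_igraph(c)
  w <- if (c$weighted) 1 / igraph::E(g)$weight else NA
  bc <- igraph::betweenness(g, weights = w, directed = FALSE)
  if (normalized) bc <- bc / ((n - 1) * (n - 2) / 2)
  metric_vector("BC", c$labels, bc[c$labels], normalized)
}

#' Eigenvector centrality
#'
#' The principal eigenvector of the (weighted) adjacency matrix, returned
#' nonnegative with unit Euclidean norm. On disconnected graphs the dominant
#' component carries the mass; a warning reports the component count.
#'
#' @param c an undirected connectome with nonnegative weights.
#' @return a \code{\link{metric_vector}} with \code{metric_name = "EC"}.
#' @export
eigenvector_centrality <- function(c) {
  stopifnot_connectome(c, undirected = TRUE)
  n <- length(c$labels)
  if (n == 0 || all(c$weights == 0)) stop("eigenvector centrality undefined for an empty graph")
  comp <- igraph::components(as_igraph(c))
  if (comp$no > 1) {
    warning("graph has ", comp$no,
            " components; eigenvector mass concentrates on the dominant one")
  }
  es <- eigen(c$weights, symmetric = TRUE)
  v <- es$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)           # clip tiny negative fp noise
  v <- v / sqrt(sum(v^2))
  metric_vector("EC", c$labels, v, normalized = TRUE)
}

#' Clustering coefficient
#'
#' Per-region triangle density. Binary: \eqn{C_i = 2 t_i / (d_i (d_i - 1))}
#' with \eqn{t_i} the triangle count at \eqn{i}. Weighted: the Onnela
#' geometric-mean form, with weights scaled by the network maximum and
#' triangle intensity \eqn{\hat t_i = \frac{1}{2}\sum_{jh} (\hat w_{ij}
#' \hat w_{ih} \hat w_{jh})^{1/3}}; the degree in the denominator is taken
#' on the binary support. Regions of degree < 2 get 0 by convention.
#'
#' @param c an undirected connectome.
#' @return a \code{\link{metric_vector}} with \code{metric_name = "C"}.
#' @export
clustering_coefficient <- function(c) {
  stopifnot_connectome(c, undirected = TRUE)
  A <- adjacency(c)
  d <- rowSums(A)
  if (c$weighted && max(c$weights) > 0) {
    What <- (c$weights / max(c$weights))^(1 / 3)
    tri <- diag(What %*% What %*% What)   # 2 x triangle intensity
  } else {
    tri <- diag(A %*% A %*% A)            # 2 x triangle count
  }
  vals <- ifelse(d > 1, tri / (d * (d - 1)), 0)
  metric_vector("C", c$labels, vals, normalized = TRUE)
}

#' Degree (or strength) metric vector
#'
#' @param c an undirected connectome.
#' @param use_weights if \code{TRUE} and the connectome is weighted, return
#'   the strength (sum of incident weights) instead of the degree.
#' @return a \code{\link{metric_vector}}.
#' @export
degree_centrality <- function(c, use_weights = FALSE) {
  stopifnot_connectome(c, undirected = TRUE)
  if (use_weights && c$weighted) {
    metric_vector("strength", c$labels, rowSums(c$weights))
  } else {
    metric_vector("degree", c$labels, rowSums(adjacency(c)))
  }
}

#' Cross-species rank correlation of a metric
#'
#' Spearman's rank correlation between the same per-region metric computed
#' in the two species, with tie-corrected (midrank) ranks and a two-sided
#' p-value from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n - 2} degrees of freedom.
#'
#' @param m1,m2 \code{\link{metric_vector}}s over identical labels, same
#'   order.
#' @return list with \code{rho} and \code{p} (both \code{NA} if either
#'   vector is constant).
#' @export
cross_species_correlation <- function(m1, m2) {
  if (!identical(m1$labels, m2$labels)) {
    stop("metric vectors must share the same labels in the same order")
  }
  x <- as.numeric(m1$values); y <- as.numeric(m2$values)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < MIN_COR_PAIRS || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Flag hub (or anti-hub) regions by the mean + 1 SD rule
#'
#' A region is flagged when its metric value exceeds the mean plus one
#' standard deviation of the metric over all regions
#' (\code{direction = "above"}), or falls below mean minus one SD
#' (\code{direction = "below"}).
#'
#' @param m a \code{\link{metric_vector}}.
#' @param direction \code{"above"} or \code{"below"}.
#' @return named logical vector.
#' @export
hub_flags <- function(m, direction = c("above", "below")) {
  direction <- match.arg(direction)
  v <- m$values
  mu <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
  out <- if (direction == "above") v > mu + s else v < mu - s
  out[is.na(out)] <- FALSE
  setNames(as.logical(out), m$labels)
}
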