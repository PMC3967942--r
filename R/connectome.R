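#' @importFrom stats cor pnorm pt quantile sd setNames
#' @importFrom utils read.table write.table head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package funnel
# through this so that a single integer seed makes a run reproducible without
# clobbering the user's RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; keeps derived seeds inside the
# 32-bit integer range expected by set.seed().
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647L)
}

#' Region table for a brain parcellation
#'
#' A region table fixes the canonical region order of a parcellation and
#' carries per-region annotation: the hemisphere (\code{"L"} or \code{"R"})
#' and a coarse lobe classification. The row order of the table defines the
#' canonical index order of every connectome matrix built against it.
#'
#' @param label character vector of unique region labels.
#' @param hemisphere character vector, one of \code{"L"}, \code{"R"} per
#'   region.
#' @param lobe_class character vector of lobe classes; one of
#'   \code{"frontal"}, \code{"temporal"}, \code{"parietal"},
#'   \code{"occipital"}, \code{"limbic"}, \code{"insular"},
#'   \code{"subcortical"}, \code{"allocortical"}, \code{"isocortical"},
#'   \code{"unknown"}. Defaults to \code{"unknown"}.
#' @return a \code{data.frame} of class \code{"region_table"} with columns
#'   \code{label}, \code{hemisphere}, \code{lobe_class}.
#' @export
#' @examples
#' rt <- region_table(c("V1.L", "V1.R"), c("L", "R"), c("occipital", "occipital"))
region_table <- function(label, hemisphere,
                         lobe_class = rep("unknown", length(label))) {
  label <- as.character(label)
  hemisphere <- as.character(hemisphere)
  lobe_class <- as.character(lobe_class)
  if (anyDuplicated(label)) stop("region labels must be unique")
  if (length(hemisphere) != length(label) || length(lobe_class) != length(label)) {
    stop("label, hemisphere and lobe_class must have equal length")
  }
  if (!all(hemisphere %in% c("L", "R"))) {
    stop("hemisphere must be 'L' or 'R' for every region")
  }
  allowed <- c("frontal", "temporal", "parietal", "occipital", "limbic",
               "insular", "subcortical", "allocortical", "isocortical",
               "unknown")
  if (!all(lobe_class %in% allowed)) {
    stop("unknown lobe_class value(s): ",
         paste(setdiff(lobe_class, allowed), collapse = ", "))
  }
  out <- data.frame(label = label, hemisphere = hemisphere,
                    lobe_class = lobe_class, stringsAsFactors = FALSE)
  class(out) <- c("region_table", "data.frame")
  out
}

#' Read a region table from TSV
#'
#' Expects columns \code{label}, \code{hemisphere} and (optionally)
#' \code{lobe_class}.
#'
#' @param path path to a tab-separated file with a header row.
#' @return a \code{\link{region_table}}.
#' @export
read_region_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("label", "hemisphere") %in% names(df))) {
    stop("region table file must have 'label' and 'hemisphere' columns")
  }
  region_table(df$label, df$hemisphere,
               df$lobe_class %||% rep("unknown", nrow(df)))
}

#' Write a region table to TSV
#'
#' @param rt a \code{\link{region_table}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_region_table <- function(rt, path) {
  utils::write.table(as.data.frame(rt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Labeled connectome container
#'
#' A connectome is a square, labeled, nonnegative adjacency matrix together
#' with flags describing its type. The diagonal is forced to zero
#' (self-connections are not modeled; a warning is emitted if any are
#' dropped). Undirected connectomes must have a symmetric matrix; binary
#' (unweighted) connectomes must contain only 0/1 entries.
#'
#' @param weights square numeric matrix of nonnegative connection values.
#'   Dimnames, when present, must agree with \code{labels}.
#' @param labels character vector of region labels in matrix order; defaults
#'   to the matrix rownames.
#' @param directed logical; is the matrix to be interpreted as directed?
#' @param weighted logical; if \code{FALSE} entries must be 0/1. Defaults to
#'   \code{TRUE} unless all entries are 0/1.
#' @param species_tag free-form string identifying the dataset ("macaque",
#'   "human", ...).
#' @return an object of class \code{"connectome"}.
#' @export
#' @examples
#' w <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' connectome(w, species_tag = "toy")
connectome <- function(weights, labels = rownames(weights), directed = FALSE,
                       weighted = NULL, species_tag = "") {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be a square matrix")
  if (is.null(labels)) stop("labels are required (or set rownames on weights)")
  labels <- as.character(labels)
  if (length(labels) != nrow(weights)) {
    stop("length(labels) must equal the matrix dimension")
  }
  if (anyDuplicated(labels)) stop("region labels must be unique")
  storage.mode(weights) <- "double"
  if (anyNA(weights)) stop("weights must not contain NA")
  if (any(weights < 0)) stop("negative connection weights are not allowed")
  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal entries (self-connections) set to zero")
    diag(weights) <- 0
  }
  if (is.null(weighted)) weighted <- !all(weights %in% c(0, 1))
  if (!weighted && !all(weights %in% c(0, 1))) {
    stop("weighted = FALSE but matrix has entries other than 0/1")
  }
  if (!directed && !isTRUE(all.equal(weights, t(weights),
                                     check.attributes = FALSE))) {
    stop("undirected connectome requires a symmetric matrix; ",
         "use symmetrize_binarize() or set directed = TRUE")
  }
  if (!directed) weights <- (weights + t(weights)) / 2  # remove fp asymmetry
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = labels, weights = weights,
                 directed = isTRUE(directed), weighted = isTRUE(weighted),
                 species_tag = as.character(species_tag)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome%s: %d regions, %s, %s, L = %d, density = %.3f>\n",
              if (nzchar(x$species_tag)) paste0(" '", x$species_tag, "'") else "",
              length(x$labels),
              if (x$directed) "directed" else "undirected",
              if (x$weighted) "weighted" else "binary",
              edge_count(x), density(x)))
  invisible(x)
}

#' Test for connectome objects
#' @param x object.
#' @return logical.
#' @export
is_connectome <- function(x) inherits(x, "connectome")

stopifnot_connectome <- function(x, undirected = FALSE, binary = FALSE,
                                 weighted = FALSE) {
  if (!is_connectome(x)) stop("expected a connectome object")
  if (undirected && x$directed) stop("expected an undirected connectome")
  if (binary && x$weighted) stop("expected a binary connectome")
  if (weighted && !x$weighted) stop("expected a weighted connectome")
  invisible(x)
}

stopifnot_same_labels <- function(a, b) {
  if (!identical(a$labels, b$labels)) {
    stop("connectomes must have identical label sequences (no fuzzy matching)")
  }
  invisible(NULL)
}

# binary 0/1 support matrix
adjacency <- function(c) (c$weights != 0) * 1

#' Number of edges of a connectome
#'
#' Counts unordered nonzero pairs for undirected connectomes, ordered nonzero
#' pairs for directed ones.
#'
#' @param c a connectome.
#' @return integer edge count.
#' @export
edge_count <- function(c) {
  stopifnot_connectome(c)
  a <- adjacency(c)
  as.integer(if (c$directed) sum(a) else sum(a[upper.tri(a)]))
}

#' Connection density of an undirected connectome
#'
#' The fraction of unordered region pairs that are connected,
#' \eqn{L / (N(N-1)/2)}.
#'
#' @param x an undirected connectome.
#' @param ... unused.
#' @return density in \eqn{[0, 1]}.
#' @export
density.connectome <- function(x, ...) {
  stopifnot_connectome(x, undirected = TRUE)
  n <- length(x$labels)
  if (n < 2) stop("density undefined for fewer than 2 regions")
  edge_count(x) / (n * (n - 1) / 2)
}

#' Degree sequence on the binary support
#'
#' @param c an undirected connectome.
#' @return named integer vector of degrees.
#' @export
degrees <- function(c) {
  stopifnot_connectome(c, undirected = TRUE)
  setNames(as.integer(rowSums(adjacency(c))), c$labels)
}

# upper-triangle edge table: data.frame(i, j, from, to, weight), i < j,
# ordered lexicographically by (from, to) label
edge_table <- function(c) {
  w <- c$weights
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             from = c$labels[idx[, 1]], to = c$labels[idx[, 2]],
             weight = w[idx], stringsAsFactors = FALSE)
}

#' Read a labeled connectome from file
#'
#' Two plain-text dialects are supported. \code{fmt = "dense"}: a
#' tab/whitespace-separated square matrix with a header row of labels and a
#' first column of (identical) labels. \code{fmt = "edgelist"}: three
#' tab-separated columns \code{from}, \code{to}, \code{weight} (header
#' optional); an optional leading \code{# labels:} comment line fixes the
#' label universe and order (isolated regions round-trip through it); pairs
#' absent from the file are zero, and symmetric duplicates of an undirected
#' edge collapse (their weights must agree).
#'
#' @param path path to the file.
#' @param fmt \code{"dense"} or \code{"edgelist"}.
#' @param region_table optional \code{\link{region_table}}; when supplied the
#'   output follows its canonical label order and unknown labels are an
#'   error. Otherwise labels keep first-appearance order.
#' @param directed logical, interpretation of the matrix (default
#'   undirected).
#' @param species_tag free-form dataset tag.
#' @return a \code{\link{connectome}}.
#' @export
read_connectome <- function(path, fmt = c("dense", "edgelist"),
                            region_table = NULL, directed = FALSE,
                            species_tag = "") {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "dense") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    w <- as.matrix(df)
    if (nrow(w) != ncol(w)) stop("dense connectome file must be square")
    if (!identical(rownames(w), colnames(w))) {
      stop("dense file row and column labels must be identical and in order")
    }
    labels <- rownames(w)
  } else {
    first <- readLines(path, n = 1)
    label_universe <- NULL
    if (startsWith(first, "# labels:")) {
      label_universe <- strsplit(sub("^# labels:[ ]?", "", first),
                                 "\t", fixed = TRUE)[[1]]
    }
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) != 3) stop("edge list must have exactly 3 columns")
    if (!is.numeric(df[[3]])) {  # header row present
      names_row <- df[1, ]
      df <- df[-1, , drop = FALSE]
      df[[3]] <- as.numeric(df[[3]])
    }
    names(df) <- c("from", "to", "weight")
    df$from <- as.character(df$from); df$to <- as.character(df$to)
    if (anyNA(df$weight)) stop("non-numeric weight in edge list")
    if (any(df$weight < 0)) stop("negative connection weights are not allowed")
    if (any(df$from == df$to)) stop("self-connections are not allowed")
    labels <- label_universe %||% unique(c(rbind(df$from, df$to)))
    if (!is.null(region_table)) labels <- region_table$label
    w <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    missing_lab <- setdiff(unique(c(df$from, df$to)), labels)
    if (length(missing_lab)) {
      stop("edge-list labels absent from region table: ",
           paste(missing_lab, collapse = ", "))
    }
    for (r in seq_len(nrow(df))) {
      i <- df$from[r]; j <- df$to[r]
      if (!directed && w[j, i] != 0 && w[j, i] != df$weight[r]) {
        stop("conflicting weights for undirected pair ", i, "-", j)
      }
      if (directed) {
        w[i, j] <- df$weight[r]
      } else {
        w[i, j] <- df$weight[r]; w[j, i] <- df$weight[r]
      }
    }
  }
  if (!is.null(region_table)) {
    extra <- setdiff(labels, region_table$label)
    if (length(extra)) {
      stop("labels absent from region table: ", paste(extra, collapse = ", "))
    }
    keep <- intersect(region_table$label, labels)
    w <- w[keep, keep, drop = FALSE]
    labels <- keep
  }
  connectome(w, labels = labels, directed = directed,
             species_tag = species_tag)
}

# full-precision numeric formatting so that read/write round trips bit-exactly
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) sprintf("%.0f", v)
    else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a labeled connectome to file
#'
#' Inverse of \code{\link{read_connectome}}; both formats round-trip
#' bit-exactly (full \code{\%.17g} precision for non-integer weights).
#' Undirected edge lists store each unordered pair once, lexicographically.
#'
#' @param c a \code{\link{connectome}}.
#' @param path output path.
#' @param fmt \code{"dense"} or \code{"edgelist"}.
#' @return invisibly, \code{path}.
#' @export
write_connectome <- function(c, path, fmt = c("dense", "edgelist")) {
  fmt <- match.arg(fmt)
  stopifnot_connectome(c)
  if (fmt == "dense") {
    n <- length(c$labels)
    lines <- c(paste(c("", c$labels), collapse = "\t"),
               vapply(seq_len(n), function(i) {
                 paste(c(c$labels[i], fmt_num(c$weights[i, ])),
                       collapse = "\t")
               }, character(1)))
    writeLines(lines, path)
  } else {
    if (c$directed) {
      idx <- which(c$weights != 0, arr.ind = TRUE)
      et <- data.frame(from = c$labels[idx[, 1]], to = c$labels[idx[, 2]],
                       weight = c$weights[idx], stringsAsFactors = FALSE)
    } else {
      et <- edge_table(c)[, c("from", "to", "weight")]
    }
    et <- et[order(et$from, et$to), , drop = FALSE]
    lines <- c(paste0("# labels: ", paste(c$labels, collapse = "\t")),
               "from\tto\tweight",
               if (nrow(et)) paste(et$from, et$to, fmt_num(et$weight),
                                   sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Symmetrize and binarize a connectome
#'
#' An undirected binary edge is placed wherever the input has any nonzero
#' entry in either direction, irrespective of its strength. This is the
#' standard construction for turning a directed, ordinally weighted
#' tract-tracing matrix into a binary undirected connectome. Idempotent.
#'
#' @param c a connectome (possibly directed and weighted).
#' @return an undirected, binary connectome.
#' @export
symmetrize_binarize <- function(c) {
  stopifnot_connectome(c)
  w <- (c$weights != 0 | t(c$weights) != 0) * 1
  connectome(w, labels = c$labels, directed = FALSE, weighted = FALSE,
             species_tag = c$species_tag)
}

#' Average per-subject weighted connectomes
#'
#' Entry-wise arithmetic mean of identically labeled weighted matrices, the
#' group-level construction used before density-matched thresholding.
#'
#' @param cs list of undirected weighted connectomes with identical labels.
#' @return an undirected weighted connectome.
#' @export
average_subjects <- function(cs) {
  if (!length(cs)) stop("empty subject list")
  for (c in cs) stopifnot_connectome(c, undirected = TRUE)
  for (c in cs[-1]) stopifnot_same_labels(cs[[1]], c)
  w <- Reduce(`+`, lapply(cs, function(c) c$weights)) / length(cs)
  connectome(w, labels = cs[[1]]$labels, directed = FALSE, weighted = TRUE,
             species_tag = cs[[1]]$species_tag)
}

# deterministic ranking of nonzero unordered pairs: weight descending, then
# lexicographic (from, to) ascending — the declared tie-break at the cut
ranked_pairs <- function(c) {
  et <- edge_table(c)
  et[order(-et$weight, et$from, et$to), , drop = FALSE]
}

#' Threshold a weighted connectome to a fixed edge count
#'
#' Keeps exactly the \code{target_L} largest weights (density-matched
#' thresholding against a reference connectome's edge count). Ties at the cut
#' are resolved deterministically: weight descending, then lexicographic
#' (label_i, label_j) ascending.
#'
#' @param c an undirected weighted connectome.
#' @param target_L number of edges to keep; must not exceed the number of
#'   nonzero pairs.
#' @param binarize if \code{TRUE} (default) the result is binary; if
#'   \code{FALSE} the selected edges retain their weights (used by the
#'   weighted hemisphere-wise analysis).
#' @return a connectome with exactly \code{target_L} edges.
#' @export
threshold_to_edge_count <- function(c, target_L, binarize = TRUE) {
  stopifnot_connectome(c, undirected = TRUE)
  et <- ranked_pairs(c)
  if (target_L > nrow(et)) {
    stop("target_L (", target_L, ") exceeds available nonzero pairs (",
         nrow(et), ")")
  }
  keep <- et[seq_len(target_L), , drop = FALSE]
  n <- length(c$labels)
  w <- matrix(0, n, n, dimnames = list(c$labels, c$labels))
  vals <- if (binarize) rep(1, nrow(keep)) else keep$weight
  w[cbind(keep$i, keep$j)] <- vals
  w[cbind(keep$j, keep$i)] <- vals
  connectome(w, labels = c$labels, directed = FALSE, weighted = !binarize,
             species_tag = c$species_tag)
}

#' Split a connectome into its two within-hemisphere subnetworks
#'
#' Returns the induced subnetworks on the left- and right-hemisphere regions;
#' interhemispheric entries are discarded.
#'
#' @param c a connectome whose labels all appear in \code{rt}.
#' @param rt a \code{\link{region_table}} with hemisphere assignments.
#' @return a list with components \code{L} and \code{R}, each a connectome.
#' @export
split_hemispheres <- function(c, rt) {
  stopifnot_connectome(c)
  missing_lab <- setdiff(c$labels, rt$label)
  if (length(missing_lab)) {
    stop("labels missing from region table: ",
         paste(missing_lab, collapse = ", "))
  }
  hemi <- setNames(rt$hemisphere, rt$label)[c$labels]
  out <- lapply(c("L", "R"), function(h) {
    keep <- c$labels[hemi == h]
    connectome(c$weights[keep, keep, drop = FALSE], labels = keep,
               directed = c$directed, weighted = c$weighted,
               species_tag = paste0(c$species_tag,
                                    if (nzchar(c$species_tag)) "." else "", h))
  })
  names(out) <- c("L", "R")
  out
}

#' Consistency of thresholded subject connectomes
#'
#' Two diagnostics of inter-subject agreement: (i) the fraction of edges of
#' the thresholded group-average connectome that are present in at least
#' \code{m} of the individually thresholded subject connectomes (each
#' thresholded to the same edge count), and (ii) the Pearson correlation of
#' the upper-triangle weight vectors for every unordered subject pair
#' (computed on the unthresholded matrices).
#'
#' @param cs list of >= 2 undirected weighted connectomes, identical labels.
#' @param target_L edge count for thresholding.
#' @param m minimum number of subjects an edge must appear in.
#' @return list with \code{fraction} (scalar) and \code{pairwise_correlations}
#'   (numeric vector, one per unordered subject pair).
#' @export
subject_consistency <- function(cs, target_L, m) {
  if (length(cs) < 2) stop("need at least 2 subjects")
  if (m > length(cs)) stop("m exceeds the number of subjects")
  avg <- average_subjects(cs)
  avg_thr <- threshold_to_edge_count(avg, target_L)
  subj_thr <- lapply(cs, threshold_to_edge_count, target_L = target_L)
  count <- Reduce(`+`, lapply(subj_thr, adjacency))
  a <- adjacency(avg_thr)
  ut <- upper.tri(a)
  sel <- ut & a == 1
  fraction <- mean(count[sel] >= m)
  pairs <- utils::combn(length(cs), 2)
  cors <- apply(pairs, 2, function(p) {
    stats::cor(cs[[p[1]]]$weights[ut], cs[[p[2]]]$weights[ut])
  })
  list(fraction = fraction, pairwise_correlations = as.numeric(cors))
}

#' Relabel / permute a connectome
#'
#' Reorders regions to a new label order (a permutation of the existing
#' labels). Mainly used to check permutation invariance of metrics.
#'
#' @param c a connectome.
#' @param labels permutation of \code{c$labels}.
#' @return a connectome in the new order.
#' @export
permute_connectome <- function(c, labels) {
  stopifnot_connectome(c)
  if (!setequal(labels, c$labels) || length(labels) != length(c$labels)) {
    stop("labels must be a permutation of the connectome's labels")
  }
  connectome(c$weights[labels, labels, drop = FALSE], labels = labels,
             directed = c$directed, weighted = c$weighted,
             species_tag = c$species_tag)
}
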