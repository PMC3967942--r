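# End-to-end orchestration of the comparative analysis: the whole-brain
# binary arm and the hemisphere-wise weighted arm, TSV reports, and the CLI
# entry point.

#' Analysis configuration
#'
#' Bundles the inputs and parameters of a pipeline run. Species inputs may
#' be connectome objects or file paths (dense format assumed for paths);
#' species B may instead be a list of per-subject weighted connectomes,
#' which the whole-brain arm averages and thresholds to species A's edge
#' count.
#'
#' @param species_a connectome or path for species A (the reference whose
#'   edge count sets the density matching).
#' @param species_b connectome or path for species B, or \code{NULL} when
#'   \code{subjects_b} is given.
#' @param subjects_b optional list of weighted connectomes (or paths), one
#'   per subject of species B.
#' @param region_table a \code{\link{region_table}} or path; required for
#'   the hemisphere arm.
#' @param arm \code{"whole_brain_binary"} or \code{"hemisphere_weighted"}.
#' @param n_null null-ensemble size (default 10000; scale down for quick
#'   runs).
#' @param alpha significance level (default 0.05).
#' @param correction \code{"bonferroni"} (whole-brain default) or
#'   \code{"fdr_bh"}.
#' @param p_method \code{"empirical"} (tail count against the null
#'   ensemble; the minimum attainable p is \eqn{1/(n_{null}+1)}) or
#'   \code{"zscore"} (Gaussian tail of the null z-score; appropriate when
#'   \code{n_null} is too small for the empirical floor to clear the
#'   corrected threshold).
#' @param seed master seed; every stage derives its own stream from it.
#' @param perturbations optional list of \code{\link{perturbation_spec}}s
#'   for robustness re-runs.
#' @param n_swap_per_edge rewiring mixing parameter.
#' @return object of class \code{"analysis_config"}.
#' @export
analysis_config <- function(species_a, species_b = NULL, subjects_b = NULL,
                            region_table = NULL,
                            arm = c("whole_brain_binary",
                                    "hemisphere_weighted"),
                            n_null = 10000, alpha = 0.05,
                            correction = c("bonferroni", "fdr_bh"),
                            p_method = c("empirical", "zscore"),
                            seed = 1, perturbations = NULL,
                            n_swap_per_edge = 10) {
  arm <- match.arg(arm)
  correction <- match.arg(correction)
  p_method <- match.arg(p_method)
  if (n_null < 1) stop("n_null must be at least 1")
  if (is.null(species_b) && is.null(subjects_b)) {
    stop("provide species_b or subjects_b")
  }
  structure(list(species_a = species_a, species_b = species_b,
                 subjects_b = subjects_b, region_table = region_table,
                 arm = arm, n_null = n_null, alpha = alpha,
                 correction = correction, p_method = p_method,
                 seed = seed, perturbations = perturbations,
                 n_swap_per_edge = n_swap_per_edge),
            class = "analysis_config")
}

load_connectome_input <- function(x, species_tag = "") {
  if (is_connectome(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    return(read_connectome(x, fmt = "dense", species_tag = species_tag))
  }
  stop("species input must be a connectome or a dense-format file path")
}

load_region_table_input <- function(x) {
  if (inherits(x, "region_table")) return(x)
  if (is.character(x) && length(x) == 1) return(read_region_table(x))
  stop("region_table must be a region_table or a file path")
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[comparanet] ", fmt), ...))
}

# Null draws rewiring BOTH networks independently; evaluates the
# cross-network statistics on each null pair in one pass.
pair_null_stats <- function(a, b, n, seed, n_swap_per_edge = 10,
                            weighted = FALSE,
                            stats = c("intersection", "hcs", "hmis")) {
  ga <- as_igraph(if (weighted) symmetrize_binarize(a) else a)
  gb <- as_igraph(if (weighted) symmetrize_binarize(b) else b)
  nit_a <- max(1L, round(n_swap_per_edge * edge_count(a)))
  nit_b <- max(1L, round(n_swap_per_edge * edge_count(b)))
  nreg <- length(a$labels)
  inter <- numeric(n)
  hcs_m <- matrix(NA_real_, n, nreg)
  hmis_m <- matrix(NA_real_, n, nreg)
  with_seed(seed, {
    for (i in seq_len(n)) {
      na_adj <- rewired_adjacency(ga, nit_a)
      nb_adj <- rewired_adjacency(gb, nit_b)
      if (weighted) {
        wa <- reshuffle_weights_on(na_adj, a)$weights
        wb <- reshuffle_weights_on(nb_adj, b)$weights
        hmis_m[i, ] <- row_correlations(
          weighted_matching_index_matrix(wa, a$labels),
          weighted_matching_index_matrix(wb, b$labels), a$labels)
      } else {
        if ("intersection" %in% stats) {
          x <- na_adj * nb_adj
          inter[i] <- sum(x[upper.tri(x)]) / edge_count(a)
        }
        if ("hcs" %in% stats) {
          hcs_m[i, ] <- hcs_matrices(na_adj, nb_adj, a$labels)
        }
        if ("hmis" %in% stats) {
          hmis_m[i, ] <- row_correlations(
            matching_index_matrix(na_adj, a$labels),
            matching_index_matrix(nb_adj, b$labels), a$labels)
        }
      }
    }
  })
  colnames(hcs_m) <- colnames(hmis_m) <- a$labels
  list(intersection = inter, hcs = hcs_m, hmis = hmis_m)
}

region_results <- function(observed, null_matrix, p_method, correction,
                           alpha, labels) {
  st <- empirical_stats_vec(observed, null_matrix, side = "greater")
  p <- if (p_method == "zscore") {
    ifelse(is.na(st$z), NA_real_, stats::pnorm(-st$z))
  } else st$p
  sig <- correct_pvalues(setNames(p, labels), method = correction,
                         alpha = alpha)
  data.frame(label = labels, observed = as.numeric(observed),
             null_mean = st$null_mean, null_std = st$null_std,
             z = st$z, p = p, significant = as.logical(sig),
             stringsAsFactors = FALSE)
}

topology_block <- function(a, b, normalized = FALSE) {
  mets <- list(
    BC = list(betweenness_centrality(a, normalized = normalized),
              betweenness_centrality(b, normalized = normalized)),
    EC = list(eigenvector_centrality(a), eigenvector_centrality(b)),
    C = list(clustering_coefficient(a), clustering_coefficient(b)))
  lapply(mets, function(pair) {
    ct <- cross_species_correlation(pair[[1]], pair[[2]])
    list(a = pair[[1]], b = pair[[2]], rho = ct$rho, p = ct$p,
         hubs_a = hub_flags(pair[[1]], "above"),
         hubs_b = hub_flags(pair[[2]], "above"))
  })
}

#' Whole-brain binary comparative analysis
#'
#' Runs the full binary arm: construct both connectomes on a common edge
#' count (averaging and density-matched thresholding of species B subjects
#' when needed), then compute the edge intersection ratio, region-wise HCS
#' and HMIS with null z/p and corrected significance flags, centrality and
#' clustering with cross-species Spearman correlations and hub flags,
#' normalized rich-club curves with peak extraction and the rich-club
#' overlap permutation test, plus optional perturbation robustness re-runs.
#' All nulls rewire both networks independently per draw
#' (degree-preserving).
#'
#' @param config an \code{\link{analysis_config}} with
#'   \code{arm = "whole_brain_binary"}.
#' @param verbose log one line per stage (default TRUE).
#' @return a \code{"comparative_report"} list; see
#'   \code{\link{write_report}}.
#' @export
run_whole_brain <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  if (config$arm != "whole_brain_binary") {
    stop("config$arm must be 'whole_brain_binary' for run_whole_brain")
  }
  a <- load_connectome_input(config$species_a, "species_a")
  if (a$directed || a$weighted) a <- symmetrize_binarize(a)
  L <- edge_count(a)
  log_stage(verbose, "species A: %d regions, L = %d, density = %.3f",
            length(a$labels), L, density(a))

  if (!is.null(config$subjects_b)) {
    subjects <- lapply(config$subjects_b, load_connectome_input)
    avg <- average_subjects(subjects)
    b <- threshold_to_edge_count(avg, L)
    log_stage(verbose, "species B: averaged %d subjects, thresholded to L = %d",
              length(subjects), L)
  } else {
    b <- load_connectome_input(config$species_b, "species_b")
    if (b$weighted) {
      b <- threshold_to_edge_count(b, L)
    } else if (b$directed) {
      b <- symmetrize_binarize(b)
    }
  }
  stopifnot_same_labels(a, b)
  if (edge_count(b) != L) {
    stop("density mismatch after thresholding: L(a) = ", L, ", L(b) = ",
         edge_count(b))
  }

  obs_inter <- intersection_ratio(a, b)
  obs_hcs <- hcs(a, b)
  obs_hmis <- hmis(a, b)
  log_stage(verbose, "building %d null pairs (degree-preserving, seed %d)",
            config$n_null, config$seed)
  nulls <- pair_null_stats(a, b, config$n_null,
                           seed = child_seed(config$seed, 1),
                           n_swap_per_edge = config$n_swap_per_edge)
  inter_stats <- empirical_stats(obs_inter, nulls$intersection, "greater")
  hcs_tab <- region_results(obs_hcs, nulls$hcs, config$p_method,
                            config$correction, config$alpha, a$labels)
  hmis_tab <- region_results(obs_hmis, nulls$hmis, config$p_method,
                             config$correction, config$alpha, a$labels)
  log_stage(verbose, "intersection ratio %.3f (null %.3f +/- %.3f, p = %.4g)",
            obs_inter, inter_stats$null_mean, inter_stats$null_std,
            inter_stats$p)

  topo <- topology_block(a, b)

  log_stage(verbose, "rich-club analysis (n_null = %d)", config$n_null)
  rc_a <- normalized_rcc(a, n_null = config$n_null,
                         seed = child_seed(config$seed, 2),
                         n_swap_per_edge = config$n_swap_per_edge)
  rc_b <- normalized_rcc(b, n_null = config$n_null,
                         seed = child_seed(config$seed, 3),
                         n_swap_per_edge = config$n_swap_per_edge)
  peak_a <- rich_club_peak(rc_a)
  peak_b <- rich_club_peak(rc_b)
  overlap <- if (!is.null(peak_a) && !is.null(peak_b)) {
    overlap_test(a, b, peak_a$k, peak_b$k, n_draws = config$n_null,
                 seed = child_seed(config$seed, 4))
  } else NULL

  robustness <- NULL
  if (!is.null(config$perturbations)) {
    robustness <- lapply(seq_along(config$perturbations), function(i) {
      ps <- config$perturbations[[i]]
      ap <- perturb(a, ps)
      bp <- perturb(b, perturbation_spec(ps$kind, ps$parameter,
                                         child_seed(ps$seed %||%
                                                    config$seed, 90 + i)))
      ri <- intersection_ratio(ap, bp)
      rn <- pair_null_stats(ap, bp, config$n_null,
                            seed = child_seed(config$seed, 10 + i),
                            n_swap_per_edge = config$n_swap_per_edge)
      hc <- region_results(hcs(ap, bp), rn$hcs, config$p_method,
                           config$correction, config$alpha, a$labels)
      list(spec = ps,
           intersection = c(list(observed = ri),
                            empirical_stats(ri, rn$intersection, "greater")),
           n_significant_hcs = sum(hc$significant))
    })
  }

  structure(list(arm = "whole_brain_binary",
                 config = config,
                 species_a = a, species_b = b,
                 intersection = c(list(observed = obs_inter), inter_stats),
                 hcs = hcs_tab, hmis = hmis_tab,
                 topology = topo,
                 richclub = list(a = rc_a, b = rc_b,
                                 peak_a = peak_a, peak_b = peak_b,
                                 overlap = overlap),
                 robustness = robustness),
            class = "comparative_report")
}

#' Hemisphere-wise weighted comparative analysis
#'
#' Splits both species into within-hemisphere subnetworks, thresholds
#' species B's hemisphere to species A's within-hemisphere edge count
#' (retaining weights), and computes the weighted metrics that do not
#' require cross-matrix weight comparability: weighted HMIS (with
#' link-and-weight-reshuffle nulls, FDR-corrected by default), weighted
#' BC/EC/C with cross-species Spearman correlations, and the weighted
#' normalized rich-club curve per species. The intersection ratio and HCS
#' are deliberately absent from this arm: they operate across the two
#' weight matrices, whose scales are not comparable.
#'
#' @param config an \code{\link{analysis_config}} with
#'   \code{arm = "hemisphere_weighted"}; \code{region_table} is required.
#' @param verbose log one line per stage.
#' @return a \code{"comparative_report"} list with one entry per
#'   hemisphere.
#' @export
run_hemisphere_weighted <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  if (config$arm != "hemisphere_weighted") {
    stop("config$arm must be 'hemisphere_weighted'")
  }
  if (is.null(config$region_table)) {
    stop("hemisphere arm requires a region_table with hemisphere labels")
  }
  rt <- load_region_table_input(config$region_table)
  a <- load_connectome_input(config$species_a, "species_a")
  b <- if (!is.null(config$subjects_b)) {
    average_subjects(lapply(config$subjects_b, load_connectome_input))
  } else {
    load_connectome_input(config$species_b, "species_b")
  }
  stopifnot_connectome(a, undirected = TRUE, weighted = TRUE)
  stopifnot_connectome(b, undirected = TRUE, weighted = TRUE)
  stopifnot_same_labels(a, b)
  ha <- split_hemispheres(a, rt)
  hb <- split_hemispheres(b, rt)

  hemis <- lapply(c(L = "L", R = "R"), function(h) {
    ah <- ha[[h]]
    Lh <- edge_count(ah)
    bh <- threshold_to_edge_count(hb[[h]], Lh, binarize = FALSE)
    log_stage(verbose, "hemisphere %s: L = %d, density = %.3f",
              h, Lh, density(ah))
    nulls <- pair_null_stats(ah, bh, config$n_null,
                             seed = child_seed(config$seed,
                                               if (h == "L") 21 else 22),
                             n_swap_per_edge = config$n_swap_per_edge,
                             weighted = TRUE)
    whmis_tab <- region_results(weighted_hmis(ah, bh), nulls$hmis,
                                config$p_method, config$correction,
                                config$alpha, ah$labels)
    topo <- topology_block(ah, bh, normalized = TRUE)
    rc_a <- normalized_rcc(ah, n_null = config$n_null,
                           seed = child_seed(config$seed,
                                             if (h == "L") 23 else 25),
                           n_swap_per_edge = config$n_swap_per_edge)
    rc_b <- normalized_rcc(bh, n_null = config$n_null,
                           seed = child_seed(config$seed,
                                             if (h == "L") 24 else 26),
                           n_swap_per_edge = config$n_swap_per_edge)
    list(species_a = ah, species_b = bh,
         weighted_hmis = whmis_tab, topology = topo,
         richclub = list(a = rc_a, b = rc_b,
                         peak_a = rich_club_peak(rc_a),
                         peak_b = rich_club_peak(rc_b)))
  })

  structure(list(arm = "hemisphere_weighted", config = config,
                 hemispheres = hemis),
            class = "comparative_report")
}

#' @export
print.comparative_report <- function(x, ...) {
  cat(sprintf("<comparative_report: %s arm>\n", x$arm))
  if (x$arm == "whole_brain_binary") {
    cat(sprintf("  intersection ratio %.3f (z = %.2f, p = %.4g)\n",
                x$intersection$observed, x$intersection$z,
                x$intersection$p))
    cat(sprintf("  significant HCS regions: %d / %d\n",
                sum(x$hcs$significant), nrow(x$hcs)))
    cat(sprintf("  significant HMIS regions: %d / %d\n",
                sum(x$hmis$significant), nrow(x$hmis)))
    if (!is.null(x$richclub$overlap)) {
      cat(sprintf("  rich-club overlap %d/%d at k = %d/%d (p = %.4g)\n",
                  x$richclub$overlap$overlap,
                  min(x$richclub$overlap$n_a, x$richclub$overlap$n_b),
                  x$richclub$peak_a$k, x$richclub$peak_b$k,
                  x$richclub$overlap$p))
    }
  } else {
    for (h in names(x$hemispheres)) {
      cat(sprintf("  hemisphere %s: %d / %d significant weighted-HMIS regions\n",
                  h, sum(x$hemispheres[[h]]$weighted_hmis$significant),
                  nrow(x$hemispheres[[h]]$weighted_hmis)))
    }
  }
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

curve_to_df <- function(curve) {
  df <- as.data.frame(curve)
  mem <- attr(curve, "members")
  df$members <- vapply(as.character(df$k), function(k) {
    paste(mem[[k]], collapse = "|")
  }, character(1))
  df
}

topology_to_df <- function(topo) {
  do.call(rbind, lapply(names(topo), function(mn) {
    t <- topo[[mn]]
    data.frame(metric = mn, label = t$a$labels,
               value_a = as.numeric(t$a$values),
               value_b = as.numeric(t$b$values),
               hub_a = as.logical(t$hubs_a), hub_b = as.logical(t$hubs_b),
               rho = t$rho, rho_p = t$p, stringsAsFactors = FALSE)
  }))
}

#' Write a comparative report to a directory of TSV files
#'
#' Emits per-region tables (HCS/HMIS or weighted HMIS with z, p and
#' significance flags), topology tables, rich-club curves with pipe-joined
#' member sets, the overlap test, the intersection summary, and a manifest
#' recording the seed, ensemble sizes and package version.
#'
#' @param r a \code{"comparative_report"}.
#' @param outdir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(r, outdir) {
  stopifnot(inherits(r, "comparative_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv(df, p)
    files <<- c(files, p)
  }
  cfg <- r$config
  manifest <- data.frame(
    key = c("arm", "seed", "n_null", "alpha", "correction", "p_method",
            "n_swap_per_edge", "package_version"),
    value = c(r$arm, cfg$seed, cfg$n_null, cfg$alpha, cfg$correction,
              cfg$p_method, cfg$n_swap_per_edge,
              as.character(utils::packageVersion("comparanet"))),
    stringsAsFactors = FALSE)
  emit(manifest, "manifest.tsv")

  if (r$arm == "whole_brain_binary") {
    per_region <- merge(
      setNames(r$hcs, c("label", paste0("hcs_", names(r$hcs)[-1]))),
      setNames(r$hmis, c("label", paste0("hmis_", names(r$hmis)[-1]))),
      by = "label", sort = FALSE)
    emit(per_region, "regions.tsv")
    inter <- r$intersection
    emit(data.frame(observed = inter$observed, null_mean = inter$null_mean,
                    null_std = inter$null_std, z = inter$z, p = inter$p,
                    n_null = inter$n), "intersection.tsv")
    emit(topology_to_df(r$topology), "topology.tsv")
    emit(curve_to_df(r$richclub$a), "richclub_a.tsv")
    emit(curve_to_df(r$richclub$b), "richclub_b.tsv")
    if (!is.null(r$richclub$overlap)) {
      ov <- r$richclub$overlap
      emit(data.frame(k_a = r$richclub$peak_a$k, k_b = r$richclub$peak_b$k,
                      n_a = ov$n_a, n_b = ov$n_b, overlap = ov$overlap,
                      p = ov$p), "richclub_overlap.tsv")
    }
    if (!is.null(r$robustness)) {
      rob <- do.call(rbind, lapply(r$robustness, function(x) {
        data.frame(kind = x$spec$kind, parameter = x$spec$parameter,
                   intersection = x$intersection$observed,
                   z = x$intersection$z, p = x$intersection$p,
                   n_significant_hcs = x$n_significant_hcs,
                   stringsAsFactors = FALSE)
      }))
      emit(rob, "robustness.tsv")
    }
  } else {
    for (h in names(r$hemispheres)) {
      rh <- r$hemispheres[[h]]
      emit(rh$weighted_hmis, sprintf("weighted_hmis_%s.tsv", h))
      emit(topology_to_df(rh$topology), sprintf("topology_%s.tsv", h))
      emit(curve_to_df(rh$richclub$a), sprintf("richclub_a_%s.tsv", h))
      emit(curve_to_df(rh$richclub$b), sprintf("richclub_b_%s.tsv", h))
    }
  }
  invisible(files)
}
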