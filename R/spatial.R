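#' Homotypic aggregation parameters
#'
#' The DBSCAN reachability radius can be given directly (`eps_um`) or
#' derived from a minimum cell density: a disk of radius `eps` holding
#' `min_points` cells at exactly `density_per_mm2` gives
#' `eps = sqrt(min_points / (pi * density_per_mm2))` (converted to
#' micrometres).
#'
#' @param min_points minimum points per cluster (>= 2); default 5.
#' @param density_per_mm2 minimum density in cells per square millimetre.
#' @param eps_um reachability radius in micrometres. Exactly one of
#'   `density_per_mm2` / `eps_um` must be given.
#' @return A list of class `homotypic_params` with the resolved `eps_um`.
#' @export
homotypic_params <- function(min_points = 5L, density_per_mm2 = NULL,
                             eps_um = NULL) {
  if (min_points < 2L) stop("min_points must be >= 2")
  if (is.null(density_per_mm2) == is.null(eps_um)) {
    stop("give exactly one of density_per_mm2 or eps_um")
  }
  if (is.null(eps_um)) {
    if (density_per_mm2 <= 0) stop("density_per_mm2 must be positive")
    eps_um <- sqrt(min_points / (pi * density_per_mm2)) * 1000
  }
  if (eps_um <= 0) stop("eps_um must be positive")
  structure(list(min_points = as.integer(min_points), eps_um = eps_um),
            class = "homotypic_params")
}

# grid-bucketed eps-neighbour counts and core-point adjacency; the
# neighbourhood of a point includes the point itself
dbscan_neighbours <- function(xy, eps) {
  n <- nrow(xy)
  gx <- floor(xy[, 1] / eps)
  gy <- floor(xy[, 2] / eps)
  key <- paste(gx, gy)
  buckets <- split(seq_len(n), key)
  eps2 <- eps^2
  lapply(seq_len(n), function(i) {
    cand <- unlist(buckets[paste(rep(gx[i] + (-1:1), each = 3),
                                 gy[i] + (-1:1))],
                   use.names = FALSE)
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    cand[d2 <= eps2]
  })
}

#' Homotypic spatial clusters (DBSCAN)
#'
#' Density-based clustering of the centroids of cells of one type.
#' Core points (at least `min_points` cells, itself included, within
#' `eps_um`) connected through their eps-neighbourhoods form clusters;
#' non-core cells within `eps_um` of a core point join the cluster of the
#' nearest such core (ties to the core with the lexicographically smaller
#' coordinates), making the labelling invariant to input order; remaining
#' cells are noise (cluster 0). Clusters are numbered by descending size.
#'
#' @param cells a `cell_table` subset of one type, with `centroid_x_um`
#'   and `centroid_y_um` columns.
#' @param params a [homotypic_params].
#' @return Integer vector of per-cell cluster ids (0 = noise), aligned
#'   with the rows of `cells`.
#' @export
homotypic_clusters <- function(cells, params) {
  stopifnot(inherits(params, "homotypic_params"))
  n <- nrow(cells)
  if (n == 0L) return(integer(0))
  xy <- cbind(cells$centroid_x_um, cells$centroid_y_um)
  eps <- params$eps_um
  nb <- dbscan_neighbours(xy, eps)
  is_core <- lengths(nb) >= params$min_points
  labels <- integer(n)
  if (!any(is_core)) return(labels)
  # connected components of core points through eps-neighbourhoods
  comp <- integer(n)
  cid <- 0L
  for (s in which(is_core)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      nxt <- nb[[p]][is_core[nb[[p]]] & comp[nb[[p]]] == 0L]
      comp[nxt] <- cid
      queue <- c(queue, nxt)
    }
  }
  labels[is_core] <- comp[is_core]
  # border points: nearest reachable core, ties by core coordinates
  for (i in which(!is_core)) {
    cores <- nb[[i]][is_core[nb[[i]]]]
    if (length(cores) == 0L) next
    d2 <- (xy[cores, 1] - xy[i, 1])^2 + (xy[cores, 2] - xy[i, 2])^2
    best <- cores[order(d2, xy[cores, 1], xy[cores, 2])][1L]
    labels[i] <- comp[best]
  }
  # renumber by descending size; ties by smallest member coordinates
  ids <- sort(unique(labels[labels > 0L]))
  sizes <- vapply(ids, function(k) sum(labels == k), integer(1))
  minx <- vapply(ids, function(k) min(xy[labels == k, 1]), numeric(1))
  miny <- vapply(ids, function(k) min(xy[labels == k, 2]), numeric(1))
  ord <- ids[order(-sizes, minx, miny)]
  out <- labels
  out[labels > 0L] <- match(labels[labels > 0L], ord)
  out
}

#' Nearest heterotypic distances
#'
#' For every source cell, the Euclidean distance (micrometres, between
#' centroids) to the nearest target cell of the same sample. A cell
#' present in both sets never matches itself. Samples without any
#' (non-self) target are skipped with a warning.
#'
#' @param sources,targets `cell_table` subsets with `sample_id`,
#'   `cell_id`, `centroid_x_um`, `centroid_y_um`.
#' @param source_type,target_type labels recorded in the output; default
#'   to the subsets' `cell_type` (first value).
#' @return A `distance_table` data frame with columns `cell_id`,
#'   `sample_id`, `source_type`, `target_type`, `nearest_distance_um`,
#'   `nearest_target_id`.
#' @export
nearest_distances <- function(sources, targets,
                              source_type = NULL, target_type = NULL) {
  if (is.null(source_type)) {
    source_type <- if (nrow(sources)) as.character(sources$cell_type[1L])
                   else NA_character_
  }
  if (is.null(target_type)) {
    target_type <- if (nrow(targets)) as.character(targets$cell_type[1L])
                   else NA_character_
  }
  res <- lapply(unique(sources$sample_id), function(sid) {
    S <- sources[sources$sample_id == sid, , drop = FALSE]
    T_ <- targets[targets$sample_id == sid, , drop = FALSE]
    if (nrow(T_) == 0L) {
      warning("sample '", sid, "' has no target cells; sources skipped")
      return(NULL)
    }
    d2 <- outer(S$centroid_x_um, T_$centroid_x_um, `-`)^2 +
          outer(S$centroid_y_um, T_$centroid_y_um, `-`)^2
    self <- outer(S$cell_id, T_$cell_id, `==`)
    d2[self] <- Inf
    j <- apply(d2, 1L, which.min)
    dmin <- sqrt(d2[cbind(seq_len(nrow(S)), j)])
    ok <- is.finite(dmin)
    if (!all(ok)) {
      warning("source cell(s) in sample '", sid,
              "' have no non-self target; dropped")
    }
    data.frame(cell_id = S$cell_id[ok], sample_id = sid,
               source_type = source_type, target_type = target_type,
               nearest_distance_um = dmin[ok],
               nearest_target_id = T_$cell_id[j][ok],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(), sample_id = character(),
                      source_type = character(), target_type = character(),
                      nearest_distance_um = numeric(),
                      nearest_target_id = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("distance_table", "data.frame")
  out
}

#' Classify cells as proximal or distal
#'
#' A source cell is proximal when its nearest-target distance is strictly
#' lower than the cutoff ("lower than" is strict: a cell exactly at the
#' cutoff is distal).
#'
#' @param distances a `distance_table`.
#' @param cutoff_um distance cutoff in micrometres (> 0). The default
#'   12 um corresponds to twice a 6-um maximum cell radius.
#' @return The table with an added `proximity` column
#'   (`"proximal"`/`"distal"`).
#' @export
classify_proximity <- function(distances, cutoff_um = 12) {
  if (!is.numeric(cutoff_um) || cutoff_um <= 0) {
    stop("cutoff_um must be positive")
  }
  distances$proximity <- ifelse(distances$nearest_distance_um < cutoff_um,
                                "proximal", "distal")
  distances
}

#' Compare nearest-distance distributions between sample groups
#'
#' For each (source type, target type) comparison the cell-level nearest
#' distances are pooled per group (or reduced to per-sample medians with
#' `per_sample_median = TRUE`) and compared with a two-sided Wilcoxon
#' rank-sum test (tie-corrected normal approximation with continuity
#' correction). p-values are Benjamini-Hochberg adjusted across all
#' comparisons in the list. A comparison is flagged `relevant` when the
#' absolute difference of group medians reaches `relevance_um` (default
#' 8 um, a B/T-cell diameter) and the FDR is below `q_cutoff`
#' (default 0.1).
#'
#' @param distances a `distance_table` (may hold several type pairs).
#' @param group_map named character vector mapping `sample_id` to group.
#' @param comparisons optional data frame with columns `source_type`,
#'   `target_type`; defaults to every pair present in `distances`.
#' @param groups length-2 character vector naming group A and group B;
#'   defaults to the sorted unique groups.
#' @param relevance_um minimum |median difference| for relevance.
#' @param q_cutoff FDR cutoff for relevance.
#' @param per_sample_median compare per-sample medians instead of pooled
#'   cell-level distances.
#' @return A data frame with one row per comparison: group sizes, group
#'   medians, `delta_median_um`, `wilcoxon_p`, `fdr_q` and `relevant`.
#' @export
compare_groups <- function(distances, group_map, comparisons = NULL,
                           groups = NULL, relevance_um = 8,
                           q_cutoff = 0.1, per_sample_median = FALSE) {
  if (is.null(groups)) groups <- sort(unique(as.character(group_map)))
  if (length(groups) != 2L) {
    stop("exactly two sample groups are required; got ",
         paste(groups, collapse = ", "))
  }
  if (is.null(comparisons)) {
    comparisons <- unique(distances[, c("source_type", "target_type")])
  }
  distances$group <- as.character(group_map[distances$sample_id])
  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    st <- comparisons$source_type[i]
    tt <- comparisons$target_type[i]
    d <- distances[distances$source_type == st &
                   distances$target_type == tt, , drop = FALSE]
    pick <- function(g) {
      dd <- d[d$group == g, , drop = FALSE]
      if (per_sample_median) {
        as.vector(tapply(dd$nearest_distance_um, dd$sample_id, stats::median))
      } else {
        dd$nearest_distance_um
      }
    }
    a <- pick(groups[1L])
    b <- pick(groups[2L])
    if (length(a) < 2L || length(b) < 2L) {
      warning("comparison ", st, " -> ", tt,
              " skipped: a group has fewer than 2 observations")
      return(NULL)
    }
    w <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    data.frame(source_type = st, target_type = tt,
               group_a = groups[1L], group_b = groups[2L],
               n_a = length(a), n_b = length(b),
               median_a_um = stats::median(a),
               median_b_um = stats::median(b),
               delta_median_um = stats::median(a) - stats::median(b),
               wilcoxon_p = w$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$fdr_q <- stats::p.adjust(out$wilcoxon_p, method = "BH")
  out$relevant <- abs(out$delta_median_um) >= relevance_um &
                  out$fdr_q < q_cutoff
  rownames(out) <- NULL
  out
}

# per-sample squared-distance matrices and type vectors, reused by every
# permutation so each reshuffle costs only index bookkeeping
prepare_permutation_data <- function(cells) {
  lapply(split(seq_len(nrow(cells)), cells$sample_id), function(idx) {
    x <- cells$centroid_x_um[idx]
    y <- cells$centroid_y_um[idx]
    d2 <- outer(x, x, `-`)^2 + outer(y, y, `-`)^2
    diag(d2) <- Inf
    list(d2 = d2, types = as.character(cells$cell_type[idx]),
         sample_id = cells$sample_id[idx[1L]])
  })
}

min_dist_sq <- function(d2, src, tgt) {
  M <- d2[tgt, src, drop = FALSE]
  if (nrow(M) == 1L) return(as.vector(M))
  Reduce(pmin, lapply(seq_len(nrow(M)), function(i) M[i, ]))
}

group_delta_stat <- function(per_sample, group_of, source_type, target_type,
                             groups, type_lists) {
  pooled <- list(numeric(0), numeric(0))
  for (s in seq_along(per_sample)) {
    ps <- per_sample[[s]]
    types <- type_lists[[s]]
    src <- which(types == source_type)
    tgt <- which(types == target_type)
    if (length(src) == 0L || length(tgt) == 0L) next
    g <- match(group_of[s], groups)
    if (is.na(g)) next
    d <- sqrt(min_dist_sq(ps$d2, src, tgt))
    pooled[[g]] <- c(pooled[[g]], d)
  }
  stats::median(pooled[[1L]]) - stats::median(pooled[[2L]])
}

#' Permutation null for a between-group distance difference
#'
#' The statistic is the difference of the pooled median nearest
#' source-to-target distances between the two sample groups. Its null
#' distribution is obtained by reshuffling the cell-type identities among
#' all cells within each sample (positions fixed, type counts preserved)
#' `K` times and recomputing the statistic. The two-tailed p-value is
#' `(1 + #\{|null| >= |observed|\}) / (K + 1)`.
#'
#' @param cells a `cell_table` covering all samples (all cell types; the
#'   reshuffle permutes every cell's identity).
#' @param group_map named character vector mapping `sample_id` to group.
#' @param source_type,target_type the cell types compared.
#' @param K number of permutations (default 10000).
#' @param seed RNG seed.
#' @param groups length-2 vector naming group A and B; defaults to sorted
#'   unique groups.
#' @return An object of class `permutation_result`: a list with
#'   `observed_delta_um`, `n_permutations`, `null_deltas`,
#'   `p_two_tailed`, `fdr_q` (`NA` until adjusted across a comparison
#'   set, see [permutation_tests]), and `seed`.
#' @export
permutation_null <- function(cells, group_map, source_type, target_type,
                             K = 10000L, seed = 1L, groups = NULL) {
  if (K < 1L) stop("K must be >= 1")
  if (is.null(groups)) groups <- sort(unique(as.character(group_map)))
  if (length(groups) != 2L) stop("exactly two sample groups are required")
  per_sample <- prepare_permutation_data(cells)
  group_of <- vapply(per_sample, function(ps) {
    as.character(group_map[ps$sample_id])
  }, character(1))
  obs_types <- lapply(per_sample, `[[`, "types")
  observed <- group_delta_stat(per_sample, group_of, source_type,
                               target_type, groups, obs_types)
  set.seed(seed)
  null_deltas <- vapply(seq_len(K), function(k) {
    perm_types <- lapply(obs_types, function(tv) tv[sample.int(length(tv))])
    group_delta_stat(per_sample, group_of, source_type, target_type,
                     groups, perm_types)
  }, numeric(1))
  p <- (1 + sum(abs(null_deltas) >= abs(observed))) / (K + 1)
  structure(list(observed_delta_um = observed,
                 n_permutations = as.integer(K),
                 null_deltas = null_deltas,
                 p_two_tailed = p, fdr_q = NA_real_,
                 seed = as.integer(seed),
                 source_type = source_type, target_type = target_type),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result %s -> %s: observed delta = %.2f um, p = %.4g (K = %d)\n",
    x$source_type, x$target_type, x$observed_delta_um, x$p_two_tailed,
    x$n_permutations))
  invisible(x)
}

#' Run permutation tests over a set of comparisons with BH adjustment
#'
#' @param cells,group_map,K,seed,groups see [permutation_null].
#' @param comparisons data frame with columns `source_type`,
#'   `target_type`.
#' @return A list of [permutation_null] results with `fdr_q` filled by
#'   Benjamini-Hochberg adjustment across the comparison set.
#' @export
permutation_tests <- function(cells, group_map, comparisons, K = 10000L,
                              seed = 1L, groups = NULL) {
  res <- lapply(seq_len(nrow(comparisons)), function(i) {
    permutation_null(cells, group_map,
                     comparisons$source_type[i], comparisons$target_type[i],
                     K = K, seed = seed + i - 1L, groups = groups)
  })
  q <- stats::p.adjust(vapply(res, `[[`, numeric(1), "p_two_tailed"),
                       method = "BH")
  for (i in seq_along(res)) res[[i]]$fdr_q <- q[i]
  res
}
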