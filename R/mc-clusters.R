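#' Micellar clusters and aggregation number
#'
#' Two chains belong to the same cluster when any A monomer of one occupies a
#' nearest-neighbour site of an A monomer of the other (head-head and
#' head-tail contacts do not aggregate).  The aggregation number `N_a` is the
#' number-average cluster size in chains; the weight (chain-weighted) average
#' is also reported since figure conventions differ between studies.
#'
#' @param state A `lattice_state`.
#' @return List with `membership` (cluster id per chain), `sizes` (chains per
#'   cluster), `n_clusters`, `n_a` (number-average) and `n_a_weight`
#'   (weight-average).
#' @export
find_clusters <- function(state) {
  membership <- cpp_find_clusters(state$L, state$coords, state$species,
                                  state$chain_len)
  sizes <- as.integer(table(membership))
  list(membership = membership, sizes = sizes, n_clusters = length(sizes),
       n_a = mean(sizes), n_a_weight = sum(sizes^2) / sum(sizes))
}

#' Thresholds for phase classification
#'
#' The labels follow the morphology sequence seen in lattice self-assembly of
#' gemini pentablock chains: spherical micelles (M), micelles mixed with
#' elongated rod-like micelles (M/R), rods merging into three-dimensional
#' Y-channels (R/CH), pure channels (CH) and cylinders (C).  The rules are
#' deliberately simple, deterministic and configurable:
#' relative gyration-tensor asphericity above `aspherical` marks a cluster as
#' elongated; a percolating cluster with at least `branching` skeleton branch
#' points is a channel network, a percolating cluster with fewer is a
#' cylinder; without percolation the chain-weighted fraction of elongated
#' clusters below `frac_elongated_mr` gives M, below `frac_elongated_rch`
#' gives M/R, and above it R/CH.
#'
#' @param aspherical Asphericity threshold for "elongated" (0 sphere, 1 rod).
#' @param branching Minimum skeleton branch points for a channel network.
#' @param frac_elongated_mr,frac_elongated_rch Chain-weighted elongated
#'   fractions separating M from M/R and M/R from R/CH.
#' @param cell Coarse-graining cell size (lattice units) for the cluster
#'   skeleton graph.
#' @param prune Leaf-pruning rounds applied to the skeleton before counting
#'   branch points.
#' @param min_cluster Ignore clusters with fewer chains when aggregating the
#'   elongated fraction (free chains carry no shape signal).
#' @return Named list of thresholds.
#' @export
phase_thresholds <- function(aspherical = 0.4, branching = 2L,
                             frac_elongated_mr = 0.1,
                             frac_elongated_rch = 0.5,
                             cell = 3L, prune = 2L, min_cluster = 2L) {
  list(aspherical = aspherical, branching = as.integer(branching),
       frac_elongated_mr = frac_elongated_mr,
       frac_elongated_rch = frac_elongated_rch,
       cell = as.integer(cell), prune = as.integer(prune),
       min_cluster = as.integer(min_cluster))
}

#' Per-cluster shape diagnostics
#'
#' For every cluster the monomer contact graph is traversed breadth-first to
#' obtain image-consistent coordinates; loops that close with a non-zero
#' coordinate mismatch reveal percolation through the periodic boundary.
#' From the traversal coordinates the gyration tensor, its relative
#' asphericity
#' `((l1-l2)^2 + (l1-l3)^2 + (l2-l3)^2) / (2 (l1+l2+l3)^2)`
#' and a coarse skeleton branch-point count are computed.
#'
#' @param state A `lattice_state`.
#' @param clusters Optional result of [find_clusters()] (recomputed if
#'   missing).
#' @param thresholds See [phase_thresholds()] (cell size and pruning rounds
#'   are used here).
#' @return Tibble with one row per cluster: `cluster`, `n_chains`,
#'   `asphericity`, `rg2`, `branch_points`, `perc_x`, `perc_y`, `perc_z`,
#'   `n_perc_axes`.
#' @export
cluster_metrics <- function(state, clusters = NULL,
                            thresholds = phase_thresholds()) {
  if (is.null(clusters)) clusters <- find_clusters(state)
  geo <- cpp_cluster_geometry(state$L, state$coords, state$species,
                              state$chain_len, clusters$membership)
  bfs <- geo$bfs_coords
  perc <- geo$percolates
  mono_cluster <- rep(clusters$membership, each = state$chain_len)

  rows <- lapply(seq_len(clusters$n_clusters), function(cl) {
    p <- bfs[mono_cluster == cl, , drop = FALSE]
    ctr <- colMeans(p)
    q <- base::sweep(p, 2, ctr)
    gyr <- crossprod(q) / nrow(q)
    ev <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    tr <- sum(ev)
    asph <- if (tr > 0)
      ((ev[1] - ev[2])^2 + (ev[1] - ev[3])^2 + (ev[2] - ev[3])^2) / (2 * tr^2)
    else 0
    tibble::tibble(
      cluster = cl,
      n_chains = clusters$sizes[cl],
      asphericity = asph,
      rg2 = tr,
      branch_points = skeleton_branch_points(p, thresholds$cell, thresholds$prune),
      perc_x = perc[cl, 1], perc_y = perc[cl, 2], perc_z = perc[cl, 3],
      n_perc_axes = sum(perc[cl, ]))
  })
  do.call(rbind, rows)
}

# Coarse skeleton of a cluster: map traversal coordinates to cells of edge
# `cell`, connect cells within a king-move neighbourhood, reduce the cell
# graph to its minimum spanning tree (a thin tubular cluster gives a path,
# a channel junction a degree-3 node), prune leaf cells `prune` times, and
# count remaining cells of degree >= 3.  Sub-cell-scale objects have no
# meaningful skeleton and report 0.
skeleton_branch_points <- function(coords, cell = 3L, prune = 2L) {
  cells <- unique(floor(coords / cell))
  n <- nrow(cells)
  if (n < 3) return(0L)
  d1 <- abs(outer(cells[, 1], cells[, 1], "-")) <= 1
  d2 <- abs(outer(cells[, 2], cells[, 2], "-")) <= 1
  d3 <- abs(outer(cells[, 3], cells[, 3], "-")) <= 1
  adj <- d1 & d2 & d3
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g <- igraph::mst(g)
  for (i in seq_len(prune)) {
    leaves <- which(igraph::degree(g) <= 1)
    if (length(leaves) == 0 || igraph::vcount(g) - length(leaves) < 3) break
    g <- igraph::delete_vertices(g, leaves)
  }
  sum(igraph::degree(g) >= 3)
}

#' Classify the morphology of a configuration
#'
#' Applies the fixed threshold rules of [phase_thresholds()] to the cluster
#' diagnostics.  Deterministic: the same configuration always yields the same
#' label.
#'
#' @param state A `lattice_state` (or `NULL` when `metrics` is supplied).
#' @param clusters Optional [find_clusters()] result.
#' @param metrics Optional precomputed [cluster_metrics()] tibble.
#' @param thresholds See [phase_thresholds()].
#' @return List with `label` (one of `"disordered"`, `"M"`, `"M/R"`,
#'   `"R/CH"`, `"CH"`, `"C"`) and the diagnostic summary used
#'   (`frac_elongated`, `max_branch_points`, `max_perc_axes`, `metrics`).
#' @export
classify_phase <- function(state = NULL, clusters = NULL, metrics = NULL,
                           thresholds = phase_thresholds()) {
  if (is.null(metrics)) {
    if (is.null(state)) stop("either a state or a metrics table is required", call. = FALSE)
    metrics <- cluster_metrics(state, clusters, thresholds)
  }
  if (is.null(metrics) || nrow(metrics) == 0)
    return(list(label = "disordered", frac_elongated = NA_real_,
                max_branch_points = NA_integer_, max_perc_axes = NA_integer_,
                metrics = metrics))

  percolating <- metrics[metrics$n_perc_axes >= 1, , drop = FALSE]
  big <- metrics[metrics$n_chains >= thresholds$min_cluster, , drop = FALSE]
  frac_elong <- if (nrow(big) > 0)
    sum(big$n_chains[big$asphericity > thresholds$aspherical]) / sum(big$n_chains)
  else 0

  label <-
    if (nrow(percolating) > 0) {
      branched <- percolating$branch_points >= thresholds$branching
      if (any(branched & percolating$n_perc_axes >= 2)) "CH"
      else if (any(!branched)) "C"
      else "CH"
    } else if (frac_elong < thresholds$frac_elongated_mr) "M"
    else if (frac_elong < thresholds$frac_elongated_rch) "M/R"
    else "R/CH"

  list(label = label, frac_elongated = frac_elong,
       max_branch_points = max(metrics$branch_points),
       max_perc_axes = max(metrics$n_perc_axes), metrics = metrics)
}
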