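#' All-pairs shortest-path lengths by breadth-first search
#'
#' Distances on an unweighted undirected graph; unreachable pairs are `Inf`
#' and the diagonal is 0. Implemented as a frontier expansion over boolean
#' matrix products, which is exact for 0/1 adjacency.
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @return Matrix of shortest-path lengths.
#' @export
bfs_distances <- function(adjacency) {
  bfs_impl(check_adjacency(adjacency))
}

bfs_impl <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reached <- diag(n) > 0
  frontier <- a > 0
  step <- 1
  while (any(frontier & !reached)) {
    new <- frontier & !reached
    d[new] <- step
    reached <- reached | frontier
    frontier <- ((frontier * 1) %*% a) > 0
    step <- step + 1
  }
  dimnames(d) <- dimnames(a)
  d
}

#' Clustering coefficient and transitivity
#'
#' Nodal clustering is `2 t_i / (k_i (k_i - 1))` where `t_i` counts triangles
#' through node i; nodes of degree < 2 contribute 0. The network value is the
#' mean over all nodes. Transitivity is the global ratio
#' `sum(2 t_i) / sum(k_i (k_i - 1))` (0 when no node has degree >= 2).
#'
#' @inheritParams bfs_distances
#' @return Named list with `clustering` and `transitivity`.
#' @export
clustering_and_transitivity <- function(adjacency) {
  clustering_impl(check_adjacency(adjacency))
}

clustering_impl <- function(a) {
  k <- rowSums(a)
  t2 <- diag(a %*% a %*% a) # 2 * triangles through each node
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, t2 / denom, 0)
  list(
    clustering = mean(ci),
    transitivity = if (sum(denom) > 0) sum(t2) / sum(denom) else 0
  )
}

#' Characteristic path length and global efficiency
#'
#' Characteristic path length averages the finite off-diagonal entries of the
#' distance matrix (`NaN` when every pair is disconnected); global efficiency
#' averages `1 / d` over all ordered pairs with `1 / Inf = 0`, so
#' disconnection lowers efficiency instead of breaking the average.
#'
#' @param distances Matrix from [bfs_distances()].
#' @return Named list with `char_path_length` and `efficiency`.
#' @export
integration_metrics <- function(distances) {
  n <- nrow(distances)
  if (n < 2) abort("Need at least 2 nodes.")
  off <- distances[row(distances) != col(distances)]
  finite <- off[is.finite(off)]
  list(
    char_path_length = if (length(finite) > 0) mean(finite) else NaN,
    efficiency = mean(ifelse(is.finite(off), 1 / off, 0))
  )
}

#' Mean nodal betweenness centrality
#'
#' Brandes' accumulation of pair dependencies on an unweighted undirected
#' graph: unnormalized shortest-path counts, endpoints excluded, each
#' unordered pair counted once; unreachable pairs contribute nothing.
#'
#' @inheritParams bfs_distances
#' @param nodal If `TRUE` return the per-node vector instead of the mean.
#' @return Mean nodal betweenness (or the nodal vector).
#' @export
betweenness_mean <- function(adjacency, nodal = FALSE) {
  betweenness_impl(check_adjacency(adjacency), nodal)
}

betweenness_impl <- function(a, nodal = FALSE) {
  n <- nrow(a)
  nbr <- lapply(seq_len(n), function(i) which(a[i, ] > 0))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n)
    sigma[s] <- 1
    dist <- rep(-1L, n)
    dist[s] <- 0L
    preds <- vector("list", n)
    queue <- integer(n)
    queue[1] <- s
    head <- 1L
    tail <- 1L
    visited <- integer(n)
    nv <- 0L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      nv <- nv + 1L
      visited[nv] <- v
      for (w in nbr[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (i in rev(seq_len(nv))) {
      w <- visited[i]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2 # each unordered pair accumulated from both endpoints
  if (nodal) bc else mean(bc)
}

#' Eccentricity and diameter
#'
#' A node's eccentricity is its maximum finite distance to any other node
#' (0 for isolated nodes); the network eccentricity is the nodal mean and the
#' diameter is the maximum nodal eccentricity.
#'
#' @param distances Matrix from [bfs_distances()].
#' @return Named list with `eccentricity` and `diameter`.
#' @export
eccentricity_and_diameter <- function(distances) {
  n <- nrow(distances)
  ecc <- vapply(seq_len(n), function(i) {
    di <- distances[i, -i]
    fin <- di[is.finite(di)]
    if (length(fin) > 0) max(fin) else 0
  }, numeric(1))
  list(eccentricity = mean(ecc), diameter = max(ecc, 0))
}

#' Degree assortativity
#'
#' Newman's degree assortativity: the Pearson correlation of end-node degrees
#' over all edges, each edge counted in both directions. `NaN` when the graph
#' has no edges or end-degree variance is zero (e.g. regular graphs).
#'
#' @inheritParams bfs_distances
#' @return Assortativity coefficient in `[-1, 1]`, or `NaN`.
#' @export
degree_assortativity <- function(adjacency) {
  assortativity_impl(check_adjacency(adjacency))
}

assortativity_impl <- function(a) {
  k <- rowSums(a)
  e <- which(a > 0 & upper.tri(a), arr.ind = TRUE)
  if (nrow(e) == 0) {
    return(NaN)
  }
  x <- c(k[e[, 1]], k[e[, 2]])
  y <- c(k[e[, 2]], k[e[, 1]])
  if (sd(x) == 0 || sd(y) == 0) {
    return(NaN)
  }
  cor(x, y)
}

#' Mean k-core coreness
#'
#' A node's coreness is the largest k for which it survives iterative pruning
#' of nodes with degree < k (degrees recomputed within the surviving
#' subgraph).
#'
#' @inheritParams bfs_distances
#' @param nodal If `TRUE` return the per-node coreness vector.
#' @return Mean coreness (or the nodal vector).
#' @export
kcore_mean <- function(adjacency, nodal = FALSE) {
  kcore_impl(check_adjacency(adjacency), nodal)
}

kcore_impl <- function(a, nodal = FALSE) {
  n <- nrow(a)
  core <- numeric(n)
  alive <- rep(TRUE, n)
  for (k in seq_len(max(1L, n - 1L))) {
    repeat {
      deg <- as.vector(a %*% alive)
      drop <- alive & deg < k
      if (!any(drop)) break
      alive[drop] <- FALSE
    }
    if (!any(alive)) break
    core[alive] <- k
  }
  if (nodal) core else mean(core)
}

#' The ten graph measures of one binary network
#'
#' Computes the full metric vector for one unweighted undirected graph:
#' segregation (clustering, transitivity), integration (efficiency,
#' characteristic path length), centrality (mean degree, mean betweenness,
#' mean eccentricity, diameter) and resilience (degree assortativity, mean
#' coreness). Disconnected graphs use finite-distance conventions (see the
#' individual metric functions); degenerate quantities are `NaN` rather than
#' errors so threshold sweeps over sparse graphs stay total.
#'
#' @inheritParams bfs_distances
#' @param metrics Character vector selecting a subset of
#'   `c("clustering", "transitivity", "efficiency", "char_path_length",
#'   "degree", "betweenness", "eccentricity", "diameter", "assortativity",
#'   "kcore")`. Restricting the set skips the corresponding computations.
#' @return Named numeric vector over `metrics`.
#' @examples
#' k4 <- 1 - diag(4)
#' metric_vector(k4)
#' @param check Validate the adjacency and metric names (default). Internal
#'   bulk callers that construct valid inputs may disable it.
#' @export
metric_vector <- function(adjacency, metrics = metric_names(), check = TRUE) {
  a <- adjacency
  if (check) {
    a <- check_adjacency(a)
    metrics <- match.arg(metrics, metric_names(), several.ok = TRUE)
  }
  if (nrow(a) < 2) abort("Network too small: need >= 2 nodes.")
  out <- setNames(rep(NA_real_, length(metrics)), metrics)
  if (any(c("clustering", "transitivity") %in% metrics)) {
    ct <- clustering_impl(a)
    if ("clustering" %in% metrics) out["clustering"] <- ct$clustering
    if ("transitivity" %in% metrics) out["transitivity"] <- ct$transitivity
  }
  need_dist <- c("efficiency", "char_path_length", "eccentricity", "diameter")
  if (any(need_dist %in% metrics)) {
    d <- bfs_impl(a)
    im <- integration_metrics(d)
    ed <- eccentricity_and_diameter(d)
    if ("efficiency" %in% metrics) out["efficiency"] <- im$efficiency
    if ("char_path_length" %in% metrics) out["char_path_length"] <- im$char_path_length
    if ("eccentricity" %in% metrics) out["eccentricity"] <- ed$eccentricity
    if ("diameter" %in% metrics) out["diameter"] <- ed$diameter
  }
  if ("degree" %in% metrics) out["degree"] <- mean(rowSums(a))
  if ("betweenness" %in% metrics) out["betweenness"] <- betweenness_impl(a)
  if ("assortativity" %in% metrics) out["assortativity"] <- assortativity_impl(a)
  if ("kcore" %in% metrics) out["kcore"] <- kcore_impl(a)
  out
}

#' Window-resolved graph metrics for a cohort
#'
#' Binarizes every windowed FC matrix across the threshold sweep, restricts
#' to each named network (plus `"brain"`), and computes the selected graph
#' metrics, returning one long tibble — the exact input of
#' [summarize_windows()].
#'
#' @param fc_tbl Output of [compute_fc()] (list-column `fc`).
#' @param map A [network_map()] whose ROI labels match the FC matrices.
#' @param thresholds Binarization thresholds (default [default_thresholds()]).
#' @param networks Networks to analyse; default all named networks plus
#'   `"brain"`.
#' @param metrics Metric subset passed to [metric_vector()].
#' @return Long tibble with columns `participant_id`, `group`, `condition`,
#'   `epoch`, `network`, `threshold`, `window`, `metric`, `value`.
#' @export
graph_metrics <- function(fc_tbl, map,
                          thresholds = default_thresholds(),
                          networks = c(network_names(map), "brain"),
                          metrics = metric_names()) {
  stopifnot(is.data.frame(fc_tbl), "fc" %in% names(fc_tbl))
  thresholds <- check_thresholds(thresholds)
  metrics <- match.arg(metrics, metric_names(), several.ok = TRUE)
  metrics <- metric_names()[metric_names() %in% metrics] # canonical order
  want <- metric_names() %in% metrics
  roi_names <- rownames(fc_tbl$fc[[1]])
  roi_idx <- lapply(setNames(networks, networks), function(nw) {
    if (identical(nw, "brain")) {
      return(seq_along(roi_names))
    }
    idx <- match(network_rois(map, nw), roi_names)
    if (anyNA(idx)) {
      abort(paste0("Network ", nw, " has ROI labels missing from the data."))
    }
    idx
  })
  per_epoch <- purrr::map(seq_len(nrow(fc_tbl)), function(i) {
    fc <- fc_tbl$fc[[i]]
    n_win <- dim(fc)[3]
    cells <- expand.grid(
      metric = metrics, window = seq_len(n_win), threshold = thresholds,
      network = networks,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    cells$value <- unlist(lapply(networks, function(nw) {
      cpp_window_metric_sweep(
        fc, dim(fc), as.integer(roi_idx[[nw]]), thresholds, want
      )
    }), use.names = FALSE)
    cells
  })
  meta <- fc_tbl[rep(seq_len(nrow(fc_tbl)), vapply(per_epoch, nrow, integer(1))),
    intersect(c("participant_id", "group", "condition", "epoch"), names(fc_tbl)),
    drop = FALSE
  ]
  out <- dplyr::bind_cols(as_tibble(meta), as_tibble(dplyr::bind_rows(per_epoch)))
  dplyr::relocate(out, "metric", "value", .after = dplyr::last_col())
}
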