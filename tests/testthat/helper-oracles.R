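# Independent brute-force oracles for the graph metrics. These deliberately
# use different algorithms from the package (Floyd-Warshall instead of BFS,
# explicit triple/path enumeration instead of matrix products and Brandes,
# naive per-k pruning) so agreement is informative.

random_graph <- function(n, p) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  a + t(a)
}

floyd_warshall_ref <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

clustering_ref <- function(a) {
  n <- nrow(a)
  tri <- numeric(n)
  if (n >= 3) {
    for (i in 1:(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        for (k in (j + 1):n) {
          if (a[i, j] && a[j, k] && a[i, k]) {
            tri[c(i, j, k)] <- tri[c(i, j, k)] + 1
          }
        }
      }
    }
  }
  k <- rowSums(a)
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, 2 * tri / denom, 0)
  list(
    clustering = mean(ci),
    transitivity = if (sum(denom) > 0) sum(2 * tri) / sum(denom) else 0
  )
}

# All shortest paths between s and t, enumerated by walking neighbors that
# step closer to t (using the Floyd-Warshall distances).
enumerate_shortest_paths <- function(a, d, s, t) {
  if (!is.finite(d[s, t])) {
    return(list())
  }
  if (s == t) {
    return(list(s))
  }
  paths <- list()
  for (v in which(a[s, ] > 0)) {
    if (d[v, t] == d[s, t] - 1) {
      for (p in enumerate_shortest_paths(a, d, v, t)) {
        paths[[length(paths) + 1]] <- c(s, p)
      }
    }
  }
  paths
}

betweenness_ref <- function(a) {
  n <- nrow(a)
  d <- floyd_warshall_ref(a)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enumerate_shortest_paths(a, d, s, t)
      if (length(paths) == 0) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(paths)
      }
    }
  }
  bc
}

eccentricity_ref <- function(a) {
  d <- floyd_warshall_ref(a)
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    fin <- di[is.finite(di)]
    if (length(fin)) max(fin) else 0
  }, numeric(1))
}

assortativity_ref <- function(a) {
  k <- rowSums(a)
  xs <- c()
  ys <- c()
  n <- nrow(a)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && a[i, j] > 0) {
        xs <- c(xs, k[i])
        ys <- c(ys, k[j])
      }
    }
  }
  if (length(xs) == 0 || stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(NaN)
  }
  stats::cor(xs, ys)
}

# Coreness by naive per-k pruning: for each k, independently prune nodes of
# degree < k to a fixed point; a node's coreness is the largest k at which it
# survives.
kcore_ref <- function(a) {
  n <- nrow(a)
  core <- numeric(n)
  for (k in seq_len(n)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- as.vector(a %*% alive)
      drop <- alive & deg < k
      if (!any(drop)) break
      alive[drop] <- FALSE
    }
    if (!any(alive)) break
    core[alive] <- k
  }
  core
}

metric_vector_ref <- function(a) {
  d <- floyd_warshall_ref(a)
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  ct <- clustering_ref(a)
  ecc <- eccentricity_ref(a)
  c(
    clustering = ct$clustering,
    transitivity = ct$transitivity,
    efficiency = mean(ifelse(is.finite(off), 1 / off, 0)),
    char_path_length = if (length(fin)) mean(fin) else NaN,
    degree = mean(rowSums(a)),
    betweenness = mean(betweenness_ref(a)),
    eccentricity = mean(ecc),
    diameter = max(ecc, 0),
    assortativity = assortativity_ref(a),
    kcore = mean(kcore_ref(a))
  )
}

# Rank-then-Pearson Spearman oracle (midranks on ties).
spearman_ref <- function(x) {
  n <- nrow(x)
  out <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ri <- rank(x[i, ])
      rj <- rank(x[j, ])
      r <- if (stats::sd(ri) == 0 || stats::sd(rj) == 0) {
        NaN
      } else {
        sum((ri - mean(ri)) * (rj - mean(rj))) /
          sqrt(sum((ri - mean(ri))^2) * sum((rj - mean(rj))^2))
      }
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

expect_metric_equal <- function(x, y, tol = 1e-10) {
  for (m in names(x)) {
    if (is.nan(x[[m]]) || is.nan(y[[m]])) {
      testthat::expect_true(is.nan(x[[m]]) && is.nan(y[[m]]),
        label = paste0(m, ": NaN mismatch")
      )
    } else {
      testthat::expect_equal(unname(x[[m]]), unname(y[[m]]),
        tolerance = tol, label = m
      )
    }
  }
}
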