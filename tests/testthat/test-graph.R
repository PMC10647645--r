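path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

star_graph <- function(n) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}

test_that("BFS distances match hand counts and the Floyd-Warshall oracle", {
  p4 <- path_graph(4)
  expect_equal(bfs_distances(p4)[1, 4], 3)
  two_edges <- matrix(0, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- two_edges[3, 4] <- two_edges[4, 3] <- 1
  expect_equal(bfs_distances(two_edges)[1, 3], Inf)
  withr::with_seed(11, {
    for (i in 1:30) {
      a <- random_graph(12, runif(1, 0.1, 0.9))
      d <- bfs_distances(a)
      expect_equal(d, floyd_warshall_ref(a))
      expect_equal(d, t(d))
      expect_equal(diag(d), rep(0, 12))
    }
  })
})

test_that("complete-graph metrics take their closed-form values", {
  k4 <- 1 - diag(4)
  mv <- metric_vector(k4)
  expect_equal(mv[["clustering"]], 1)
  expect_equal(mv[["transitivity"]], 1)
  expect_equal(mv[["efficiency"]], 1)
  expect_equal(mv[["char_path_length"]], 1)
  expect_equal(mv[["degree"]], 3)
  expect_equal(mv[["betweenness"]], 0)
  expect_equal(mv[["eccentricity"]], 1)
  expect_equal(mv[["diameter"]], 1)
  expect_true(is.nan(mv[["assortativity"]])) # regular graph: zero variance
  expect_equal(mv[["kcore"]], 3)
})

test_that("path-graph metrics match hand enumeration", {
  p4 <- path_graph(4)
  mv <- metric_vector(p4)
  expect_equal(mv[["clustering"]], 0)
  expect_equal(mv[["transitivity"]], 0)
  expect_equal(mv[["char_path_length"]], 10 / 6) # distances 1,2,3,1,2,1
  expect_equal(mv[["diameter"]], 3)
  expect_equal(mv[["eccentricity"]], mean(c(3, 2, 2, 3)))
  expect_equal(betweenness_mean(p4, nodal = TRUE), c(0, 2, 2, 0))
  expect_equal(mv[["betweenness"]], 1)
})

test_that("disconnected-graph conventions hold", {
  # two disjoint K2: 4 of 12 ordered pairs reachable at distance 1
  two_k2 <- matrix(0, 4, 4)
  two_k2[1, 2] <- two_k2[2, 1] <- two_k2[3, 4] <- two_k2[4, 3] <- 1
  mv <- metric_vector(two_k2)
  expect_equal(mv[["efficiency"]], 1 / 3)
  expect_equal(mv[["char_path_length"]], 1)
  # isolated node next to a triangle: eccentricity 0 there, diameter 1
  iso_k3 <- rbind(cbind(1 - diag(3), 0), 0)
  mv2 <- metric_vector(iso_k3)
  expect_equal(eccentricity_and_diameter(bfs_distances(iso_k3))$diameter, 1)
  expect_equal(mv2[["eccentricity"]], mean(c(1, 1, 1, 0)))
  # empty graph
  mv3 <- metric_vector(matrix(0, 5, 5))
  expect_equal(mv3[["degree"]], 0)
  expect_equal(mv3[["efficiency"]], 0)
  expect_equal(mv3[["clustering"]], 0)
  expect_equal(mv3[["transitivity"]], 0)
  expect_equal(mv3[["kcore"]], 0)
  expect_true(is.nan(mv3[["char_path_length"]]))
  expect_true(is.nan(mv3[["assortativity"]]))
})

test_that("star graphs are perfectly disassortative", {
  expect_equal(degree_assortativity(star_graph(5)), -1)
  expect_true(is.nan(degree_assortativity(path_graph(2)))) # regular
  expect_true(is.nan(degree_assortativity(matrix(0, 3, 3)))) # no edges
})

test_that("coreness follows iterative pruning", {
  expect_equal(kcore_mean(1 - diag(4), nodal = TRUE), rep(3, 4))
  k4_pendant <- rbind(cbind(1 - diag(4), c(1, 0, 0, 0)), c(1, 0, 0, 0, 0))
  expect_equal(kcore_mean(k4_pendant, nodal = TRUE), c(3, 3, 3, 3, 1))
  expect_equal(kcore_mean(k4_pendant), 2.6)
})

test_that("all ten metrics agree with brute-force oracles on random graphs", {
  withr::with_seed(2024, {
    for (i in 1:60) {
      n <- sample(4:10, 1)
      a <- random_graph(n, runif(1, 0.1, 0.9))
      expect_metric_equal(metric_vector(a), metric_vector_ref(a))
    }
  })
})

test_that("metrics agree with igraph where conventions coincide", {
  skip_if_not_installed("igraph")
  withr::with_seed(77, {
    checked <- 0
    while (checked < 25) {
      n <- sample(5:12, 1)
      a <- random_graph(n, runif(1, 0.3, 0.8))
      g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
      if (!igraph::is_connected(g)) next # igraph conventions differ when split
      checked <- checked + 1
      mv <- metric_vector(a)
      expect_equal(mv[["clustering"]],
        mean(igraph::transitivity(g, type = "localundirected", isolates = "zero")),
        tolerance = 1e-10
      )
      expect_equal(mv[["transitivity"]], igraph::transitivity(g, type = "global"),
        tolerance = 1e-10
      )
      expect_equal(mv[["efficiency"]], igraph::global_efficiency(g),
        tolerance = 1e-10
      )
      expect_equal(mv[["char_path_length"]], igraph::mean_distance(g),
        tolerance = 1e-10
      )
      expect_equal(mv[["betweenness"]], mean(igraph::betweenness(g)),
        tolerance = 1e-10
      )
      expect_equal(mv[["diameter"]], igraph::diameter(g), tolerance = 1e-10)
      expect_equal(mv[["eccentricity"]], mean(igraph::eccentricity(g)),
        tolerance = 1e-10
      )
      expect_equal(mv[["kcore"]], mean(igraph::coreness(g)), tolerance = 1e-10)
      assort <- igraph::assortativity_degree(g)
      if (is.nan(mv[["assortativity"]])) {
        expect_true(is.nan(assort))
      } else {
        expect_equal(mv[["assortativity"]], assort, tolerance = 1e-10)
      }
    }
  })
})

test_that("metrics are invariant under node relabeling", {
  withr::with_seed(13, {
    for (i in 1:10) {
      a <- random_graph(9, 0.4)
      perm <- sample(9)
      expect_metric_equal(metric_vector(a), metric_vector(a[perm, perm]))
    }
  })
})

test_that("adding an edge never decreases efficiency, degree, or coreness", {
  withr::with_seed(21, {
    for (i in 1:15) {
      a <- random_graph(8, 0.3)
      absent <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
      if (nrow(absent) == 0) next
      e <- absent[sample(nrow(absent), 1), ]
      b <- a
      b[e[1], e[2]] <- b[e[2], e[1]] <- 1
      expect_gte(metric_vector(b)[["efficiency"]], metric_vector(a)[["efficiency"]])
      expect_gte(metric_vector(b)[["degree"]], metric_vector(a)[["degree"]])
      expect_true(all(kcore_mean(b, nodal = TRUE) >= kcore_mean(a, nodal = TRUE)))
    }
  })
})

test_that("metric bounds hold over random graphs of varying density", {
  withr::with_seed(31, {
    for (i in 1:100) {
      n <- sample(4:20, 1)
      a <- random_graph(n, runif(1, 0.1, 0.9))
      mv <- metric_vector(a)
      expect_true(mv[["clustering"]] >= 0 && mv[["clustering"]] <= 1)
      expect_true(mv[["transitivity"]] >= 0 && mv[["transitivity"]] <= 1)
      expect_true(mv[["efficiency"]] >= 0 && mv[["efficiency"]] <= 1)
      expect_true(mv[["degree"]] >= 0 && mv[["degree"]] <= n - 1)
      expect_true(mv[["kcore"]] >= 0 && mv[["kcore"]] <= n - 1)
      if (!is.nan(mv[["assortativity"]])) {
        expect_true(abs(mv[["assortativity"]]) <= 1 + 1e-12)
      }
      if (!is.nan(mv[["char_path_length"]])) {
        expect_gte(mv[["diameter"]], mv[["char_path_length"]])
        expect_gte(mv[["char_path_length"]], 1)
      }
    }
  })
})

test_that("invalid adjacencies and tiny networks are rejected", {
  expect_error(metric_vector(matrix(0, 1, 1)), "too small")
  bad <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(metric_vector(bad), "symmetric")
  expect_error(metric_vector(diag(2)), "diagonal")
  expect_error(metric_vector(matrix(0.5, 2, 2) - 0.5 * diag(2)), "0/1")
})

test_that("the bulk metric sweep agrees with per-graph computation", {
  withr::with_seed(55, {
    x <- matrix(rnorm(8 * 600), nrow = 8)
    rownames(x) <- sprintf("ROI%02d", 1:8)
    map <- split_network_map(8, c("N1", "N2"))
    cohort <- tibble::tibble(
      participant_id = "P1", group = "A", condition = "OT", epoch = 1L,
      sampling_rate_hz = 200, data = list(x)
    )
    fc_tbl <- compute_fc(cohort, 1000, 0.5)
    ths <- c(0.15, 0.3, 0.45)
    wm <- graph_metrics(fc_tbl, map, thresholds = ths)
    fc <- fc_tbl$fc[[1]]
    for (nw in c("N1", "N2", "brain")) {
      for (th in ths) {
        for (w in seq_len(dim(fc)[3])) {
          sub <- extract_network_subgraph(fc[, , w], map, nw)
          ref <- metric_vector(binarize(sub, th))
          got <- wm |>
            dplyr::filter(
              network == nw, abs(threshold - th) < 1e-12, window == w
            )
          expect_equal(
            setNames(got$value, got$metric)[names(ref)],
            ref,
            tolerance = 1e-12
          )
        }
      }
    }
  })
})
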