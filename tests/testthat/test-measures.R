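# Degree, eigenvector centrality, density, activation timelines.

test_that("degree reproduces the printed worked examples", {
  net <- build_session_network(worked_example_tokens(), "child2", "CS", 3L)
  deg <- node_degree(net)
  expect_equal(deg$degree[deg$node == "Qal.Present.Fm.Sg"], 4)
  expect_true(all(deg$degree[deg$class == "root"] == 1))
  f1 <- build_session_network(fig1_tokens(), "d", "CS", 1L)
  expect_equal(node_degree(f1)$degree[node_degree(f1)$node == "l-m-d"], 2)
})

test_that("degree equals the number of distinct partners (set oracle) and is order-invariant", {
  set.seed(17)
  for (i in 1:10) {
    toks <- random_stratum_tokens(25)
    net <- build_session_network(toks, "d", "CS", 1L)
    deg <- node_degree(net)
    # independent set-based oracle from the raw token table
    labels <- pattern_label(toks$binyan, toks$temporal, toks$person,
                            toks$number, toks$gender)
    for (r in unique(toks$root)) {
      expect_equal(deg$degree[deg$node == r],
                   length(unique(labels[toks$root == r])))
    }
    shuffled <- build_session_network(toks[sample(nrow(toks)), ], "d", "CS", 1L)
    expect_equal(node_degree(shuffled), deg)
  }
  empty <- build_session_network(fig1_tokens(), "d", "CDS", 1L)
  expect_true(isTRUE(attr(node_degree(empty), "undefined")))
})

test_that("power iteration matches a dense eigendecomposition oracle", {
  # connected graphs only: with tied components the leading eigenvector is
  # not unique and no pointwise oracle comparison is defined
  set.seed(23)
  for (i in 1:50) {
    net <- random_bipartite_network(n_roots = sample(2:9, 1),
                                    n_patterns = sample(2:9, 1),
                                    connected = TRUE)
    res <- eigenvector_centrality(net)
    A <- adjacency_matrix(net, full = TRUE)
    eig <- eigen(A, symmetric = TRUE)
    v <- abs(eig$vectors[, 1])
    v <- v / sqrt(sum(v^2))
    expect_lt(max(abs(res$centrality$centrality - v)), 1e-8)
    expect_lt(abs(res$lambda - eig$values[1]), 1e-8)
    # the defining residual bound holds for every reported result
    expect_lt(max(abs(A %*% res$centrality$centrality -
                        res$lambda * res$centrality$centrality)), res$tol)
  }
})

test_that("star and single-link closed forms are recovered", {
  # one pattern linked to 3 roots: center 1/sqrt(2), leaves 1/sqrt(6),
  # lambda = sqrt(3)
  star <- worked_example_tokens()[1:3, ]
  res <- eigenvector_centrality(build_session_network(star, "child2", "CS", 3L))
  cen <- res$centrality
  expect_equal(unname(cen$centrality[cen$class == "pattern"]), 1 / sqrt(2),
               tolerance = 1e-9)
  expect_equal(unname(cen$centrality[cen$class == "root"]),
               rep(1 / sqrt(6), 3), tolerance = 1e-9)
  expect_equal(res$lambda, sqrt(3), tolerance = 1e-9)
  # a single link: both endpoints 1/sqrt(2)
  single <- build_session_network(fig1_tokens()[1, ], "d", "CS", 1L)
  res1 <- eigenvector_centrality(single)
  expect_equal(unname(res1$centrality$centrality), rep(1 / sqrt(2), 2),
               tolerance = 1e-9)
  empty <- build_session_network(fig1_tokens(), "d", "CDS", 1L)
  expect_error(eigenvector_centrality(empty), "no links")
})

test_that("centrality agrees with the igraph implementation on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(41)
  for (i in 1:10) {
    net <- random_bipartite_network(connected = TRUE)
    res <- eigenvector_centrality(net)
    g <- igraph::graph_from_biadjacency_matrix(
      adjacency_matrix(net, full = FALSE))
    ig <- igraph::eigen_centrality(g)$vector
    ig <- ig[c(net$root_nodes, net$pattern_nodes)]
    ig <- ig / sqrt(sum(ig^2))
    expect_lt(max(abs(res$centrality$centrality - ig)), 1e-6)
  }
})

test_that("density matches the printed formula on fixtures and stays in range", {
  # n=4, m=3 -> 3 / (4*3/2) = 0.5
  toks <- worked_example_tokens()[1:3, ]
  net <- build_session_network(toks, "child2", "CS", 3L)
  expect_equal(network_density(net), 0.5)
  # the two-wordform example: 2 / (3*2/2) = 2/3 printed-formula,
  # 1.0 with the bipartite maximum
  f1 <- build_session_network(fig1_tokens(), "d", "CS", 1L)
  expect_equal(network_density(f1), 2 / 3)
  expect_equal(network_density(f1, "bipartite"), 1)
  # a single link (n=2): density exactly 1; n>=3: always <= 1 even with the
  # unipartite denominator (bipartite m <= n^2/4 < n(n-1)/2)
  single <- build_session_network(fig1_tokens()[1, ], "d", "CS", 1L)
  expect_equal(network_density(single), 1)
  set.seed(53)
  for (i in 1:20) {
    net <- random_bipartite_network(p_edge = 0.9)
    expect_lte(network_density(net), 1)
    expect_gt(network_density(net), 0)
  }
  empty <- build_session_network(fig1_tokens(), "d", "CDS", 1L)
  expect_true(is.na(network_density(empty)))
})

test_that("activation spans count runs and gaps as intermittency statistics", {
  # a node active in sessions 6 and 8 has 2 runs and 1 gap of length 1
  toks <- dplyr::bind_rows(
    dplyr::mutate(fig1_tokens(), session_index = 5L, age_days = 650L),
    dplyr::mutate(fig1_tokens()[1, ], session_index = 6L, age_days = 653L),
    dplyr::mutate(fig1_tokens()[1, ], session_index = 7L, age_days = 656L,
                  temporal = "Present", person = NA),
    dplyr::mutate(fig1_tokens()[1, ], session_index = 8L, age_days = 659L))
  series <- build_network_series(toks, "d")
  act <- activation_timeline(series, "CS")
  # Piel.Past.3.Masc.Sg is active at 5, 6, 8: two runs, one gap of 1
  sp <- dplyr::filter(act$spans, node == "Piel.Past.3.Masc.Sg")
  expect_equal(sp$n_runs, 2)
  expect_equal(sp$n_gaps, 1)
  expect_equal(sp$mean_gap_length, 1)
  expect_equal(sp$onset, 5L)
  expect_equal(sp$offset, 8L)
  # the root is active every session: one run, no gaps
  rt <- dplyr::filter(act$spans, node == "l-m-d")
  expect_equal(rt$n_runs, 1)
  expect_equal(rt$n_gaps, 0)
  # activity matrix agrees with network membership
  a6 <- dplyr::filter(act$activity, node == "Piel.Future.3.Masc.Sg")
  expect_equal(a6$active[order(a6$session_index)], c(TRUE, FALSE, FALSE, FALSE))
})

test_that("the measure table is one node row per active node plus one density row per stratum", {
  set.seed(67)
  toks <- dplyr::bind_rows(
    random_stratum_tokens(12, session = 1L), random_stratum_tokens(12, session = 2L),
    random_stratum_tokens(12, session = 1L, speaker = "CDS"),
    random_stratum_tokens(12, session = 2L, speaker = "CDS"))
  series <- build_network_series(toks, "d")
  mt <- measure_table(series)
  expect_equal(sum(mt$level == "network"), 4) # 2 sessions x 2 speakers
  n_active <- sum(purrr::map_int(series$networks, ~ .x$n))
  expect_equal(sum(mt$level == "node"), n_active)
  # referential integrity: every node row has a matching density row
  key <- function(d) paste(d$session_index, d$speaker)
  expect_true(all(key(mt[mt$level == "node", ]) %in%
                    key(mt[mt$level == "network", ])))
  # measures invariant under input row permutation
  series2 <- build_network_series(toks[sample(nrow(toks)), ], "d")
  expect_equal(measure_table(series2), mt)
  # node_level = FALSE keeps only the density rows
  expect_equal(nrow(measure_table(series, node_level = FALSE)), 4)
})
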