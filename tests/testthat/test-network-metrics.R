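test_that("density matches definition and brute force on all fixtures", {
  expect_equal(net_density(make_net(5, combn(5, 2, simplify = FALSE))), 1.0)
  expect_equal(net_density(make_net(4, list(c(1, 2), c(2, 3), c(3, 4)))), 0.5)
  expect_error(net_density(make_net(1, list())), "fewer than 2")
  for (g in fixture_graphs()) expect_equal(net_density(g), bf_density(g))
})

test_that("mean distance equals the all-pairs shortest-path oracle", {
  expect_equal(net_mean_distance(make_net(3, list(c(1, 2), c(2, 3)))), 4 / 3)
  expect_equal(net_mean_distance(make_net(4, combn(4, 2, simplify = FALSE))), 1)
  expect_error(net_mean_distance(make_net(3, list())), "no edges")
  for (g in fixture_graphs()) {
    if (nrow(g$edges) == 0) next
    expect_equal(net_mean_distance(g), bf_mean_distance(g), tolerance = 1e-12)
  }
})

test_that("degree centrality equals adjacency row sums", {
  star <- make_net(6, lapply(2:6, function(i) c(1, i)))
  d <- degree_centrality(star)
  expect_identical(d[practice_id == "v01", degree], 5L)
  expect_equal(d[practice_id == "v01", degree_normalized], 1.0)
  iso <- make_net(3, list(c(1, 2)))
  expect_identical(degree_centrality(iso)[practice_id == "v03", degree], 0L)
  for (g in fixture_graphs()) {
    A <- adjacency_of(g)
    d <- degree_centrality(g)
    expect_equal(d$degree[match(rownames(A), d$practice_id)],
                 unname(rowSums(A)))
  }
})

test_that("eigenvector centrality matches the dominant eigenvector", {
  cm <- eigenvector_centrality(make_net(4, combn(4, 2, simplify = FALSE)))
  expect_equal(cm$ev_centrality, rep(1, 4), tolerance = 1e-6)
  p3 <- eigenvector_centrality(make_net(3, list(c(1, 2), c(2, 3))))
  ## 3x3 eigenproblem by hand: center = 1, leaves = 1/sqrt(2)
  expect_equal(p3[practice_id == "v02", ev_centrality], 1, tolerance = 1e-6)
  expect_equal(p3[practice_id == "v01", ev_centrality], 1 / sqrt(2),
               tolerance = 1e-6)
  for (g in fixture_graphs()) {
    if (nrow(g$edges) == 0) next
    ## a (near-)tied dominant eigenvalue makes the dominant eigenvector
    ## non-unique (e.g. isomorphic components); skip those graphs
    ev <- eigen(adjacency_of(g), symmetric = TRUE, only.values = TRUE)$values
    if (length(ev) > 1 && ev[1] - ev[2] < 1e-6) next
    got <- eigenvector_centrality(g)
    oracle <- bf_eigenvector(g)
    expect_equal(got$ev_centrality, unname(oracle[got$practice_id]),
                 tolerance = 1e-5)
  }
  ## isomorphism invariance: relabelling nodes permutes scores
  g <- random_net(7, 0.5, seed = 101)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  g2 <- make_net(7, lapply(seq_len(nrow(g$edges)), function(r) {
    c(perm[match(g$edges$node_a[r], g$nodes$practice_id)],
      perm[match(g$edges$node_b[r], g$nodes$practice_id)])
  }))
  e1 <- eigenvector_centrality(g)
  e2 <- eigenvector_centrality(g2)
  expect_equal(e2$ev_centrality[match(sprintf("v%02d", perm), e2$practice_id)],
               e1$ev_centrality[match(g$nodes$practice_id, e1$practice_id)],
               tolerance = 1e-6)
})

test_that("betweenness centrality equals exhaustive path enumeration", {
  star <- betweenness_centrality(make_net(6, lapply(2:6, function(i) c(1, i))))
  expect_equal(star[practice_id == "v01", be_centrality], 1.0)
  expect_true(all(star[practice_id != "v01", be_centrality] == 0))
  cyc <- betweenness_centrality(make_net(4, list(c(1, 2), c(2, 3),
                                                 c(3, 4), c(4, 1))))
  expect_equal(var(cyc$be_centrality), 0)
  for (g in fixture_graphs()) {
    if (nrow(g$nodes) < 3) next
    got <- betweenness_centrality(g)
    oracle <- bf_betweenness(g)
    expect_equal(got$be_centrality, unname(oracle[got$practice_id]),
                 tolerance = 1e-10)
  }
})

test_that("percentage ranking follows the average-rank tie convention", {
  expect_equal(percentile_rank(c(10, 20, 30)), c(1 / 3, 2 / 3, 1))
  expect_equal(percentile_rank(rep(5, 4)), rep(5 / 8, 4))  # (n+1)/(2n)
  set.seed(31)
  for (i in 1:10) {
    v <- sample(1:6, 12, TRUE)
    r <- percentile_rank(v)
    expect_equal(r, rank(v, ties.method = "average") / 12)
    expect_true(all(r > 0 & r <= 1))
    ## strict monotonicity across distinct values
    for (a in 1:11) for (b in (a + 1):12) {
      if (v[a] > v[b]) expect_gt(r[a], r[b])
    }
  }
})

test_that("average percentage change reproduces hand arithmetic", {
  expect_equal(average_percentage_change(c(100, 110, 99)), 0)
  expect_equal(average_percentage_change(rep(7, 5)), 0)
  pats <- regional_summary_reference()$n_patients
  expect_equal(round(average_percentage_change(pats), 2), 0.97)
  expect_error(average_percentage_change(c(3, 0, 2)), "zero")
  expect_error(average_percentage_change(5), "at least 2")
})

test_that("transformed mean distance flags degenerate nulls and separates structure", {
  ## complete graph: every G(n,m) replicate is the same graph
  expect_error(transformed_mean_distance(
    make_net(5, combn(5, 2, simplify = FALSE)), 50, seed = 1),
    "degenerate")
  ## a chain is farther from the null mean than a random graph of equal size
  chain <- make_net(12, lapply(1:11, function(i) c(i, i + 1)))
  set.seed(88)
  rnd <- NULL
  repeat {
    cand <- random_net(12, 11 / choose(12, 2), seed = sample.int(1e6, 1))
    if (nrow(cand$edges) == 11) { rnd <- cand; break }
  }
  z_chain <- transformed_mean_distance(chain, 300, seed = 2)$z
  z_rnd <- transformed_mean_distance(rnd, 300, seed = 2)$z
  expect_gt(z_chain, z_rnd)
  ## deterministic given seed
  expect_identical(transformed_mean_distance(chain, 100, seed = 9)$z,
                   transformed_mean_distance(chain, 100, seed = 9)$z)
})

test_that("network summary composes the per-year metrics", {
  b <- cached("tiny_bundle", simulate_claims(tiny_cfg(seed = 5L), seed = 5L))
  nets <- cached("tiny_nets",
                 build_networks(b$claims, b$practices, b$patients,
                                filter_config()))
  s <- cached("tiny_summary", summarize_networks(nets, 100L, seed = 3L))
  expect_identical(nrow(s$per_year), 8L)
  for (k in c(2L, 7L)) {
    expect_equal(s$per_year$density[k], net_density(nets[[k]]))
    expect_equal(s$per_year$mean_distance[k], net_mean_distance(nets[[k]]))
  }
  expect_equal(unname(s$average_change["n_patients"]),
               average_percentage_change(s$per_year$n_patients))
  ## adding an edge to a connected graph: density up, mean distance not up
  cyc8 <- lapply(1:8, function(i) c(i, i %% 8 + 1))
  g <- make_net(8, cyc8)
  g2 <- make_net(8, c(cyc8, list(c(1, 5))))
  expect_gt(net_density(g2), net_density(g))
  expect_lte(net_mean_distance(g2), net_mean_distance(g))
})
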