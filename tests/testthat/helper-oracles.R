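library(data.table)

## Independent brute-force oracles and small fixture builders.
## Everything here deliberately avoids the package's own computation paths
## (and igraph), so agreement is a genuine cross-check.

## Build a coop_yearly_network from an edge list over nodes 1..n
make_net <- function(n, edges, year = 2004, shared = NULL) {
  ids <- sprintf("v%02d", seq_len(n))
  if (length(edges) == 0L) {
    ed <- data.table::data.table(node_a = character(), node_b = character(),
                                 shared_count = integer())
  } else {
    em <- do.call(rbind, edges)
    a <- pmin(em[, 1], em[, 2]); b <- pmax(em[, 1], em[, 2])
    ed <- data.table::data.table(node_a = ids[a], node_b = ids[b],
                                 shared_count = shared %||% rep(9L, length(a)))
    data.table::setorder(ed, node_a, node_b)
  }
  structure(list(year = year,
                 nodes = data.table::data.table(practice_id = ids),
                 edges = ed, threshold_used = 9L),
            class = "coop_yearly_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## random undirected graph fixture (edge probability p), seeded
random_net <- function(n, p, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  make_net(n, lapply(which(keep), function(i) pairs[i, ]))
}

adjacency_of <- function(net) {
  ids <- net$nodes$practice_id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    ia <- match(net$edges$node_a, ids); ib <- match(net$edges$node_b, ids)
    A[cbind(ia, ib)] <- 1; A[cbind(ib, ia)] <- 1
  }
  A
}

bf_density <- function(net) {
  A <- adjacency_of(net)
  n <- nrow(A)
  sum(A[upper.tri(A)]) / choose(n, 2)
}

## Floyd-Warshall all-pairs shortest paths
bf_dist_matrix <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

bf_mean_distance <- function(net) {
  D <- bf_dist_matrix(adjacency_of(net))
  v <- D[upper.tri(D)]
  mean(v[is.finite(v)])
}

## exact betweenness by enumerating every shortest path (DFS on the distance
## matrix), even split over ties, normalized by (n-1)(n-2)/2
bf_betweenness <- function(net) {
  A <- adjacency_of(net)
  n <- nrow(A)
  D <- bf_dist_matrix(A)
  score <- numeric(n)
  all_paths <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (w in which(A[, t] > 0)) {
      if (is.finite(D[s, w]) && D[s, w] == D[s, t] - 1) {
        for (pth in all_paths(s, w)) out <- c(out, list(c(pth, t)))
      }
    }
    out
  }
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    if (!is.finite(D[s, t])) next
    paths <- all_paths(s, t)
    for (pth in paths) {
      inner <- setdiff(pth, c(s, t))
      score[inner] <- score[inner] + 1 / length(paths)
    }
  }
  stats::setNames(score / ((n - 1) * (n - 2) / 2), rownames(A))
}

## dominant eigenvector of the adjacency, unit maximum, via base eigen()
bf_eigenvector <- function(net) {
  A <- adjacency_of(net)
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- abs(v)
  stats::setNames(v / max(v), rownames(A))
}

## brute-force shared-patient count by scanning all pairs and patients
bf_shared_counts <- function(claims, year, ids) {
  sub <- unique(claims[claims$year == year &
                         claims$practice_id %in% ids,
                       c("patient_id", "practice_id")])
  n <- length(ids)
  M <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    pi <- sub$patient_id[sub$practice_id == ids[i]]
    pj <- sub$patient_id[sub$practice_id == ids[j]]
    M[i, j] <- length(intersect(pi, pj))
  }
  M
}

## small hand-rolled claims table builder
claims_rows <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(patient_id = r[[1]], practice_id = r[[2]],
                           year = as.integer(r[[3]]),
                           visit_type = if (length(r) > 3) r[[4]] else "routine",
                           specialty = if (length(r) > 4) r[[5]] else "GP")
  }))
}

## shared tiny simulated bundle + pipeline result, computed once per test run
tiny_cfg <- function(...) {
  test_scale_config(n_practices_initial = 40L, n_patients_initial = 1200L,
                    n_years = 8L, community_count = 5L, ...)
}

## fixture suite: named small graphs plus random graphs up to 8 nodes
fixture_graphs <- function() {
  gs <- list(
    complete5 = make_net(5, combn(5, 2, simplify = FALSE)),
    path3 = make_net(3, list(c(1, 2), c(2, 3))),
    star6 = make_net(6, lapply(2:6, function(i) c(1, i))),
    cycle4 = make_net(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))),
    triangle_plus_edge = make_net(5, list(c(1, 2), c(2, 3), c(1, 3),
                                          c(4, 5))),
    lollipop = make_net(6, list(c(1, 2), c(2, 3), c(1, 3), c(3, 4),
                                c(4, 5), c(5, 6)))
  )
  for (s in 1:24) {
    set.seed(s)
    n <- sample(4:8, 1)
    gs[[sprintf("random_%02d", s)]] <- random_net(n, runif(1, 0.25, 0.8),
                                                  seed = 1000 + s)
  }
  gs
}

.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}
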