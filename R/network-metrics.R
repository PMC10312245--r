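## Cooperation indicators.
##
## Two network-level indicators (density; mean shortest-path distance, plus
## its random-graph normalized transform) and three node-level centralities
## (degree, eigenvector, betweenness) with within-year percentage rankings.
## Standard graph quantities are computed with igraph; the transformed
## mean-distance statistic is this package's own construction on top of a
## G(n, m) null.

#' Network density
#'
#' Realized edges divided by possible edges, `|E| / (n(n-1)/2)`. A measure of
#' cohesion: denser networks carry more cooperation relationships per
#' practice pair.
#'
#' @param net A `coop_yearly_network`.
#' @return Proportion in `[0, 1]`.
#' @export
net_density <- function(net) {
  stopifnot(inherits(net, "coop_yearly_network"))
  n <- nrow(net$nodes)
  if (n < 2L) stop("density undefined for fewer than 2 nodes", call. = FALSE)
  nrow(net$edges) / (n * (n - 1) / 2)
}

#' Mean shortest-path distance
#'
#' Average number of edges on the shortest path over all unordered connected
#' node pairs. Pairs in different components are excluded from the average
#' (the common convention for claims networks, which keeps isolated nodes
#' from destroying the statistic).
#'
#' @param net A `coop_yearly_network`.
#' @return Mean distance in edge units (>= 1 when at least one edge exists).
#' @export
net_mean_distance <- function(net) {
  stopifnot(inherits(net, "coop_yearly_network"))
  if (nrow(net$edges) == 0L) {
    stop("mean distance undefined: network has no edges", call. = FALSE)
  }
  igraph::mean_distance(as_igraph(net), directed = FALSE, unconnected = TRUE)
}

#' Transformed mean distance: z-score against a G(n, m) null
#'
#' Expresses the observed mean distance in standard deviations from the mean
#' distance of uniform random graphs with the same number of nodes and the
#' same number of edges (hence the same density). Because density mechanically
#' drives mean distance, this transform tracks changes in path efficiency
#' that are *not* explained by density.
#'
#' @param net A `coop_yearly_network` with at least one edge.
#' @param n_replicates Number of random graphs (default 5000; use fewer, e.g.
#'   200, for exploratory runs).
#' @param seed Integer seed making the null reproducible.
#' @return List of class `coop_tmd` with `z`
#'   (`(observed - null_mean) / null_sd`), `observed`, and `null`
#'   (`n_replicates`, `null_mean`, `null_sd`, `seed`).
#' @export
transformed_mean_distance <- function(net, n_replicates = 5000L, seed = 1L) {
  stopifnot(inherits(net, "coop_yearly_network"))
  if (n_replicates < 2L) stop("`n_replicates` must be >= 2", call. = FALSE)
  if (nrow(net$edges) == 0L) {
    stop("transformed mean distance undefined: network has no edges",
         call. = FALSE)
  }
  n <- nrow(net$nodes)
  m <- nrow(net$edges)
  obs <- net_mean_distance(net)
  null_md <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      g <- igraph::sample_gnm(n, m, directed = FALSE)
      igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    }, numeric(1))
  })
  mu <- mean(null_md)
  sdev <- sd(null_md)
  if (sdev == 0) {
    stop("degenerate null: all ", n_replicates, " random graphs have mean ",
         "distance ", mu, " (graph at or near complete?)", call. = FALSE)
  }
  structure(list(z = (obs - mu) / sdev, observed = obs,
                 null = list(n_replicates = as.integer(n_replicates),
                             null_mean = mu, null_sd = sdev,
                             seed = as.integer(seed))),
            class = "coop_tmd")
}

#' @export
print.coop_tmd <- function(x, ...) {
  cat(sprintf("Transformed mean distance: z = %.3f (observed %.4f; null %.4f +/- %.4f, %d replicates)\n",
              x$z, x$observed, x$null$null_mean, x$null$null_sd,
              x$null$n_replicates))
  invisible(x)
}

#' Random G(n, m) reference network
#'
#' Draws a uniform random graph with `n` nodes and `m` edges and wraps it as
#' a yearly network object, mainly for calibration checks of the
#' transformed-mean-distance statistic against its own null.
#'
#' @param n,m Node and edge counts.
#' @param seed Integer seed.
#' @return A `coop_yearly_network`.
#' @export
gnm_network <- function(n, m, seed = 1L) {
  g <- with_seed(seed, igraph::sample_gnm(n, m, directed = FALSE))
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- sprintf("v%03d", seq_len(n))
  edges <- data.table(node_a = ids[pmin(el[, 1], el[, 2])],
                      node_b = ids[pmax(el[, 1], el[, 2])],
                      shared_count = NA_integer_)
  setorder(edges, node_a, node_b)
  structure(list(year = NA_integer_,
                 nodes = data.table(practice_id = ids),
                 edges = edges, threshold_used = NA_integer_),
            class = "coop_yearly_network")
}

#' Degree centrality
#'
#' Number of cooperation relationships of each practice, plus the normalized
#' version degree / (n - 1) comparable across years with different network
#' sizes.
#'
#' @param net A `coop_yearly_network` with >= 2 nodes.
#' @return `data.table` with `practice_id`, `degree`, `degree_normalized`.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "coop_yearly_network"))
  n <- nrow(net$nodes)
  if (n < 2L) stop("degree centrality needs >= 2 nodes", call. = FALSE)
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  data.table(practice_id = igraph::V(g)$name,
             degree = as.integer(deg),
             degree_normalized = deg / (n - 1))
}

#' Eigenvector centrality
#'
#' Scores from the dominant eigenvector of the binary adjacency matrix,
#' normalized to unit maximum. A node is central when its neighbours are
#' central: connections to highly connected practices are worth more than
#' connections to peripheral ones. On disconnected graphs the whole-graph
#' dominant eigenvector is used, so nodes outside the dominant component get
#' (near-)zero scores and rank low; scores are only comparable within one
#' network, which is why downstream analysis uses the yearly
#' [percentile_rank()].
#'
#' @param net A `coop_yearly_network` with at least one edge.
#' @param tol Power-iteration convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   iteration count.
#' @return `data.table` with `practice_id`, `ev_centrality`.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(net, "coop_yearly_network"))
  if (nrow(net$edges) == 0L) {
    stop("eigenvector centrality undefined: network has no edges", call. = FALSE)
  }
  g <- as_igraph(net)
  ## fixed seed: the ARPACK start vector is random, and estimation must be
  ## deterministic for a fixed network
  res <- with_seed(0L, igraph::eigen_centrality(
    g, directed = FALSE,
    options = list(maxiter = as.integer(max_iter), tol = tol)))
  sc <- unname(res$vector)
  ## scores within numerical noise of zero (nodes outside the dominant
  ## component) are set to exactly zero so they tie in the yearly ranking
  sc[sc < 1e-9] <- 0
  data.table(practice_id = igraph::V(g)$name, ev_centrality = sc)
}

#' Betweenness centrality
#'
#' Proportion of shortest paths between other node pairs passing through the
#' node, with even splitting across tied shortest paths, normalized by the
#' number of pairs `(n-1)(n-2)/2`. Indicates a practice's importance as a
#' relay of information between otherwise distant practices.
#'
#' @param net A `coop_yearly_network` with >= 3 nodes.
#' @return `data.table` with `practice_id`, `be_centrality` (in `[0, 1]`).
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "coop_yearly_network"))
  n <- nrow(net$nodes)
  if (n < 3L) stop("betweenness centrality needs >= 3 nodes", call. = FALSE)
  g <- as_igraph(net)
  be <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  data.table(practice_id = igraph::V(g)$name,
             be_centrality = unname(be) / ((n - 1) * (n - 2) / 2))
}

#' Within-year percentage ranking
#'
#' Transforms arbitrary-scale centrality scores into percentile positions
#' comparable across years: ascending ranks (ties get the average rank)
#' divided by the number of nodes, so ranks live in `(0, 1]` and the
#' (untied) largest score maps to 1.
#'
#' @param values Numeric scores of one year's nodes.
#' @return Numeric vector of ranks in `(0, 1]`.
#' @export
percentile_rank <- function(values) {
  if (length(values) < 1L) stop("`values` must be non-empty", call. = FALSE)
  rank(values, ties.method = "average") / length(values)
}

#' Node metrics table for all years
#'
#' Computes degree, eigenvector and betweenness centrality per practice-year
#' together with the within-year percentage rankings `ev_rank` and `be_rank`.
#' Edgeless or too-small years yield zero centralities and uniform tied
#' ranks.
#'
#' @param nets Result of [build_networks()].
#' @return `data.table` with columns `practice_id`, `year`, `degree`,
#'   `degree_normalized`, `ev_centrality`, `ev_rank`, `be_centrality`,
#'   `be_rank`.
#' @export
node_metrics <- function(nets) {
  rows <- lapply(nets, function(net) {
    n <- nrow(net$nodes)
    if (n == 0L) return(NULL)
    out <- data.table(practice_id = net$nodes$practice_id, year = net$year)
    if (n >= 2L) {
      out <- degree_centrality(net)[out, on = "practice_id"]
    } else {
      out[, `:=`(degree = 0L, degree_normalized = 0)]
    }
    if (nrow(net$edges) > 0L) {
      out <- eigenvector_centrality(net)[out, on = "practice_id"]
    } else {
      out[, ev_centrality := 0]
    }
    if (n >= 3L) {
      out <- betweenness_centrality(net)[out, on = "practice_id"]
    } else {
      out[, be_centrality := 0]
    }
    out[, ev_rank := percentile_rank(ev_centrality)]
    out[, be_rank := percentile_rank(be_centrality)]
    out
  })
  res <- rbindlist(rows, use.names = TRUE)
  setcolorder(res, c("practice_id", "year", "degree", "degree_normalized",
                     "ev_centrality", "ev_rank", "be_centrality", "be_rank"))
  setorder(res, year, practice_id)
  res[]
}

#' Average year-over-year percentage change
#'
#' Arithmetic mean of consecutive percentage changes
#' `100 * (x[t+1] / x[t] - 1)`, the summary used for the network-level
#' indicators.
#'
#' @param series Numeric vector of yearly values (>= 2, all nonzero).
#' @return Percent (e.g. `0.97` for +0.97% per year on average).
#' @export
average_percentage_change <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 2L) {
    stop("`series` needs at least 2 values", call. = FALSE)
  }
  if (any(series[-length(series)] == 0)) {
    stop("percentage change undefined: zero value in series", call. = FALSE)
  }
  mean(100 * (series[-1L] / series[-length(series)] - 1))
}

#' Network-level summary across years
#'
#' One row per year with density, mean distance, the transformed mean
#' distance (z against a G(n, m) null), node counts, integrated-practice
#' counts and distinct patient counts; plus the average-percentage-change
#' summary row across years.
#'
#' @param nets Result of [build_networks()].
#' @param n_replicates Null replicates per year for the transformed mean
#'   distance (default 5000; the test-scale default is 200).
#' @param seed Integer seed for the null draws (per-year sub-seeds derived
#'   from it).
#' @return List of class `coop_network_summary`: `per_year` (data.table with
#'   columns `year`, `density`, `mean_distance`, `transformed_mean_distance`,
#'   `n_nodes`, `n_ip_nodes`, `n_patients`) and `average_change` (named
#'   vector of average percentage changes).
#' @export
summarize_networks <- function(nets, n_replicates = 5000L, seed = 1L) {
  if (length(nets) < 2L) stop("need >= 2 yearly networks", call. = FALSE)
  rows <- lapply(seq_along(nets), function(k) {
    net <- nets[[k]]
    n <- nrow(net$nodes)
    has_ip <- "is_ip" %in% names(net$nodes) && !all(is.na(net$nodes$is_ip))
    tmd <- if (nrow(net$edges) > 0L) {
      transformed_mean_distance(net, n_replicates, seed = seed + k)$z
    } else NA_real_
    data.table(
      year = net$year,
      density = if (n >= 2L) net_density(net) else NA_real_,
      mean_distance = if (nrow(net$edges) > 0L) net_mean_distance(net) else NA_real_,
      transformed_mean_distance = tmd,
      n_nodes = n,
      n_ip_nodes = if (has_ip) sum(net$nodes$is_ip, na.rm = TRUE) else NA_integer_,
      n_patients = if (!is.null(net$n_patients_total)) {
        as.integer(net$n_patients_total)
      } else NA_integer_
    )
  })
  per_year <- rbindlist(rows)
  setorder(per_year, year)
  cols <- c("density", "mean_distance", "transformed_mean_distance",
            "n_nodes", "n_ip_nodes", "n_patients")
  avg <- vapply(cols, function(cl) {
    v <- per_year[[cl]]
    if (anyNA(v) || any(head(v, -1L) == 0)) NA_real_
    else average_percentage_change(v)
  }, numeric(1))
  structure(list(per_year = per_year, average_change = avg,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "coop_network_summary")
}

#' @export
print.coop_network_summary <- function(x, digits = 4, ...) {
  cat("Network-level cooperation indicators\n")
  print(x$per_year, digits = digits)
  cat("\nAverage percentage change (% per year):\n")
  print(round(x$average_change, 2))
  invisible(x)
}
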