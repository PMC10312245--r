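## Claims -> yearly cooperation networks.
##
## The construction follows the shared-patient approach: practices are nodes,
## and an edge connects two practices whose retained claims show at least
## `shared_patient_threshold` distinct patients in common within one calendar
## year. Emergency visits and visits to specialties with little or no role in
## care coordination are removed first; practices below a minimum yearly
## patient count are dropped as inactive; sharing is counted among the
## surviving practices only.

#' Filtering and thresholding configuration
#'
#' @param excluded_specialties Specialty labels whose visits are removed
#'   before network construction. Defaults to Anaesthesiology, Radiology and
#'   Neuropathology, which have little physician-patient contact or no role
#'   in care coordination. Labels not present in the data are ignored.
#' @param exclude_emergency Drop emergency visits before counting.
#' @param min_patients_per_year Minimum number of distinct patients a
#'   practice must serve in a year to count as active (default 30).
#' @param shared_patient_threshold Minimum number of distinct shared patients
#'   for an edge (default 9, the point where shared-patient counts reliably
#'   indicate a real information-sharing relationship).
#' @return A list of class `coop_filter_config`.
#' @export
filter_config <- function(excluded_specialties = c("Anaesthesiology",
                                                   "Radiology",
                                                   "Neuropathology"),
                          exclude_emergency = TRUE,
                          min_patients_per_year = 30L,
                          shared_patient_threshold = 9L) {
  if (shared_patient_threshold < 1L) {
    stop("`shared_patient_threshold` must be >= 1", call. = FALSE)
  }
  if (min_patients_per_year < 0L) {
    stop("`min_patients_per_year` must be >= 0", call. = FALSE)
  }
  structure(list(excluded_specialties = as.character(excluded_specialties),
                 exclude_emergency = isTRUE(exclude_emergency),
                 min_patients_per_year = as.integer(min_patients_per_year),
                 shared_patient_threshold = as.integer(shared_patient_threshold)),
            class = "coop_filter_config")
}

assert_claims <- function(claims) {
  req <- c("patient_id", "practice_id", "year")
  if (!all(req %in% names(claims))) {
    stop("claims table must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  invisible(claims)
}

#' Remove emergency and excluded-specialty visits
#'
#' @param claims Claims table (`patient_id`, `practice_id`, `year`, and
#'   optionally `visit_type`, `specialty`).
#' @param cfg A [filter_config()].
#' @return A new claims `data.table` with the excluded rows removed; row
#'   order of retained rows is preserved and the input is not modified.
#' @export
filter_claims <- function(claims, cfg = filter_config()) {
  assert_claims(claims)
  claims <- as.data.table(claims)
  keep <- rep(TRUE, nrow(claims))
  if (cfg$exclude_emergency && "visit_type" %in% names(claims)) {
    keep <- keep & claims$visit_type != "emergency"
  }
  if (length(cfg$excluded_specialties) && "specialty" %in% names(claims)) {
    keep <- keep & !(claims$specialty %in% cfg$excluded_specialties)
  }
  claims[keep]
}

#' Practices active in a year
#'
#' A practice is active when it served at least `min_patients_per_year`
#' distinct patients in that calendar year (visit multiplicity does not
#' count). Expects claims already passed through [filter_claims()].
#'
#' @param claims Filtered claims table.
#' @param year Calendar year.
#' @param cfg A [filter_config()].
#' @return Character vector of practice ids (sorted); empty when the year is
#'   absent from the claims.
#' @export
active_practices <- function(claims, year, cfg = filter_config()) {
  assert_claims(claims)
  claims <- as.data.table(claims)
  yr <- year
  counts <- claims[year == yr, .(n = data.table::uniqueN(patient_id)),
                   by = practice_id]
  sort(counts[n >= cfg$min_patients_per_year, practice_id])
}

#' Count distinct shared patients between practice pairs
#'
#' For one calendar year, counts for every pair of the given practices the
#' number of distinct patients with at least one retained visit to both.
#' Computed as the cross-product of the binary patient-by-practice incidence
#' matrix, so a patient contributes at most 1 to a pair regardless of visit
#' multiplicity.
#'
#' @param claims Filtered claims table.
#' @param year Calendar year.
#' @param node_ids Practice ids to include (typically from
#'   [active_practices()]). Ids absent from the claims get zero rows/columns.
#' @return A list of class `coop_shared_matrix` with `year`, `node_ids`, and
#'   `counts` (symmetric integer matrix, zero diagonal).
#' @export
count_shared_patients <- function(claims, year, node_ids) {
  assert_claims(claims)
  claims <- as.data.table(claims)
  yr <- year
  node_ids <- as.character(node_ids)
  sub <- unique(claims[year == yr & practice_id %in% node_ids,
                       .(patient_id, practice_id)])
  n <- length(node_ids)
  if (nrow(sub) == 0L) {
    counts <- matrix(0L, n, n, dimnames = list(node_ids, node_ids))
  } else {
    pt <- factor(sub$patient_id)
    pr <- factor(sub$practice_id, levels = node_ids)
    inc <- Matrix::sparseMatrix(i = as.integer(pt), j = as.integer(pr),
                                x = 1, dims = c(nlevels(pt), n))
    counts <- as.matrix(Matrix::crossprod(inc))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(node_ids, node_ids)
  }
  diag(counts) <- 0L
  structure(list(year = year, node_ids = node_ids, counts = counts),
            class = "coop_shared_matrix")
}

#' Threshold a shared-patient matrix into a yearly network
#'
#' An undirected, unweighted edge connects practices i and j when their
#' distinct shared-patient count is at least `threshold`. Practices without
#' any qualifying edge are kept as isolated nodes.
#'
#' @param m A `coop_shared_matrix` from [count_shared_patients()].
#' @param threshold Minimum shared-patient count for an edge (>= 1).
#' @return A `coop_yearly_network`: list with `year`, `nodes` (data.table of
#'   node attributes, filled by [build_networks()]), `edges` (data.table
#'   `node_a`, `node_b`, `shared_count`, with `node_a < node_b`), and
#'   `threshold_used`.
#' @export
apply_threshold <- function(m, threshold = 9L) {
  stopifnot(inherits(m, "coop_shared_matrix"))
  if (threshold < 1L) stop("`threshold` must be >= 1", call. = FALSE)
  idx <- which(upper.tri(m$counts) & m$counts >= threshold, arr.ind = TRUE)
  edges <- data.table(
    node_a = m$node_ids[idx[, 1L]],
    node_b = m$node_ids[idx[, 2L]],
    shared_count = m$counts[idx]
  )
  setorder(edges, node_a, node_b)
  structure(list(year = m$year,
                 nodes = data.table(practice_id = m$node_ids),
                 edges = edges,
                 threshold_used = as.integer(threshold)),
            class = "coop_yearly_network")
}

#' @export
print.coop_yearly_network <- function(x, ...) {
  cat(sprintf("<coop_yearly_network %s: %d nodes, %d edges (threshold %d)>\n",
              x$year, nrow(x$nodes), nrow(x$edges), x$threshold_used))
  invisible(x)
}

#' Convert a yearly network to an igraph object
#'
#' @param net A `coop_yearly_network`.
#' @return An undirected `igraph` graph whose vertices carry the node
#'   attribute columns.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coop_yearly_network"))
  igraph::graph_from_data_frame(
    d = net$edges[, .(node_a, node_b)],
    directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}

#' Build the yearly cooperation networks from claims
#'
#' Composes the full construction for every year present in the claims:
#' visit filtering ([filter_claims()]), the minimum-patient activity rule
#' ([active_practices()]), distinct shared-patient counting
#' ([count_shared_patients()]) and thresholding ([apply_threshold()]).
#' Node attributes `is_ip`, `specialty`, `n_patients` (distinct retained
#' patients) and `mean_charlson` (mean Charlson score over those patients)
#' are attached from the rosters.
#'
#' @param claims Raw claims table.
#' @param practices Practice attribute table (`practice_id`, `is_ip`,
#'   `specialty`).
#' @param patient_years Patient-year table (`patient_id`, `year`,
#'   `charlson_score`); optional, `mean_charlson` is `NA` when absent.
#' @param cfg A [filter_config()].
#' @param years Years to build; defaults to all years in the claims.
#' @return Named list (one element per year, ascending) of
#'   `coop_yearly_network` objects. Years with no active practice yield a
#'   zero-node network and a message.
#' @export
build_networks <- function(claims, practices = NULL, patient_years = NULL,
                           cfg = filter_config(), years = NULL) {
  assert_claims(claims)
  claims <- as.data.table(claims)
  kept <- filter_claims(claims, cfg)
  if (is.null(years)) years <- sort(unique(claims$year))
  nets <- vector("list", length(years))
  names(nets) <- as.character(years)
  for (k in seq_along(years)) {
    yr <- years[k]
    ids <- active_practices(kept, yr, cfg)
    if (length(ids) == 0L) {
      message("build_networks: no active practice in ", yr,
              "; emitting empty network")
      nets[[k]] <- structure(
        list(year = yr,
             nodes = data.table(practice_id = character(),
                                is_ip = logical(), specialty = character(),
                                n_patients = integer(),
                                mean_charlson = numeric()),
             edges = data.table(node_a = character(), node_b = character(),
                                shared_count = integer()),
             threshold_used = cfg$shared_patient_threshold,
             n_patients_total = 0L),
        class = "coop_yearly_network")
      next
    }
    m <- count_shared_patients(kept, yr, ids)
    net <- apply_threshold(m, cfg$shared_patient_threshold)
    net$nodes <- node_attributes(kept, yr, ids, practices, patient_years)
    ## distinct patients served by the year's active practices
    net$n_patients_total <- kept[year == yr & practice_id %in% ids,
                                 data.table::uniqueN(patient_id)]
    nets[[k]] <- net
  }
  nets
}

## Per-practice attributes from retained claims for one year.
node_attributes <- function(kept, yr, ids, practices, patient_years) {
  sub <- unique(kept[year == yr & practice_id %in% ids,
                     .(patient_id, practice_id)])
  if (!is.null(patient_years)) {
    py <- as.data.table(patient_years)[year == yr,
                                       .(patient_id, charlson_score)]
    sub <- py[sub, on = "patient_id"]
  } else {
    sub[, charlson_score := NA_real_]
  }
  att <- sub[, .(n_patients = .N,
                 mean_charlson = mean(charlson_score)), by = practice_id]
  nodes <- data.table(practice_id = ids)
  nodes <- att[nodes, on = "practice_id"]
  if (!is.null(practices)) {
    pr <- as.data.table(practices)
    cols <- intersect(c("practice_id", "is_ip", "specialty"), names(pr))
    nodes <- unique(pr[, cols, with = FALSE])[nodes, on = "practice_id"]
  } else {
    nodes[, `:=`(is_ip = NA, specialty = NA_character_)]
  }
  setcolorder(nodes, c("practice_id", "is_ip", "specialty",
                       "n_patients", "mean_charlson"))
  setorder(nodes, practice_id)
  nodes[]
}

#' Export per-year edge lists and node attributes
#'
#' Writes, for each yearly network, a tab-separated edge list
#' (`edges_<year>.tsv`: `node_a`, `node_b`, `shared_count`) and one combined
#' node attribute table (`nodes.csv`).
#'
#' @param nets Result of [build_networks()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_networks <- function(nets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (net in nets) {
    fwrite(net$edges, file.path(dir, sprintf("edges_%s.tsv", net$year)),
           sep = "\t")
  }
  nodes <- rbindlist(lapply(nets, function(n) {
    cbind(year = n$year, n$nodes)
  }), fill = TRUE)
  fwrite(nodes, file.path(dir, "nodes.csv"))
  invisible(dir)
}

#' Heat-map data export: group-ordered adjacency matrix
#'
#' Emits the binary adjacency matrix of one yearly network with rows and
#' columns ordered by practice group - integrated GPs, integrated
#' specialists, non-integrated GPs, non-integrated specialists - plus a
#' sidecar label table, the data product behind a cooperation heat map.
#'
#' @param net A `coop_yearly_network` with `is_ip` and `specialty` node
#'   attributes.
#' @param matrix_file,labels_file Optional paths; when given, the matrix is
#'   written as a dense tab-separated file and the labels as CSV.
#' @return List with `adjacency` (0/1 integer matrix, ordered) and `groups`
#'   (data.table `practice_id`, `group`).
#' @export
heatmap_data <- function(net, matrix_file = NULL, labels_file = NULL) {
  stopifnot(inherits(net, "coop_yearly_network"))
  nodes <- copy(net$nodes)
  nodes[, group := ifelse(is_ip & specialty == "GP", "IP-GP",
                   ifelse(is_ip, "IP-specialist",
                   ifelse(specialty == "GP", "nonIP-GP", "nonIP-specialist")))]
  order_lv <- c("IP-GP", "IP-specialist", "nonIP-GP", "nonIP-specialist")
  nodes[, group := factor(group, levels = order_lv)]
  setorder(nodes, group, practice_id)
  ids <- nodes$practice_id
  adj <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    ia <- match(net$edges$node_a, ids)
    ib <- match(net$edges$node_b, ids)
    adj[cbind(ia, ib)] <- 1L
    adj[cbind(ib, ia)] <- 1L
  }
  groups <- nodes[, .(practice_id, group = as.character(group))]
  if (!is.null(matrix_file)) {
    utils::write.table(adj, matrix_file, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  if (!is.null(labels_file)) fwrite(groups, labels_file)
  list(adjacency = adj, groups = groups)
}
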