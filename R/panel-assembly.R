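## Practice-year panel for the dynamic node-level model.

#' Panel specification
#'
#' Chooses which cooperation indicator is modelled and how many lags of it
#' enter the dynamic equation. Defaults follow the node-level models: two
#' lags for degree, one for the centrality rankings.
#'
#' @param outcome One of `"degree"` (normalized degree by default),
#'   `"ev_rank"`, `"be_rank"`.
#' @param n_lags Number of outcome lags in the model; defaults to 2 for
#'   degree and 1 otherwise.
#' @param use_normalized_degree Model normalized degree (`degree/(n-1)`,
#'   comparable across years) rather than the raw count. Recorded in the
#'   panel metadata.
#' @return List of class `coop_panel_spec`.
#' @export
panel_spec <- function(outcome = c("degree", "ev_rank", "be_rank"),
                       n_lags = NULL, use_normalized_degree = TRUE) {
  outcome <- match.arg(outcome)
  if (is.null(n_lags)) n_lags <- if (outcome == "degree") 2L else 1L
  if (n_lags < 1L) stop("`n_lags` must be >= 1", call. = FALSE)
  structure(list(outcome = outcome, n_lags = as.integer(n_lags),
                 use_normalized_degree = isTRUE(use_normalized_degree),
                 covariates = c("year_index", "ip_year", "n_patients",
                                "mean_charlson")),
            class = "coop_panel_spec")
}

#' Assemble the practice-year panel
#'
#' Builds the unbalanced panel holding all model variables: the chosen
#' outcome from the node metrics, the year index (`year - first_year`
#' of the panel), the IP indicator and its `ip_year = ip * year_index`
#' interaction, the practice's distinct retained patient count and the mean
#' Charlson score of those patients. One row per practice-year in which the
#' practice is an active network node. Lags are added with [add_lags()].
#'
#' @param nets Result of [build_networks()] (defines active practice-years).
#' @param metrics [node_metrics()] table.
#' @param claims Filtered claims (the same used to build the networks).
#' @param patient_years Patient-year table with `charlson_score`.
#' @param spec A [panel_spec()].
#' @param cfg [filter_config()] used upstream; applied to `claims` again so
#'   raw claims can be passed safely.
#' @return `data.table` of class `coop_panel` with attributes `outcome`,
#'   `n_lags`, `normalized` and lag columns `y_lag1..y_lagK`.
#' @export
assemble_panel <- function(nets, metrics, claims = NULL, patient_years = NULL,
                           spec = panel_spec(), cfg = filter_config()) {
  stopifnot(inherits(spec, "coop_panel_spec"))
  nodes <- rbindlist(lapply(nets, function(n) {
    if (nrow(n$nodes) == 0L) return(NULL)
    cbind(year = n$year, n$nodes)
  }), fill = TRUE)
  ## node attribute fallback: recompute n_patients / mean_charlson from the
  ## claims when build_networks() was run without the rosters
  if ((!"n_patients" %in% names(nodes) || anyNA(nodes$n_patients)) &&
      !is.null(claims)) {
    kept <- filter_claims(claims, cfg)
    for (k in seq_along(nets)) {
      yr <- nets[[k]]$year
      ids <- nets[[k]]$nodes$practice_id
      att <- node_attributes(kept, yr, ids, NULL, patient_years)
      nodes[year == yr, n_patients := att$n_patients[match(practice_id,
                                                           att$practice_id)]]
      nodes[year == yr,
            mean_charlson := att$mean_charlson[match(practice_id,
                                                     att$practice_id)]]
    }
  }
  if (anyNA(nodes$is_ip)) {
    stop("assemble_panel: practices with missing attributes (is_ip); ",
         "pass the practice roster to build_networks()", call. = FALSE)
  }
  ycol <- switch(spec$outcome,
                 degree = if (spec$use_normalized_degree) "degree_normalized"
                          else "degree",
                 ev_rank = "ev_rank",
                 be_rank = "be_rank")
  met <- as.data.table(metrics)[, c("practice_id", "year", ycol), with = FALSE]
  setnames(met, ycol, "y")
  panel <- met[nodes, on = c("practice_id", "year"), nomatch = NULL]
  first_year <- min(panel$year)
  panel[, year_index := year - first_year + 1L]
  panel[, ip := as.logical(is_ip)]
  panel[, ip_year := as.numeric(ip) * year_index]
  out <- panel[, .(practice_id, year, year_index, y, ip, ip_year,
                   n_patients, mean_charlson)]
  setorder(out, practice_id, year)
  out <- add_lags(out, spec$n_lags)
  setattr(out, "outcome", spec$outcome)
  setattr(out, "n_lags", spec$n_lags)
  setattr(out, "normalized",
          spec$outcome != "degree" || spec$use_normalized_degree)
  setattr(out, "class", c("coop_panel", class(out)))
  out[]
}

#' Add gap-aware lag columns
#'
#' Adds `y_lag1..y_lagK` where `y_lagk` for practice i in year t is the
#' outcome of the *calendar* year t-k. Gaps are not bridged: a practice
#' absent in t-1 has a missing `y_lag1` in t even if t-2 is observed.
#'
#' @param panel Panel with `practice_id`, `year`, `y`.
#' @param n_lags Number of lag columns.
#' @return The panel with lag columns appended (new object).
#' @export
add_lags <- function(panel, n_lags = 1L) {
  panel <- as.data.table(panel)
  out <- copy(panel)
  base <- panel[, .(practice_id, year, y)]
  for (k in seq_len(n_lags)) {
    lagged <- copy(base)[, year := year + k]
    setnames(lagged, "y", paste0("y_lag", k))
    out <- lagged[out, on = c("practice_id", "year")]
  }
  setcolorder(out, c(names(panel), paste0("y_lag", seq_len(n_lags))))
  setorder(out, practice_id, year)
  ## carry simulation/bookkeeping attributes (fe, eps, outcome, ...) through
  std <- c("names", "row.names", "class", ".internal.selfref", "sorted", "index")
  for (a in setdiff(names(attributes(panel)), std)) {
    setattr(out, a, attr(panel, a))
  }
  out[]
}

#' Write a panel as CSV with a metadata header
#'
#' The header comment lines record the outcome, normalization and lag
#' convention so a written panel is self-describing.
#'
#' @param panel A `coop_panel`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_panel <- function(panel, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# outcome: %s", attr(panel, "outcome") %||% "unknown"),
    sprintf("# normalized: %s", isTRUE(attr(panel, "normalized"))),
    sprintf("# n_lags: %s", attr(panel, "n_lags") %||% "unknown"),
    "# lag convention: calendar-year lags, gaps not bridged"
  ), con)
  utils::write.csv(panel, con, row.names = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
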