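## Synthetic regional claims generator.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: a roster of physician practices (a minority participating in an
## integrated-care system) that enters and exits over yearly waves, a slowly
## growing patient pool with gamma-distributed Charlson comorbidity scores,
## and visit-level claims in which patients attach to practices through a
## community-block model with an integrated-practice bonus that grows over
## time. Emergency visits and excluded-specialty practices are generated on
## purpose so the network filters have something to remove.

## Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Yearly target sizes under compound net growth, rounded to integers.
growth_targets <- function(n0, rate, n_years) {
  as.integer(round(n0 * (1 + rate)^(seq_len(n_years) - 1L)))
}

draw_specialties <- function(n, cfg) {
  u <- runif(n)
  out <- character(n)
  excl <- u < cfg$excluded_specialty_fraction
  out[excl] <- sample(EXCLUDED_SPECIALTIES, sum(excl), replace = TRUE)
  gp <- !excl & (u < cfg$excluded_specialty_fraction +
                   (1 - cfg$excluded_specialty_fraction) * cfg$gp_fraction)
  out[gp] <- "GP"
  rest <- !excl & !gp
  out[rest] <- sample(OTHER_SPECIALTIES, sum(rest), replace = TRUE)
  out
}

#' Generate the practice roster
#'
#' Creates the yearly roster of physician practices. The first wave has
#' exactly `n_practices_initial` practices, of which `round(n * ip_fraction)`
#' are integrated practices (IPs). In each later wave a random
#' `practice_turnover` share of practices exits and enough new practices
#' enter that the active count follows the configured net growth path, so
#' the panel of practices is unbalanced with contiguous activity spells.
#'
#' @param config A [sim_config()].
#' @param rng_seed Integer seed; identical seeds give identical rosters.
#' @return A `data.table` with one row per practice: `practice_id`, `is_ip`,
#'   `specialty`, `community`, `entry_year`, `exit_year` (both inclusive).
#' @export
generate_practices <- function(config, rng_seed = config$seed) {
  validate_sim_config(config)
  years <- sim_years(config)
  targets <- growth_targets(config$n_practices_initial,
                            config$practice_growth_rate, config$n_years)
  with_seed(rng_seed, {
    n0 <- config$n_practices_initial
    n_ip0 <- as.integer(round(n0 * config$ip_fraction))
    roster <- data.table(
      practice_id = sprintf("pr%05d", seq_len(n0)),
      is_ip = seq_len(n0) %in% sample.int(n0, n_ip0),
      specialty = draw_specialties(n0, config),
      community = sample.int(config$community_count, n0, replace = TRUE),
      entry_year = years[1L],
      exit_year = years[length(years)]
    )
    next_id <- n0 + 1L
    active <- rep(TRUE, n0)  # tracks rows of `roster` active in current year
    for (k in seq_along(years)[-1L]) {
      idx <- which(active)
      exits <- idx[runif(length(idx)) < config$practice_turnover]
      ## never shrink below the growth target
      max_exits <- max(0L, length(idx) - targets[k])
      if (length(exits) > max_exits) exits <- exits[seq_len(max_exits)]
      if (length(exits)) {
        roster$exit_year[exits] <- years[k - 1L]
        active[exits] <- FALSE
      }
      n_new <- targets[k] - sum(active)
      if (n_new > 0L) {
        surviving_ip <- sum(roster$is_ip[active])
        ip_target <- as.integer(round(targets[k] * config$ip_fraction))
        n_new_ip <- min(n_new, max(0L, ip_target - surviving_ip))
        new_ip <- c(rep(TRUE, n_new_ip), rep(FALSE, n_new - n_new_ip))
        add <- data.table(
          practice_id = sprintf("pr%05d", seq.int(next_id, length.out = n_new)),
          is_ip = sample(new_ip),
          specialty = draw_specialties(n_new, config),
          community = sample.int(config$community_count, n_new, replace = TRUE),
          entry_year = years[k],
          exit_year = years[length(years)]
        )
        roster <- rbind(roster, add)
        active <- c(active, rep(TRUE, n_new))
        next_id <- next_id + n_new
      }
    }
    roster[]
  })
}

#' Generate patient-year records
#'
#' Builds the patient pool and one record per patient-year. The pool grows
#' at `patient_growth_rate` net per year (new patients are appended; existing
#' patients stay). Charlson comorbidity scores are drawn independently per
#' patient-year from a gamma distribution with mean `charlson_mean` and
#' standard deviation `charlson_dispersion` (right-skewed, nonnegative);
#' a zero dispersion collapses to the constant mean.
#'
#' @param config A [sim_config()].
#' @param rng_seed Integer seed.
#' @return A `data.table` with columns `patient_id`, `year`, `charlson_score`
#'   and the patient's latent `community` (used by [generate_claims()]).
#' @export
generate_patients <- function(config, rng_seed = config$seed) {
  validate_sim_config(config)
  years <- sim_years(config)
  targets <- growth_targets(config$n_patients_initial,
                            config$patient_growth_rate, config$n_years)
  with_seed(rng_seed, {
    n_pool <- targets[length(targets)]
    pool <- data.table(
      patient_id = sprintf("pt%06d", seq_len(n_pool)),
      community = sample.int(config$community_count, n_pool, replace = TRUE)
    )
    rows <- lapply(seq_along(years), function(k) {
      data.table(patient_id = pool$patient_id[seq_len(targets[k])],
                 community = pool$community[seq_len(targets[k])],
                 year = years[k])
    })
    out <- rbindlist(rows)
    m <- config$charlson_mean
    s <- config$charlson_dispersion
    if (s <= .Machine$double.eps || m == 0) {
      out[, charlson_score := m]
    } else {
      out[, charlson_score := rgamma(.N, shape = (m / s)^2, rate = m / s^2)]
    }
    setcolorder(out, c("patient_id", "year", "charlson_score", "community"))
    out[]
  })
}

#' Generate visit-level claims
#'
#' Draws, for every patient-year, a Poisson number of visits and assigns each
#' visit to an active practice with probability proportional to an attachment
#' weight: a shared baseline of 1, multiplied by `community_affinity` when
#' practice and patient share a community, and by
#' `1 + ip_cooperation_drift * (year_index + 1)` for integrated practices.
#' A configured fraction of visits is flagged as emergency. The practice's
#' specialty is copied onto each claim row.
#'
#' @param config A [sim_config()].
#' @param practices Roster from [generate_practices()] (same config).
#' @param patients Patient-year table from [generate_patients()] (same config).
#' @param rng_seed Integer seed.
#' @return A claims `data.table`: `patient_id`, `practice_id`, `year`,
#'   `visit_type` (`"routine"`/`"emergency"`), `specialty`.
#' @export
generate_claims <- function(config, practices, patients,
                            rng_seed = config$seed) {
  validate_sim_config(config)
  req_pr <- c("practice_id", "is_ip", "specialty", "community",
              "entry_year", "exit_year")
  req_pt <- c("patient_id", "year", "community")
  if (!all(req_pr %in% names(practices))) {
    stop("generate_claims: practice roster is missing columns ",
         paste(setdiff(req_pr, names(practices)), collapse = ", "),
         " - was it generated with generate_practices()?", call. = FALSE)
  }
  if (!all(req_pt %in% names(patients))) {
    stop("generate_claims: patient table is missing columns ",
         paste(setdiff(req_pt, names(patients)), collapse = ", "), call. = FALSE)
  }
  years <- sim_years(config)
  if (!all(patients$year %in% years)) {
    stop("generate_claims: patient years outside the configured range; ",
         "rosters must come from the same config", call. = FALSE)
  }
  practices <- as.data.table(practices)
  patients <- as.data.table(patients)
  empty <- data.table(patient_id = character(), practice_id = character(),
                      year = integer(), visit_type = character(),
                      specialty = character())
  if (config$visits_per_patient_year == 0) return(empty)

  with_seed(rng_seed, {
    pieces <- vector("list", length(years) * config$community_count)
    pc <- 0L
    for (k in seq_along(years)) {
      yr <- years[k]
      act <- practices[entry_year <= yr & exit_year >= yr]
      if (nrow(act) == 0L) next
      ip_mult <- 1 + config$ip_cooperation_drift * k  # k = year_index + 1
      pts <- patients[year == yr]
      n_visits <- rpois(nrow(pts), config$visits_per_patient_year)
      for (cm in seq_len(config$community_count)) {
        sel <- pts$community == cm
        total <- sum(n_visits[sel])
        if (total == 0L) next
        w <- (1 + (config$community_affinity - 1) * (act$community == cm)) *
          ifelse(act$is_ip, ip_mult, 1)
        drawn <- sample.int(nrow(act), total, replace = TRUE, prob = w)
        pc <- pc + 1L
        pieces[[pc]] <- data.table(
          patient_id = rep(pts$patient_id[sel], n_visits[sel]),
          practice_id = act$practice_id[drawn],
          year = yr,
          specialty = act$specialty[drawn]
        )
      }
    }
    if (pc == 0L) return(empty)
    claims <- rbindlist(pieces[seq_len(pc)])
    claims[, visit_type := ifelse(runif(.N) < config$emergency_fraction,
                                  "emergency", "routine")]
    setcolorder(claims, c("patient_id", "practice_id", "year",
                          "visit_type", "specialty"))
    claims[]
  })
}

#' Simulate the full synthetic claims bundle
#'
#' Convenience wrapper running [generate_practices()], [generate_patients()]
#' and [generate_claims()] with sub-seeds derived deterministically from one
#' master seed.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed (defaults to `config$seed`).
#' @return A list with elements `practices`, `patients`, `claims`, `config`,
#'   `seed`.
#' @export
simulate_claims <- function(config = sim_config(), seed = config$seed) {
  seed <- as.integer(seed)
  practices <- generate_practices(config, rng_seed = seed)
  patients <- generate_patients(config, rng_seed = seed + 1L)
  claims <- generate_claims(config, practices, patients, rng_seed = seed + 2L)
  list(practices = practices, patients = patients, claims = claims,
       config = config, seed = seed)
}

#' Write a simulated claims bundle to CSV
#'
#' Writes `claims.csv`, `patients.csv`, `practices.csv` and a `metadata.json`
#' recording the configuration and seed.
#'
#' @param bundle Result of [simulate_claims()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(bundle$claims, file.path(dir, "claims.csv"))
  fwrite(bundle$patients, file.path(dir, "patients.csv"))
  fwrite(bundle$practices, file.path(dir, "practices.csv"))
  meta <- c(unclass(bundle$config), list(master_seed = bundle$seed))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
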