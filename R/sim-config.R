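#' Simulation configuration for the synthetic claims generator
#'
#' Bundles every knob of the synthetic regional claims simulator. The default
#' values emulate the magnitudes of a regional integrated-care network in
#' Germany over 14 yearly waves: roughly 200 physician practices of which
#' about one in seven participates in the integrated system ("integrated
#' practices", IPs), about 26,000 insured patients growing just under 1% a
#' year, and a latent cooperation process in which IP practices attach
#' patients at a rate that starts slightly above and drifts further above
#' that of comparable non-IP practices.
#'
#' @param n_practices_initial Number of practices active in the first year.
#' @param ip_fraction Fraction of practices participating in the integrated
#'   system. Constant over time within a practice.
#' @param n_patients_initial Number of patients in the first year.
#' @param n_years Number of yearly waves (>= 3 so lagged models are possible).
#' @param first_year First calendar year of the simulation.
#' @param patient_growth_rate Net yearly growth rate of the patient pool
#'   (proportion per year, e.g. 0.0097 for 0.97%).
#' @param practice_growth_rate Net yearly growth rate of the practice roster.
#' @param practice_turnover Yearly probability that an active practice exits;
#'   entries are added on top so the roster still grows at
#'   `practice_growth_rate` net. Produces the unbalanced panel.
#' @param visits_per_patient_year Mean number of retained visits a patient
#'   makes per year (Poisson rate).
#' @param community_count Number of latent patient/practice communities; visit
#'   probability concentrates within a community.
#' @param community_affinity Weight multiplier for practices sharing the
#'   patient's community relative to the shared baseline of 1.
#' @param ip_cooperation_drift Extra attachment weight per elapsed year for IP
#'   practices; the IP multiplier in year-index `t` (0-based) is
#'   `1 + ip_cooperation_drift * (t + 1)`, so a positive drift gives IPs both
#'   a baseline advantage and a growing one, while 0 makes IP and non-IP
#'   practices exchangeable conditional on community.
#' @param emergency_fraction Fraction of visits flagged as emergency.
#' @param excluded_specialty_fraction Fraction of practices assigned to the
#'   specialties excluded by the default network filter (Anaesthesiology,
#'   Radiology, Neuropathology), so the filters have work to do.
#' @param gp_fraction Fraction of non-excluded practices that are general
#'   practitioners (the rest draw other specialties).
#' @param charlson_mean Mean of the patient-year Charlson comorbidity score.
#' @param charlson_dispersion Standard deviation of the Charlson score
#'   (gamma-distributed; 0 collapses to the constant `charlson_mean`).
#' @param seed Default integer seed recorded with the config.
#'
#' @return A list of class `coop_sim_config`.
#' @seealso [test_scale_config()] for a small configuration used in examples
#'   and tests, [generate_practices()], [generate_patients()],
#'   [generate_claims()].
#' @export
sim_config <- function(n_practices_initial = 197,
                       ip_fraction = 28 / 197,
                       n_patients_initial = 25979,
                       n_years = 14,
                       first_year = 2004,
                       patient_growth_rate = 0.0097,
                       practice_growth_rate = 0.0115,
                       practice_turnover = 0.06,
                       visits_per_patient_year = 4,
                       community_count = 8,
                       community_affinity = 30,
                       ip_cooperation_drift = 0.02,
                       emergency_fraction = 0.05,
                       excluded_specialty_fraction = 0.06,
                       gp_fraction = 0.55,
                       charlson_mean = 2,
                       charlson_dispersion = 1.5,
                       seed = 1L) {
  cfg <- list(
    n_practices_initial = as.integer(n_practices_initial),
    ip_fraction = ip_fraction,
    n_patients_initial = as.integer(n_patients_initial),
    n_years = as.integer(n_years),
    first_year = as.integer(first_year),
    patient_growth_rate = patient_growth_rate,
    practice_growth_rate = practice_growth_rate,
    practice_turnover = practice_turnover,
    visits_per_patient_year = visits_per_patient_year,
    community_count = as.integer(community_count),
    community_affinity = community_affinity,
    ip_cooperation_drift = ip_cooperation_drift,
    emergency_fraction = emergency_fraction,
    excluded_specialty_fraction = excluded_specialty_fraction,
    gp_fraction = gp_fraction,
    charlson_mean = charlson_mean,
    charlson_dispersion = charlson_dispersion,
    seed = as.integer(seed)
  )
  class(cfg) <- "coop_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Small-scale simulation configuration
#'
#' A reduced configuration (60 practices, 2,000 patients, 8 communities) with
#' the same qualitative structure as [sim_config()] defaults, sized so a full
#' pipeline run takes seconds. Used throughout the examples and test suite.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `coop_sim_config`.
#' @export
test_scale_config <- function(...) {
  defaults <- list(
    n_practices_initial = 60L,
    ip_fraction = 10 / 60,
    n_patients_initial = 2000L,
    n_years = 14L,
    community_affinity = 20,
    ip_cooperation_drift = 0.03
  )
  do.call(sim_config, modifyList(defaults, list(...)))
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "coop_sim_config"))
  props <- c("ip_fraction", "emergency_fraction", "excluded_specialty_fraction",
             "gp_fraction", "practice_turnover")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("sim_config: `", p, "` must be a proportion in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_practices_initial < 1L || cfg$n_patients_initial < 1L ||
      cfg$community_count < 1L) {
    stop("sim_config: counts must be >= 1", call. = FALSE)
  }
  if (cfg$n_years < 3L) {
    stop("sim_config: `n_years` must be >= 3 (lagged models need at least 3 waves)",
         call. = FALSE)
  }
  if (cfg$visits_per_patient_year < 0) {
    stop("sim_config: `visits_per_patient_year` must be nonnegative", call. = FALSE)
  }
  if (cfg$ip_cooperation_drift < 0) {
    stop("sim_config: `ip_cooperation_drift` must be nonnegative", call. = FALSE)
  }
  if (cfg$charlson_mean < 0 || cfg$charlson_dispersion < 0) {
    stop("sim_config: Charlson mean and dispersion must be nonnegative", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.coop_sim_config <- function(x, ...) {
  cat("<coop_sim_config>\n")
  cat(sprintf("  practices: %d initial (%.1f%% IP), net growth %.2f%%/yr\n",
              x$n_practices_initial, 100 * x$ip_fraction,
              100 * x$practice_growth_rate))
  cat(sprintf("  patients:  %d initial, growth %.2f%%/yr\n",
              x$n_patients_initial, 100 * x$patient_growth_rate))
  cat(sprintf("  years:     %d (%d-%d)\n", x$n_years, x$first_year,
              x$first_year + x$n_years - 1L))
  cat(sprintf("  visits/patient-year %.1f, %d communities, IP drift %.3f\n",
              x$visits_per_patient_year, x$community_count,
              x$ip_cooperation_drift))
  invisible(x)
}

## Calendar years covered by a config
sim_years <- function(cfg) seq(cfg$first_year, length.out = cfg$n_years)

## Specialty vocabulary. The first three are the ones excluded by the
## default network filter.
EXCLUDED_SPECIALTIES <- c("Anaesthesiology", "Radiology", "Neuropathology")
OTHER_SPECIALTIES <- c("Internal Medicine", "Surgery", "Gynaecology",
                       "Paediatrics", "Orthopaedics", "Dermatology",
                       "Ophthalmology", "Neurology", "Psychiatry", "ENT")

#' Specialty vocabulary used by the simulator
#'
#' @return Character vector of specialty labels; the excluded-by-default
#'   labels (Anaesthesiology, Radiology, Neuropathology) come first.
#' @export
specialty_vocabulary <- function() c(EXCLUDED_SPECIALTIES, "GP", OTHER_SPECIALTIES)
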