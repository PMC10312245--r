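#' Simulate a dynamic panel directly from the node-level model
#'
#' Generates an outcome panel straight from the dynamic fixed-effects model
#' used for the node-level analysis,
#' \deqn{y_{it} = \theta_1 y_{i,t-1} + \theta_2 year_{it}
#'   + \theta_3 IP_i year_{it} + \theta_4 Npatients_{it}
#'   + \theta_5 Charlson_{it} + FE_i + \epsilon_{it},}
#' bypassing the claims/network stages. This is the ground-truth generator
#' used to evaluate the system-GMM estimator: coefficients are known, fixed
#' effects are Normal(0, `fe_sd`), idiosyncratic errors Normal(0, `noise_sd`),
#' and covariates are drawn independently (IP indicator Bernoulli(`ip_share`),
#' patient counts Poisson(`patients_mean`), Charlson scores gamma with mean 2
#' and standard deviation 1). A burn-in with the year term held at zero is
#' discarded so the autoregression starts near its stationary path.
#'
#' @param theta Numeric vector of the five coefficients
#'   (lag-1, year, IP x year, patient count, Charlson).
#' @param fe_sd Standard deviation of the node fixed effect.
#' @param noise_sd Standard deviation of the idiosyncratic error.
#' @param n_nodes Number of nodes (practices).
#' @param n_years Number of observed yearly waves (>= 4).
#' @param rng_seed Integer seed.
#' @param ip_share Share of nodes with the IP indicator set.
#' @param patients_mean Mean of the Poisson patient counts.
#' @param first_year Calendar year mapped to year index 1.
#' @param burn_in Discarded pre-sample periods.
#' @return A `data.table` with columns `practice_id`, `year`, `year_index`,
#'   `y`, `ip`, `n_patients`, `mean_charlson`, carrying the realized fixed
#'   effects and errors in attributes `fe` (per node) and `eps` (per row) so
#'   the model identity can be reconstructed exactly.
#' @export
generate_panel_from_model <- function(theta, fe_sd, noise_sd,
                                      n_nodes, n_years, rng_seed = 1L,
                                      ip_share = 0.15, patients_mean = 100,
                                      first_year = 2004L, burn_in = 50L) {
  theta <- as.numeric(theta)
  if (length(theta) != 5L) {
    stop("`theta` must have length 5 (lag-1, year, IPxyear, patients, Charlson)",
         call. = FALSE)
  }
  if (abs(theta[1L]) >= 1) {
    stop("|theta_1| must be < 1 for stationary dynamics", call. = FALSE)
  }
  if (n_years < 4L) stop("`n_years` must be >= 4", call. = FALSE)
  stopifnot(fe_sd >= 0, noise_sd >= 0, n_nodes >= 1)

  with_seed(rng_seed, {
    ip <- rbinom(n_nodes, 1L, ip_share)
    fe <- if (fe_sd > 0) rnorm(n_nodes, 0, fe_sd) else numeric(n_nodes)
    draw_cov <- function() {
      list(np = rpois(n_nodes, patients_mean),
           ch = rgamma(n_nodes, shape = 4, rate = 2))  # mean 2, sd 1
    }
    ## burn-in: year term off, start at per-node stationary mean
    cv <- draw_cov()
    y <- (fe + theta[4] * cv$np + theta[5] * cv$ch) / (1 - theta[1])
    for (b in seq_len(burn_in)) {
      cv <- draw_cov()
      e <- if (noise_sd > 0) rnorm(n_nodes, 0, noise_sd) else numeric(n_nodes)
      y <- theta[1] * y + theta[4] * cv$np + theta[5] * cv$ch + fe + e
    }
    rows <- vector("list", n_years)
    eps_all <- vector("list", n_years)
    for (t in seq_len(n_years)) {
      cv <- draw_cov()
      e <- if (noise_sd > 0) rnorm(n_nodes, 0, noise_sd) else numeric(n_nodes)
      y <- theta[1] * y + theta[2] * t + theta[3] * ip * t +
        theta[4] * cv$np + theta[5] * cv$ch + fe + e
      rows[[t]] <- data.table(
        practice_id = sprintf("n%05d", seq_len(n_nodes)),
        year = first_year + t - 1L,
        year_index = t,
        y = y,
        ip = as.logical(ip),
        n_patients = cv$np,
        mean_charlson = cv$ch
      )
      eps_all[[t]] <- e
    }
    panel <- rbindlist(rows)
    setorder(panel, practice_id, year)
    ## eps must follow the same (node, year) sort order
    eps <- as.vector(t(do.call(cbind, eps_all)))  # node-major after transpose
    setattr(panel, "fe", stats::setNames(fe, sprintf("n%05d", seq_len(n_nodes))))
    setattr(panel, "eps", eps)
    setattr(panel, "theta", theta)
    panel[]
  })
}
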