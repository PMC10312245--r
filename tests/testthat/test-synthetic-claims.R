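test_that("practice roster matches configured first-year composition", {
  cfg <- sim_config(seed = 11L)
  pr <- generate_practices(cfg, rng_seed = 11L)
  first <- pr[entry_year == 2004]
  expect_identical(nrow(first), 197L)
  expect_identical(sum(first$is_ip), 28L)
  ## degenerate single practice
  solo <- generate_practices(sim_config(n_practices_initial = 1,
                                        ip_fraction = 0), rng_seed = 1L)
  expect_identical(nrow(solo[entry_year == 2004]), 1L)
  ## determinism
  expect_identical(generate_practices(cfg, rng_seed = 11L), pr)
})

test_that("roster and patient growth track configured rates at regional scale", {
  cfg <- sim_config(seed = 3L)
  pr <- generate_practices(cfg, rng_seed = 3L)
  yearly <- sapply(2004:2017, function(y) {
    pr[entry_year <= y & exit_year >= y, .N]
  })
  expect_lt(abs(average_percentage_change(yearly) -
                  100 * cfg$practice_growth_rate), 0.2)
  pt <- generate_patients(cfg, rng_seed = 3L)
  counts <- pt[, .N, by = year][order(year)]$N
  expect_lt(abs(average_percentage_change(counts) -
                  100 * cfg$patient_growth_rate), 0.2)
  ## final-year patient count near the compound-growth target
  expect_lt(abs(counts[14] - 29421) / 29421, 0.01)
  ## activity spells are contiguous and unbalanced
  expect_true(all(pr$exit_year >= pr$entry_year))
  expect_gt(uniqueN(pr$practice_id), 197L)
})

test_that("Charlson scores have the configured mean and degenerate limit", {
  cfg <- test_scale_config(n_patients_initial = 10000L, n_years = 3L,
                           charlson_mean = 2, charlson_dispersion = 1.5)
  pt <- generate_patients(cfg, rng_seed = 5L)
  draws <- pt[year == min(year), charlson_score]
  se <- 1.5 / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 2), 3 * se)
  expect_true(all(draws >= 0))
  ## zero dispersion collapses to the constant mean
  pt0 <- generate_patients(test_scale_config(charlson_dispersion = 0),
                           rng_seed = 5L)
  expect_true(all(pt0$charlson_score == 2))
})

test_that("claims generation is deterministic and honors degenerate configs", {
  cfg <- tiny_cfg(seed = 9L)
  b1 <- simulate_claims(cfg, seed = 9L)
  b2 <- simulate_claims(cfg, seed = 9L)
  expect_identical(b1$claims, b2$claims)
  expect_identical(b1$practices, b2$practices)
  ## zero visit rate -> empty claims with full schema
  cfg0 <- tiny_cfg(visits_per_patient_year = 0)
  b0 <- simulate_claims(cfg0, seed = 1L)
  expect_identical(nrow(b0$claims), 0L)
  expect_named(b0$claims, c("patient_id", "practice_id", "year",
                            "visit_type", "specialty"))
  ## all-emergency claims leave no edges after filtering
  cfg_em <- tiny_cfg(emergency_fraction = 1)
  b_em <- simulate_claims(cfg_em, seed = 1L)
  nets <- suppressMessages(
    build_networks(b_em$claims, b_em$practices, b_em$patients))
  expect_true(all(vapply(nets, function(n) nrow(n$edges), 1L) == 0L))
})

test_that("claims reject mismatched rosters", {
  cfg <- tiny_cfg()
  b <- simulate_claims(cfg, seed = 2L)
  expect_error(generate_claims(cfg, b$practices[, .(practice_id)], b$patients),
               "missing columns")
  bad_patients <- data.table::copy(b$patients)[, year := year + 100L]
  expect_error(generate_claims(cfg, b$practices, bad_patients),
               "outside the configured range")
})

test_that("zero IP drift makes IP and non-IP sharing exchangeable", {
  ## conditional on community, expected shared-patient counts must not
  ## differ by IP status when the drift is 0
  diffs <- sapply(1:20, function(s) {
    cfg <- tiny_cfg(ip_cooperation_drift = 0, n_years = 3L, seed = s)
    b <- simulate_claims(cfg, seed = s)
    nets <- build_networks(b$claims, b$practices, b$patients,
                           filter_config(shared_patient_threshold = 1L))
    net <- nets[[1]]
    deg <- degree_centrality(net)
    deg <- net$nodes[deg, on = "practice_id"]
    mean(deg[is_ip == TRUE, degree]) - mean(deg[is_ip == FALSE, degree])
  })
  ## two-sided sign test at alpha ~ 1%: under exchangeability the sign of
  ## the IP/non-IP degree gap is a fair coin
  expect_gte(sum(diffs > 0), 4)
  expect_lte(sum(diffs > 0), 16)
})

test_that("positive IP drift raises the IP degree trend", {
  wins <- sapply(1:10, function(s) {
    cfg <- tiny_cfg(ip_cooperation_drift = 0.08, seed = s)
    b <- simulate_claims(cfg, seed = s)
    nets <- build_networks(b$claims, b$practices, b$patients)
    met <- node_metrics(nets)
    met <- merge(met, b$practices[, .(practice_id, is_ip)], by = "practice_id")
    trend <- function(sub) {
      if (uniqueN(sub$year) < 2) return(NA_real_)
      unname(coef(lm(degree ~ year, sub))[2])
    }
    mean(trend(met[is_ip == TRUE]), na.rm = TRUE) >
      mean(trend(met[is_ip == FALSE]), na.rm = TRUE)
  })
  ## one-sided sign test: IP trend should dominate in most seeds
  expect_gte(sum(wins), 8)
})

test_that("direct model simulation satisfies the model identity exactly", {
  th <- c(0.4, 0.01, 0.002, 0.0005, 0.05)
  pan <- generate_panel_from_model(th, fe_sd = 0.3, noise_sd = 0.2,
                                   n_nodes = 40, n_years = 6, rng_seed = 8L)
  pan <- add_lags(pan, 1L)
  fe <- attr(pan, "fe")[pan$practice_id]
  eps <- attr(pan, "eps")
  pred <- th[1] * pan$y_lag1 + th[2] * pan$year_index +
    th[3] * as.numeric(pan$ip) * pan$year_index +
    th[4] * pan$n_patients + th[5] * pan$mean_charlson + fe + eps
  ok <- !is.na(pan$y_lag1)
  expect_equal(pan$y[ok], unname(pred[ok]), tolerance = 1e-12)
})

test_that("direct model simulation has the theoretical lag-1 autocorrelation", {
  pan <- generate_panel_from_model(c(0.5, 0, 0, 0, 0), fe_sd = 0,
                                   noise_sd = 1, n_nodes = 4000, n_years = 6,
                                   rng_seed = 21L)
  pan <- add_lags(pan, 1L)
  ok <- !is.na(pan$y_lag1)
  expect_lt(abs(cor(pan$y[ok], pan$y_lag1[ok]) - 0.5), 0.03)
})

test_that("direct model simulation rejects nonstationary and trivial inputs", {
  expect_error(generate_panel_from_model(c(1, 0, 0, 0, 0), 0.1, 0.1, 10, 5),
               "stationary")
  expect_error(generate_panel_from_model(rep(0, 5), 0.1, 0.1, 10, 3),
               ">= 4")
  pan0 <- generate_panel_from_model(rep(0, 5), 0, 0, 10, 5, rng_seed = 1L)
  expect_true(all(pan0$y == 0))
  p1 <- generate_panel_from_model(c(0.3, 0, 0, 0, 0), 0.1, 0.1, 15, 5, rng_seed = 4L)
  p2 <- generate_panel_from_model(c(0.3, 0, 0, 0, 0), 0.1, 0.1, 15, 5, rng_seed = 4L)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})
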