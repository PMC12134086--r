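test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(p_initial_occupancy = 1.2), "probability")
  expect_error(sim_config(p_background_extinction = -0.1), "probability")
  expect_error(sim_config(settlement_preference = -1), ">= 0")
  expect_error(sim_config(mean_initial_dwellings = 0), "positive")
  expect_error(sim_config(site_genus_weights = matrix(1, 2, 2)), "n_sites")
})

test_that("initial occupancy honours boundary probabilities", {
  cfg0 <- small_config(p_initial_occupancy = 0)
  ds0 <- generate_host_community(cfg0)
  expect_equal(nrow(ds0$dwelling_table), 0L)

  cfg1 <- small_config(p_initial_occupancy = 1, mean_initial_dwellings = 1)
  ds1 <- generate_host_community(cfg1)
  per_colony <- table(ds1$dwelling_table$colony_id)
  expect_equal(sort(unique(ds1$colony_table$colony_id)), sort(names(per_colony)))
  expect_true(all(per_colony >= 1))
})

test_that("T0 occupancy fraction is within 3 binomial SE of the target", {
  cfg <- sim_config(n_sites = 4L, transects_per_site = 3L,
                    colonies_per_transect = 43L,
                    p_initial_occupancy = 0.25, seed = 1L)
  ds <- generate_host_community(cfg)
  n <- length(unique(ds$colony_table$colony_id))
  expect_equal(n, 516L)
  occ <- length(unique(ds$dwelling_table$colony_id)) / n
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(occ - 0.25), 3 * se)
})

test_that("frozen dynamics leave the survey invariant across time points", {
  cfg <- small_config(colonization_intensity = 0,
                      p_background_extinction = 0,
                      p_host_full_mortality_pre = 0, p_host_full_mortality_post = 0,
                      p_host_partial_mortality_pre = 0, p_host_partial_mortality_post = 0)
  ds <- simulate_fate_tracking(cfg)
  expect_equal(nrow(ds$true_event_log), 0L)
  counts <- tapply(ds$dwelling_table$status == "occupied",
                   ds$dwelling_table$time_point, sum)
  expect_true(all(counts == counts[1]))
  expect_true(all(ds$colony_table$mortality_state == "alive"))
})

test_that("certain full mortality kills every colony after the disturbance", {
  cfg <- small_config(p_host_full_mortality_post = 1, p_host_full_mortality_pre = 0,
                      p_host_partial_mortality_pre = 0, p_host_partial_mortality_post = 0,
                      p_background_extinction = 0, disturbance_time_point = 2L,
                      p_initial_occupancy = 1)
  ds <- simulate_fate_tracking(cfg)
  at3 <- ds$colony_table[ds$colony_table$time_point == 3L, ]
  expect_true(all(at3$mortality_state == "dead_recent"))
  lost <- ds$true_event_log[ds$true_event_log$event_type != "colonization", ]
  expect_true(all(lost$event_type == "host_mortality_extinction"))
})

test_that("simulation is bitwise-identical under a fixed seed", {
  a <- simulate_fate_tracking(small_config(seed = 42))
  b <- simulate_fate_tracking(small_config(seed = 42))
  expect_identical(a, b)
  c <- simulate_fate_tracking(small_config(seed = 43))
  expect_false(identical(a$dwelling_table, c$dwelling_table))
})

test_that("dwelling accounting identity holds on every simulated transition", {
  for (seed in c(2, 9)) {
    ds <- simulate_fate_tracking(small_config(seed = seed))
    tr <- transition_rates(ds)
    expect_true(all(tr$D_curr == tr$D_prev + tr$C - tr$E - tr$HM))
  }
})

test_that("settlement preference steers colonizations toward inhabited hosts", {
  frac_inhabited_targets <- function(psi, seed) {
    cfg <- sim_config(n_sites = 1L, transects_per_site = 1L,
                      colonies_per_transect = 500L, time_points = 2L,
                      p_initial_occupancy = 0.5, mean_initial_dwellings = 1,
                      colonization_intensity = 30,
                      settlement_preference = psi,
                      p_background_extinction = 0,
                      p_host_full_mortality_pre = 0, p_host_full_mortality_post = 0,
                      p_host_partial_mortality_pre = 0, p_host_partial_mortality_post = 0,
                      site_labels = "AS", seed = seed)
    ds <- simulate_fate_tracking(cfg)
    inh0 <- unique(ds$dwelling_table$colony_id[
      ds$dwelling_table$time_point == 0 & ds$dwelling_table$status == "occupied"])
    col <- ds$true_event_log[ds$true_event_log$event_type == "colonization", ]
    mean(col$colony_id %in% inh0)
  }
  n_rep <- 200L
  f10 <- vapply(seq_len(n_rep), function(i) frac_inhabited_targets(10, 7 + i), numeric(1))
  f0 <- vapply(seq_len(n_rep), function(i) frac_inhabited_targets(0, 7000 + i), numeric(1))
  gap <- mean(f10) - mean(f0)
  se_gap <- sqrt(var(f10) / n_rep + var(f0) / n_rep)
  expect_gt(gap, 3 * se_gap)
  # psi = 10 with 50% occupancy: inhabited weight 11 vs 1 -> expected share 11/12
  expect_gt(mean(f10), 0.85)
  expect_lt(mean(f0), 0.6)
})

test_that("BEINF sampler matches its nominal zero mass", {
  y <- generate_beinf_sample(10000, mu = 0.4, sigma = 0.3, nu = 0.3, tau = 0.2,
                             seed = 3)
  expect_lt(abs(mean(y == 0) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  expect_true(all(y >= 0 & y <= 1))
  expect_error(generate_beinf_sample(10, nu = 1.5), "nu")
})

test_that("temperature generator reproduces its construction", {
  flat <- generate_temperature_series(annual_amplitude = 0,
                                      heatwave_peak_anomaly = 0, noise_sd = 0,
                                      seed = 1)
  expect_equal(diff(range(flat$temp_c)), 0)

  bump <- generate_temperature_series(annual_amplitude = 0,
                                      heatwave_peak_anomaly = 2,
                                      heatwave_start = as.Date("2023-06-01"),
                                      heatwave_days = 60, noise_sd = 0, seed = 1)
  expect_equal(max(bump$temp_c), max(flat$temp_c) + 2, tolerance = 1e-6)

  a <- generate_temperature_series(noise_sd = 0.1, seed = 5)
  b <- generate_temperature_series(noise_sd = 0.1, seed = 5)
  expect_identical(a, b)

  expect_error(generate_temperature_series(interval_minutes = 15), "10 or 30")
})
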