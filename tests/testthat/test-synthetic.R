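# Generators: determinism, ground-truth consistency, and the statistical
# structure the downstream analysis assumes.

test_that("generators are bitwise reproducible from their seed", {
  cfg <- sim_config(seed = 99, duration_s = 60)
  a <- simulate_tcc_trace(cfg, tau_tcc_s = 3)
  b <- simulate_tcc_trace(cfg, tau_tcc_s = 3)
  expect_identical(a$trace$extension_nm, b$trace$extension_nm)
  expect_identical(a$events, b$events)

  r1 <- simulate_relaxation_trace(cfg, tau_apic_s = 10, total_turns = 10)
  r2 <- simulate_relaxation_trace(cfg, tau_apic_s = 10, total_turns = 10)
  expect_identical(r1$trace$extension_nm, r2$trace$extension_nm)

  f1 <- simulate_force_jump(cfg, n_per_force = 10)
  f2 <- simulate_force_jump(cfg, n_per_force = 10)
  expect_identical(f1, f2)

  k1 <- simulate_ensemble_kinetics(seed = 5)
  k2 <- simulate_ensemble_kinetics(seed = 5)
  expect_identical(k1, k2)

  a1 <- simulate_afm_particles(100, 100, seed = 3)
  a2 <- simulate_afm_particles(100, 100, seed = 3)
  expect_identical(a1, a2)
})

test_that("capture-trace events follow the configured exponential process", {
  cfg <- sim_config(seed = 17, duration_s = 3600)
  sim <- simulate_tcc_trace(cfg, tau_tcc_s = 3, bare_duration_s = 20)
  n_events <- sum(sim$events$kind == "step")
  expected <- (3600 - 20) / 3
  # Poisson count within 4 sd
  expect_lt(abs(n_events - expected), 4 * sqrt(expected))
  # dwell sample mean within 3 SE of the configured lifetime
  dwells <- sim$true_dwells_s
  expect_lt(abs(mean(dwells) - 3), 3 * 3 / sqrt(length(dwells)))
  # trace grid is uniform at the sampling rate
  expect_equal(diff(sim$trace$time_s),
               rep(1 / 58, nrow(sim$trace) - 1), tolerance = 1e-9)
})

test_that("noiseless traces re-derive their own event log exactly", {
  cfg <- sim_config(seed = 21, duration_s = 120, noise_sd_nm = 0)
  sim <- simulate_tcc_trace(cfg, tau_tcc_s = 6, sigma_z_reduction_nm = 0,
                            min_step_nm = 15)
  fit <- find_steps(sim$trace)
  truth <- sim$events[sim$events$kind == "step", ]
  expect_identical(fit$n_steps, nrow(truth))
  expect_equal(fit$step_sizes_nm, truth$value, tolerance = 1e-9)
  expect_equal(fit$step_times_s, truth$time_s, tolerance = 1 / 58)
})

test_that("released turns per relaxation event are geometric", {
  # p = 1: every event releases exactly one turn
  cfg <- sim_config(seed = 4, noise_sd_nm = 0)
  sim <- simulate_relaxation_trace(cfg, tau_apic_s = 1,
                                   rebind_prob_per_turn = 1,
                                   total_turns = 30)
  expect_true(all(sim$events$value == 1))

  # mean released turns -> 1/p within 3 SE over >= 500 events
  p <- 0.4
  pooled <- unlist(lapply(1:60, function(s) {
    simulate_relaxation_trace(sim_config(seed = s, noise_sd_nm = 0),
                              tau_apic_s = 1, rebind_prob_per_turn = p,
                              total_turns = 30)$events$value
  }))
  expect_gt(length(pooled), 500)
  # truncation at the remaining-turn budget biases the mean down slightly;
  # drop final events of each trace by filtering values below the cap
  se <- stats::sd(pooled) / sqrt(length(pooled))
  expect_lt(abs(mean(pooled) - 1 / p), 3 * se + 0.1)
  expect_error(
    simulate_relaxation_trace(cfg, rebind_prob_per_turn = 0),
    "rebind_prob")
})

test_that("force-jump tables honour the Bell model and its edge cases", {
  cfg <- sim_config(seed = 12)
  # delta x = 0: lifetime independent of force
  tab <- simulate_force_jump(cfg, tau0_days = 0.01, delta_x_nm = 0,
                             forces_pN = c(30, 50), n_per_force = 400,
                             loop_fraction = 0)
  m30 <- mean(tab$rupture_time_s[tab$force_pN == 30])
  m50 <- mean(tab$rupture_time_s[tab$force_pN == 50])
  pooled_se <- sqrt(m30^2 / 400 + m50^2 / 400)
  expect_lt(abs(m30 - m50), 3 * pooled_se)

  expect_identical(nrow(simulate_force_jump(cfg, n_per_force = 0)), 0L)
  expect_error(simulate_force_jump(cfg, forces_pN = numeric(0)), "force")

  # loop releases precede final rupture whenever present
  tab2 <- simulate_force_jump(cfg, n_per_force = 60)
  both <- is.finite(tab2$loop_time_s)
  expect_true(all(tab2$loop_time_s[both] < tab2$rupture_time_s[both]))
})

test_that("ensemble kinetics table reduces to the ODE solution", {
  truth <- kinetic_params()
  tab <- simulate_ensemble_kinetics(truth, noise_sd = 0, replicates = 1,
                                    seed = 8)
  for (L in unique(tab$length_bp)) {
    d <- tab[tab$length_bp == L, ]
    traj <- integrate_model(truth, L, d$time_min)
    expect_equal(d$fs_fraction_mean, traj$full_site, tolerance = 1e-8)
  }
  # t = 0 rows are exactly zero product
  expect_true(all(tab$fs_fraction_mean[tab$time_min == 0] == 0))
  expect_error(
    simulate_ensemble_kinetics(kinetic_params(k_hs = -1)), "non-negative")
})

test_that("AFM particle counts match the configured class statistics", {
  tab <- simulate_afm_particles(4000, 4000, seed = 6)
  oc <- tab$n_crossings[tab$true_class == "open_circular"]
  sc <- tab$n_crossings[tab$true_class == "supercoiled"]
  expect_true(all(tab$n_crossings >= 0))
  expect_true(all(tab$n_crossings == round(tab$n_crossings)))
  expect_lt(abs(mean(oc) - 2.4), 3 * stats::sd(oc) / sqrt(length(oc)) + 0.1)
  expect_lt(abs(mean(sc) - 12.2), 3 * stats::sd(sc) / sqrt(length(sc)))
  only_sc <- simulate_afm_particles(0, 50, seed = 1)
  expect_true(all(only_sc$true_class == "supercoiled"))
  expect_error(simulate_afm_particles(-1, 10), "non-negative")
})
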