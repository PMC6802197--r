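# Step finder: exactness on clean staircases, rejection of pure noise,
# oracle equivalence on toy traces, and the algebraic invariants.

make_trace <- function(y, rate = 58) {
  data.frame(time_s = (seq_along(y) - 1) / rate, extension_nm = y,
             magnet_turns = 0, force_pN = 0.5)
}

test_that("a noiseless staircase is recovered exactly", {
  levels <- c(0, 40, -20, 100, 60, 90)
  y <- rep(levels, each = 30)
  fit <- find_steps(make_trace(y))
  expect_identical(fit$n_steps, 5L)
  expect_equal(fit$step_sizes_nm, diff(levels), tolerance = 1e-12)
  expect_equal(fit$plateau_levels_nm, levels, tolerance = 1e-12)
  # dwell times are first differences of step times; plateaus = steps + 1
  expect_equal(fit$dwell_times_s, diff(fit$step_times_s))
  expect_identical(length(fit$plateau_levels_nm), fit$n_steps + 1L)
})

test_that("pure noise yields zero accepted steps", {
  withr::with_seed(31, {
    for (i in 1:5) {
      y <- stats::rnorm(2000, 500, 8)
      fit <- find_steps(make_trace(y))
      expect_identical(fit$n_steps, 0L)
    }
  })
})

test_that("first placed step matches the exhaustive-search oracle", {
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(6:12, 1)
      y <- c(stats::rnorm(n %/% 2, 0, 1), stats::rnorm(n - n %/% 2, 6, 1))
      best <- brute_force_best_split(y)
      fit <- find_steps(make_trace(y), min_dwell_s = 1 / 58,
                        acceptance_threshold = 0)
      # compare the first greedy split (largest residual reduction) with
      # the brute-force single-split optimum
      split1 <- intadyn:::.best_split(c(0, cumsum(y)), c(0, cumsum(y^2)),
                                      1L, length(y), 1L)
      expect_identical(split1$t, best)
    }
  })
})

test_that("step finding is idempotent on its own reconstruction", {
  sim <- simulate_tcc_trace(sim_config(seed = 13, duration_s = 120),
                            tau_tcc_s = 4, min_step_nm = 24)
  fit <- find_steps(sim$trace)
  tr2 <- as.data.frame(sim$trace)
  tr2$extension_nm <- reconstruct_steps(fit, sim$trace)
  fit2 <- find_steps(tr2)
  expect_identical(fit2$n_steps, fit$n_steps)
  expect_equal(fit2$step_times_s, fit$step_times_s)
  expect_equal(fit2$step_sizes_nm, fit$step_sizes_nm, tolerance = 1e-9)
})

test_that("scaling the trace scales step sizes and preserves step times", {
  sim <- simulate_tcc_trace(sim_config(seed = 23, duration_s = 90),
                            tau_tcc_s = 4, min_step_nm = 24)
  fit1 <- find_steps(sim$trace)
  tr2 <- as.data.frame(sim$trace)
  tr2$extension_nm <- 3 * tr2$extension_nm
  fit2 <- find_steps(tr2, min_step_nm = 0)
  expect_identical(fit2$n_steps, fit1$n_steps)
  expect_equal(fit2$step_times_s, fit1$step_times_s)
  expect_equal(fit2$step_sizes_nm, 3 * fit1$step_sizes_nm,
               tolerance = 1e-9)
})

test_that("steps during commanded magnet rotation are masked", {
  withr::with_seed(5, {
    n <- 1200
    y <- stats::rnorm(n, 0, 3)
    y[601:n] <- y[601:n] + 60          # genuine step at sample 600
    y[301:n] <- y[301:n] + 80          # artefact step during rotation
    tr <- make_trace(y)
    tr$magnet_turns <- c(rep(0, 295), seq(0, 10, length.out = 12),
                         rep(10, n - 307))
    fit_masked <- find_steps(tr, mask_rotation = TRUE)
    fit_raw <- find_steps(tr, mask_rotation = FALSE)
    in_rotation <- function(t) t > 294 / 58 & t < 308 / 58
    expect_false(any(in_rotation(fit_masked$step_times_s)))
    expect_true(any(in_rotation(fit_raw$step_times_s)))
    # the genuine step survives masking
    expect_true(any(abs(fit_masked$step_times_s - 600 / 58) < 0.1))
  })
})

test_that("short traces return a flagged zero-step fit", {
  fit <- find_steps(make_trace(c(1, 2, 3)), min_dwell_s = 1)
  expect_identical(fit$n_steps, 0L)
  expect_identical(fit$flag, "too_short")
})

test_that("rolling sigma_z measures the local fluctuation level", {
  # constant trace: all zero
  tr <- make_trace(rep(5, 300))
  expect_true(all(rolling_sigma(tr)$sigma_z_nm == 0))
  # pure Gaussian noise: mean sigma_z within 5% of the true SD
  withr::with_seed(41, {
    tr <- make_trace(stats::rnorm(5000, 0, 8))
    sz <- rolling_sigma(tr, window_s = 0.5)  # 29 samples at 58 Hz
    expect_lt(abs(mean(sz$sigma_z_nm) - 8) / 8, 0.05)
  })
  # capture trace: sigma_z drops after the bind event
  sim <- simulate_tcc_trace(sim_config(seed = 3, duration_s = 120),
                            tau_tcc_s = 1e6, sigma_z_reduction_nm = 5,
                            bare_duration_s = 60)
  sz <- rolling_sigma(sim$trace)
  before <- sz$sigma_z_nm[sz$time_s < 55]
  after <- sz$sigma_z_nm[sz$time_s > 65]
  expect_lt(stats::t.test(after, before, alternative = "less")$p.value,
            0.01)
  expect_error(rolling_sigma(make_trace(stats::rnorm(10)), window_s = 10),
               "longer than")
})

test_that("direction-filtered step sizes partition the fit", {
  sim <- simulate_tcc_trace(sim_config(seed = 29, duration_s = 120),
                            tau_tcc_s = 4, min_step_nm = 24)
  fit <- find_steps(sim$trace)
  up <- detrended_step_sizes(fit, "up")
  down <- detrended_step_sizes(fit, "down")
  both <- detrended_step_sizes(fit, "both")
  expect_identical(length(up) + length(down), length(both))
  expect_true(all(up > 0) && all(down > 0))
  # all-up staircase has no downward steps
  y <- rep(c(0, 50, 100, 150), each = 40)
  fit_up <- find_steps(make_trace(y))
  expect_identical(detrended_step_sizes(fit_up, "down"), numeric(0))
})

test_that("two-sided exponential step sizes are recovered by MLE", {
  # generator contract: |step| - min_step is exponential with the decay
  # length; the step finder's recovered sizes preserve that structure
  sim <- simulate_tcc_trace(sim_config(seed = 37, duration_s = 1500),
                            tau_tcc_s = 3, step_decay_nm = 45,
                            min_step_nm = 24)
  fit <- find_steps(sim$trace)
  sizes <- detrended_step_sizes(fit, "both") - 24
  sizes <- sizes[sizes > 0]
  est <- fit_exponential_mle(sizes)
  expect_gt(45, est$ci95_low)
  expect_lt(45, est$ci95_high + 5)
})
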