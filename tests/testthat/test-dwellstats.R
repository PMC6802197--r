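# Dwell-time and step-size statistics: exponential MLE with chi-square
# CIs, KDE quantization analysis, the periodicity spectrum, and two-sample
# comparisons.

test_that("exponential MLE equals the sample mean with a chi-square CI", {
  fit <- fit_exponential_mle(c(1, 2, 3, 4, 5))
  expect_equal(fit$tau, 3)
  expect_identical(fit$n, 5L)
  expect_true(fit$ci95_low <= fit$tau && fit$tau <= fit$ci95_high)
  expect_error(fit_exponential_mle(7), "insufficient")
  expect_error(fit_exponential_mle(c(-1, 2, 3)), "positive")

  # left truncation: memorylessness makes the MLE the mean excess
  x <- c(0.5, 1.5, 2.5, 3.5)
  fit_c <- fit_exponential_mle(x, min_cutoff = 1)
  expect_equal(fit_c$tau, mean(c(1.5, 2.5, 3.5) - 1))
  expect_identical(fit_c$n, 3L)

  # at n = 724 the chi-square CI half-width is ~1.96 tau / sqrt(n)
  withr::with_seed(101, {
    draws <- stats::rexp(724, 1 / 3)
    f <- fit_exponential_mle(draws)
    hw <- (f$ci95_high - f$ci95_low) / 2
    expect_equal(hw, 1.96 * f$tau / sqrt(724), tolerance = 0.02)
  })
})

test_that("chi-square CI attains nominal coverage", {
  withr::with_seed(55, {
    hits <- vapply(1:200, function(i) {
      draws <- stats::rexp(724, 1 / 3)
      f <- fit_exponential_mle(draws)
      f$ci95_low <= 3 && 3 <= f$ci95_high
    }, logical(1))
    expect_gte(mean(hits), 0.92)
    expect_lte(mean(hits), 0.98)
  })
})

test_that("bootstrap CI cross-checks the chi-square pivot", {
  withr::with_seed(77, {
    draws <- stats::rexp(400, 1 / 5)
    a <- fit_exponential_mle(draws)
    b <- fit_exponential_mle(draws, ci = "bootstrap", n_boot = 1500)
    expect_equal(b$ci95_low, a$ci95_low, tolerance = 0.05)
    expect_equal(b$ci95_high, a$ci95_high, tolerance = 0.05)
  })
})

test_that("the kernel density integrates to one and resolves quantization", {
  d1 <- kde_linking_density(rep(2, 6))
  expect_equal(d1$turns[which.max(d1$density)], 2, tolerance = 0.051)
  expect_equal(sum(d1$density) * 0.05, 1, tolerance = 1e-3)
  expect_true(all(d1$density >= 0))
  expect_error(kde_linking_density(rep(1, 5), bandwidth_turns = 0),
               "bandwidth")
  expect_error(kde_linking_density(numeric(0)), "non-empty")

  # integer-quantized sample: local maxima at the integers 1..5
  withr::with_seed(19, {
    lk <- pmin(stats::rgeom(600, 0.45) + 1, 5) +
      stats::rnorm(600, 0, 0.05)
    d <- kde_linking_density(lk)
    for (m in 1:5) {
      near <- d$density[abs(d$turns - m) <= 0.05]
      off <- d$density[abs(d$turns - m - 0.5) <= 0.05]
      expect_gt(max(near), max(off))
    }
    # invariant to sample ordering
    d_shuf <- kde_linking_density(sample(lk))
    expect_equal(d$density, d_shuf$density)
  })
})

test_that("the periodicity spectrum flags integer-comb structure only", {
  # pure exponential background: no dominant peak
  x <- seq(0, 12, by = 0.05)
  bg <- data.frame(turns = x, density = exp(-x / 2) / 2)
  sp0 <- periodicity_spectrum(bg)
  expect_lt(sp0$peak_ratio, 3)

  # exponential x integer comb: dominant frequency 1 cycle/turn
  comb <- exp(-x / 2) * exp(-((x - round(x))^2) / (2 * 0.15^2))
  spc <- periodicity_spectrum(data.frame(turns = x, density = comb))
  grid_bin <- 1 / (length(x) * 0.05)
  expect_lt(abs(spc$dominant_frequency - 1), grid_bin + 1e-9)
  expect_gt(spc$peak_ratio, 3)

  # amplitude scale-invariance after background normalization: scaling the
  # density scales the spectrum linearly, leaving the peak location fixed
  spc2 <- periodicity_spectrum(data.frame(turns = x, density = 7 * comb))
  expect_equal(spc2$dominant_frequency, spc$dominant_frequency)
  expect_equal(spc2$amplitude / 7, spc$amplitude, tolerance = 1e-6)

  expect_error(
    periodicity_spectrum(data.frame(turns = c(0, 0.1, 0.3),
                                    density = c(1, 1, 1))), "uniform")
})

test_that("KS comparison distinguishes the observed lifetime contrast", {
  x <- stats::rexp(100, 1)
  same <- compare_two_samples_ks(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_two_samples_ks(1:3, 1:10), "insufficient")

  # power at the 67 s vs 110 s contrast with n = 400 per side
  withr::with_seed(65, {
    reject <- vapply(1:100, function(i) {
      a <- stats::rexp(400, 1 / 67)
      b <- stats::rexp(400, 1 / 110)
      compare_two_samples_ks(a, b)$p_value < 0.01
    }, logical(1))
    expect_gte(mean(reject), 0.95)
  })
})

test_that("large-step fractions use per-trace Welch comparison", {
  # all steps small: fraction zero
  res0 <- fraction_large_steps(rep(2, 30), rep(1:3, each = 10))
  expect_true(all(res0$per_trace$fraction == 0))

  # geometric step counts with p = 0.3 vs 0.1: detectable at 20 traces
  withr::with_seed(9, {
    make_cond <- function(p, id0) {
      lk <- stats::rgeom(20 * 50, p) + 1
      list(lk = lk, trace = rep(id0 + 1:20, each = 50))
    }
    a <- make_cond(0.3, 0)
    b <- make_cond(0.1, 100)
    res <- fraction_large_steps(c(a$lk, b$lk), c(a$trace, b$trace),
                                condition = rep(c("wt", "mut"),
                                                each = 1000))
    expect_lt(res$t_test$p.value, 0.01)
  })

  # single trace per condition: descriptive only
  res1 <- fraction_large_steps(c(1, 2, 12, 3), c(1, 1, 2, 2),
                               condition = c("a", "a", "b", "b"))
  expect_null(res1$t_test)
  expect_match(res1$note, "fewer than 2")
  expect_error(fraction_large_steps(numeric(0), integer(0)), "no steps")
})
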