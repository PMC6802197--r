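# Closed-form mechanics: printed-value reproduction and algebraic
# invariants.

test_that("topology conversions reproduce the pBR322 bookkeeping", {
  expect_identical(reference_linking_number(4361), 415L)
  expect_identical(reference_linking_number(21), 2L)
  expect_error(reference_linking_number(0), "positive")

  expect_equal(linking_difference(4361, 0.05), 20.75)
  expect_equal(linking_difference(4361, 0), 0)
  expect_equal(linking_difference(1800, 0.05), 8.55)

  top <- plasmid_topology(4361, sigma = -0.05)
  expect_equal(top$linking_difference, -20.75)
  expect_error(plasmid_topology(4361), "exactly one")
})

test_that("free-energy formulas match their printed examples", {
  expect_equal(as.numeric(supercoiling_free_energy(4361, 20.75)),
               108.6, tolerance = 0.005)
  expect_equal(as.numeric(supercoiling_free_energy(1234, 0)), 0)
  expect_equal(as.numeric(supercoiling_free_energy(7900, 25)),
               87.0, tolerance = 0.005)
  expect_error(supercoiling_free_energy(-5, 10), "positive")

  expect_equal(as.numeric(bending_free_energy(60, 14)), 4.6,
               tolerance = 0.01)
  expect_equal(as.numeric(bending_free_energy(10, 14)), 0.13,
               tolerance = 0.02)
  expect_equal(as.numeric(bending_free_energy(0, 14)), 0)
  expect_error(bending_free_energy(60, -1), "l_bp")

  expect_equal(as.numeric(prebend_corrected_penalty(60, 10, 14)), 4.5,
               tolerance = 0.01)
  expect_equal(as.numeric(prebend_corrected_penalty(60, 0, 14)),
               as.numeric(bending_free_energy(60, 14)))
  expect_equal(as.numeric(prebend_corrected_penalty(60, 60, 14)), 0)
  expect_error(prebend_corrected_penalty(30, 60, 14), "geometry")

  expect_equal(as.numeric(interface_free_energy(110, 0.0132)), 9.0,
               tolerance = 0.01)
  expect_equal(as.numeric(interface_free_energy(67, 0.0156)), 8.4,
               tolerance = 0.01)
  expect_equal(as.numeric(interface_free_energy(5, 5)), 0)
  expect_error(interface_free_energy(0, 1), "positive")
})

test_that("Bell lifetime obeys its limits and the derived numeric example", {
  expect_equal(bell_lifetime(123, 0.5, 0), 123)
  expect_equal(bell_lifetime(1, 0, 50), 1)
  # kBT(298 K) = 4.1143 pN nm; 245 * exp(-30 * 0.89 / 4.1143) = 0.3722
  expect_equal(bell_lifetime(245, 0.89, 30, 298), 0.3722,
               tolerance = 0.001)
  expect_error(bell_lifetime(-1, 0.5, 10), "tau0")
  # monotone decreasing in force for positive delta x
  taus <- vapply(c(0, 10, 20, 40), function(f) bell_lifetime(5, 1, f),
                 numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("extension/linking conversion and tip convolution are exact", {
  expect_equal(extension_to_linking(0, 45), 0)
  expect_equal(extension_to_linking(45, 45), 1)
  expect_equal(extension_to_linking(135.7, 45), 3.0156, tolerance = 1e-4)
  expect_error(extension_to_linking(10, 0), "c_nm_per_turn")

  expect_equal(tip_convolution_fwhm(18, 4, 10), 18.7, tolerance = 0.002)
  expect_equal(tip_convolution_fwhm(18, 0, 10), 18)
  expect_equal(tip_convolution_fwhm(18, 4, 0), 18)
  expect_error(tip_convolution_fwhm(18, 4, 90), "alpha")
})

test_that("free-energy invariants hold for random inputs", {
  withr::with_seed(11, {
    for (i in 1:20) {
      n_bp <- sample(1000:10000, 1)
      dlk <- stats::runif(1, -30, 30)
      g <- as.numeric(supercoiling_free_energy(n_bp, dlk))
      # even in the sign of the linking difference, 1/N scaling
      expect_equal(g, as.numeric(supercoiling_free_energy(n_bp, -dlk)))
      expect_equal(as.numeric(supercoiling_free_energy(2 * n_bp, dlk)),
                   g / 2)
      # quadratic angle scaling of the bending energy
      th <- stats::runif(1, 1, 90)
      expect_equal(as.numeric(bending_free_energy(2 * th, 20)),
                   4 * as.numeric(bending_free_energy(th, 20)))
      # interface free energy antisymmetry
      a <- stats::runif(1, 0.01, 100)
      b <- stats::runif(1, 0.01, 100)
      expect_equal(as.numeric(interface_free_energy(a, b)),
                   -as.numeric(interface_free_energy(b, a)))
      # extension-to-linking linearity
      x <- stats::runif(2, -200, 200)
      expect_equal(extension_to_linking(sum(x), 45),
                   sum(extension_to_linking(x, 45)))
    }
  })
})

test_that("two noiseless (force, lifetime) pairs invert to the Bell inputs", {
  tau0 <- 245
  dx <- 0.89
  f <- c(30, 50)
  tau <- vapply(f, function(ff) bell_lifetime(tau0, dx, ff, 298), numeric(1))
  slope <- diff(log(tau)) / diff(f)
  expect_equal(-slope * kBT_pN_nm(298), dx, tolerance = 1e-12)
  expect_equal(exp(log(tau[1]) - slope * f[1]), tau0, tolerance = 1e-9)
})

test_that("energy container enforces its contract", {
  expect_error(energy_kBT(-1), "non-negative")
  expect_error(energy_kBT(1, temperature_K = 100), "temperature")
  e <- supercoiling_free_energy(4361, 20.75)
  # kBT -> kJ/mol at 310 K: factor R*T = 2.577 kJ/mol
  expect_equal(kBT_to_kJ_per_mol(e), as.numeric(e) * 2.5773,
               tolerance = 1e-3)
})
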