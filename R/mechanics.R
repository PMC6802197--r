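# Closed-form DNA mechanics: supercoiling, bending and interface free
# energies, Bell-model force dependence, topology conversions and the AFM
# tip-convolution geometry.

#' Mechanical constants of the tethered-DNA assay
#'
#' Bundles the constants used throughout the mechanics calculations: the
#' double-helical repeat, the helical rise, the bending persistence length,
#' the working temperatures for bulk reactions and for the magnetic-tweezers
#' (MT) flow cell, and the slope of extension versus linking difference in
#' the plectonemic regime.
#'
#' @param helical_repeat_bp Base pairs per helical turn. Default 10.5.
#' @param rise_per_bp_nm Helical rise in nm per base pair. Default 0.34.
#' @param persistence_length_nm Bending persistence length A in nm.
#'   Default 40.
#' @param temperature_bulk_K Temperature of bulk reactions in K. Default 310.
#' @param temperature_mt_K Temperature of MT experiments in K. Default 298.
#' @param extension_per_turn_nm Extension change per turn in the plectonemic
#'   regime at the working force, in nm/turn. Default 45.
#'
#' @return An object of class `mech_params`.
#' @examples
#' mech_params()
#' @export
mech_params <- function(helical_repeat_bp = 10.5,
                        rise_per_bp_nm = 0.34,
                        persistence_length_nm = 40,
                        temperature_bulk_K = 310,
                        temperature_mt_K = 298,
                        extension_per_turn_nm = 45) {
  check_positive_scalar(helical_repeat_bp, "helical_repeat_bp")
  check_positive_scalar(rise_per_bp_nm, "rise_per_bp_nm")
  check_positive_scalar(persistence_length_nm, "persistence_length_nm")
  check_temperature(temperature_bulk_K)
  check_temperature(temperature_mt_K)
  check_positive_scalar(extension_per_turn_nm, "extension_per_turn_nm")
  structure(
    list(helical_repeat_bp = helical_repeat_bp,
         rise_per_bp_nm = rise_per_bp_nm,
         persistence_length_nm = persistence_length_nm,
         temperature_bulk_K = temperature_bulk_K,
         temperature_mt_K = temperature_mt_K,
         extension_per_turn_nm = extension_per_turn_nm),
    class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat("DNA mechanics parameters\n")
  cat(sprintf("  helical repeat:        %.2f bp/turn\n", x$helical_repeat_bp))
  cat(sprintf("  rise per bp:           %.3f nm\n", x$rise_per_bp_nm))
  cat(sprintf("  persistence length A:  %.1f nm\n", x$persistence_length_nm))
  cat(sprintf("  T (bulk / MT):         %.0f / %.0f K\n",
              x$temperature_bulk_K, x$temperature_mt_K))
  cat(sprintf("  plectonemic slope c:   %.1f nm/turn\n",
              x$extension_per_turn_nm))
  invisible(x)
}

#' Relaxed linking number of a closed circular DNA
#'
#' The linking number of the torsionally relaxed plasmid, `round(N / h)`
#' with helical repeat `h`. Rounding to the nearest integer turn is required
#' for a covalently closed circle, whose linking number is a topological
#' integer.
#'
#' @param n_bp Plasmid size in base pairs (positive integer).
#' @param params A [mech_params()] object.
#' @return Integer number of helical turns.
#' @examples
#' reference_linking_number(4361) # pBR322: 415 turns
#' @export
reference_linking_number <- function(n_bp, params = mech_params()) {
  if (!is.numeric(n_bp) || length(n_bp) != 1L || !is.finite(n_bp) ||
      n_bp < 1) {
    stop("'n_bp' must be a positive number of base pairs", call. = FALSE)
  }
  as.integer(round(n_bp / params$helical_repeat_bp))
}

#' Linking difference at a given supercoiling density
#'
#' Converts a supercoiling density sigma into a linking difference
#' `dLk = sigma * Lk0(N)`.
#'
#' @inheritParams reference_linking_number
#' @param sigma Supercoiling density (dimensionless, signed).
#' @return Linking difference in turns (signed).
#' @examples
#' linking_difference(4361, 0.05) # 20.75 turns for pBR322 at |sigma| = 0.05
#' @export
linking_difference <- function(n_bp, sigma, params = mech_params()) {
  sigma * reference_linking_number(n_bp, params)
}

#' Supercoiling free energy of a plasmid
#'
#' Empirical quadratic free energy of supercoiling,
#' `dG = (1100 / N) * dLk^2` in units of kBT, for a plasmid of `N` base
#' pairs carrying a linking difference `dLk`. Symmetric in the sign of the
#' linking difference.
#'
#' @inheritParams reference_linking_number
#' @param delta_lk Linking difference in turns (signed).
#' @param temperature_K Temperature at which kBT is taken, for bookkeeping.
#' @return An `energy_kBT` object (numeric kBT value with temperature
#'   attribute).
#' @examples
#' supercoiling_free_energy(4361, 20.75) # ~108.6 kBT, i.e. ~110 kBT
#' @export
supercoiling_free_energy <- function(n_bp, delta_lk, temperature_K = 310) {
  if (!is.numeric(n_bp) || length(n_bp) != 1L || !is.finite(n_bp) ||
      n_bp < 1) {
    stop("'n_bp' must be a positive number of base pairs", call. = FALSE)
  }
  energy_kBT(1100 / n_bp * delta_lk^2, temperature_K)
}

#' Harmonic bending free energy of a DNA segment
#'
#' Free energy to bend a DNA segment of length `l` by angle `theta` in the
#' harmonic worm-like-chain approximation, `dG = A * theta^2 / (2 l)` in
#' kBT, with the persistence length `A` and `l` both in nm. The segment
#' length is given in base pairs and converted at the helical rise.
#'
#' @param theta_deg Bend angle in degrees, in \[0, 180\].
#' @param l_bp Segment length in base pairs.
#' @param A_nm Bending persistence length in nm.
#' @param rise_per_bp_nm Helical rise, nm per bp.
#' @param temperature_K Temperature label for the returned energy.
#' @return An `energy_kBT` object.
#' @examples
#' bending_free_energy(60, 14)  # ~4.6 kBT: target DNA bend in the active site
#' bending_free_energy(10, 14)  # ~0.13 kBT: plectoneme pre-bend
#' @export
bending_free_energy <- function(theta_deg, l_bp, A_nm = 40,
                                rise_per_bp_nm = 0.34,
                                temperature_K = 310) {
  check_positive_scalar(l_bp, "l_bp")
  check_positive_scalar(A_nm, "A_nm")
  if (!is.numeric(theta_deg) || length(theta_deg) != 1L ||
      !is.finite(theta_deg) || theta_deg < 0 || theta_deg > 180) {
    stop("'theta_deg' must be in [0, 180] degrees", call. = FALSE)
  }
  theta <- deg2rad(theta_deg)
  l_nm <- l_bp * rise_per_bp_nm
  energy_kBT(A_nm * theta^2 / (2 * l_nm), temperature_K)
}

#' Bending penalty relative to a pre-bent state
#'
#' Bending free energy of a full bend minus that of a pre-existing bend of
#' the same segment: the additional work to take DNA already bent by
#' `theta_pre` (e.g. inside a plectoneme) to the final bound-state angle.
#'
#' @inheritParams bending_free_energy
#' @param theta_pre_deg Pre-bend angle in degrees; must not exceed
#'   `theta_deg`.
#' @return An `energy_kBT` object, non-negative.
#' @examples
#' prebend_corrected_penalty(60, 10, 14) # ~4.5 kBT
#' @export
prebend_corrected_penalty <- function(theta_deg, theta_pre_deg, l_bp,
                                      A_nm = 40, rise_per_bp_nm = 0.34,
                                      temperature_K = 310) {
  if (theta_pre_deg > theta_deg) {
    stop("pre-bend angle exceeds the final bend angle: inconsistent geometry",
         call. = FALSE)
  }
  full <- bending_free_energy(theta_deg, l_bp, A_nm, rise_per_bp_nm,
                              temperature_K)
  pre <- bending_free_energy(theta_pre_deg, l_bp, A_nm, rise_per_bp_nm,
                             temperature_K)
  energy_kBT(as.numeric(full) - as.numeric(pre), temperature_K)
}

#' Interface free energy from bound and unbound lifetimes
#'
#' Free-energy contribution of a DNA-binding interface estimated from the
#' times spent bound versus unbound, `dG = kBT * ln(tau_bound / tau_unbound)`.
#' Antisymmetric under exchange of the two lifetimes.
#'
#' @param tau_bound_s Lifetime of the bound state, s.
#' @param tau_unbound_s Lifetime of the unbound state, s.
#' @param temperature_K Temperature label for the returned energy.
#' @return An `energy_kBT` object (signed).
#' @examples
#' interface_free_energy(110, 0.0132) # ~9.0 kBT (negative torque)
#' interface_free_energy(67, 0.0156)  # ~8.4 kBT (positive torque)
#' @export
interface_free_energy <- function(tau_bound_s, tau_unbound_s,
                                  temperature_K = 310) {
  check_positive_scalar(tau_bound_s, "tau_bound_s")
  check_positive_scalar(tau_unbound_s, "tau_unbound_s")
  energy_kBT(log(tau_bound_s / tau_unbound_s), temperature_K,
             allow_negative = TRUE)
}

#' Bell-model lifetime under applied force
#'
#' Lifetime of a bond under a constant stretching force,
#' `tau(F) = tau0 * exp(-F * dx / kBT)`, with `dx` the distance to the
#' transition state. The unit of `tau0` is preserved.
#'
#' @param tau0 Zero-force lifetime (any time unit).
#' @param delta_x_nm Distance to the transition state, nm.
#' @param force_pN Applied force, pN (non-negative).
#' @param temperature_K Temperature in K used for kBT.
#' @return Lifetime at the given force, in the unit of `tau0`.
#' @examples
#' bell_lifetime(245, 0.89, 30) # days, if tau0 is in days
#' @export
bell_lifetime <- function(tau0, delta_x_nm, force_pN, temperature_K = 298) {
  check_positive_scalar(tau0, "tau0")
  check_nonneg_scalar(force_pN, "force_pN")
  tau0 * exp(-force_pN * delta_x_nm / kBT_pN_nm(temperature_K))
}

#' Convert an extension change to released turns
#'
#' In the plectonemic regime the tether extension is linear in the linking
#' difference; an extension step of `delta_z` nm therefore corresponds to
#' `delta_z / c` released turns, with `c` the extension change per turn.
#'
#' @param delta_z_nm Extension change in nm (signed).
#' @param c_nm_per_turn Plectonemic slope in nm per turn (positive).
#' @return Released turns (signed real).
#' @examples
#' extension_to_linking(135.7, 45)
#' @export
extension_to_linking <- function(delta_z_nm, c_nm_per_turn = 45) {
  check_positive_scalar(c_nm_per_turn, "c_nm_per_turn")
  delta_z_nm / c_nm_per_turn
}

#' Tip-convolution model of the AFM full width at half maximum
#'
#' Apparent full width at half maximum of a particle of true width `D` and
#' height `h` imaged with a conical tip of half-cone angle `alpha`:
#' `FWHM = D + h * tan(alpha)`.
#'
#' @param D_nm True lateral dimension, nm (non-negative).
#' @param h_nm Particle height, nm (non-negative).
#' @param alpha_deg Tip half-cone angle in degrees, in \[0, 90).
#' @return Predicted FWHM in nm.
#' @examples
#' tip_convolution_fwhm(18, 4, 10) # 18.7 nm for the intasome long axis
#' @export
tip_convolution_fwhm <- function(D_nm, h_nm, alpha_deg) {
  check_nonneg_scalar(D_nm, "D_nm")
  check_nonneg_scalar(h_nm, "h_nm")
  if (!is.numeric(alpha_deg) || length(alpha_deg) != 1L ||
      !is.finite(alpha_deg) || alpha_deg < 0 || alpha_deg >= 90) {
    stop("'alpha_deg' must be in [0, 90) degrees", call. = FALSE)
  }
  D_nm + h_nm * tan(deg2rad(alpha_deg))
}

#' Energy value in units of kBT
#'
#' Lightweight container for an energy expressed in units of the thermal
#' energy, carrying the temperature at which kBT is taken.
#'
#' @param magnitude_kBT Energy in kBT.
#' @param temperature_K Temperature in K.
#' @param allow_negative Whether signed differences are permitted.
#' @return Numeric of class `energy_kBT` with a `temperature_K` attribute.
#' @export
energy_kBT <- function(magnitude_kBT, temperature_K = 310,
                       allow_negative = FALSE) {
  check_temperature(temperature_K)
  if (!is.numeric(magnitude_kBT) || length(magnitude_kBT) != 1L ||
      !is.finite(magnitude_kBT)) {
    stop("energy must be a single finite number", call. = FALSE)
  }
  if (!allow_negative && magnitude_kBT < 0) {
    stop("energy must be non-negative", call. = FALSE)
  }
  structure(magnitude_kBT, temperature_K = temperature_K,
            class = "energy_kBT")
}

#' @export
print.energy_kBT <- function(x, ...) {
  cat(sprintf("%.4g kBT (T = %.0f K)\n", as.numeric(x),
              attr(x, "temperature_K")))
  invisible(x)
}

#' Convert an energy in kBT to kJ/mol
#'
#' @param energy An `energy_kBT` object or plain kBT value.
#' @param temperature_K Temperature, taken from the object if present.
#' @return Energy in kJ/mol.
#' @export
kBT_to_kJ_per_mol <- function(energy, temperature_K = NULL) {
  temp <- attr(energy, "temperature_K")
  if (is.null(temp)) temp <- temperature_K
  if (is.null(temp)) stop("temperature required", call. = FALSE)
  # R = 8.31446e-3 kJ/(mol K)
  as.numeric(energy) * 8.31446e-3 * temp
}

#' Topological state of a closed circular plasmid
#'
#' Records plasmid size together with a consistent pair of linking
#' difference and supercoiling density. Supply either `sigma` or `delta_lk`;
#' the other is derived from the relaxed linking number.
#'
#' @param n_bp Plasmid size in base pairs.
#' @param sigma Supercoiling density (signed), or `NULL`.
#' @param delta_lk Linking difference in turns (signed), or `NULL`.
#' @param params A [mech_params()] object.
#' @return An object of class `plasmid_topology` with fields `n_bp`,
#'   `linking_difference` and `supercoiling_density`.
#' @examples
#' plasmid_topology(4361, sigma = -0.05)
#' @export
plasmid_topology <- function(n_bp, sigma = NULL, delta_lk = NULL,
                             params = mech_params()) {
  lk0 <- reference_linking_number(n_bp, params)
  if (is.null(sigma) == is.null(delta_lk)) {
    stop("supply exactly one of 'sigma' or 'delta_lk'", call. = FALSE)
  }
  if (is.null(delta_lk)) delta_lk <- sigma * lk0 else sigma <- delta_lk / lk0
  stopifnot(abs(sigma - delta_lk / lk0) < 1e-9)
  structure(list(n_bp = as.integer(n_bp), linking_difference = delta_lk,
                 supercoiling_density = sigma, lk0 = lk0),
            class = "plasmid_topology")
}

#' @export
print.plasmid_topology <- function(x, ...) {
  cat(sprintf("plasmid: %d bp, Lk0 = %d, dLk = %.3g (sigma = %.4g)\n",
              x$n_bp, x$lk0, x$linking_difference, x$supercoiling_density))
  invisible(x)
}
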