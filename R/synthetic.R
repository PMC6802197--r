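# Seeded generators for every input the analysis pipeline consumes:
# magnetic-tweezers extension traces (target capture and supercoil
# relaxation), force-jump rupture tables, ensemble integration kinetics and
# AFM particle tables. Each generator is a pure function of its arguments
# and seed, and returns the ground truth alongside the rendered data so that
# recovery tests can score the analysis against it.

#' Simulation configuration for magnetic-tweezers traces
#'
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param sampling_rate_hz Camera sampling rate in Hz. Default 58.
#' @param noise_sd_nm Gaussian extension noise per sample, nm. Default 8.
#' @param duration_s Trace duration in seconds.
#' @param force_pN Constant stretching force recorded in the trace, pN.
#' @param mechanics A [mech_params()] object.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, sampling_rate_hz = 58, noise_sd_nm = 8,
                       duration_s = 600, force_pN = 0.5,
                       mechanics = mech_params()) {
  check_positive_scalar(sampling_rate_hz, "sampling_rate_hz")
  check_nonneg_scalar(noise_sd_nm, "noise_sd_nm")
  check_positive_scalar(duration_s, "duration_s")
  check_nonneg_scalar(force_pN, "force_pN")
  stopifnot(inherits(mechanics, "mech_params"))
  structure(list(seed = as.integer(seed),
                 sampling_rate_hz = sampling_rate_hz,
                 noise_sd_nm = noise_sd_nm,
                 duration_s = duration_s,
                 force_pN = force_pN,
                 mechanics = mechanics),
            class = "sim_config")
}

# Assemble an mt_trace data.frame with config metadata attached.
new_trace <- function(time_s, extension_nm, magnet_turns, force_pN, config) {
  stopifnot(length(time_s) == length(extension_nm),
            length(time_s) == length(magnet_turns))
  df <- data.frame(time_s = time_s,
                   extension_nm = extension_nm,
                   magnet_turns = magnet_turns,
                   force_pN = rep_len(force_pN, length(time_s)))
  attr(df, "config") <- config
  class(df) <- c("mt_trace", "data.frame")
  df
}

#' @export
print.mt_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("magnetic-tweezers trace: %d samples, %.1f s at %.0f Hz\n",
              nrow(x), max(x$time_s), cfg$sampling_rate_hz))
  cat(sprintf("  extension %.0f-%.0f nm, force %.2g pN, noise SD %.2g nm\n",
              min(x$extension_nm), max(x$extension_nm), x$force_pN[1],
              cfg$noise_sd_nm))
  invisible(x)
}

new_event_log <- function(time_s, kind, value) {
  ord <- order(time_s)
  structure(data.frame(time_s = time_s[ord], kind = kind[ord],
                       value = value[ord]),
            class = c("event_log", "data.frame"))
}

#' Simulate a target-capture extension trace
#'
#' Renders the magnetic-tweezers signature of target capture by an intasome
#' with a blocked active site: after an initial bare-DNA period the complex
#' captures the tether (reducing the extension fluctuation SD), and the
#' extension then moves as a piecewise-constant staircase. Dwell times
#' between repositioning steps are exponential with mean `tau_tcc_s`; signed
#' step sizes are drawn from a two-sided exponential with decay length
#' `step_decay_nm` (optionally truncated below at `min_step_nm` to control
#' the signal-to-noise ratio of benchmark traces).
#'
#' @param config A [sim_config()] object.
#' @param tau_tcc_s Mean dwell time between repositioning steps, s.
#' @param step_decay_nm Decay length of the step-size magnitude, nm.
#'   Default 45.
#' @param sigma_z_reduction_nm Reduction of the per-sample noise SD after
#'   capture, nm. Default 4.
#' @param bare_duration_s Length of the bare-DNA period before capture, s.
#'   Default 20.
#' @param min_step_nm Lower truncation of step magnitudes, nm. Default 0.
#' @param baseline_nm Mean extension of the bare tether, nm. Default 1000.
#' @return A list with elements `trace` (an `mt_trace`) and `events` (an
#'   `event_log` holding the ground-truth bind time, step times, true step
#'   sizes and true dwells).
#' @examples
#' sim <- simulate_tcc_trace(sim_config(seed = 7, duration_s = 120),
#'                           tau_tcc_s = 3)
#' head(sim$events)
#' @export
simulate_tcc_trace <- function(config, tau_tcc_s, step_decay_nm = 45,
                               sigma_z_reduction_nm = 4,
                               bare_duration_s = 20, min_step_nm = 0,
                               baseline_nm = 1000) {
  stopifnot(inherits(config, "sim_config"))
  check_positive_scalar(tau_tcc_s, "tau_tcc_s")
  check_positive_scalar(step_decay_nm, "step_decay_nm")
  check_nonneg_scalar(min_step_nm, "min_step_nm")
  if (sigma_z_reduction_nm < 0 || sigma_z_reduction_nm > config$noise_sd_nm) {
    stop("'sigma_z_reduction_nm' must lie in [0, noise_sd_nm]", call. = FALSE)
  }
  if (bare_duration_s >= config$duration_s) {
    stop("bare period must be shorter than the trace", call. = FALSE)
  }
  withr::with_seed(config$seed, {
    dt <- 1 / config$sampling_rate_hz
    time_s <- seq(0, config$duration_s - dt, by = dt)
    n <- length(time_s)

    # ground-truth event schedule
    t_bind <- bare_duration_s
    step_times <- numeric(0)
    t <- t_bind + stats::rexp(1, 1 / tau_tcc_s)
    while (t < config$duration_s) {
      step_times <- c(step_times, t)
      t <- t + stats::rexp(1, 1 / tau_tcc_s)
    }
    k <- length(step_times)
    step_sizes <- (min_step_nm + stats::rexp(k, 1 / step_decay_nm)) *
      sample(c(-1, 1), k, replace = TRUE)

    # piecewise-constant extension plus state-dependent noise
    level <- if (k == 0L) {
      rep(baseline_nm, n)
    } else {
      baseline_nm + stats::stepfun(step_times, c(0, cumsum(step_sizes)))(time_s)
    }
    sd_per_sample <- ifelse(time_s < t_bind, config$noise_sd_nm,
                            config$noise_sd_nm - sigma_z_reduction_nm)
    extension <- level + stats::rnorm(n, 0, sd_per_sample)

    events <- new_event_log(
      c(t_bind, step_times),
      c("bind", rep("step", k)),
      c(NA_real_, step_sizes))
    trace <- new_trace(time_s, extension, magnet_turns = rep(0, n),
                       force_pN = config$force_pN, config = config)
    list(trace = trace, events = events,
         true_dwells_s = if (k > 1) diff(step_times) else numeric(0))
  })
}

#' Simulate a stepwise supercoil-release trace
#'
#' Renders the post-strand-transfer signature: supercoils trapped by the
#' apical interfaces are released in bursts when an interface transiently
#' unbinds. Plateau dwell times are exponential with mean `tau_apic_s`; the
#' number of turns released per unbinding event is geometric with success
#' probability `rebind_prob_per_turn` (the interface has a fixed chance of
#' reforming after every released turn), converted to extension via the
#' plectonemic slope. Each release is rendered as a finite-speed ramp at
#' `turn_time_s` per turn rather than an instantaneous jump.
#'
#' @param config A [sim_config()] object; `duration_s` is ignored (the trace
#'   ends when all turns are released).
#' @param tau_apic_s Mean plateau dwell time (apical interface lifetime), s.
#' @param rebind_prob_per_turn Probability in (0, 1] that the interface
#'   reforms after each released turn.
#' @param turn_time_s Time to release a single turn, s. Default 0.004.
#' @param total_turns Total trapped turns to release (positive integer).
#' @param baseline_nm Extension at full supercoiling, nm. Default 600.
#' @return A list with `trace`, `events` (one `release` row per burst whose
#'   value is the integer number of turns released) and `true_dwells_s`.
#' @export
simulate_relaxation_trace <- function(config, tau_apic_s = 90,
                                      rebind_prob_per_turn = 0.5,
                                      turn_time_s = 0.004,
                                      total_turns = 25,
                                      baseline_nm = 600) {
  stopifnot(inherits(config, "sim_config"))
  check_positive_scalar(tau_apic_s, "tau_apic_s")
  check_positive_scalar(turn_time_s, "turn_time_s")
  if (!is.numeric(rebind_prob_per_turn) || length(rebind_prob_per_turn) != 1L ||
      rebind_prob_per_turn <= 0 || rebind_prob_per_turn > 1) {
    stop("'rebind_prob_per_turn' must lie in (0, 1]", call. = FALSE)
  }
  if (total_turns < 1) stop("'total_turns' must be >= 1", call. = FALSE)
  c_nm <- config$mechanics$extension_per_turn_nm
  withr::with_seed(config$seed, {
    # event schedule: dwell, then a burst of geometrically many turns
    release_t <- numeric(0)
    release_n <- integer(0)
    released <- 0L
    t <- 0
    while (released < total_turns) {
      t <- t + stats::rexp(1, 1 / tau_apic_s)
      n_rel <- stats::rgeom(1, rebind_prob_per_turn) + 1L
      n_rel <- min(n_rel, total_turns - released)
      release_t <- c(release_t, t)
      release_n <- c(release_n, n_rel)
      released <- released + n_rel
    }
    dt <- 1 / config$sampling_rate_hz
    t_end <- release_t[length(release_t)] +
      release_n[length(release_n)] * turn_time_s + tau_apic_s / 2
    time_s <- seq(0, t_end, by = dt)

    # render plateaus with finite-speed ramps between them
    level <- numeric(length(time_s)) + baseline_nm
    cum <- 0
    for (i in seq_along(release_t)) {
      t0 <- release_t[i]
      t1 <- t0 + release_n[i] * turn_time_s
      ramp <- time_s >= t0 & time_s < t1
      level[ramp] <- baseline_nm + (cum + (time_s[ramp] - t0) / turn_time_s) *
        c_nm
      after <- time_s >= t1
      cum <- cum + release_n[i]
      level[after] <- baseline_nm + cum * c_nm
    }
    extension <- level + stats::rnorm(length(time_s), 0, config$noise_sd_nm)
    events <- new_event_log(release_t, rep("release", length(release_t)),
                            as.numeric(release_n))
    trace <- new_trace(time_s, extension,
                       magnet_turns = rep(total_turns, length(time_s)),
                       force_pN = config$force_pN, config = config)
    list(trace = trace, events = events,
         true_dwells_s = diff(c(0, release_t)))
  })
}

#' Simulate a force-jump rupture experiment
#'
#' For each applied force, rupture times of strand-transfer complexes are
#' drawn from an exponential whose mean follows the Bell model
#' [bell_lifetime()]. A fraction of tethers additionally shows an earlier
#' loop-release event, governed by its own Bell parameters, whose extension
#' jump is proportional to the tether's fluctuation-reduction depth.
#'
#' @param config A [sim_config()] object (supplies the seed and mechanics).
#' @param tau0_days Zero-force lifetime of the complex, days.
#' @param delta_x_nm Distance to the transition state of final rupture, nm.
#' @param forces_pN Vector of applied forces, pN (non-empty).
#' @param n_per_force Tethers per force level (0 gives an empty table).
#' @param loop_fraction Fraction of tethers with a loop-release event.
#' @param tau0_loop_days,delta_x_loop_nm Bell parameters of loop release.
#' @param jump_per_sigma Proportionality between loop jump (nm) and the
#'   fluctuation reduction depth (nm). Default 20.
#' @param temperature_K Temperature for kBT in the Bell model. Default 298.
#' @return A `rupture_table` data.frame with columns `tether_id`, `force_pN`,
#'   `loop_time_s`, `loop_jump_nm`, `rupture_time_s`, `dsigma_nm` (loop
#'   columns are `NA` where no loop release occurred before rupture).
#' @export
simulate_force_jump <- function(config, tau0_days = 245, delta_x_nm = 0.89,
                                forces_pN = c(30, 40, 50), n_per_force = 40,
                                loop_fraction = 0.9,
                                tau0_loop_days = 1.25,
                                delta_x_loop_nm = 0.51,
                                jump_per_sigma = 20,
                                temperature_K = 298) {
  stopifnot(inherits(config, "sim_config"))
  check_positive_scalar(tau0_days, "tau0_days")
  if (length(forces_pN) == 0) {
    stop("'forces_pN' must contain at least one force", call. = FALSE)
  }
  if (n_per_force < 0) stop("'n_per_force' must be >= 0", call. = FALSE)
  empty <- data.frame(tether_id = integer(0), force_pN = numeric(0),
                      loop_time_s = numeric(0), loop_jump_nm = numeric(0),
                      rupture_time_s = numeric(0), dsigma_nm = numeric(0))
  class(empty) <- c("rupture_table", "data.frame")
  if (n_per_force == 0) return(empty)
  withr::with_seed(config$seed, {
    rows <- lapply(seq_along(forces_pN), function(i) {
      f <- forces_pN[i]
      n <- n_per_force
      tau_s <- bell_lifetime(tau0_days, delta_x_nm, f, temperature_K) * 86400
      tau_loop_s <- bell_lifetime(tau0_loop_days, delta_x_loop_nm, f,
                                  temperature_K) * 86400
      rupture <- stats::rexp(n, 1 / tau_s)
      has_loop <- stats::runif(n) < loop_fraction
      loop <- ifelse(has_loop, stats::rexp(n, 1 / tau_loop_s), NA_real_)
      loop[!is.na(loop) & loop >= rupture] <- NA_real_
      dsigma <- stats::rexp(n, 1 / 3) + 1  # per-tether bridging depth, nm
      jump <- ifelse(is.na(loop), NA_real_,
                     jump_per_sigma * dsigma + stats::rnorm(n, 0, 2))
      data.frame(tether_id = (i - 1L) * n + seq_len(n), force_pN = f,
                 loop_time_s = loop, loop_jump_nm = jump,
                 rupture_time_s = rupture, dsigma_nm = dsigma)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("rupture_table", "data.frame")
    out
  })
}

#' Simulate an ensemble integration kinetics table
#'
#' Integrates the ensemble strand-transfer model (see [integrate_model()])
#' for each plasmid length, adds Gaussian noise to the full-site product
#' fraction, and returns the mean and SD over replicates for every
#' (length, time) pair -- the observable of the bulk gel-based assay.
#'
#' @param params A [kinetic_params()] object whose `k_on` is named by
#'   plasmid length.
#' @param lengths_bp Plasmid lengths in bp; must match `names(params$k_on)`.
#' @param times_min Sampling times in minutes.
#' @param noise_sd Gaussian noise SD on the full-site fraction. Default 0.05.
#' @param replicates Number of replicates per point. Default 3.
#' @param seed Integer seed.
#' @return A data.frame with columns `length_bp`, `time_min`,
#'   `fs_fraction_mean`, `fs_fraction_sd`.
#' @export
simulate_ensemble_kinetics <- function(params = kinetic_params(),
                                       lengths_bp = c(1800, 2700, 4600, 7200),
                                       times_min = c(0, 15, 30, 60, 120, 240),
                                       noise_sd = 0.05, replicates = 3,
                                       seed = 1L) {
  stopifnot(inherits(params, "kinetic_params"))
  check_nonneg_scalar(noise_sd, "noise_sd")
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    rows <- lapply(lengths_bp, function(L) {
      traj <- integrate_model(params, length_bp = L, times_min = times_min)
      reps <- vapply(seq_len(replicates), function(r) {
        pmin(pmax(traj$full_site + stats::rnorm(length(times_min), 0,
                                                noise_sd), 0), 1)
      }, numeric(length(times_min)))
      reps <- matrix(reps, nrow = length(times_min))
      data.frame(length_bp = L, time_min = times_min,
                 fs_fraction_mean = rowMeans(reps),
                 fs_fraction_sd = apply(reps, 1, stats::sd))
    })
    do.call(rbind, rows)
  })
}

#' Simulate AFM crossing-count observations
#'
#' Draws integer self-crossing counts for open-circular and supercoiled
#' plasmids from rounded Gaussians (truncated at zero by rejection) with the
#' class-specific means and common SD observed by AFM, labelled with the
#' ground-truth class.
#'
#' @param n_oc Number of open-circular molecules.
#' @param n_sc Number of supercoiled molecules.
#' @param seed Integer seed.
#' @param mean_oc,mean_sc Class means of the crossing number. Defaults 2.4
#'   and 12.2.
#' @param sd_n Common SD of the crossing number. Default 1.7.
#' @return A data.frame with columns `n_crossings` (non-negative integer)
#'   and `true_class` (`"open_circular"` or `"supercoiled"`).
#' @export
simulate_afm_particles <- function(n_oc, n_sc, seed = 1L,
                                   mean_oc = 2.4, mean_sc = 12.2,
                                   sd_n = 1.7) {
  if (n_oc < 0 || n_sc < 0) {
    stop("particle counts must be non-negative", call. = FALSE)
  }
  draw_counts <- function(n, mu) {
    out <- integer(0)
    while (length(out) < n) {
      cand <- as.integer(round(stats::rnorm(n - length(out), mu, sd_n)))
      out <- c(out, cand[cand >= 0])
    }
    out
  }
  withr::with_seed(as.integer(seed), {
    data.frame(
      n_crossings = c(draw_counts(n_oc, mean_oc), draw_counts(n_sc, mean_sc)),
      true_class = rep(c("open_circular", "supercoiled"), c(n_oc, n_sc)))
  })
}
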