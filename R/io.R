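# Trace and table I/O in a plain-text TSV dialect, run configuration, and
# the end-to-end pipeline driver. Traces carry their metadata in '#'
# key=value header lines; gzip-compressed files are read and written
# transparently via R's connection layer.

#' Write an extension trace to TSV
#'
#' Columns `time_s`, `extension_nm`, `magnet_turns`, `force_pN`, preceded by
#' `#` header lines carrying `key=value` metadata (sampling rate, noise SD,
#' seed). Files ending in `.gz` are gzip-compressed.
#'
#' @param trace An `mt_trace`.
#' @param path Output path (TSV, optionally `.gz`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  cfg <- attr(trace, "config")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  meta <- c(schema = "intadyn-trace-1")
  if (!is.null(cfg)) {
    meta <- c(meta,
              sampling_rate_hz = cfg$sampling_rate_hz,
              noise_sd_nm = cfg$noise_sd_nm,
              seed = cfg$seed)
  }
  writeLines(sprintf("# %s=%s", names(meta), unname(meta)), con)
  utils::write.table(
    df[, c("time_s", "extension_nm", "magnet_turns", "force_pN")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an extension trace from TSV
#'
#' Parses the dialect written by [write_trace()], validating the column set
#' and the monotonicity of the time channel; parse errors name the first
#' offending line.
#'
#' @param path Input path (TSV, optionally `.gz`).
#' @return An `mt_trace` with a `metadata` attribute (named character
#'   vector from the `#` header).
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty trace file: ", path, call. = FALSE)
  is_meta <- grepl("^#", lines)
  meta_lines <- sub("^#\\s*", "", lines[is_meta])
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  metadata <- stats::setNames(
    vapply(kv, function(p) paste(p[-1], collapse = "="), character(1)),
    vapply(kv, `[`, character(1), 1))
  body <- lines[!is_meta]
  if (length(body) < 2) stop("empty trace file: ", path, call. = FALSE)
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  need <- c("time_s", "extension_nm", "magnet_turns", "force_pN")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    header_offset <- sum(is_meta) + 1L
    stop(sprintf("non-monotonic time at line %d of %s",
                 bad[1] + 1L + header_offset, path), call. = FALSE)
  }
  out <- new_trace(df$time_s, df$extension_nm, df$magnet_turns,
                   df$force_pN, config = NULL)
  attr(out, "metadata") <- metadata
  out
}

#' Write a step fit to TSV
#'
#' Columns `step_time_s`, `step_size_nm`, `dwell_s`, `level_nm` (the level
#' after the step; the first plateau level is recorded in the header).
#'
#' @param fit A `step_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stepfit <- function(fit, path) {
  k <- fit$n_steps
  df <- data.frame(
    step_time_s = fit$step_times_s,
    step_size_nm = fit$step_sizes_nm,
    dwell_s = c(NA_real_, fit$dwell_times_s)[seq_len(k)],
    level_nm = fit$plateau_levels_nm[-1][seq_len(k)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# schema=intadyn-steps-1",
               sprintf("# first_level_nm=%.9g", fit$plateau_levels_nm[1]),
               sprintf("# quality=%.6g", fit$quality)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a run configuration
#'
#' Run configurations are YAML mappings holding seeds, mechanics constants
#' and per-stage parameters; [read_run_config()] and [write_run_config()]
#' round-trip them losslessly.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config Named list to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full simulate-and-analyse pipeline
#'
#' Executes, as configured: target-capture trace simulation, step finding
#' and dwell-time MLE; supercoil-release simulation with step-size KDE and
#' periodicity spectrum; force-jump simulation and the Bell-model fit;
#' ensemble kinetics simulation and the global kinetic fit; and the AFM
#' topology census. Stage failures are isolated: each failed stage is
#' reported in the bundle and flagged, and remaining stages still run.
#'
#' @param config Named list (or path to a YAML file) with an integer `seed`
#'   and optional per-stage blocks `tcc`, `relaxation`, `force_jump`,
#'   `kinetics`, `afm`; see the shipped demo config
#'   (`system.file("extdata", "demo_config.yaml", package = "intadyn")`).
#' @param out_dir Optional directory: when given, a machine-readable JSON
#'   report and the simulated tables are written there.
#' @return A list of class `intadyn_report` with one element per stage
#'   (estimates with CIs and the seeds used) and `failed` (character vector
#'   of failed stages, empty on full success).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(config$seed %||% 1L)
  seeds <- derive_seeds(seed, 5)
  report <- list(schema = "intadyn-report-1", seed = seed)
  failed <- character(0)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      failed <<- c(failed, name)
      list(error = conditionMessage(e))
    })
  }

  tcc_cfg <- config$tcc %||% list()
  report$tcc <- run_stage("tcc", function() {
    cfg <- sim_config(seed = seeds[1],
                      duration_s = tcc_cfg$duration_s %||% 600,
                      noise_sd_nm = tcc_cfg$noise_sd_nm %||% 8)
    sim <- simulate_tcc_trace(cfg, tau_tcc_s = tcc_cfg$tau_tcc_s %||% 3,
                              min_step_nm = tcc_cfg$min_step_nm %||% 24)
    fit <- find_steps(sim$trace)
    dwell <- fit_exponential_mle(fit$dwell_times_s)
    list(seed = seeds[1], n_steps = fit$n_steps,
         tau_tcc_s = dwell$tau, ci95 = c(dwell$ci95_low, dwell$ci95_high),
         n_dwells = dwell$n)
  })

  rel_cfg <- config$relaxation %||% list()
  report$relaxation <- run_stage("relaxation", function() {
    cfg <- sim_config(seed = seeds[2],
                      noise_sd_nm = rel_cfg$noise_sd_nm %||% 8)
    sim <- simulate_relaxation_trace(
      cfg, tau_apic_s = rel_cfg$tau_apic_s %||% 90,
      rebind_prob_per_turn = rel_cfg$rebind_prob %||% 0.5,
      total_turns = rel_cfg$total_turns %||% 25)
    fit <- find_steps(sim$trace)
    up <- detrended_step_sizes(fit, "up")
    lk <- extension_to_linking(up, cfg$mechanics$extension_per_turn_nm)
    dwell <- fit_exponential_mle(fit$dwell_times_s)
    kde <- if (length(lk) >= 5) kde_linking_density(lk) else NULL
    pspec <- if (!is.null(kde)) periodicity_spectrum(kde) else NULL
    list(seed = seeds[2], n_release_steps = length(up),
         tau_apic_s = dwell$tau,
         mean_delta_lk = mean(lk),
         dominant_frequency = if (is.null(pspec)) NA_real_ else
           pspec$dominant_frequency)
  })

  fj_cfg <- config$force_jump %||% list()
  report$force_jump <- run_stage("force_jump", function() {
    cfg <- sim_config(seed = seeds[3])
    tab <- simulate_force_jump(
      cfg, tau0_days = fj_cfg$tau0_days %||% 245,
      delta_x_nm = fj_cfg$delta_x_nm %||% 0.89,
      forces_pN = fj_cfg$forces_pN %||% c(30, 40, 50),
      n_per_force = fj_cfg$n_per_force %||% 40)
    lts <- fit_force_lifetimes(tab, "final")
    bell <- fit_bell(lts, temperature_K = fj_cfg$temperature_K %||% 298)
    list(seed = seeds[3], tau0_s = bell$tau0, se_tau0_s = bell$se_tau0,
         delta_x_nm = bell$delta_x_nm, se_delta_x_nm = bell$se_delta_x_nm)
  })

  kin_cfg <- config$kinetics %||% list()
  report$kinetics <- run_stage("kinetics", function() {
    truth <- kinetic_params()
    tab <- simulate_ensemble_kinetics(
      truth, noise_sd = kin_cfg$noise_sd %||% 0.03,
      replicates = kin_cfg$replicates %||% 3, seed = seeds[4])
    fit <- global_fit(tab, n_starts = kin_cfg$n_starts %||% 3,
                      seed = seeds[4])
    list(seed = seeds[4], estimate = as.list(fit$estimate),
         se = as.list(fit$se), ssr = fit$ssr, converged = fit$converged)
  })

  afm_cfg <- config$afm %||% list()
  report$afm <- run_stage("afm", function() {
    tab <- simulate_afm_particles(afm_cfg$n_oc %||% 500,
                                  afm_cfg$n_sc %||% 500, seed = seeds[5])
    rates <- classification_error_rates(tab)
    list(seed = seeds[5],
         error_open_circular = rates$error_open_circular,
         error_supercoiled = rates$error_supercoiled)
  })

  report$failed <- failed
  class(report) <- "intadyn_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.intadyn_report <- function(x, ...) {
  cat("intadyn pipeline report (seed", x$seed, ")\n")
  if (length(x$failed)) {
    cat("  FAILED stages:", paste(x$failed, collapse = ", "), "\n")
  }
  if (is.null(x$tcc$error)) {
    cat(sprintf("  target capture: tau = %.3g s (n = %d dwells)\n",
                x$tcc$tau_tcc_s, x$tcc$n_dwells))
  }
  if (is.null(x$relaxation$error)) {
    cat(sprintf("  supercoil release: tau_apic = %.3g s, <dLk> = %.3g turns\n",
                x$relaxation$tau_apic_s, x$relaxation$mean_delta_lk))
  }
  if (is.null(x$force_jump$error)) {
    cat(sprintf("  Bell fit: dx = %.3g nm, tau0 = %.3g s\n",
                x$force_jump$delta_x_nm, x$force_jump$tau0_s))
  }
  if (is.null(x$kinetics$error)) {
    cat(sprintf("  kinetics: SSR = %.3g (%s)\n", x$kinetics$ssr,
                if (x$kinetics$converged) "converged" else "not converged"))
  }
  if (is.null(x$afm$error)) {
    cat(sprintf("  AFM classifier errors: OC %.2g%%, SC %.2g%%\n",
                100 * x$afm$error_open_circular,
                100 * x$afm$error_supercoiled))
  }
  invisible(x)
}
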