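# Survival analysis of forced strand-transfer-complex disassembly and the
# Bell-model fit of force-dependent lifetimes.

#' Empirical cumulative rupture curve
#'
#' Right-continuous empirical cumulative fraction of dissociated tethers
#' versus time; its complement is the survival function.
#'
#' @param times Rupture times (positive, non-empty).
#' @return A data.frame of class `survival_curve` with columns `time_s` and
#'   `cum_fraction`, plus attribute `ecdf` (the [stats::ecdf()] function).
#' @examples
#' survival_curve(c(1, 2, 3))
#' @export
survival_curve <- function(times) {
  if (length(times) == 0 || any(!is.finite(times))) {
    stop("'times' must be non-empty and finite", call. = FALSE)
  }
  fn <- stats::ecdf(times)
  ts <- sort(unique(times))
  out <- data.frame(time_s = ts, cum_fraction = fn(ts))
  attr(out, "ecdf") <- fn
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Per-force exponential lifetimes from a rupture table
#'
#' Applies [fit_exponential_mle()] to the chosen event type within each
#' force level. Force levels with fewer than `min_n` events are still
#' reported but flagged unreliable.
#'
#' @param table A `rupture_table` (see [simulate_force_jump()]), or any
#'   data.frame with columns `force_pN`, `rupture_time_s` and optionally
#'   `loop_time_s`.
#' @param event `"final"` (STC disassembly) or `"loop"` (loop release).
#' @param min_n Minimum reliable sample size per force. Default 5.
#' @return A data.frame of class `force_lifetimes` with columns `force_pN`,
#'   `tau`, `ci95_low`, `ci95_high`, `n`, `reliable`; zero rows (with a
#'   warning) when no events of the requested type exist.
#' @export
fit_force_lifetimes <- function(table, event = c("final", "loop"),
                                min_n = 5L) {
  event <- match.arg(event)
  df <- as.data.frame(table)
  col <- if (event == "final") "rupture_time_s" else "loop_time_s"
  if (!all(c("force_pN", col) %in% names(df))) {
    stop(sprintf("table must have columns 'force_pN' and '%s'", col),
         call. = FALSE)
  }
  df <- df[is.finite(df[[col]]), , drop = FALSE]
  if (nrow(df) == 0L) {
    warning(sprintf("no '%s' events in the table", event), call. = FALSE)
    out <- data.frame(force_pN = numeric(0), tau = numeric(0),
                      ci95_low = numeric(0), ci95_high = numeric(0),
                      n = integer(0), reliable = logical(0))
    class(out) <- c("force_lifetimes", "data.frame")
    return(out)
  }
  out <- do.call(rbind, lapply(split(df, df$force_pN), function(g) {
    fit <- fit_exponential_mle(g[[col]])
    data.frame(force_pN = g$force_pN[1], tau = fit$tau,
               ci95_low = fit$ci95_low, ci95_high = fit$ci95_high,
               n = fit$n, reliable = fit$n >= min_n)
  }))
  rownames(out) <- NULL
  out <- out[order(out$force_pN), , drop = FALSE]
  class(out) <- c("force_lifetimes", "data.frame")
  out
}

#' Bell-model fit of force-dependent lifetimes
#'
#' Weighted linear regression of `ln(tau)` on force: under the Bell model
#' `tau(F) = tau0 * exp(-F dx / kBT)`, the slope is `-dx/kBT` and the
#' intercept `ln(tau0)`. For exponential lifetime estimates the variance of
#' `ln(tau_hat)` is `1/n`, so the default weights are the per-force sample
#' sizes, and the standard errors use these known variances directly
#' (`(X'WX)^-1`) rather than the residual variance, which would rest on a
#' single degree of freedom for three forces. An unweighted fit (with
#' conventional residual-based errors) is available for sensitivity
#' analysis. `tau0` errors propagate by the delta method.
#'
#' @param lifetimes A `force_lifetimes` data.frame, or any data.frame with
#'   columns `force_pN`, `tau` and optionally `n`.
#' @param temperature_K Temperature for kBT. Default 298.
#' @param weighted Weight by per-force `n` (default TRUE; falls back to
#'   unweighted if `n` is absent).
#' @return An object of class `bell_fit` with fields `tau0` (zero-force
#'   lifetime, units of the input `tau`), `delta_x_nm`, `se_log_tau0`,
#'   `se_tau0`, `se_delta_x_nm`, `temperature_K`, `lm` (the underlying
#'   linear model) and `lifetimes`.
#' @examples
#' lt <- data.frame(force_pN = c(30, 40, 50),
#'                  tau = bell_lifetime(245, 0.89, c(30, 40, 50)),
#'                  n = c(55, 41, 36))
#' fit_bell(lt)
#' @export
fit_bell <- function(lifetimes, temperature_K = 298, weighted = TRUE) {
  df <- as.data.frame(lifetimes)
  if (!all(c("force_pN", "tau") %in% names(df))) {
    stop("need columns 'force_pN' and 'tau'", call. = FALSE)
  }
  if (any(df$tau <= 0) || any(!is.finite(df$tau))) {
    stop("lifetimes must be positive and finite", call. = FALSE)
  }
  if (length(unique(df$force_pN)) < 2L) {
    stop("insufficient data: need at least 2 distinct forces", call. = FALSE)
  }
  kbt <- kBT_pN_nm(temperature_K)
  use_known_var <- weighted && "n" %in% names(df)
  w <- if (use_known_var) df$n else rep(1, nrow(df))
  fit <- stats::lm(log(tau) ~ force_pN, data = df, weights = w)
  cf <- stats::coef(fit)
  se <- if (use_known_var) {
    # For exponential-MLE lifetimes the variance of ln(tau_hat) is known
    # exactly (1/n per force), so the coefficient covariance is
    # (X' W X)^-1 with W = diag(n) -- not scaled by the residual variance,
    # which would carry only (forces - 2) degrees of freedom
    X <- cbind(1, df$force_pN)
    sqrt(diag(solve(crossprod(X * sqrt(w)))))
  } else {
    sqrt(diag(stats::vcov(fit)))
  }
  tau0 <- exp(unname(cf[1]))
  dx <- -unname(cf[2]) * kbt
  structure(list(tau0 = tau0,
                 delta_x_nm = dx,
                 se_log_tau0 = unname(se[1]),
                 se_tau0 = tau0 * unname(se[1]),
                 se_delta_x_nm = unname(se[2]) * kbt,
                 temperature_K = temperature_K,
                 weighted = weighted,
                 lm = fit,
                 lifetimes = df),
            class = "bell_fit")
}

#' @export
print.bell_fit <- function(x, ...) {
  cat("Bell-model fit of force-dependent lifetimes\n")
  cat(sprintf("  tau(F=0) = %.4g +/- %.2g (same unit as input lifetimes)\n",
              x$tau0, x$se_tau0))
  cat(sprintf("  delta x  = %.3g +/- %.2g nm (%.3g +/- %.2g Angstrom)\n",
              x$delta_x_nm, x$se_delta_x_nm,
              10 * x$delta_x_nm, 10 * x$se_delta_x_nm))
  cat(sprintf("  T = %.0f K, %s fit over %d forces\n", x$temperature_K,
              if (x$weighted) "n-weighted" else "unweighted",
              nrow(x$lifetimes)))
  invisible(x)
}

#' Correlation of loop-release jump size with fluctuation reduction
#'
#' Pearson correlation between the loop-release extension jump and the
#' depth of the sigma_z reduction across tethers where both were measured.
#'
#' @param table A `rupture_table` with columns `loop_jump_nm`, `dsigma_nm`.
#' @return A list with `r`, `p_value` and `n`.
#' @export
correlate_jump_with_sigma <- function(table) {
  df <- as.data.frame(table)
  if (!all(c("loop_jump_nm", "dsigma_nm") %in% names(df))) {
    stop("need columns 'loop_jump_nm' and 'dsigma_nm'", call. = FALSE)
  }
  ok <- is.finite(df$loop_jump_nm) & is.finite(df$dsigma_nm)
  if (sum(ok) < 3L) {
    stop("insufficient data: need at least 3 paired observations",
         call. = FALSE)
  }
  ct <- stats::cor.test(df$loop_jump_nm[ok], df$dsigma_nm[ok],
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
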