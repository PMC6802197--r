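# Unbiased decomposition of extension traces into plateaus and steps by
# iterative chi-square step fitting with counter-fit quality control, plus
# the moving-window fluctuation statistic sigma_z.
#
# The step finder places, at each iteration, the single step that maximally
# reduces the residual sum of squares over all plateaus, yielding a nested
# sequence of candidate fits. The accepted number of steps is the one whose
# counter-fit (steps forced to plateau centres, the worst consistent
# placement) raises the residuals by the largest factor; the fit is rejected
# outright when that factor never reaches the acceptance threshold.

# Residual sum of squares of segment [i, j] from cumulative sums.
.seg_sse <- function(c1, c2, i, j) {
  s1 <- c1[j + 1L] - c1[i]
  s2 <- c2[j + 1L] - c2[i]
  s2 - s1^2 / (j - i + 1L)
}

# Best single split of plateau [i, j]: split index t means the step falls
# between samples t and t + 1. Ties break to the earliest index.
.best_split <- function(c1, c2, i, j, md) {
  lo <- i + md - 1L
  hi <- j - md
  if (hi < lo) return(NULL)
  t <- lo:hi
  left_n <- t - i + 1L
  right_n <- j - t
  s1l <- c1[t + 1L] - c1[i]
  s2l <- c2[t + 1L] - c2[i]
  s1r <- c1[j + 1L] - c1[t + 1L]
  s2r <- c2[j + 1L] - c2[t + 1L]
  sse_split <- (s2l - s1l^2 / left_n) + (s2r - s1r^2 / right_n)
  red <- .seg_sse(c1, c2, i, j) - sse_split
  best <- which.max(red)
  list(t = t[best], reduction = red[best])
}

# SSE of the piecewise-constant fit defined by sorted split indices.
.fit_sse <- function(c1, c2, splits, n) {
  bounds <- c(0L, splits, n)
  sum(vapply(seq_len(length(bounds) - 1L), function(p) {
    .seg_sse(c1, c2, bounds[p] + 1L, bounds[p + 1L])
  }, numeric(1)))
}

# Counter-fit: steps at the centres of the plateaus of the current fit.
.counter_sse <- function(c1, c2, splits, n) {
  bounds <- c(0L, sort(splits), n)
  centres <- floor((bounds[-length(bounds)] + bounds[-1L]) / 2)
  centres <- centres[centres > 0L & centres < n]
  centres <- unique(centres)
  .fit_sse(c1, c2, sort(centres), n)
}

#' Decompose an extension trace into plateaus and steps
#'
#' Iterative chi-square step fitting: the step that maximally reduces the
#' squared residuals is placed first, then the next best within the
#' resulting plateaus, and so on. The candidate fit with `k` steps is scored
#' by the ratio of the residuals of its counter-fit (steps at plateau
#' centres) to its own residuals; the `k` maximizing this ratio is accepted,
#' provided the ratio reaches `acceptance_threshold`. Steps closer together
#' than `min_dwell_s` are never placed; steps smaller than `min_step_nm`
#' are merged away. Samples recorded during commanded magnet rotation
#' (changes in the `magnet_turns` channel) can be masked so that rotation
#' artefacts are not reported as steps.
#'
#' @param trace An `mt_trace` or data.frame with columns `time_s` and
#'   `extension_nm` (uniformly sampled).
#' @param min_dwell_s Minimum plateau duration in seconds. Default 3 samples
#'   at the trace's sampling rate.
#' @param acceptance_threshold Minimum counter-fit/fit residual ratio for
#'   accepting any steps. Default 1.3.
#' @param min_step_nm Minimum absolute step size retained, nm. Default 0.
#' @param max_steps Cap on candidate steps; default scales with trace length.
#' @param mask_rotation Drop steps that fall where `magnet_turns` is
#'   changing. Default TRUE.
#' @return An object of class `step_fit` with fields `step_times_s`,
#'   `step_sizes_nm`, `dwell_times_s`, `plateau_levels_nm`,
#'   `plateau_bounds`, `quality` (accepted counter-fit ratio), `n_steps`
#'   and `flag` (`"ok"` or `"too_short"`).
#' @examples
#' sim <- simulate_tcc_trace(sim_config(seed = 2, duration_s = 60,
#'                                      noise_sd_nm = 4),
#'                           tau_tcc_s = 5, min_step_nm = 20)
#' fit <- find_steps(sim$trace)
#' fit$n_steps
#' @export
find_steps <- function(trace, min_dwell_s = NULL, acceptance_threshold = 1.3,
                       min_step_nm = 0, max_steps = NULL,
                       mask_rotation = TRUE) {
  df <- as.data.frame(trace)
  if (!all(c("time_s", "extension_nm") %in% names(df))) {
    stop("trace must have columns 'time_s' and 'extension_nm'", call. = FALSE)
  }
  n <- nrow(df)
  if (n < 2L) stop("trace is empty or has a single sample", call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * stats::median(dt)) {
    stop("trace must be uniformly sampled with increasing time", call. = FALSE)
  }
  dt <- stats::median(dt)
  if (is.null(min_dwell_s)) min_dwell_s <- 3 * dt
  md <- max(1L, as.integer(round(min_dwell_s / dt)))
  if (n < 2L * md) {
    return(new_step_fit(df, integer(0), quality = NA_real_,
                        flag = "too_short"))
  }
  if (is.null(max_steps)) max_steps <- min(2000L, n %/% (2L * md))

  y <- df$extension_nm
  c1 <- c(0, cumsum(y))
  c2 <- c(0, cumsum(y^2))
  sse0 <- .seg_sse(c1, c2, 1L, n)
  tol <- 1e-10 * max(sse0, 1)
  # candidate steps must beat the residual reduction expected from placing
  # the best of ~n splits in pure noise (BIC-style penalty); the noise SD is
  # estimated robustly from first differences, which step transitions barely
  # perturb
  sigma_hat <- stats::mad(diff(y)) / sqrt(2)
  penalty <- max(tol, 2 * sigma_hat^2 * log(n))

  # greedy nested sequence of splits; per-plateau best split is cached
  plateaus <- list(list(i = 1L, j = n, cand = .best_split(c1, c2, 1L, n, md)))
  split_order <- integer(0)
  sse_seq <- numeric(0)
  sse_cur <- sse0
  while (length(split_order) < max_steps) {
    reds <- vapply(plateaus, function(p) {
      if (is.null(p$cand)) -Inf else p$cand$reduction
    }, numeric(1))
    best <- which.max(reds)
    if (!is.finite(reds[best]) || reds[best] <= penalty) break
    p <- plateaus[[best]]
    t <- p$cand$t
    split_order <- c(split_order, t)
    sse_cur <- sse_cur - p$cand$reduction
    sse_seq <- c(sse_seq, sse_cur)
    left <- list(i = p$i, j = t, cand = .best_split(c1, c2, p$i, t, md))
    right <- list(i = t + 1L, j = p$j,
                  cand = .best_split(c1, c2, t + 1L, p$j, md))
    plateaus[[best]] <- left
    plateaus[[length(plateaus) + 1L]] <- right
  }

  k_max <- length(split_order)
  if (k_max == 0L) {
    return(new_step_fit(df, integer(0), quality = NA_real_, flag = "ok"))
  }

  # counter-fit quality for each nested candidate fit
  quality <- vapply(seq_len(k_max), function(k) {
    cf <- .counter_sse(c1, c2, split_order[seq_len(k)], n)
    fs <- sse_seq[k]
    if (fs <= tol) {
      if (cf <= tol) 1 else Inf
    } else {
      cf / fs
    }
  }, numeric(1))
  k_star <- which.max(quality)
  if (quality[k_star] < acceptance_threshold) {
    return(new_step_fit(df, integer(0), quality = max(quality), flag = "ok"))
  }
  splits <- sort(split_order[seq_len(k_star)])

  # mask steps during commanded magnet rotation
  if (mask_rotation && "magnet_turns" %in% names(df)) {
    rotating <- c(FALSE, diff(df$magnet_turns) != 0)
    keep <- !(rotating[splits] | rotating[pmin(splits + 1L, n)])
    splits <- splits[keep]
  }

  # merge steps below the minimum size, smallest first
  if (min_step_nm > 0) {
    repeat {
      if (length(splits) == 0L) break
      bounds <- c(0L, splits, n)
      lev <- vapply(seq_len(length(bounds) - 1L), function(p) {
        mean(y[(bounds[p] + 1L):bounds[p + 1L]])
      }, numeric(1))
      sizes <- diff(lev)
      small <- which.min(abs(sizes))
      if (abs(sizes[small]) >= min_step_nm) break
      splits <- splits[-small]
    }
  }
  new_step_fit(df, splits,
               quality = if (length(splits)) quality[k_star] else NA_real_,
               flag = "ok")
}

# Build the step_fit result from final split indices.
new_step_fit <- function(df, splits, quality, flag) {
  n <- nrow(df)
  y <- df$extension_nm
  bounds <- c(0L, splits, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(p) {
    mean(y[(bounds[p] + 1L):bounds[p + 1L]])
  }, numeric(1))
  step_times <- if (length(splits)) {
    (df$time_s[splits] + df$time_s[splits + 1L]) / 2
  } else {
    numeric(0)
  }
  structure(list(
    step_times_s = step_times,
    step_sizes_nm = if (length(splits)) diff(levels) else numeric(0),
    dwell_times_s = if (length(splits) > 1L) diff(step_times) else numeric(0),
    plateau_levels_nm = levels,
    plateau_bounds = bounds,
    quality = quality,
    n_steps = length(splits),
    flag = flag),
    class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("step fit: %d steps (%s), counter-fit quality %.3g\n",
              x$n_steps, x$flag, x$quality))
  if (x$n_steps > 0) {
    cat(sprintf("  |step| median %.3g nm, dwell median %.3g s\n",
                stats::median(abs(x$step_sizes_nm)),
                if (length(x$dwell_times_s)) stats::median(x$dwell_times_s)
                else NA_real_))
  }
  invisible(x)
}

#' Piecewise-constant reconstruction of a step fit
#'
#' @param fit A `step_fit`.
#' @param trace The trace the fit was computed on.
#' @return Numeric vector of fitted levels, one per trace sample.
#' @export
reconstruct_steps <- function(fit, trace) {
  df <- as.data.frame(trace)
  bounds <- fit$plateau_bounds
  out <- numeric(nrow(df))
  for (p in seq_len(length(bounds) - 1L)) {
    out[(bounds[p] + 1L):bounds[p + 1L]] <- fit$plateau_levels_nm[p]
  }
  out
}

#' Moving-window extension fluctuation sigma_z
#'
#' Sample SD of the extension within a centred sliding window; windows are
#' truncated at the trace edges.
#'
#' @param trace An `mt_trace` or data.frame with `time_s`, `extension_nm`.
#' @param window_s Window length in seconds. Default 0.5.
#' @return A data.frame of class `sigma_series` with columns `time_s` and
#'   `sigma_z_nm`.
#' @examples
#' sim <- simulate_tcc_trace(sim_config(seed = 3, duration_s = 60),
#'                           tau_tcc_s = 4)
#' sz <- rolling_sigma(sim$trace)
#' @export
rolling_sigma <- function(trace, window_s = 0.5) {
  df <- as.data.frame(trace)
  dt <- stats::median(diff(df$time_s))
  w <- as.integer(round(window_s / dt))
  if (w < 2L) stop("window must span at least 2 samples", call. = FALSE)
  if (w > nrow(df)) stop("window longer than the trace", call. = FALSE)
  sig <- zoo::rollapply(df$extension_nm, width = w, FUN = stats::sd,
                        partial = 2, align = "center")
  out <- data.frame(time_s = df$time_s, sigma_z_nm = as.numeric(sig))
  class(out) <- c("sigma_series", "data.frame")
  out
}

#' Step-size magnitudes filtered by direction
#'
#' Extracts the absolute step sizes from a step fit, optionally keeping only
#' upward or downward steps, for downstream distribution fitting.
#'
#' @param fit A `step_fit`.
#' @param direction One of `"both"`, `"up"`, `"down"`.
#' @return Numeric vector of |step size| in nm (possibly empty).
#' @export
detrended_step_sizes <- function(fit, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  s <- fit$step_sizes_nm
  s <- switch(direction,
              both = s,
              up = s[s > 0],
              down = s[s < 0])
  abs(s)
}
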