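# Independent oracles used to freeze expected values in the tests. These
# deliberately re-derive quantities by routes different from the package
# implementation: brute-force enumeration for the step finder and the
# closed-form Bateman solution for the kinetic chain.

# Exhaustive single-step placement: the split index (last sample of the
# left plateau) minimizing the residual sum of squares, ties to the
# earliest index. O(n^2), for toy traces only.
brute_force_best_split <- function(y) {
  n <- length(y)
  sse <- vapply(1:(n - 1), function(t) {
    sum((y[1:t] - mean(y[1:t]))^2) +
      sum((y[(t + 1):n] - mean(y[(t + 1):n]))^2)
  }, numeric(1))
  which.min(sse)
}

# Closed-form full-site fraction of the irreversible linear chain
# T -> C -> H -> F with distinct rates k1, k2, k3 and active-branch
# amplitude f: the three-exponential Bateman solution.
bateman_full_site <- function(f, k1, k2, k3, t) {
  stopifnot(length(unique(c(k1, k2, k3))) == 3)
  f * (1 -
         k2 * k3 / ((k2 - k1) * (k3 - k1)) * exp(-k1 * t) -
         k1 * k3 / ((k1 - k2) * (k3 - k2)) * exp(-k2 * t) -
         k1 * k2 / ((k1 - k3) * (k2 - k3)) * exp(-k3 * t))
}

# Wrapped-normal sample on the circle (degrees), for angle-statistics
# recovery checks.
rwrapped_normal_deg <- function(n, mean_deg, sd_deg) {
  (stats::rnorm(n, mean_deg, sd_deg)) %% 360
}

# Score a step fit against ground-truth step times: fraction of true steps
# recovered and fraction of reported steps with no true counterpart.
score_step_recovery <- function(fit, true_times, tol_s) {
  recovered <- vapply(true_times, function(t) {
    any(abs(fit$step_times_s - t) <= tol_s)
  }, logical(1))
  spurious <- if (fit$n_steps == 0) logical(0) else {
    vapply(fit$step_times_s, function(t) {
      !any(abs(true_times - t) <= tol_s)
    }, logical(1))
  }
  list(recovery = mean(recovered),
       false_rate = if (length(spurious)) mean(spurious) else 0,
       n_true = length(true_times), n_found = fit$n_steps)
}
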