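# Statistics on AFM-derived particle measurements: topology classification
# by self-crossing number, count-fraction errors and two-proportion tests,
# circular statistics of DNA entry/exit angles, and the confusion matrix of
# the crossing-number classifier on labelled data.

#' Classify plasmid topology from the self-crossing number
#'
#' Open-circular plasmids lie flat and show few self-crossings; negatively
#' supercoiled plasmids are interwound and show many. A molecule is called
#' open circular when `n_crossings <= threshold` and covalently closed
#' (supercoiled) otherwise.
#'
#' @param n_crossings Non-negative integer crossing counts (vectorized).
#' @param threshold Classification threshold. Default 6 (inclusive).
#' @return Character vector, `"open_circular"` or `"covalently_closed"`.
#' @examples
#' classify_topology(c(0, 6, 7, 15))
#' @export
classify_topology <- function(n_crossings, threshold = 6) {
  if (any(!is.finite(n_crossings)) || any(n_crossings < 0)) {
    stop("crossing counts must be finite and non-negative", call. = FALSE)
  }
  ifelse(n_crossings <= threshold, "open_circular", "covalently_closed")
}

#' Count fraction with Poisson counting error
#'
#' Fraction `k / n_tot` of molecules in a category, with the counting error
#' `sqrt(k) / n_tot` used in AFM census plots (the Poisson error on the
#' category count).
#'
#' @param k Category count, `0 <= k <= n_tot`.
#' @param n_tot Total count, `>= 1`.
#' @return A list with `fraction` and `error`.
#' @examples
#' fraction_with_counting_error(100, 400) # 0.25 +/- 0.025
#' @export
fraction_with_counting_error <- function(k, n_tot) {
  if (n_tot < 1) stop("'n_tot' must be >= 1", call. = FALSE)
  if (k < 0 || k > n_tot) {
    stop("'k' must lie in [0, n_tot]", call. = FALSE)
  }
  list(fraction = k / n_tot, error = sqrt(k) / n_tot)
}

#' Compare two count fractions
#'
#' Two-proportion comparison of `k1/n1` versus `k2/n2`. Fisher's exact test
#' is used when any expected cell count is below 5 (and by default, since
#' the AFM censuses are small); otherwise the normal-approximation
#' two-proportion test.
#'
#' @param k1,n1 Count and total of the first sample.
#' @param k2,n2 Count and total of the second sample.
#' @param exact Force Fisher's exact test. Default TRUE.
#' @return A list with `p_value`, `method`, and the two fractions.
#' @examples
#' compare_fractions(71, 100, 0, 214)
#' @export
compare_fractions <- function(k1, n1, k2, n2, exact = TRUE) {
  if (n1 < 1 || n2 < 1) stop("totals must be >= 1", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("counts must lie in [0, n]", call. = FALSE)
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- exact || any(expected < 5)
  if (use_fisher) {
    p <- stats::fisher.test(tab)$p.value
    method <- "fisher"
  } else {
    p <- suppressWarnings(
      stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE))$p.value
    method <- "two-proportion"
  }
  list(p_value = p, method = method,
       fraction1 = k1 / n1, fraction2 = k2 / n2)
}

#' Circular statistics of DNA entry/exit angles
#'
#' Vector-mean circular statistics of angles measured relative to the
#' intasome long axis: the circular mean, the circular SD
#' `sqrt(-2 ln R)` (with `R` the mean resultant length), the standard error
#' of the mean direction, and per-mode occupancies with `sqrt(k)/n`
#' counting errors. All statistics are invariant under adding multiples of
#' 360 degrees to any observation.
#'
#' @param angles_deg Angles in degrees.
#' @param mode_label Optional binding-mode label per angle (e.g. `"apical"`
#'   or `"longitudinal"`).
#' @param fold_180 Fold angles to \[0, 180) before averaging, appropriate
#'   when the reference axis is orientation-free. Default FALSE.
#' @return A list with `mean_deg`, `circ_sd_deg`, `se_mean_deg`, `R`, `n`,
#'   and `occupancy` (data.frame per mode, or NULL).
#' @examples
#' angle_statistics(c(350, 10)) # mean 0, not 180
#' @export
angle_statistics <- function(angles_deg, mode_label = NULL,
                             fold_180 = FALSE) {
  if (length(angles_deg) == 0 || any(!is.finite(angles_deg))) {
    stop("angles must be non-empty and finite", call. = FALSE)
  }
  a <- angles_deg %% 360
  period <- 360
  if (fold_180) {
    a <- a %% 180
    period <- 180
  }
  th <- 2 * pi * a / period
  C <- mean(cos(th))
  S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  mean_th <- atan2(S, C) %% (2 * pi)
  mean_deg <- mean_th * period / (2 * pi)
  if (period - mean_deg < 1e-9) mean_deg <- 0  # guard the 360-degree wrap
  circ_sd <- if (R > 0) sqrt(-2 * log(R)) * period / (2 * pi) else Inf
  n <- length(a)
  se_mean <- if (R > 0) circ_sd / sqrt(n) else Inf
  occupancy <- NULL
  if (!is.null(mode_label)) {
    tab <- table(mode_label)
    occupancy <- data.frame(mode = names(tab),
                            k = as.integer(tab),
                            fraction = as.numeric(tab) / n,
                            error = sqrt(as.numeric(tab)) / n)
    rownames(occupancy) <- NULL
  }
  list(mean_deg = mean_deg, circ_sd_deg = circ_sd, se_mean_deg = se_mean,
       R = R, n = n, occupancy = occupancy)
}

#' Confusion matrix of the crossing-number topology classifier
#'
#' Applies [classify_topology()] to a labelled particle table and tabulates
#' misassignment rates per true class.
#'
#' @param table Data.frame with columns `n_crossings` and `true_class`
#'   (values `"open_circular"` / `"supercoiled"`).
#' @param threshold Classification threshold passed to
#'   [classify_topology()].
#' @return A list with `confusion` (2x2 table of truth vs call),
#'   `error_open_circular` and `error_supercoiled` (misassignment rates).
#' @export
classification_error_rates <- function(table, threshold = 6) {
  df <- as.data.frame(table)
  if (nrow(df) == 0) stop("empty particle table", call. = FALSE)
  if (!all(c("n_crossings", "true_class") %in% names(df))) {
    stop("need columns 'n_crossings' and 'true_class'", call. = FALSE)
  }
  if (any(is.na(df$true_class))) {
    stop("missing truth labels", call. = FALSE)
  }
  call <- classify_topology(df$n_crossings, threshold)
  truth <- df$true_class
  conf <- table(truth = truth, call = call)
  err_oc <- if ("open_circular" %in% truth) {
    mean(call[truth == "open_circular"] != "open_circular")
  } else {
    NA_real_
  }
  err_sc <- if ("supercoiled" %in% truth) {
    mean(call[truth == "supercoiled"] != "covalently_closed")
  } else {
    NA_real_
  }
  list(confusion = conf, error_open_circular = err_oc,
       error_supercoiled = err_sc)
}
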