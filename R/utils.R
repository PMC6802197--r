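# Internal helpers shared across modules.

# Boltzmann constant in pN nm / K
.kB_pN_nm <- 0.0138064852

#' Thermal energy in piconewton-nanometres
#'
#' @param temperature_K Absolute temperature in kelvin.
#' @return kBT in pN nm.
#' @examples
#' kBT_pN_nm(298) # ~4.11 pN nm
#' @export
kBT_pN_nm <- function(temperature_K) {
  check_temperature(temperature_K)
  .kB_pN_nm * temperature_K
}

check_temperature <- function(temperature_K) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K < 250 || temperature_K > 400) {
    stop("temperature must be a single finite value in [250, 400] K",
         call. = FALSE)
  }
  invisible(temperature_K)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single finite positive number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("'%s' must be a single finite non-negative number", name),
         call. = FALSE)
  }
  invisible(x)
}

deg2rad <- function(deg) deg * pi / 180

# Derive a reproducible stream of sub-seeds from one master seed, staying
# within 32-bit integer range.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
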