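#' Decompose association/dissociation rates into microscopic and diffusional parts
#'
#' A macroscopic (observed) association rate constant `a` is the series
#' combination of the intrinsic (microscopic) rate `k_a` and the rate due to
#' diffusional encounter `k_D`:
#' \deqn{1/a = 1/k_a + 1/k_D,}
#' so that \eqn{a = k_a / (1 + \gamma)} with the degree of diffusion control
#' \eqn{\gamma = k_a / k_D}. The corresponding dissociation constant scales the
#' same way, \eqn{d = k_d / (1 + \gamma)}. A reaction with \eqn{\gamma \gg 1}
#' is diffusion limited (\eqn{a \approx k_D}); with \eqn{\gamma \ll 1} it is
#' limited by the intrinsic chemistry (\eqn{a \approx k_a}).
#'
#' Units are fixed throughout the kinetics functions of this package:
#' association rates in nM^-1 s^-1, first-order rates in s^-1,
#' concentrations in nM.
#'
#' @param k_a intrinsic association rate constant (nM^-1 s^-1), > 0
#' @param k_d intrinsic dissociation rate constant (s^-1), > 0
#' @param gamma degree of diffusion control, >= 0; `gamma = 0` encodes the
#'   purely reaction-limited case `k_D = Inf`
#' @return an object of class `rate_decomposition`: a list with fields
#'   `k_a`, `k_d`, `k_D` (possibly `Inf`), `gamma`, `a`, `d`
#' @seealso [micro_from_macroscopic()], [michaelis_constant()]
#' @examples
#' macroscopic_from_micro(k_a = 0.027, k_d = 1.35, gamma = 1)
#' @export
macroscopic_from_micro <- function(k_a, k_d, gamma) {
  stopifnot(is.numeric(k_a), is.numeric(k_d), is.numeric(gamma),
            length(k_a) == 1L, length(k_d) == 1L, length(gamma) == 1L)
  if (!is.finite(k_a) || k_a <= 0) stop("'k_a' must be a finite positive number")
  if (!is.finite(k_d) || k_d <= 0) stop("'k_d' must be a finite positive number")
  if (is.na(gamma) || gamma < 0) stop("'gamma' must be >= 0")
  k_D <- if (gamma == 0) Inf else k_a / gamma
  new_rate_decomposition(
    k_a = k_a, k_d = k_d, k_D = k_D, gamma = gamma,
    a = k_a / (1 + gamma), d = k_d / (1 + gamma)
  )
}

#' Recover microscopic rate constants from macroscopic ones
#'
#' Inverse of [macroscopic_from_micro()]: given the observed rates and the
#' degree of diffusion control, the intrinsic constants are
#' \eqn{k_a = a(1+\gamma)} and \eqn{k_d = d(1+\gamma)}.
#'
#' @param a macroscopic association rate constant (nM^-1 s^-1), > 0
#' @param d macroscopic dissociation rate constant (s^-1), > 0
#' @inheritParams macroscopic_from_micro
#' @return a `rate_decomposition` (see [macroscopic_from_micro()])
#' @export
micro_from_macroscopic <- function(a, d, gamma) {
  stopifnot(is.numeric(a), is.numeric(d), is.numeric(gamma),
            length(a) == 1L, length(d) == 1L, length(gamma) == 1L)
  if (!is.finite(a) || a <= 0) stop("'a' must be a finite positive number")
  if (!is.finite(d) || d <= 0) stop("'d' must be a finite positive number")
  if (is.na(gamma) || gamma < 0) stop("'gamma' must be >= 0")
  k_a <- a * (1 + gamma)
  new_rate_decomposition(
    k_a = k_a, k_d = d * (1 + gamma),
    k_D = if (gamma == 0) Inf else k_a / gamma,
    gamma = gamma, a = a, d = d
  )
}

new_rate_decomposition <- function(k_a, k_d, k_D, gamma, a, d) {
  structure(list(k_a = k_a, k_d = k_d, k_D = k_D, gamma = gamma, a = a, d = d),
            class = "rate_decomposition")
}

#' @export
print.rate_decomposition <- function(x, ...) {
  cat("Rate decomposition (nM^-1 s^-1 / s^-1):\n")
  cat(sprintf("  microscopic : k_a = %g, k_d = %g\n", x$k_a, x$k_d))
  cat(sprintf("  diffusional : k_D = %g  (gamma = %g)\n", x$k_D, x$gamma))
  cat(sprintf("  macroscopic : a = %g, d = %g\n", x$a, x$d))
  invisible(x)
}

#' Michaelis constant of a binding/turnover cycle
#'
#' \eqn{K_M = (k_{cat} + d) / a} for the cycle
#' E + S <-> ES -> E + P with association `a`, dissociation `d` and turnover
#' `k_cat`. The concentration at which the cycle runs at half its maximal
#' velocity.
#'
#' @param a association rate constant (nM^-1 s^-1), > 0
#' @param d dissociation rate constant (s^-1), >= 0
#' @param k_cat turnover number (s^-1), >= 0
#' @return the Michaelis constant in nM
#' @export
michaelis_constant <- function(a, d, k_cat) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a finite positive number")
  if (d < 0 || k_cat < 0) stop("'d' and 'k_cat' must be >= 0")
  (k_cat + d) / a
}
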