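km1 <- function(p) michaelis_constant(p$a1, p$d1, p$k1)
km2 <- function(p) michaelis_constant(p$a2, p$d2, p$k2)
kmch <- function(p) michaelis_constant(p$a_ch, p$d_ch, p$k1_ch)

#' Steady-state production velocity of the fully channeled system
#'
#' For the cycle S + E12 <-> SE12 -> IE12 -> E12I -> E12 + P with a single
#' metabolite in the complex at a time, the steady flux through the
#' four-state cycle is
#' \deqn{v_{ch} = \frac{k_1 k_{ch} k_2 [S] [E_{12}]}
#'   {k_{ch} k_2 K_M^{ch} + [S](k_{ch} k_2 + k_1 k_2 + k_1 k_{ch})},}
#' with \eqn{K_M^{ch} = (k_1 + d_{ch})/a_{ch}} (here \eqn{k_1, k_2} are the
#' complex turnovers `k1_ch`, `k2_ch`). Its saturation limit is the harmonic
#' combination \eqn{(1/k_1 + 1/k_{ch} + 1/k_2)^{-1} [E_{12}]}: the complex
#' processes metabolites strictly in series.
#'
#' @param params a [cascade_params()] object with `E12_tot > 0`
#' @param S substrate concentration (nM), vectorised
#' @return production velocity in nM/s
#' @export
v_channeled <- function(params, S) {
  if (any(S < 0)) stop("'S' must be >= 0")
  p <- params
  KM <- kmch(p)
  num <- p$k1_ch * p$k_ch * p$k2_ch * S * p$E12_tot
  den <- p$k_ch * p$k2_ch * KM +
    S * (p$k_ch * p$k2_ch + p$k1_ch * p$k2_ch + p$k1_ch * p$k_ch)
  num / den
}

#' Steady-state velocity of the non-channeled cascade
#'
#' Below the threshold substrate concentration (see [s_threshold()]) the
#' first reaction is rate limiting, the intermediate pool is finite, and
#' \deqn{v_{non} = k_1 [S] [E_1] / (K_M^{(1)} + [S]).}
#' Above it the first enzyme outruns the second: the intermediate pool grows
#' without bound, the second enzyme saturates, and the velocity settles at
#' \eqn{k_2 [E_2]}.
#'
#' @inheritParams v_channeled
#' @return a `steady_state_result` list: `v` (nM/s), `I_ss` (nM, `Inf` in the
#'   diverging regime), `regime` (`"first-limiting"` or `"diverging"`), and
#'   `S_threshold`
#' @export
v_nonchanneled <- function(params, S) {
  if (length(S) != 1L || S < 0) stop("'S' must be a single value >= 0")
  p <- params
  S_th <- s_threshold(p)
  if (S < S_th) {
    v <- p$k1 * S * p$E1_tot / (km1(p) + S)
    I_ss <- iss_mixed(p, S, x_ch = 0)
    regime <- "first-limiting"
  } else {
    v <- p$k2 * p$E2_tot
    I_ss <- Inf
    regime <- "diverging"
  }
  structure(list(v = v, I_ss = I_ss, regime = regime, S_threshold = S_th),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("Steady state: v = %g nM/s, I_ss = %g nM, regime = %s (S_threshold = %g nM)\n",
              x$v, x$I_ss, x$regime, x$S_threshold))
  invisible(x)
}

#' Substrate threshold for intermediate-pool divergence
#'
#' The borderline between the first-reaction-limited regime (finite
#' intermediate pool) and the regime in which the intermediate accumulates
#' without bound:
#' \deqn{[S]_{th} = \frac{K_M^{(1)} k_2 [E_2]}{k_1 [E_1] - k_2 [E_2]},}
#' infinite when \eqn{k_1 [E_1] \le k_2 [E_2]} (the second enzyme can always
#' keep up).
#'
#' @inheritParams v_channeled
#' @return threshold in nM, possibly `Inf`
#' @export
s_threshold <- function(params) {
  p <- params
  excess <- p$k1 * p$E1_tot - p$k2 * p$E2_tot
  if (excess <= 0) return(Inf)
  km1(p) * p$k2 * p$E2_tot / excess
}

#' Saturation (maximal) velocities
#'
#' At saturating substrate the non-channeled cascade runs at
#' \eqn{k_1 [E_1]} (first reaction limiting), the single-occupancy channeled
#' system at the harmonic-sum rate
#' \eqn{(1/k_1 + 1/k_{ch} + 1/k_2)^{-1} [E_{12}]}, and the two-occupancy
#' extension at \eqn{k_2 k_{ch} [E_{12}]/(k_2 + k_{ch})}. Since the harmonic
#' sum is strictly below \eqn{k_1}, a channeled reaction with
#' \eqn{[E_{12}] = [E_1]} can never beat the non-channeled one in
#' saturation.
#'
#' @inheritParams v_channeled
#' @return named numeric vector `c(v_non_max, v_ch_max, v_ch_max_two_site)`
#' @export
v_max <- function(params) {
  p <- params
  c(v_non_max = p$k1 * p$E1_tot,
    v_ch_max = 1 / (1 / p$k1_ch + 1 / p$k_ch + 1 / p$k2_ch) * p$E12_tot,
    v_ch_max_two_site = p$k2_ch * p$k_ch * p$E12_tot / (p$k2_ch + p$k_ch))
}

#' First-order (low-substrate) velocities
#'
#' At \eqn{[S]} far below both Michaelis constants the velocities reduce to
#' \eqn{v_{non} = k_1 [E_1] [S]/K_M^{(1)}} and
#' \eqn{v_{ch} = k_1 [E_{12}] [S]/K_M^{ch}}: whether channeling accelerates
#' the cascade at low substrate is decided purely by the ratio
#' \eqn{K_M^{ch}/K_M^{(1)}}, i.e. by whether complex formation lowers the
#' degree of diffusion control. No range check is enforced; the caller is
#' responsible for `S` being small.
#'
#' @inheritParams v_channeled
#' @return named vector `c(v_non, v_ch)` in nM/s
#' @export
low_s_velocities <- function(params, S) {
  p <- params
  c(v_non = p$k1 * p$E1_tot * S / km1(p),
    v_ch = p$k1_ch * p$E12_tot * S / kmch(p))
}

#' Steady intermediate pool of the mixed system
#'
#' In a system containing both free enzymes and complexes, the bulk
#' intermediate is produced and consumed only by the free enzymes (the
#' complex channels internally), so the steady pool is
#' \deqn{[I]_{ss} = \frac{K_M^{(2)}}{K_M^{(1)}}
#'   \frac{k_1 [E_1]_0}{k_2 [E_2]_0}
#'   [S] \frac{[S]_{th}}{[S]_{th} - [S]},}
#' with the single-enzyme totals \eqn{[E_i]_0 = [E_i] - [E_{12}]} and the
#' threshold evaluated at these totals. The degree of channeling is
#' \eqn{x_{ch} = [E_{12}]/\min([E_1],[E_2])}. Differentiating under the
#' constraint \eqn{k_1[E_1] = k_2[E_2]} shows the pool grows with channeling
#' when the first enzyme is more abundant (\eqn{[E_1] > [E_2]}), shrinks when
#' it is scarcer, and is exactly flat when \eqn{[E_1] = [E_2]}.
#'
#' @inheritParams v_channeled
#' @param S substrate concentration (nM), single value
#' @param x_ch degree of channeling in `[0, 1)`; the complex concentration is
#'   `x_ch * min(E1_tot, E2_tot)` and is subtracted from both enzyme totals
#' @return steady intermediate concentration in nM, `Inf` when `S` is at or
#'   above the free-enzyme threshold
#' @export
iss_mixed <- function(params, S, x_ch) {
  p <- params
  if (x_ch < 0 || x_ch >= 1) stop("'x_ch' must lie in [0, 1)")
  if (S < 0) stop("'S' must be >= 0")
  E12 <- x_ch * min(p$E1_tot, p$E2_tot)
  E10 <- p$E1_tot - E12
  E20 <- p$E2_tot - E12
  if (E20 <= 0 || E10 <= 0) {
    if (S == 0) return(0)
    # no free second enzyme left to consume the intermediate
    if (E10 > 0) return(Inf)
    return(0)
  }
  den <- km1(p) * p$k2 * E20 - S * (p$k1 * E10 - p$k2 * E20)
  if (den <= 0) return(Inf)
  km2(p) * p$k1 * E10 * S / den
}

#' Steady state with intermediate degradation
#'
#' With a first-order loss `k_deg [I]` added to the intermediate balance, the
#' steady pool solves
#' \deqn{v_{non}^{(0)} - \frac{k_2 [I]_{ss} [E_2]}{K_M^{(2)} + [I]_{ss}}
#'   - k_{deg} [I]_{ss} = 0,}
#' a quadratic in \eqn{[I]_{ss}} with a unique non-negative root
#' (\eqn{v_{non}^{(0)}} is the velocity without degradation). The production
#' velocity is then \eqn{v_{non} = v_{non}^{(0)} - k_{deg}[I]_{ss}}: whatever
#' degrades never becomes product. The channeled system is untouched by
#' `k_deg` since its intermediates are never released into the bulk.
#'
#' @inheritParams iss_mixed
#' @param k_deg degradation rate (s^-1), >= 0
#' @return list with `I_ss` (nM), `v_non` (nM/s), and the residual of the
#'   steady-state balance
#' @export
solve_degradation <- function(params, S, k_deg) {
  p <- params
  if (k_deg < 0) stop("'k_deg' must be >= 0")
  KM2 <- km2(p)
  v0 <- p$k1 * S * p$E1_tot / (km1(p) + S)
  if (k_deg == 0) {
    res <- v_nonchanneled(p, S)
    return(list(I_ss = res$I_ss, v_non = res$v, residual = 0))
  }
  # k_deg I^2 + (k2 E2 + k_deg KM2 - v0) I - v0 KM2 = 0
  b <- p$k2 * p$E2_tot + k_deg * KM2 - v0
  cc <- -v0 * KM2
  disc <- b^2 - 4 * k_deg * cc
  I_ss <- if (b >= 0) {
    # numerically stable form avoiding cancellation
    2 * (-cc) / (b + sqrt(disc))
  } else {
    (-b + sqrt(disc)) / (2 * k_deg)
  }
  resid <- v0 - p$k2 * I_ss * p$E2_tot / (KM2 + I_ss) - k_deg * I_ss
  list(I_ss = I_ss, v_non = v0 - k_deg * I_ss, residual = resid)
}

#' Steady state with a reversible first reaction
#'
#' When the first enzyme also catalyses the back reaction
#' E1 + I -> SE1 (rate `kbar1`), the production velocity and the
#' intermediate pool solve the simultaneous pair
#' \deqn{v = \frac{k_2 [E_2] [I]_{ss}}{K_M^{(2)} + [I]_{ss}}, \qquad
#'  v = \frac{[E_1]}{1 + [S]/K_M^{(1)} + [I]_{ss}/\bar K_M^{(1)}}
#'      \left(\frac{k_1 [S]}{K_M^{(1)}}
#'          - \frac{d_1 [I]_{ss}}{\bar K_M^{(1)}}\right),}
#' with \eqn{\bar K_M^{(1)} = (k_1 + d_1)/\bar k_1}. The net forward flux of
#' the first reaction falls as the intermediate builds up, so the velocity
#' decreases monotonically with the degree of reversibility
#' \eqn{\bar k_1/a_1}. Solved by bracketed root finding on \eqn{[I]_{ss}}
#' (the bracket end is the pool at which the net forward flux vanishes),
#' followed by a Newton polish.
#'
#' @inheritParams iss_mixed
#' @param kbar1 reverse association rate of the first reaction
#'   (nM^-1 s^-1), >= 0
#' @return list with `I_ss` (nM), `v_non` (nM/s), and the residual of the
#'   matched pair of equations
#' @export
solve_reversible <- function(params, S, kbar1) {
  p <- params
  if (kbar1 < 0) stop("'kbar1' must be >= 0")
  if (kbar1 == 0) {
    res <- v_nonchanneled(p, S)
    return(list(I_ss = res$I_ss, v_non = res$v, residual = 0))
  }
  KM1 <- km1(p); KM2 <- km2(p)
  KM1bar <- (p$k1 + p$d1) / kbar1
  v_fwd <- function(I) {
    p$E1_tot / (1 + S / KM1 + I / KM1bar) *
      (p$k1 * S / KM1 - p$d1 * I / KM1bar)
  }
  v_2nd <- function(I) p$k2 * p$E2_tot * I / (KM2 + I)
  f <- function(I) v_fwd(I) - v_2nd(I)
  # the forward flux crosses zero at I_zero; the root lies in (0, I_zero)
  if (p$d1 > 0) {
    I_zero <- p$k1 * S * KM1bar / (KM1 * p$d1)
  } else {
    # irreversible unbinding: forward flux never reverses; bracket by doubling
    I_zero <- KM2
    while (f(I_zero) > 0) I_zero <- I_zero * 10
  }
  if (S == 0) return(list(I_ss = 0, v_non = 0, residual = 0))
  sol <- stats::uniroot(f, lower = 0, upper = I_zero, tol = 1e-14 * I_zero)
  I_ss <- sol$root
  # one Newton polish on the residual
  h <- max(I_ss, 1) * 1e-7
  fp <- (f(I_ss + h) - f(I_ss - h)) / (2 * h)
  if (is.finite(fp) && fp != 0) {
    I_new <- I_ss - f(I_ss) / fp
    if (I_new > 0 && I_new < I_zero && abs(f(I_new)) <= abs(f(I_ss)))
      I_ss <- I_new
  }
  list(I_ss = I_ss, v_non = v_2nd(I_ss), residual = f(I_ss))
}
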