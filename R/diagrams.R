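#' Build a cascade parameter set from microscopic constants and gammas
#'
#' Applies the rate decomposition per reaction: each association constant is
#' split into its intrinsic part and the diffusional encounter rate, so the
#' macroscopic constants are \eqn{a = k_a/(1+\gamma)},
#' \eqn{d = k_d/(1+\gamma)} with the reaction's own degree of diffusion
#' control \eqn{\gamma}. The microscopic constants are shared between the
#' channeled and non-channeled reactions: complex formation is allowed to
#' change only the diffusional encounter rate, never the intrinsic
#' chemistry.
#'
#' @param k_a,k_d shared microscopic association (nM^-1 s^-1) and
#'   dissociation (s^-1) constants
#' @param k1,k2 turnover numbers of the two reactions (s^-1); the complex
#'   inherits them
#' @param k_ch channeling rate (s^-1)
#' @param gamma_1,gamma_2,gamma_ch degrees of diffusion control of the first
#'   reaction, the second reaction, and the complex
#' @param E1_tot,E2_tot,E12_tot totals (nM)
#' @param ... further arguments passed to [cascade_params()] (e.g. `k_deg`,
#'   `kbar1`, `two_site`)
#' @return a [cascade_params()] object
#' @export
params_from_micro <- function(k_a, k_d, k1, k2, k_ch,
                              gamma_1 = 1, gamma_2 = 1, gamma_ch = 1,
                              E1_tot = 0, E2_tot = 0, E12_tot = 0, ...) {
  r1 <- macroscopic_from_micro(k_a, k_d, gamma_1)
  r2 <- macroscopic_from_micro(k_a, k_d, gamma_2)
  rch <- macroscopic_from_micro(k_a, k_d, gamma_ch)
  cascade_params(a1 = r1$a, d1 = r1$d, k1 = k1,
                 a2 = r2$a, d2 = r2$d, k2 = k2,
                 a_ch = rch$a, d_ch = rch$d, k_ch = k_ch,
                 E1_tot = E1_tot, E2_tot = E2_tot, E12_tot = E12_tot, ...)
}

new_demarcation_curve <- function(df, meta) {
  structure(df, class = c("demarcation_curve", "data.frame"), meta = meta)
}

#' @export
print.demarcation_curve <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Demarcation curve '%s' (%d points)\n",
              meta$kind, nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Steady-state channeling demarcation curve
#'
#' For each substrate level, the degree of diffusion control of the complex
#' at which the channeled and non-channeled steady velocities coincide:
#' below the curve channeling accelerates the cascade, above it decelerates.
#' The velocities share the microscopic constants; only the gammas differ.
#' The root is searched in `log10(gamma_ch)` over \[-6, 6\]; outside that
#' range the point is flagged `"ch-slower"` (channeling slower for every
#' physically sensible gamma) or `"ch-faster"`.
#'
#' @param micro list with shared microscopic constants `k_a`, `k_d` and the
#'   turnovers `k1`, `k2`, `k_ch` (see [params_from_micro()])
#' @param gamma_1 degree of diffusion control of the first free reaction
#'   (the second reaction plays no role below the threshold); `gamma_2`
#'   defaults to `gamma_1`
#' @param S_grid substrate grid (nM), strictly increasing
#' @param E_tot common total concentration used for both systems
#'   (`E1 = E2 = E12 = E_tot`), nM
#' @param gamma_2 degree of diffusion control of the second reaction
#' @return a `demarcation_curve` data.frame with columns `S`, `gamma_ch`
#'   (NA when flagged), `ratio` (`gamma_ch/gamma_1`), `flag`
#' @export
steady_demarcation <- function(micro, gamma_1, S_grid, E_tot = 50,
                               gamma_2 = gamma_1) {
  stopifnot(all(diff(S_grid) > 0))
  mk <- function(gch) params_from_micro(micro$k_a, micro$k_d, micro$k1,
                                        micro$k2, micro$k_ch,
                                        gamma_1 = gamma_1, gamma_2 = gamma_2,
                                        gamma_ch = gch,
                                        E1_tot = E_tot, E2_tot = E_tot,
                                        E12_tot = E_tot)
  res <- lapply(S_grid, function(S) {
    v_non <- v_nonchanneled(mk(1), S)$v  # gamma_ch irrelevant to v_non
    f <- function(lg) v_channeled(mk(10^lg), S) - v_non
    flo <- f(-6); fhi <- f(6)
    if (flo < 0) return(c(NA_real_, 1))   # slower even at gamma_ch -> 0
    if (fhi > 0) return(c(NA_real_, 2))   # faster even at gamma_ch = 1e6
    r <- stats::uniroot(f, c(-6, 6), tol = 1e-12)
    c(10^r$root, 0)
  })
  res <- do.call(rbind, res)
  new_demarcation_curve(
    data.frame(S = S_grid, gamma_ch = res[, 1],
               ratio = res[, 1] / gamma_1,
               flag = c("crossing", "ch-slower", "ch-faster")[res[, 2] + 1]),
    meta = list(kind = "steady", micro = micro, gamma_1 = gamma_1,
                E_tot = E_tot))
}

#' Maximum substrate concentration at which channeling can still accelerate
#'
#' The most favorable channeled system is the reaction-limited one
#' (`gamma_ch = 0`, diffusional rate infinite). The substrate level at which
#' even this system only matches the non-channeled velocity bounds the
#' acceleration region: above it, channeling decelerates the cascade
#' regardless of `gamma_ch`. Increases with `gamma_1` (a more
#' diffusion-limited free cascade is easier to beat).
#'
#' @inheritParams steady_demarcation
#' @return substrate concentration in nM
#' @export
s_max <- function(micro, gamma_1, E_tot = 50, gamma_2 = gamma_1) {
  p_ch <- params_from_micro(micro$k_a, micro$k_d, micro$k1, micro$k2,
                            micro$k_ch, gamma_1 = gamma_1, gamma_2 = gamma_2,
                            gamma_ch = 0, E1_tot = E_tot, E2_tot = E_tot,
                            E12_tot = E_tot)
  f <- function(lgS) {
    S <- 10^lgS
    v_channeled(p_ch, S) - v_nonchanneled(p_ch, S)$v
  }
  lo <- -6
  if (f(lo) <= 0)
    stop("channeling not favorable even at the lowest substrate level; no s_max")
  hi <- 2
  while (f(hi) > 0 && hi < 12) hi <- hi + 1
  if (f(hi) > 0) stop("no crossing found below S = 1e12 nM")
  10^stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Batch-reactor channeling demarcation curve
#'
#' For each initial substrate dose, the `gamma_ch/gamma_1` ratio at which the
#' channeled and the non-channeled batch systems need equal times to convert
#' the fraction `alpha` of the dose into product. Both times come from the
#' integrated ODE systems (pure channeled: `E12 = E_tot`; pure
#' non-channeled: `E1 = E2 = E_tot`). The favorable region shrinks as
#' `alpha` grows: a late comparison point weighs the steady-state
#' disadvantage of channeling more heavily than its head start.
#'
#' @inheritParams steady_demarcation
#' @param alpha product fraction used for the time comparison, in (0, 1)
#' @param S0_grid initial substrate dose grid (nM), strictly increasing
#' @return a `demarcation_curve` with columns `S0`, `gamma_ch`, `ratio`,
#'   `flag`
#' @export
batch_demarcation <- function(micro, gamma_1, alpha, S0_grid, E_tot = 50,
                              gamma_2 = gamma_1) {
  stopifnot(all(diff(S0_grid) > 0), alpha > 0, alpha < 1)
  p_non <- params_from_micro(micro$k_a, micro$k_d, micro$k1, micro$k2,
                             micro$k_ch, gamma_1 = gamma_1,
                             gamma_2 = gamma_2, gamma_ch = 1,
                             E1_tot = E_tot, E2_tot = E_tot, E12_tot = 0)
  mk_ch <- function(gch) params_from_micro(micro$k_a, micro$k_d, micro$k1,
                                           micro$k2, micro$k_ch,
                                           gamma_1 = gamma_1,
                                           gamma_2 = gamma_2, gamma_ch = gch,
                                           E1_tot = 0, E2_tot = 0,
                                           E12_tot = E_tot)
  res <- lapply(S0_grid, function(S0) {
    t_non <- time_to_product_fraction(p_non, S0, alpha)
    f <- function(lg) time_to_product_fraction(mk_ch(10^lg), S0, alpha) - t_non
    flo <- f(-6); fhi <- f(6)
    if (flo > 0) return(c(NA_real_, 1))   # channeled slower everywhere
    if (fhi < 0) return(c(NA_real_, 2))   # channeled faster everywhere
    r <- stats::uniroot(f, c(-6, 6), tol = 1e-10)
    c(10^r$root, 0)
  })
  res <- do.call(rbind, res)
  new_demarcation_curve(
    data.frame(S0 = S0_grid, gamma_ch = res[, 1],
               ratio = res[, 1] / gamma_1,
               flag = c("crossing", "ch-slower", "ch-faster")[res[, 2] + 1]),
    meta = list(kind = "batch", micro = micro, gamma_1 = gamma_1,
                alpha = alpha, E_tot = E_tot))
}

#' Intermediate pool size along the degree of channeling
#'
#' Evaluates the steady pool [iss_mixed()] along a grid of the degree of
#' channeling at fixed substrate. Divergent points (pool unbounded) are
#' flagged.
#'
#' @inheritParams iss_mixed
#' @param x_ch_grid grid of degrees of channeling in `[0, 1)`, strictly
#'   increasing
#' @return a `demarcation_curve` with columns `x_ch`, `I_ss`, `flag`
#' @export
pool_size_curve <- function(params, S, x_ch_grid) {
  stopifnot(all(diff(x_ch_grid) > 0))
  I <- vapply(x_ch_grid, function(x) iss_mixed(params, S, x), numeric(1))
  new_demarcation_curve(
    data.frame(x_ch = x_ch_grid, I_ss = I,
               flag = ifelse(is.finite(I), "finite", "diverging")),
    meta = list(kind = "pool", params = params, S = S))
}

#' Velocity sweeps over degradation and reversibility
#'
#' `degradation_sweep` tabulates the non-channeled velocity from
#' [solve_degradation()] along a grid of degradation rates, against the
#' (constant) channeled velocity, and locates the crossing where the
#' channeled system becomes the faster one. `reversibility_sweep` does the
#' same along a grid of reverse rates `kbar1` (abscissa reported as the
#' degree of reversibility `kbar1/a1`).
#'
#' @inheritParams iss_mixed
#' @param k_deg_grid strictly increasing grid of degradation rates (s^-1)
#' @return a `demarcation_curve` with columns `k_deg` (or `kbar1` and
#'   `reversibility`), `v_non`, `v_ch`; the crossing (if any) is stored in
#'   the metadata as `crossing`
#' @export
degradation_sweep <- function(params, S, k_deg_grid) {
  stopifnot(all(diff(k_deg_grid) > 0))
  v_ch <- v_channeled(params, S)
  v_non <- vapply(k_deg_grid,
                  function(k) solve_degradation(params, S, k)$v_non,
                  numeric(1))
  crossing <- sweep_crossing(k_deg_grid,
                             function(k) solve_degradation(params, S, k)$v_non - v_ch,
                             v_non - v_ch)
  new_demarcation_curve(
    data.frame(k_deg = k_deg_grid, v_non = v_non, v_ch = v_ch),
    meta = list(kind = "degradation", params = params, S = S,
                crossing = crossing))
}

#' @rdname degradation_sweep
#' @param kbar1_grid strictly increasing grid of reverse rates (nM^-1 s^-1)
#' @export
reversibility_sweep <- function(params, S, kbar1_grid) {
  stopifnot(all(diff(kbar1_grid) > 0))
  v_ch <- v_channeled(params, S)
  v_non <- vapply(kbar1_grid,
                  function(k) solve_reversible(params, S, k)$v_non,
                  numeric(1))
  crossing <- sweep_crossing(kbar1_grid,
                             function(k) solve_reversible(params, S, k)$v_non - v_ch,
                             v_non - v_ch)
  new_demarcation_curve(
    data.frame(kbar1 = kbar1_grid, reversibility = kbar1_grid / params$a1,
               v_non = v_non, v_ch = v_ch),
    meta = list(kind = "reversibility", params = params, S = S,
                crossing = crossing))
}

# locate the sign change of f along the grid, if the tabulated differences
# show one; returns the abscissa of the crossing or NA
sweep_crossing <- function(grid, f, diffs) {
  s <- sign(diffs)
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
}

#' Log-spaced grid helper
#'
#' @param from,to positive range endpoints
#' @param n number of points
#' @return strictly increasing numeric vector of length `n`
#' @export
log_grid <- function(from, to, n = 200) {
  stopifnot(from > 0, to > from)
  exp(seq(log(from), log(to), length.out = n))
}
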