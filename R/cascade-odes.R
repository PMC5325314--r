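#' Species of the mixed cascade system
#'
#' Integrated state: bulk metabolites S, I, P and the bound complexes SE1,
#' IE2, SE12, IE12, E12I (plus SE12I when the two-occupancy extension is on).
#' Free enzyme concentrations are eliminated by the conservation laws
#' `E1 = E1_tot - SE1`, `E2 = E2_tot - IE2`,
#' `E12 = E12_tot - SE12 - IE12 - E12I (- SE12I)`.
#'
#' @param params a [cascade_params()] object
#' @return character vector of state-variable names
#' @keywords internal
state_names <- function(params) {
  nm <- c("S", "I", "P", "SE1", "IE2", "SE12", "IE12", "E12I")
  if (params$two_site) nm <- c(nm, "SE12I")
  nm
}

#' Initial state of a simulation
#'
#' The convention used throughout: all enzymes free and unbound at t = 0,
#' no intermediate and no product, substrate at `S0` (or at the clamp level
#' in constant-substrate mode).
#'
#' @inheritParams state_names
#' @param feed a [feed_mode()] object
#' @param S0 initial substrate concentration (nM); ignored in
#'   constant-substrate mode, where the clamp level is used
#' @return named numeric state vector
#' @export
initial_state <- function(params, feed, S0 = 0) {
  y <- stats::setNames(numeric(length(state_names(params))), state_names(params))
  y["S"] <- if (feed$mode == "constant_substrate") feed$S_fixed else S0
  y
}

#' Mass-action right-hand side of the mixed cascade
#'
#' Builds the time-derivative function of the full mixed system: the
#' non-channeled cascade
#' S + E1 <-> SE1 -> E1 + I, I + E2 <-> IE2 -> E2 + P
#' running in parallel with the channeled one
#' S + E12 <-> SE12 -> IE12 -> E12I -> E12 + P,
#' plus optional intermediate degradation (`k_deg`), a reversible first step
#' (`kbar1`, adding E1 + I -> SE1) and the two-occupancy complex extension
#' (`two_site`, adding S + E12I <-> SE12I -> IE12 + P).
#'
#' Setting `E12_tot = 0` recovers the pure non-channeled cascade;
#' `E1_tot = E2_tot = 0` the pure channeled one.
#'
#' In `constant_substrate` mode `d[S]/dt` is forced to zero (the substrate is
#' clamped); the supply velocity that would be needed to hold it there is
#' reported in trajectories as the implied `v_S`.
#'
#' @inheritParams initial_state
#' @return a function `(t, y)` returning the named derivative vector, for use
#'   with [integrate_cascade()] or directly with `deSolve`
#' @export
build_rhs <- function(params, feed) {
  p <- validate_cascade_params(params)
  clamp_S <- feed$mode == "constant_substrate"
  v_feed <- if (feed$mode == "constant_feed") feed$v_S else 0
  two_site <- p$two_site

  function(t, y) {
    S <- y[["S"]]; I <- y[["I"]]
    SE1 <- y[["SE1"]]; IE2 <- y[["IE2"]]
    SE12 <- y[["SE12"]]; IE12 <- y[["IE12"]]; E12I <- y[["E12I"]]
    SE12I <- if (two_site) y[["SE12I"]] else 0

    E1 <- p$E1_tot - SE1
    E2 <- p$E2_tot - IE2
    E12 <- p$E12_tot - SE12 - IE12 - E12I - SE12I

    bind1 <- p$a1 * E1 * S
    bind2 <- p$a2 * E2 * I
    bindc <- p$a_ch * E12 * S
    rebind <- p$kbar1 * E1 * I

    dSE1 <- bind1 - (p$d1 + p$k1) * SE1 + rebind
    dIE2 <- bind2 - (p$d2 + p$k2) * IE2
    dSE12 <- bindc - (p$d_ch + p$k1_ch) * SE12
    dIE12 <- p$k1_ch * SE12 - p$k_ch * IE12
    dE12I <- p$k_ch * IE12 - p$k2_ch * E12I
    dS <- -bind1 + p$d1 * SE1 - bindc + p$d_ch * SE12 + v_feed
    dI <- p$k1 * SE1 - bind2 + p$d2 * IE2 - p$k_deg * I - rebind
    dP <- p$k2 * IE2 + p$k2_ch * E12I

    if (two_site) {
      bindc2 <- p$a_ch2 * E12I * S
      dSE12I <- bindc2 - (p$d_ch2 + p$k_ch2_turn) * SE12I
      dE12I <- dE12I - bindc2 + p$d_ch2 * SE12I
      dIE12 <- dIE12 + p$k_ch2_turn * SE12I
      dS <- dS - bindc2 + p$d_ch2 * SE12I
      dP <- dP + p$k_ch2_turn * SE12I
    }
    if (clamp_S) dS <- 0

    d <- c(S = dS, I = dI, P = dP, SE1 = dSE1, IE2 = dIE2,
           SE12 = dSE12, IE12 = dIE12, E12I = dE12I)
    if (two_site) d <- c(d, SE12I = dSE12I)
    d
  }
}

#' Production velocity of a state
#'
#' `v_P = k2 [IE2] + k2_ch [E12I] (+ k_ch2_turn [SE12I])`: the total rate at
#' which product is released by the free second enzyme and by the complex.
#'
#' @inheritParams initial_state
#' @param y named state vector (or matrix with named columns)
#' @return production velocity in nM/s
#' @export
production_velocity <- function(params, y) {
  if (is.matrix(y) || is.data.frame(y)) {
    v <- params$k2 * y[, "IE2"] + params$k2_ch * y[, "E12I"]
    if (params$two_site) v <- v + params$k_ch2_turn * y[, "SE12I"]
  } else {
    v <- params$k2 * y[["IE2"]] + params$k2_ch * y[["E12I"]]
    if (params$two_site) v <- v + params$k_ch2_turn * y[["SE12I"]]
  }
  unname(v)
}

#' Integrate the cascade ODE system
#'
#' Stiff integration (`deSolve::lsoda`) of the mass-action system built by
#' [build_rhs()]. Tight default tolerances are used because trajectories are
#' routinely compared against closed-form steady states.
#'
#' @inheritParams initial_state
#' @param state0 initial named state vector; default [initial_state()]
#'   with the given `S0`
#' @param t_end final time (s)
#' @param n_out number of output points (log-ish dense grid including 0)
#' @param rel_tol,abs_tol integrator tolerances
#' @param times optional explicit output time grid (overrides
#'   `t_end`/`n_out`)
#' @return a `cascade_trajectory`: a data.frame with time `t`, all species,
#'   the free-enzyme concentrations `E1`, `E2`, `E12`, and the production
#'   velocity `vP`; the parameter set and feed mode are attached as
#'   attributes
#' @export
integrate_cascade <- function(params, feed, S0 = 0, state0 = NULL,
                              t_end = 1e3, n_out = 400,
                              rel_tol = 1e-10, abs_tol = 1e-12,
                              times = NULL) {
  rhs <- build_rhs(params, feed)
  if (is.null(state0)) state0 <- initial_state(params, feed, S0 = S0)
  if (is.null(times)) {
    if (t_end <= 0) stop("'t_end' must be positive")
    # grid dense at early times (where the transient lives) and late times
    times <- unique(c(0, exp(seq(log(t_end * 1e-6), log(t_end),
                                 length.out = n_out - 1L))))
  }
  f <- function(t, y, parms) list(rhs(t, y))
  out <- deSolve::ode(y = state0, times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = rel_tol, atol = abs_tol,
                      maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed; last valid time ",
         max(out[, "time"], na.rm = TRUE))
  traj <- as.data.frame(out)
  names(traj)[1] <- "t"
  traj$E1 <- params$E1_tot - traj$SE1
  traj$E2 <- params$E2_tot - traj$IE2
  traj$E12 <- params$E12_tot - traj$SE12 - traj$IE12 - traj$E12I -
    (if (params$two_site) traj$SE12I else 0)
  traj$vP <- params$k2 * traj$IE2 + params$k2_ch * traj$E12I +
    (if (params$two_site) params$k_ch2_turn * traj$SE12I else 0)
  structure(traj, class = c("cascade_trajectory", "data.frame"),
            params = params, feed = feed)
}

#' Numerical steady state (or a diverging-intermediate verdict)
#'
#' Integrates in doubling time blocks until either every time derivative
#' (production excluded) falls below `tol`, or the system is recognised as
#' having an unboundedly growing intermediate pool. The divergence verdict
#' requires the maximal intermediate source to exceed the maximal sink
#' (`k1 [SE1] > k2 E2_tot` with `SE1` at its relaxed value), the observed
#' accumulation rate `d[I]/dt` to have reached 99 percent of that positive
#' excess, every other species to have relaxed (relative to the
#' accumulation rate), and the rate to be stable across a doubling of the
#' integration horizon. A slowly converging system below the threshold can
#' never trip this: its saturation excess is negative. Divergence happens in
#' constant-substrate mode whenever the first enzyme outruns the second
#' (substrate above the threshold concentration).
#'
#' @inheritParams integrate_cascade
#' @param tol derivative-norm tolerance (nM/s) for convergence
#' @param t0 initial block length (s)
#' @param t_max time budget (s); exceeded without a verdict -> error
#' @param watch_velocity if `TRUE`, also monitor the production velocity
#'   across the doubling horizons and accept its Aitken
#'   delta-squared extrapolation once two successive extrapolants agree to
#'   `v_tol` relative. Deep in saturation the intermediate pool fills like
#'   the square root of time, so the velocity converges geometrically per
#'   doubling and the extrapolation is exact in the limit; the returned
#'   `v_P` is then the extrapolated value.
#' @param v_tol relative stability tolerance for the extrapolated velocity
#' @return a list with `converged` (logical), `diverging_I` (logical),
#'   `state` (final state vector), `v_P` (production velocity), `t` (time
#'   reached), and `dI_dt` (final intermediate accumulation rate)
#' @export
steady_state_numeric <- function(params, feed, S0 = 0, state0 = NULL,
                                 tol = 1e-10, t0 = 10, t_max = 1e9,
                                 rel_tol = 1e-10, abs_tol = 1e-12,
                                 watch_velocity = FALSE, v_tol = 5e-8) {
  if (feed$mode == "batch")
    stop("steady-state search requires constant_substrate or constant_feed mode")
  rhs <- build_rhs(params, feed)
  if (is.null(state0)) state0 <- initial_state(params, feed, S0 = S0)
  f <- function(t, y, parms) list(rhs(t, y))
  y <- state0
  t_cur <- 0
  block <- t0
  dI_prev <- NA_real_
  y_prev <- NULL
  v_hist <- numeric(0)
  v_acc_prev <- NA_real_
  div_hits <- 0L
  repeat {
    out <- deSolve::ode(y = y, times = c(t_cur, t_cur + block), func = f,
                        parms = NULL, method = "bdf",
                        rtol = rel_tol, atol = abs_tol, maxsteps = 1e6)
    if (attr(out, "istate")[1] < 0)
      stop("ODE integration failed during steady-state search at t = ", t_cur)
    y <- out[nrow(out), -1]
    t_cur <- t_cur + block
    d <- rhs(t_cur, y)
    rest <- d[setdiff(names(d), c("P", "I"))]
    dI <- d[["I"]]
    # converged when all derivatives (production excluded) vanish, or when
    # the state no longer moves across a doubling of the horizon (the
    # derivative floor scales with the binding fluxes, so the absolute
    # criterion alone is unattainable at extreme substrate levels)
    state_still <- !is.null(y_prev) &&
      max(abs(y[names(y) != "P"] - y_prev[names(y) != "P"]) /
            (1e-8 + 1e-8 * abs(y[names(y) != "P"]))) < 1
    v_now <- production_velocity(params, y)
    v_out <- v_now
    v_still <- FALSE
    if (watch_velocity) {
      v_hist <- c(utils::tail(v_hist, 2), v_now)
      if (length(v_hist) == 3) {
        d1 <- v_hist[2] - v_hist[1]
        d2 <- v_hist[3] - v_hist[2]
        if (is.finite(d1) && is.finite(d2) && d2 != d1 &&
            abs(d2) < 0.95 * abs(d1)) {
          v_acc <- v_hist[3] - d2^2 / (d2 - d1)
          if (!is.na(v_acc_prev) && v_acc > 0 &&
              abs(v_acc - v_acc_prev) < v_tol * abs(v_acc)) {
            v_still <- TRUE
            v_out <- v_acc
          }
          v_acc_prev <- v_acc
        }
        # plain stability (already converged without extrapolation)
        if (!v_still && v_now > 0 && abs(d2) < v_tol * v_now) v_still <- TRUE
      }
    }
    if ((max(abs(rest)) < tol && abs(dI) < tol) || state_still || v_still) {
      return(list(converged = TRUE, diverging_I = FALSE, state = y,
                  v_P = v_out, t = t_cur, dI_dt = dI))
    }
    y_prev <- y
    # unbounded intermediate: the maximal source permanently exceeds the
    # maximal sink (k1 [SE1]_ss > k2 E2_tot, impossible below the threshold
    # since SE1 relaxes to E1 S / (KM1 + S)), the pool keeps accumulating,
    # and every bound species has relaxed relative to the accumulation
    # rate; required over two consecutive doublings of the horizon
    excess <- params$k1 * y[["SE1"]] - params$k2 * params$E2_tot
    hit <- params$k_deg == 0 && excess > tol && dI > tol &&
      max(abs(rest)) < max(tol, 1e-3 * dI) &&
      !is.na(dI_prev) && abs(dI - dI_prev) < 0.5 * dI
    if (hit && div_hits >= 1L) {
      return(list(converged = FALSE, diverging_I = TRUE, state = y,
                  v_P = production_velocity(params, y), t = t_cur,
                  dI_dt = dI))
    }
    div_hits <- if (hit) div_hits + 1L else 0L
    dI_prev <- dI
    block <- block * 2
    if (t_cur > t_max)
      stop("steady-state search inconclusive within the time budget (t = ",
           t_cur, ")")
  }
}

#' Time for a batch reactor to convert a fraction of its substrate
#'
#' Smallest `t` with `[P](t) = alpha * S0`, located by root detection on the
#' integrated batch trajectory. Products asymptote to `S0` in a batch run,
#' so `alpha >= 1` is unreachable.
#'
#' @inheritParams integrate_cascade
#' @param S0 initial substrate dose (nM)
#' @param alpha target product fraction, in (0, 1)
#' @param t_max search horizon (s), extended automatically if needed
#' @return time in seconds
#' @export
time_to_product_fraction <- function(params, S0, alpha,
                                     t_max = NULL,
                                     rel_tol = 1e-10, abs_tol = 1e-12) {
  if (!(alpha > 0 && alpha < 1))
    stop("'alpha' must lie strictly between 0 and 1 (batch product asymptotes to S0)")
  if (params$E1_tot <= 0 && params$E12_tot <= 0)
    stop("no catalyst: at least one of E1_tot, E12_tot must be positive")
  feed <- feed_mode("batch")
  rhs <- build_rhs(params, feed)
  y0 <- initial_state(params, feed, S0 = S0)
  target <- alpha * S0
  f <- function(t, y, parms) list(rhs(t, y))
  root <- function(t, y, parms) y[["P"]] - target
  if (is.null(t_max)) {
    # crude horizon from the slowest plausible conversion rate
    vmax <- max(params$k1 * params$E1_tot,
                params$k2_ch * params$E12_tot, 1e-12)
    KM1 <- if (params$a1 > 0) (params$k1 + params$d1) / params$a1 else Inf
    KMch <- if (params$a_ch > 0) (params$k1_ch + params$d_ch) / params$a_ch else Inf
    KM <- min(KM1, KMch)
    t_max <- 200 * (S0 + KM) / vmax
  }
  for (i in 1:6) {
    times <- c(0, t_max)
    out <- deSolve::lsodar(y = y0, times = times, func = f, parms = NULL,
                           rootfunc = root, rtol = rel_tol, atol = abs_tol,
                           maxsteps = 1e5)
    troot <- attr(out, "troot")
    if (!is.null(troot) && length(troot) > 0) return(troot[1])
    t_max <- t_max * 10
  }
  stop("product fraction ", alpha, " not reached within the search horizon")
}
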