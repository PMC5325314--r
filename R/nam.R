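#' Smoluchowski diffusion-limited rate onto an absorbing sphere
#'
#' \eqn{k_D = 4 \pi D R}, in nm^3/ns when `D` is in nm^2/ns and `R` in nm.
#'
#' @param D diffusion coefficient (nm^2/ns)
#' @param R absorbing radius (nm)
#' @return rate in nm^3/ns
#' @export
smoluchowski_rate <- function(D, R) 4 * pi * D * R

#' Convert a rate from nm^3/ns to nM^-1 s^-1
#'
#' `1 nm^3/ns = 1e-24 L * 1e9 /s`; multiplying by Avogadro's number and by
#' `1e-9 M/nM` gives the factor `1e-24 * 6.02214076e23 * 1e9 * 1e-9
#' = 0.602214076`.
#'
#' @param k rate in nm^3/ns
#' @return rate in nM^-1 s^-1
#' @export
rate_nm3ns_to_nMs <- function(k) k * 0.602214076

#' Diffusion-limited association rate by the Northrup-Allison-McCammon method
#'
#' Substrate molecules are launched uniformly on a sphere of radius `b`
#' (chosen so that all substrate-enzyme interactions vanish at and beyond
#' `b`) and propagated by Brownian dynamics until they either come within
#' `r_react` of the active-site bead center (capture) or cross the outer
#' sphere of radius `q` (escape). From the capture probability `beta` the
#' rate follows as
#' \deqn{k = \frac{k_D(b)\,\beta}{1 - (1-\beta)\,k_D(b)/k_D(q)},}
#' with \eqn{k_D(x) = 4\pi D x}; the denominator corrects analytically for
#' trajectories that would have returned from beyond `q`, which makes the
#' estimate insensitive to the choice of `q`. The Monte-Carlo confidence
#' interval is the delta-method propagation of the binomial error of `beta`.
#'
#' Far from the enzyme the propagation uses an enlarged time step (the free
#' displacement is kept to a quarter of the gap to the interaction
#' envelope); within interaction range the fixed base step `dt` is used.
#'
#' @param geom an [enzyme_geometry()]
#' @param b launch radius (nm); the interaction envelope must fit inside
#' @param q escape radius (nm), > `b`
#' @param r_react reaction distance to the active-site bead center (nm)
#' @param D substrate diffusion coefficient (nm^2/ns); the enzyme is held
#'   fixed
#' @param dt base time step (ns); validated so the rms free step stays below
#'   a quarter bead radius
#' @param n_traj number of independent trajectories
#' @param seed RNG seed (the run is reproducible bit-for-bit for a fixed
#'   seed and `dt`)
#' @param eps_lj LJ well depth (kT); 0 gives a freely diffusing substrate
#' @param substrate_radius substrate bead radius (nm)
#' @return an object of class `nam_estimate`: capture probability `beta`
#'   with standard error, the rate `k` in nm^3/ns and nM^-1 s^-1 with
#'   standard error, protocol parameters, and the minimum substrate-bead
#'   gap observed (a check that the LJ wall is effectively impenetrable)
#' @export
nam_rate <- function(geom, b = 5, q = 25, r_react = 0.82, D = 1,
                     dt = 2e-4, n_traj = 1e4, seed = 1,
                     eps_lj = 0.1, substrate_radius = 0.4) {
  stopifnot(inherits(geom, "enzyme_geometry"))
  if (!(r_react < b && b < q)) stop("need r_react < b < q")
  rms_free <- sqrt(6 * D * dt)
  if (geom$bead_radius > 0 && rms_free > geom$bead_radius / 4)
    stop(sprintf("dt too large: rms free step %.3g nm exceeds bead_radius/4 = %.3g nm",
                 rms_free, geom$bead_radius / 4))
  env <- max(sqrt(rowSums(geom$centers^2))) +
    2^(1 / 6) * (geom$bead_radius + substrate_radius)
  if (eps_lj > 0 && env > b)
    warning(sprintf("interaction envelope (%.2f nm) extends beyond b = %g nm; rate formula assumes free diffusion at b", env, b))
  set.seed(seed)
  res <- .nam_run(geom$centers, geom$active_site, geom$bead_radius,
                  substrate_radius, eps_lj, b, q, r_react, D, dt,
                  as.integer(n_traj), geom$core_centers,
                  if (eps_lj > 0) geom$core_radius else 0)
  beta <- res$n_react / res$n_traj
  se_beta <- sqrt(max(beta * (1 - beta), 1 / res$n_traj) / res$n_traj)
  cb <- b / q
  kD_b <- smoluchowski_rate(D, b)
  denom <- 1 - (1 - beta) * cb
  k <- kD_b * beta / denom
  dk_dbeta <- kD_b * (1 - cb) / denom^2
  se_k <- abs(dk_dbeta) * se_beta
  structure(list(beta = beta, se_beta = se_beta,
                 k = k, se_k = se_k,
                 k_nMs = rate_nm3ns_to_nMs(k),
                 se_k_nMs = rate_nm3ns_to_nMs(se_k),
                 b = b, q = q, r_react = r_react, D = D, dt = dt,
                 eps_lj = eps_lj, substrate_radius = substrate_radius,
                 n_traj = res$n_traj, n_react = res$n_react,
                 min_bead_gap = res$min_bead_gap, seed = seed),
            class = "nam_estimate")
}

#' @export
print.nam_estimate <- function(x, ...) {
  cat(sprintf("NAM rate estimate (n = %d, seed = %d):\n", x$n_traj, x$seed))
  cat(sprintf("  beta = %.5f +/- %.5f (b = %g nm, q = %g nm, r_react = %g nm)\n",
              x$beta, x$se_beta, x$b, x$q, x$r_react))
  cat(sprintf("  k = %.4f +/- %.4f nm^3/ns = %.4f +/- %.4f nM^-1 s^-1\n",
              x$k, x$se_k, x$k_nMs, x$se_k_nMs))
  invisible(x)
}

#' Capture probability between concentric absorbing/escape spheres
#'
#' First-passage closed form for a free diffuser started at radius `b`
#' between an absorbing sphere of radius `R` and an outer sphere `q`:
#' \eqn{\beta = (1/b - 1/q)/(1/R - 1/q)}. Used as the analytic oracle for
#' the bare-sphere validation of [nam_rate()].
#'
#' @param R inner absorbing radius (nm)
#' @param b start radius (nm)
#' @param q outer radius (nm)
#' @return capture probability
#' @export
capture_probability_spheres <- function(R, b, q) {
  stopifnot(R < b, b < q)
  (1 / b - 1 / q) / (1 / R - 1 / q)
}

#' Ratio of complex to single-enzyme association rates
#'
#' Runs the identical NAM protocol on both geometries (same seed, so two
#' identical geometries give a ratio of exactly one) and propagates the
#' Monte-Carlo errors in quadrature.
#'
#' @param geom_single,geom_complex geometries from [build_enzyme()] /
#'   [build_complex()]
#' @param ... protocol arguments passed to [nam_rate()] (same for both)
#' @return list with `ratio`, `se_ratio`, and the two `nam_estimate`s
#' @export
rate_ratio_complex <- function(geom_single, geom_complex, ...) {
  k1 <- nam_rate(geom_single, ...)
  k2 <- nam_rate(geom_complex, ...)
  ratio <- k2$k / k1$k
  se <- ratio * sqrt((k1$se_k / k1$k)^2 + (k2$se_k / k2$k)^2)
  list(ratio = ratio, se_ratio = se, single = k1, complex = k2)
}
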