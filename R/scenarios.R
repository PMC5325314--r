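#' MAPK-derived reference parameter set
#'
#' The default parameter set used throughout the package's examples and
#' sweeps: microscopic association/dissociation constants
#' `k_a = 0.027 nM^-1 s^-1`, `k_d = 1.35 s^-1` (values corresponding to the
#' first two reactions of the MAPK pathway), turnover numbers
#' `k1 = k2 = 1.5 s^-1` shared by the free enzymes and the complex, and a
#' channeling rate `k_ch = 1 s^-1`. Macroscopic constants follow from the
#' requested degrees of diffusion control via [macroscopic_from_micro()].
#'
#' @param gamma_1,gamma_2,gamma_ch degrees of diffusion control (default 1)
#' @param E1_tot,E2_tot,E12_tot totals in nM (default 50 each)
#' @param k1,k2,k_ch turnover and channeling rates (s^-1)
#' @param k_a,k_d microscopic constants
#' @param ... passed to [cascade_params()] (e.g. `k_deg`, `kbar1`,
#'   `two_site`)
#' @return a [cascade_params()] object
#' @export
mapk_params <- function(gamma_1 = 1, gamma_2 = 1, gamma_ch = 1,
                        E1_tot = 50, E2_tot = 50, E12_tot = 50,
                        k1 = 1.5, k2 = 1.5, k_ch = 1,
                        k_a = 0.027, k_d = 1.35, ...) {
  params_from_micro(k_a, k_d, k1, k2, k_ch,
                    gamma_1 = gamma_1, gamma_2 = gamma_2,
                    gamma_ch = gamma_ch,
                    E1_tot = E1_tot, E2_tot = E2_tot, E12_tot = E12_tot, ...)
}

#' Named simulation scenario
#'
#' A scenario bundles a parameter set, a feed mode, the initial substrate
#' level and a seed, and serializes losslessly to a flat JSON config.
#'
#' @param name scenario name
#' @param params a [cascade_params()]
#' @param feed a [feed_mode()]
#' @param S0 initial substrate (nM; batch dose or clamp level)
#' @param seed integer seed recorded in every output
#' @return an object of class `scenario`
#' @export
scenario <- function(name, params, feed, S0 = 0, seed = 1L) {
  structure(list(name = name, params = params, feed = feed,
                 S0 = S0, seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (S0 = %g nM, seed = %d)\n", x$name, x$S0, x$seed))
  print(x$feed)
  print(x$params)
  invisible(x)
}

#' Reference scenarios for the constant-substrate base case
#'
#' The base case behind the worked examples: [mapk_params()] constants, all
#' gammas and totals at their defaults, substrate clamped at 90 nM. Variants
#' honouring the balanced-capability constraint `k1*E1 = k2*E2` are
#' available via the `variant` argument (used by the pool-size analysis):
#' `"balanced"` (k2 = 1.5, E2 = 50), `"slow2"` (k2 = 1, E2 = 75) and
#' `"fast2"` (k2 = 2, E2 = 37.5).
#'
#' @param gamma_1,gamma_2,gamma_ch degrees of diffusion control
#' @param S clamped substrate level (nM)
#' @param E_tot total for `E1`, `E12` (and `E2` in the balanced variant), nM
#' @param variant one of `"balanced"`, `"slow2"`, `"fast2"`
#' @param seed recorded seed
#' @return a [scenario()]
#' @export
mapk_scenario <- function(gamma_1 = 1, gamma_2 = 1, gamma_ch = 1,
                          S = 90, E_tot = 50,
                          variant = c("balanced", "slow2", "fast2"),
                          seed = 1L) {
  variant <- match.arg(variant)
  k2 <- switch(variant, balanced = 1.5, slow2 = 1, fast2 = 2)
  E2 <- switch(variant, balanced = E_tot, slow2 = 1.5 * E_tot,
               fast2 = 0.75 * E_tot)
  p <- mapk_params(gamma_1 = gamma_1, gamma_2 = gamma_2,
                   gamma_ch = gamma_ch, E1_tot = E_tot, E2_tot = E2,
                   E12_tot = E_tot, k2 = k2)
  scenario(sprintf("mapk-%s-g1_%g-gch_%g", variant, gamma_1, gamma_ch),
           p, feed_mode("constant_substrate", S_fixed = S), S0 = S,
           seed = seed)
}

#' Reproducible random parameter ensembles
#'
#' Draws `n` parameter sets around the reference constants of
#' [mapk_params()]: each rate (`k_a`, `k_d`, `k1`, `k2`, `k_ch`) is
#' multiplied by an independent log-uniform factor in `rate_range`, the
#' degrees of diffusion control are log-uniform in `gamma_range`, the totals
#' log-uniform in `total_range` (nM) and the substrate log-uniform in
#' `S_range` (nM). With `require_convergent = TRUE` draws are filtered to
#' substrate levels safely below the divergence threshold of the
#' non-channeled system (S below 90 percent of the threshold), so that every
#' retained scenario has a finite steady state; the generator keeps drawing
#' until `n` scenarios survive.
#'
#' @param n number of scenarios
#' @param seed RNG seed (same seed, same ensemble)
#' @param rate_range,gamma_range,total_range,S_range log-uniform ranges
#' @param require_convergent filter to convergent steady states
#' @param max_tries give up (with an error suggesting wider ranges) after
#'   this many raw draws
#' @return list of [scenario()] objects in constant-substrate mode
#' @export
random_ensemble <- function(n, seed = 1L,
                            rate_range = c(1e-3, 1e1),
                            gamma_range = c(0.1, 10),
                            total_range = c(5, 500),
                            S_range = c(1, 1e4),
                            require_convergent = TRUE,
                            max_tries = 1000 * n) {
  stopifnot(n >= 1)
  set.seed(seed)
  runif_log <- function(range) exp(stats::runif(1, log(range[1]), log(range[2])))
  out <- vector("list", n)
  kept <- 0L; tries <- 0L
  while (kept < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("ensemble filtering rejected too many draws; widen the ranges")
    p <- mapk_params(
      gamma_1 = runif_log(gamma_range),
      gamma_2 = runif_log(gamma_range),
      gamma_ch = runif_log(gamma_range),
      E1_tot = runif_log(total_range),
      E2_tot = runif_log(total_range),
      E12_tot = runif_log(total_range),
      k1 = 1.5 * runif_log(rate_range),
      k2 = 1.5 * runif_log(rate_range),
      k_ch = 1 * runif_log(rate_range),
      k_a = 0.027 * runif_log(rate_range),
      k_d = 1.35 * runif_log(rate_range))
    S <- runif_log(S_range)
    if (require_convergent && S >= 0.9 * s_threshold(p)) next
    kept <- kept + 1L
    out[[kept]] <- scenario(sprintf("ensemble-%03d", kept), p,
                            feed_mode("constant_substrate", S_fixed = S),
                            S0 = S, seed = seed)
  }
  out
}

#' Serialize a scenario to / from a flat JSON config
#'
#' @param scn a [scenario()]
#' @param path file path
#' @return `write_scenario_config` returns `path` invisibly;
#'   `read_scenario_config` the reconstructed [scenario()].
#' @export
write_scenario_config <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  x <- c(list(name = scn$name, mode = scn$feed$mode, v_S = scn$feed$v_S,
              S_fixed = scn$feed$S_fixed, S0 = scn$S0, seed = scn$seed),
         unclass(scn$params))
  x <- lapply(x, function(v) {
    if (is.numeric(v) && length(v) == 1 && is.infinite(v)) "inf"
    else if (is.numeric(v) && length(v) == 1 && is.na(v)) "na"
    else v
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- lapply(x, function(v) {
    if (is.character(v) && tolower(v) == "inf") Inf
    else if (is.character(v) && tolower(v) == "na") NA_real_
    else v
  })
  meta <- c("name", "mode", "v_S", "S_fixed", "S0", "seed")
  params <- do.call(cascade_params, x[setdiff(names(x), meta)])
  feed <- feed_mode(x$mode, v_S = x$v_S, S_fixed = x$S_fixed)
  scenario(x$name, params, feed, S0 = x$S0, seed = x$seed)
}

#' Run a configured analysis stage end to end
#'
#' Reads a JSON config, executes the requested stage and writes its outputs
#' (CSV for curves and trajectories, JSON for point estimates) together with
#' the fully resolved parameter set and seed, so that any output can be
#' reproduced from its own sidecar metadata. Stages:
#' `"simulate"` (trajectory of a scenario), `"steady"` (closed-form velocity
#' scan over a substrate grid), `"pool"` (pool-size curve), and `"bd_rate"`
#' (NAM rate of the bead-model single enzyme or complex).
#'
#' @param config_path path to a JSON config with at least a `stage` field;
#'   scenario-based stages embed the [write_scenario_config()] fields, the
#'   `bd_rate` stage takes `geometry` (`"single"`/`"complex"`) and the
#'   [nam_rate()] protocol fields
#' @param out_dir output directory, created if missing
#' @return (invisibly) the paths of the files written
#' @export
run_pipeline <- function(config_path, out_dir) {
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  if (is.null(cfg$stage))
    stop("config error: missing required key 'stage'")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- cfg$stage
  written <- character(0)
  sidecar <- function(base, meta) {
    path <- file.path(out_dir, paste0(base, "_meta.json"))
    meta$stage <- stage
    meta <- rapply(meta, function(v) {
      if (is.numeric(v) && length(v) == 1 && is.infinite(v)) "inf" else v
    }, how = "replace")
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
  }
  if (stage %in% c("simulate", "steady", "pool")) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(cfg[setdiff(names(cfg), c("stage", "t_end",
                                                   "S_grid", "x_ch_grid"))],
                         tmp, auto_unbox = TRUE, digits = NA)
    scn <- read_scenario_config(tmp)
  }
  if (stage == "simulate") {
    t_end <- if (is.null(cfg$t_end)) 1e3 else cfg$t_end
    traj <- integrate_cascade(scn$params, scn$feed, S0 = scn$S0,
                              t_end = t_end)
    f <- file.path(out_dir, "trajectory.csv")
    utils::write.csv(as.data.frame(traj), f, row.names = FALSE)
    written <- c(f, sidecar("trajectory",
                            list(config = cfg, t_end = t_end)))
  } else if (stage == "steady") {
    S_grid <- if (is.null(cfg$S_grid)) log_grid(1, 1000, 200) else cfg$S_grid
    rows <- lapply(S_grid, function(S) {
      nc <- v_nonchanneled(scn$params, S)
      data.frame(S = S, v_non = nc$v,
                 v_ch = v_channeled(scn$params, S),
                 regime = nc$regime, I_ss = nc$I_ss)
    })
    f <- file.path(out_dir, "steady.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    written <- c(f, sidecar("steady", list(config = cfg)))
  } else if (stage == "pool") {
    grid <- if (is.null(cfg$x_ch_grid)) seq(0, 0.95, by = 0.05) else cfg$x_ch_grid
    curve <- pool_size_curve(scn$params, scn$S0, grid)
    f <- file.path(out_dir, "pool.csv")
    utils::write.csv(as.data.frame(curve), f, row.names = FALSE)
    written <- c(f, sidecar("pool", list(config = cfg)))
  } else if (stage == "bd_rate") {
    g <- build_enzyme()
    if (identical(cfg$geometry, "complex")) g <- build_complex(g)
    args <- cfg[intersect(names(cfg), c("b", "q", "r_react", "D", "dt",
                                        "n_traj", "seed", "eps_lj",
                                        "substrate_radius"))]
    est <- do.call(nam_rate, c(list(geom = g), args))
    f <- file.path(out_dir, "bd_rate.json")
    jsonlite::write_json(unclass(est), f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(f, sidecar("bd_rate", list(config = cfg)))
  } else {
    stop("config error: unknown stage '", stage, "'")
  }
  invisible(written)
}
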