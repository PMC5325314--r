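#' Parameter set of the mixed channeled / non-channeled cascade
#'
#' Collects every rate constant and total concentration of the mixed system
#' in which free enzymes E1 and E2 (the ordinary two-step cascade
#' S -> I -> P) coexist with enzyme-enzyme complexes E12 that channel the
#' intermediate internally:
#' S + E12 <-> SE12 -> IE12 -> E12I -> E12 + P.
#'
#' By default the turnover numbers inside the complex equal those of the free
#' enzymes (`k1_ch = k1`, `k2_ch = k2`): a fair comparison isolates the
#' effect of channeling itself from any change of the catalytic chemistry on
#' complex formation. Pass `k1_ch` / `k2_ch` explicitly to break this.
#'
#' Units: associations in nM^-1 s^-1, all first-order rates in s^-1,
#' concentrations in nM.
#'
#' @param a1,d1,k1 macroscopic association, dissociation and turnover of the
#'   first free enzyme
#' @param a2,d2,k2 same for the second free enzyme
#' @param a_ch,d_ch substrate binding/unbinding of the enzyme complex
#' @param k_ch channeling rate: inverse of the time an intermediate needs to
#'   travel between the two active sites of the complex
#' @param k1_ch,k2_ch turnovers of the two active sites of the complex;
#'   default equal to `k1` and `k2`
#' @param k_deg first-order degradation / side-consumption rate of the free
#'   intermediate (default 0)
#' @param kbar1 reverse rate of the first reaction, E1 + I -> SE1
#'   (nM^-1 s^-1, default 0: irreversible first step)
#' @param two_site logical; allow a second metabolite in the complex via
#'   S + E12I <-> SE12I -> IE12 + P (default `FALSE`). The extra binding
#'   step reuses `a_ch`/`d_ch` and turnover `k2_ch` unless
#'   `a_ch2`/`d_ch2`/`k_ch2_turn` are given.
#' @param a_ch2,d_ch2,k_ch2_turn optional overrides for the two-site binding
#'   and turnover constants
#' @param E1_tot,E2_tot,E12_tot total concentrations (nM) of free-enzyme
#'   species and of complexes
#' @return an object of class `cascade_params` (a validated list)
#' @seealso [mapk_params()] for the default parameter set used throughout
#'   the worked examples, [build_rhs()], [v_channeled()]
#' @export
cascade_params <- function(a1, d1, k1, a2, d2, k2,
                           a_ch, d_ch, k_ch,
                           k1_ch = k1, k2_ch = k2,
                           k_deg = 0, kbar1 = 0,
                           two_site = FALSE,
                           a_ch2 = a_ch, d_ch2 = d_ch, k_ch2_turn = k2_ch,
                           E1_tot = 0, E2_tot = 0, E12_tot = 0) {
  p <- list(a1 = a1, d1 = d1, k1 = k1,
            a2 = a2, d2 = d2, k2 = k2,
            a_ch = a_ch, d_ch = d_ch, k_ch = k_ch,
            k1_ch = k1_ch, k2_ch = k2_ch,
            k_deg = k_deg, kbar1 = kbar1,
            two_site = isTRUE(two_site),
            a_ch2 = a_ch2, d_ch2 = d_ch2, k_ch2_turn = k_ch2_turn,
            E1_tot = E1_tot, E2_tot = E2_tot, E12_tot = E12_tot)
  validate_cascade_params(structure(p, class = "cascade_params"))
}

validate_cascade_params <- function(p) {
  rates <- c("a1", "d1", "k1", "a2", "d2", "k2", "a_ch", "d_ch", "k_ch",
             "k1_ch", "k2_ch", "k_deg", "kbar1", "a_ch2", "d_ch2",
             "k_ch2_turn")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("rate constant '%s' must be a single non-negative number", nm))
  }
  for (nm in c("E1_tot", "E2_tot", "E12_tot")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("total concentration '%s' must be a single non-negative number", nm))
  }
  p
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("Cascade parameters (nM, s):\n")
  cat(sprintf("  free E1    : a1 = %g, d1 = %g, k1 = %g\n", x$a1, x$d1, x$k1))
  cat(sprintf("  free E2    : a2 = %g, d2 = %g, k2 = %g\n", x$a2, x$d2, x$k2))
  cat(sprintf("  complex    : a_ch = %g, d_ch = %g, k1_ch = %g, k_ch = %g, k2_ch = %g\n",
              x$a_ch, x$d_ch, x$k1_ch, x$k_ch, x$k2_ch))
  cat(sprintf("  extensions : k_deg = %g, kbar1 = %g, two_site = %s\n",
              x$k_deg, x$kbar1, x$two_site))
  cat(sprintf("  totals     : E1 = %g, E2 = %g, E12 = %g nM\n",
              x$E1_tot, x$E2_tot, x$E12_tot))
  invisible(x)
}

#' Substrate feeding mode of the reactor
#'
#' Three operating conditions are supported:
#' * `"batch"`: a fixed initial substrate dose, no supply (`v_S = 0`);
#' * `"constant_substrate"`: the substrate concentration is clamped at
#'   `S_fixed` (chemostat-like, the typical cellular condition); the implied
#'   supply velocity `v_S(t)` is reported post hoc from the substrate balance;
#' * `"constant_feed"`: substrate supplied at a constant rate `v_S`.
#'
#' @param mode one of `"batch"`, `"constant_substrate"`, `"constant_feed"`
#' @param v_S substrate supply velocity (nM/s), used by `"constant_feed"`
#' @param S_fixed clamped substrate level (nM), used by `"constant_substrate"`
#' @return an object of class `feed_mode`
#' @export
feed_mode <- function(mode = c("batch", "constant_substrate", "constant_feed"),
                      v_S = 0, S_fixed = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "batch" && v_S != 0)
    stop("batch mode implies v_S = 0")
  if (mode == "constant_feed" && (!is.finite(v_S) || v_S < 0))
    stop("constant_feed requires a finite v_S >= 0")
  if (mode == "constant_substrate" &&
      (!is.numeric(S_fixed) || !is.finite(S_fixed) || S_fixed < 0))
    stop("constant_substrate requires a finite S_fixed >= 0")
  structure(list(mode = mode, v_S = v_S, S_fixed = S_fixed),
            class = "feed_mode")
}

#' @export
print.feed_mode <- function(x, ...) {
  cat(sprintf("Feed mode: %s", x$mode))
  if (x$mode == "constant_feed") cat(sprintf(" (v_S = %g nM/s)", x$v_S))
  if (x$mode == "constant_substrate") cat(sprintf(" (S = %g nM)", x$S_fixed))
  cat("\n")
  invisible(x)
}

#' Read / write parameter sets as flat key-value config files
#'
#' Parameter sets are stored as a flat JSON object whose keys mirror the
#' [cascade_params()] fields. Infinite values survive the round trip as the
#' literal string `"inf"`; `gamma = 0` thus encodes `k_D = Inf` everywhere.
#'
#' @param params a `cascade_params` object
#' @param path file path
#' @return `write_params_config` returns `path` invisibly;
#'   `read_params_config` returns a `cascade_params`.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "cascade_params"))
  x <- unclass(params)
  x <- lapply(x, function(v) if (is.numeric(v) && is.infinite(v)) "inf" else v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- lapply(x, function(v) {
    if (is.character(v) && tolower(v) %in% c("inf", "+inf", "infinity")) Inf else v
  })
  do.call(cascade_params, x)
}
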