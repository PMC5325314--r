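# shared fixtures: reference microscopic constants and common parameter sets

ref_micro <- list(k_a = 0.027, k_d = 1.35, k1 = 1.5, k2 = 1.5, k_ch = 1)

base_channeled <- function(...) {
  mapk_params(E1_tot = 0, E2_tot = 0, E12_tot = 50, ...)
}

base_nonchanneled <- function(...) {
  mapk_params(E1_tot = 50, E2_tot = 50, E12_tot = 0, ...)
}

clamp <- function(S) feed_mode("constant_substrate", S_fixed = S)

# weighted metabolite total of a trajectory (SE12I carries two metabolites)
metabolite_total <- function(traj, two_site = FALSE) {
  tot <- traj$S + traj$I + traj$P + traj$SE1 + traj$IE2 + traj$SE12 +
    traj$IE12 + traj$E12I
  if (two_site) tot <- tot + 2 * traj$SE12I
  tot
}

bare_sphere <- function(R = 0.82) {
  enzyme_geometry(matrix(0, 1, 3), bead_radius = R, core_radius = R,
                  active_site = 1)
}
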