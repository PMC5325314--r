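test_that("the right-hand side respects the reaction scheme", {
  # no catalyst: nothing moves except the substrate feed
  p <- mapk_params(E1_tot = 0, E2_tot = 0, E12_tot = 0)
  rhs <- build_rhs(p, feed_mode("constant_feed", v_S = 2.5))
  y <- initial_state(p, feed_mode("constant_feed", v_S = 2.5), S0 = 10)
  d <- rhs(0, y)
  expect_equal(d[["S"]], 2.5)
  expect_true(all(d[names(d) != "S"] == 0))

  # E12_tot = 0: channel species stay identically zero, free-enzyme part
  # follows the plain mass-action cascade
  p <- base_nonchanneled()
  rhs <- build_rhs(p, feed_mode("batch"))
  y <- initial_state(p, feed_mode("batch"), S0 = 90)
  y[c("I", "SE1", "IE2")] <- c(5, 10, 3)
  d <- rhs(0, y)
  expect_equal(unname(d[c("SE12", "IE12", "E12I")]), c(0, 0, 0))
  E1 <- 50 - 10; E2 <- 50 - 3
  expect_equal(d[["SE1"]], p$a1 * E1 * 90 - (p$d1 + p$k1) * 10)
  expect_equal(d[["I"]], p$k1 * 10 - p$a2 * E2 * 5 + p$d2 * 3)
  expect_equal(d[["P"]], p$k2 * 3)
})

test_that("metabolite derivatives sum to the supply rate", {
  set.seed(21)
  for (i in 1:20) {
    two_site <- i %% 2 == 0
    p <- mapk_params(gamma_1 = 10^runif(1, -1, 1), E1_tot = runif(1, 0, 80),
                     E2_tot = runif(1, 0, 80), E12_tot = runif(1, 0, 80),
                     kbar1 = runif(1, 0, 0.01), two_site = two_site)
    vS <- runif(1, 0, 5)
    feed <- feed_mode("constant_feed", v_S = vS)
    rhs <- build_rhs(p, feed)
    y <- initial_state(p, feed)
    y["S"] <- runif(1, 0, 200); y["I"] <- runif(1, 0, 50)
    y["SE1"] <- runif(1, 0, p$E1_tot); y["IE2"] <- runif(1, 0, p$E2_tot)
    bound <- runif(3, 0, p$E12_tot / 4)
    y[c("SE12", "IE12", "E12I")] <- bound
    if (two_site) y["SE12I"] <- runif(1, 0, p$E12_tot / 4)
    d <- rhs(0, y)
    total <- d[["S"]] + d[["I"]] + d[["P"]] + d[["SE1"]] + d[["IE2"]] +
      d[["SE12"]] + d[["IE12"]] + d[["E12I"]] +
      (if (two_site) 2 * d[["SE12I"]] else 0)
    expect_equal(total, vS, tolerance = 1e-12)
  }
})

test_that("batch trajectories conserve enzymes and metabolites and finish", {
  p <- mapk_params()
  traj <- integrate_cascade(p, feed_mode("batch"), S0 = 90, t_end = 2000)
  expect_lt(max(abs(metabolite_total(traj) - 90)) / 90, 1e-8)
  expect_lt(max(abs(traj$SE1 + traj$E1 - 50)) / 50, 1e-8)
  expect_lt(max(abs(traj$IE2 + traj$E2 - 50)) / 50, 1e-8)
  expect_lt(max(abs(traj$SE12 + traj$IE12 + traj$E12I + traj$E12 - 50)) / 50,
            1e-8)
  expect_true(all(traj[-1, -1] > -1e-9))
  # irreversible batch endpoint: everything becomes product
  expect_equal(traj$P[nrow(traj)], 90, tolerance = 1e-6)
  expect_lt(traj$I[nrow(traj)], 1e-4)
  expect_lt(traj$S[nrow(traj)], 1e-4)
  # stored production velocity matches its definition at every point
  expect_equal(traj$vP, p$k2 * traj$IE2 + p$k2_ch * traj$E12I)
})

test_that("strong intermediate degradation drains the pool", {
  p <- mapk_params(E2_tot = 0, E12_tot = 0, k_deg = 1e5)
  traj <- integrate_cascade(p, clamp(90), t_end = 100)
  expect_lt(max(traj$I), 1e-3)
  expect_lt(max(traj$vP), 1e-12)
})

test_that("long-time clamped velocities match the closed forms", {
  ss <- steady_state_numeric(base_channeled(), clamp(90))
  expect_true(ss$converged)
  expect_equal(ss$v_P, v_channeled(base_channeled(), 90), tolerance = 1e-6)
  expect_equal(ss$v_P, 14.17736, tolerance = 1e-5)

  ss2 <- steady_state_numeric(base_nonchanneled(), clamp(90))
  expect_equal(ss2$v_P, v_nonchanneled(base_nonchanneled(), 90)$v,
               tolerance = 1e-6)
  expect_equal(ss2$state[["I"]], iss_mixed(base_nonchanneled(), 90, 0),
               tolerance = 1e-6)
})

test_that("the divergence verdict flips at the threshold substrate level", {
  p <- mapk_params(E1_tot = 50, E2_tot = 40, E12_tot = 0)
  sth <- s_threshold(p)
  below <- steady_state_numeric(p, clamp(0.98 * sth))
  above <- steady_state_numeric(p, clamp(1.02 * sth))
  expect_true(below$converged)
  expect_false(below$diverging_I)
  expect_true(above$diverging_I)
  # a pure channeled system cannot diverge: occupancy is bounded by E12_tot
  ch <- steady_state_numeric(base_channeled(), clamp(1e5),
                             watch_velocity = TRUE)
  expect_true(ch$converged)
})

test_that("batch conversion times behave like first-passage times", {
  p <- mapk_params()
  t25 <- time_to_product_fraction(p, 90, 0.25)
  t50 <- time_to_product_fraction(p, 90, 0.50)
  t90 <- time_to_product_fraction(p, 90, 0.90)
  expect_true(t25 < t50 && t50 < t90)
  expect_lt(time_to_product_fraction(p, 90, 1e-4), 0.2)
  expect_error(time_to_product_fraction(p, 90, 1.2), "alpha")
  expect_error(time_to_product_fraction(mapk_params(E1_tot = 0, E12_tot = 0),
                                        90, 0.5), "catalyst")

  # linear (low-substrate) kinetics: doubling the enzymes halves the time.
  # Totals are kept low so the conversion is much slower than the
  # enzyme-binding relaxation (which does not scale with the totals).
  S0 <- 0.5  # far below both Michaelis constants (~161 nM)
  t1 <- time_to_product_fraction(mapk_params(E1_tot = 5, E2_tot = 5,
                                             E12_tot = 0), S0, 0.5)
  t2 <- time_to_product_fraction(mapk_params(E1_tot = 10, E2_tot = 10,
                                             E12_tot = 0), S0, 0.5)
  expect_equal(t1 / t2, 2, tolerance = 0.05)
})
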