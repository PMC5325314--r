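test_that("channeled velocity has the correct limits and values", {
  p <- base_channeled()
  expect_equal(v_channeled(p, 0), 0)
  # saturation approaches the harmonic-sum maximum
  KMch <- michaelis_constant(p$a_ch, p$d_ch, p$k1_ch)
  vm <- v_max(p)[["v_ch_max"]]
  expect_lt(abs(v_channeled(p, 1e9 * KMch) / vm - 1), 1e-6)
  # frozen value cross-checked against the ODE steady state
  expect_equal(v_channeled(p, 90), 14.17736, tolerance = 1e-6)
  expect_error(v_channeled(p, -1), "S")
})

test_that("non-channeled velocity switches branch at the threshold", {
  # balanced capabilities: threshold infinite, always the finite-pool branch
  p <- base_nonchanneled()
  expect_identical(s_threshold(p), Inf)
  r <- v_nonchanneled(p, 1e6)
  expect_equal(r$regime, "first-limiting")
  expect_equal(v_nonchanneled(p, 90)$v, 26.88053, tolerance = 1e-6)

  # k1 E1 = 2 k2 E2: threshold equals the first Michaelis constant
  p2 <- mapk_params(E1_tot = 50, E2_tot = 25, E12_tot = 0)
  expect_equal(s_threshold(p2), michaelis_constant(p2$a1, p2$d1, p2$k1))

  # the reference threshold case
  p3 <- mapk_params(E1_tot = 50, E2_tot = 40, E12_tot = 0)
  expect_equal(s_threshold(p3), 161.1111 * 60 / 15, tolerance = 1e-4)
  above <- v_nonchanneled(p3, 700)
  expect_equal(above$regime, "diverging")
  expect_equal(above$v, p3$k2 * 40)
  expect_identical(above$I_ss, Inf)

  # balanced-capability variant with a slower, more abundant second enzyme
  p4 <- mapk_params(E1_tot = 50, E2_tot = 75, E12_tot = 0, k2 = 1)
  expect_identical(s_threshold(p4), Inf)
})

test_that("saturation velocities obey the harmonic-sum inequality", {
  vm <- v_max(mapk_params())
  expect_equal(vm[["v_non_max"]], 75)
  expect_equal(vm[["v_ch_max"]], 50 / (1 / 1.5 + 1 / 1 + 1 / 1.5),
               tolerance = 1e-12)
  expect_equal(vm[["v_ch_max"]], 21.42857, tolerance = 1e-6)
  expect_equal(vm[["v_ch_max_two_site"]], 1.5 * 1 * 50 / 2.5)

  # k_ch -> infinity limits
  vf <- v_max(mapk_params(k_ch = 1e12))
  expect_equal(vf[["v_ch_max"]], 50 / (1 / 1.5 + 1 / 1.5), tolerance = 1e-9)
  expect_equal(vf[["v_ch_max_two_site"]], 1.5 * 50, tolerance = 1e-9)

  # channeling can never win in saturation at equal totals
  set.seed(31)
  for (i in 1:1000) {
    k <- 10^runif(3, -3, 3)
    p <- mapk_params(k1 = k[1], k2 = k[2], k_ch = k[3])
    vm <- v_max(p)
    expect_lt(vm[["v_ch_max"]], vm[["v_non_max"]])
  }
})

test_that("low-substrate velocities reduce to the Michaelis-ratio law", {
  p <- mapk_params()  # equal micro constants, equal gammas, equal totals
  v <- low_s_velocities(p, 1)
  expect_equal(v[["v_non"]], v[["v_ch"]])

  # lower diffusion control of the complex means a smaller K_M and a faster
  # channeled reaction
  p2 <- mapk_params(gamma_ch = 0.2)
  v2 <- low_s_velocities(p2, 1)
  expect_gt(v2[["v_ch"]], v2[["v_non"]])

  # first-order agreement with the full expressions
  KM1 <- michaelis_constant(p$a1, p$d1, p$k1)
  S <- 1e-3 * KM1
  full_non <- v_nonchanneled(p, S)$v
  full_ch <- v_channeled(p, S)
  # the first-order forms sit above the full expressions by O(S / K_M)
  lo <- low_s_velocities(p, S)
  expect_equal(lo[["v_non"]], full_non, tolerance = 5e-3)
  expect_equal(lo[["v_ch"]], full_ch, tolerance = 5e-3)
})

test_that("the mixed-system intermediate pool follows the enzyme imbalance", {
  # equal enzymes: pool independent of the degree of channeling (= S here)
  p <- mapk_params()
  for (x in c(0, 0.3, 0.6, 0.9))
    expect_equal(iss_mixed(p, 90, x), 90, tolerance = 1e-12)

  # slower but more abundant second enzyme: channeling shrinks the pool
  p2 <- mapk_params(E2_tot = 75, k2 = 1)
  expect_equal(iss_mixed(p2, 90, 0), 69.31034, tolerance = 1e-6)
  expect_equal(iss_mixed(p2, 90, 0.5), 45.612708, tolerance = 1e-6)

  # faster but scarcer second enzyme: channeling grows the pool, and the
  # pool diverges at a finite degree of channeling
  p3 <- mapk_params(E2_tot = 37.5, k2 = 2)
  I <- vapply(seq(0, 0.8, 0.1), function(x) iss_mixed(p3, 90, x), numeric(1))
  expect_true(all(diff(I) > 0))
  expect_identical(iss_mixed(p3, 90, 0.95), Inf)

  # sign law by finite differences under the balanced-capability constraint
  h <- 1e-4
  d_flat <- (iss_mixed(p, 90, h) - iss_mixed(p, 90, 0)) / h
  d_down <- (iss_mixed(p2, 90, h) - iss_mixed(p2, 90, 0)) / h
  d_up <- (iss_mixed(p3, 90, h) - iss_mixed(p3, 90, 0)) / h
  expect_equal(d_flat, 0, tolerance = 1e-8)
  expect_lt(d_down, 0)
  expect_gt(d_up, 0)

  expect_error(iss_mixed(p, 90, 1), "x_ch")
})

test_that("degradation steady states solve the quadratic balance", {
  p <- base_nonchanneled()
  # continuity at zero degradation
  s0 <- solve_degradation(p, 90, 0)
  expect_equal(s0$I_ss, iss_mixed(p, 90, 0))
  expect_equal(s0$v_non, v_nonchanneled(p, 90)$v)

  ks <- 10^seq(-3, 3, length.out = 13)
  sols <- lapply(ks, function(k) solve_degradation(p, 90, k))
  v <- vapply(sols, `[[`, numeric(1), "v_non")
  I <- vapply(sols, `[[`, numeric(1), "I_ss")
  res <- vapply(sols, `[[`, numeric(1), "residual")
  expect_true(all(diff(v) < 0))
  expect_true(all(diff(I) < 0))
  expect_lt(max(abs(res)), 1e-10)
  # strong degradation drains everything
  s_inf <- solve_degradation(p, 90, 1e9)
  expect_lt(s_inf$I_ss, 1e-6)
  expect_lt(s_inf$v_non, 1e-4)
})

test_that("reversible first reaction lowers the velocity monotonically", {
  p <- base_nonchanneled()
  s0 <- solve_reversible(p, 90, 0)
  expect_equal(s0$v_non, v_nonchanneled(p, 90)$v)

  kb <- p$a1 * 10^seq(-2, 2, length.out = 9)   # degrees of reversibility
  v <- vapply(kb, function(k) solve_reversible(p, 90, k)$v_non, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_true(all(v < s0$v_non))
  res <- vapply(kb, function(k) solve_reversible(p, 90, k)$residual,
                numeric(1))
  expect_lt(max(abs(res)), 1e-8)

  # the velocity ratio to the channeled system is scale invariant
  p10 <- mapk_params(E1_tot = 500, E2_tot = 500, E12_tot = 500)
  for (k in c(0.00135, 0.0135, 0.135)) {
    r1 <- solve_reversible(p, 90, k)$v_non / v_channeled(mapk_params(), 90)
    r10 <- solve_reversible(p10, 90, k)$v_non /
      v_channeled(p10, 90)
    expect_equal(r1, r10, tolerance = 1e-10)
  }
})

test_that("closed forms agree with the ODE oracle across a random ensemble", {
  ens <- random_ensemble(12, seed = 77)
  for (scn in ens) {
    S <- scn$feed$S_fixed
    pch <- scn$params; pch$E1_tot <- 0; pch$E2_tot <- 0
    pnc <- scn$params; pnc$E12_tot <- 0
    ode_ch <- steady_state_numeric(pch, scn$feed)
    ode_nc <- steady_state_numeric(pnc, scn$feed)
    expect_equal(ode_ch$v_P, v_channeled(pch, S), tolerance = 1e-4)
    expect_equal(ode_nc$v_P, v_nonchanneled(pnc, S)$v, tolerance = 1e-4)
  }
})
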