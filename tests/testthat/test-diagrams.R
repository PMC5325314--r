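test_that("the steady-state demarcation curve separates the velocity orders", {
  curve <- steady_demarcation(ref_micro, gamma_1 = 1,
                              S_grid = log_grid(1, 100, 12))
  cross <- curve[curve$flag == "crossing", ]
  expect_gt(nrow(cross), 5)
  # the favourable-channeling region shrinks with substrate
  expect_true(all(diff(cross$gamma_ch) < 0))
  # each demarcation point is a genuine velocity equality
  for (i in seq_len(nrow(cross))) {
    p <- params_from_micro(ref_micro$k_a, ref_micro$k_d, ref_micro$k1,
                           ref_micro$k2, ref_micro$k_ch, gamma_1 = 1,
                           gamma_ch = cross$gamma_ch[i],
                           E1_tot = 50, E2_tot = 50, E12_tot = 50)
    v_ch <- v_channeled(p, cross$S[i])
    v_non <- v_nonchanneled(p, cross$S[i])$v
    expect_lt(abs(v_ch - v_non) / v_non, 1e-6)
  }
  # beyond the maximal substrate channeling loses for every gamma_ch
  expect_true(all(curve$flag[curve$S > s_max(ref_micro, 1)] == "ch-slower"))
})

test_that("the acceleration window closes at a substrate level growing with gamma_1", {
  sm <- vapply(c(0.5, 1, 2, 5), function(g) s_max(ref_micro, g), numeric(1))
  expect_true(all(diff(sm) > 0))
  # at the crossing, the most favourable channeled system just matches the
  # non-channeled velocity
  p0 <- params_from_micro(ref_micro$k_a, ref_micro$k_d, ref_micro$k1,
                          ref_micro$k2, ref_micro$k_ch, gamma_1 = 1,
                          gamma_ch = 0, E1_tot = 50, E2_tot = 50,
                          E12_tot = 50)
  expect_equal(v_channeled(p0, sm[2]), v_nonchanneled(p0, sm[2])$v,
               tolerance = 1e-9)
  # brute-force scan oracle: the velocity difference changes sign at s_max
  S_lo <- sm[2] * 0.9; S_hi <- sm[2] * 1.1
  expect_gt(v_channeled(p0, S_lo) - v_nonchanneled(p0, S_lo)$v, 0)
  expect_lt(v_channeled(p0, S_hi) - v_nonchanneled(p0, S_hi)$v, 0)
})

test_that("batch demarcation points equalise the conversion times", {
  S0 <- c(2, 20, 120)
  curve <- batch_demarcation(ref_micro, gamma_1 = 1, alpha = 0.5,
                             S0_grid = S0, E_tot = 50)
  cross <- curve[curve$flag == "crossing", ]
  expect_gt(nrow(cross), 0)
  for (i in seq_len(nrow(cross))) {
    p_non <- params_from_micro(ref_micro$k_a, ref_micro$k_d, ref_micro$k1,
                               ref_micro$k2, ref_micro$k_ch, gamma_1 = 1,
                               E1_tot = 50, E2_tot = 50, E12_tot = 0)
    p_ch <- params_from_micro(ref_micro$k_a, ref_micro$k_d, ref_micro$k1,
                              ref_micro$k2, ref_micro$k_ch, gamma_1 = 1,
                              gamma_ch = cross$gamma_ch[i],
                              E1_tot = 0, E2_tot = 0, E12_tot = 50)
    t_non <- time_to_product_fraction(p_non, cross$S0[i], 0.5)
    t_ch <- time_to_product_fraction(p_ch, cross$S0[i], 0.5)
    expect_lt(abs(t_ch - t_non) / t_non, 1e-3)
  }
  # head-start dominance at a tiny dose: equal gammas, channeled faster
  p_ch1 <- params_from_micro(ref_micro$k_a, ref_micro$k_d, ref_micro$k1,
                             ref_micro$k2, ref_micro$k_ch, gamma_1 = 1,
                             gamma_ch = 1, E1_tot = 0, E2_tot = 0,
                             E12_tot = 50)
  p_non1 <- params_from_micro(ref_micro$k_a, ref_micro$k_d, ref_micro$k1,
                              ref_micro$k2, ref_micro$k_ch, gamma_1 = 1,
                              E1_tot = 50, E2_tot = 50, E12_tot = 0)
  expect_lt(time_to_product_fraction(p_ch1, 1, 0.5),
            time_to_product_fraction(p_non1, 1, 0.5))
})

test_that("pool-size curves reproduce the three canonical shapes", {
  grid <- seq(0, 0.9, 0.15)
  flat <- pool_size_curve(mapk_scenario(variant = "balanced")$params, 90, grid)
  down <- pool_size_curve(mapk_scenario(variant = "slow2")$params, 90, grid)
  up <- pool_size_curve(mapk_scenario(variant = "fast2")$params, 90, grid)
  expect_lt(max(abs(flat$I_ss - 90)), 1e-10)
  expect_true(all(diff(down$I_ss) < 0))
  fin <- up$flag == "finite"
  expect_true(all(diff(up$I_ss[fin]) > 0))
  expect_true(any(up$flag == "diverging"))
})

test_that("degradation and reversibility sweeps fall off monotonically", {
  p <- mapk_params()  # equal totals throughout
  ds <- degradation_sweep(p, 90, log_grid(1e-3, 10, 15))
  expect_true(all(diff(ds$v_non) < 0))
  expect_equal(ds$v_ch[1], v_channeled(p, 90))
  # the no-degradation endpoint equals the plain steady velocity
  expect_equal(solve_degradation(p, 90, 0)$v_non, v_nonchanneled(p, 90)$v)
  # channeling becomes favourable around degradation rates of order 1/s
  crossing <- attr(ds, "meta")$crossing
  expect_true(is.finite(crossing))
  expect_gt(crossing, 0.05)
  expect_lt(crossing, 10)

  rs <- reversibility_sweep(p, 90, p$a1 * log_grid(1e-2, 1e2, 11))
  expect_true(all(diff(rs$v_non) < 0))
  p10 <- mapk_params(E1_tot = 500, E2_tot = 500, E12_tot = 500)
  rs10 <- reversibility_sweep(p10, 90, p10$a1 * log_grid(1e-2, 1e2, 11))
  expect_equal(rs$v_non / rs$v_ch, rs10$v_non / rs10$v_ch,
               tolerance = 1e-10)
})
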