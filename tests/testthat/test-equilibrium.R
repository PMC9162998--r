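test_that("Frank-Starling curve matches hand-computed values and is linear in S", {
  # log term cancels k at P = P0 + exp(-k)
  expect_equal(frank_starling_co(3, 2 + exp(-1), P0 = 2, k = 1), 0)
  # ln(e) = 1 so CO = S * (1 + k) = 3 * 2
  expect_equal(frank_starling_co(3, 2 + exp(1), P0 = 2, k = 1), 6)
  co1 <- frank_starling_co(7, 12, P0 = 2.03, k = 0.8)
  expect_equal(frank_starling_co(14, 12, P0 = 2.03, k = 0.8), 2 * co1)
  # strictly increasing in preload
  p <- seq(3, 25, length.out = 50)
  expect_true(all(diff(frank_starling_co(5, p, P0 = 2.03, k = 0.8)) > 0))
  expect_error(frank_starling_co(3, 1.9, P0 = 2, k = 1), "preload below")
})

test_that("venous return surface is the stated plane", {
  mc <- model_constants(W = 0.1, G_L = 0.2, G_R = 0.3)
  expect_equal(venous_return_co(10, 10, 10, mc), 50)  # (10 - 2 - 3)/0.1
  expect_equal(venous_return_co(0.2 * 10 + 0.3 * 10, 10, 10, mc), 0)
  # exact sensitivity dCO/dV = 1/W
  expect_equal(venous_return_co(11, 10, 10, mc) - venous_return_co(10, 10, 10, mc),
               1 / 0.1)
  expect_error(venous_return_co(4, 10, 10, mc), "negative venous return")
  # decreasing in both atrial pressures
  expect_true(venous_return_co(10, 11, 10, mc) < venous_return_co(10, 10, 10, mc))
  expect_true(venous_return_co(10, 10, 11, mc) < venous_return_co(10, 10, 10, mc))
})

test_that("parameter estimation inverts the model closed-form", {
  mc <- model_constants(P0_L = 2, k_L = 1)
  st <- hemo_state(AP = 100, CO = 90, P_LA = 10, P_RA = 10)
  expect_equal(estimate_parameters(st, mc)$R, 1)  # (100 - 10)/90
  # inverse of the Frank-Starling worked example: CO = 6 at P_LA = 2 + e
  st2 <- hemo_state(AP = 100, CO = 6, P_LA = 2 + exp(1), P_RA = 9)
  expect_equal(estimate_parameters(st2, mc)$S_L, 3)
  expect_error(
    estimate_parameters(hemo_state(AP = 90, CO = 50, P_LA = 1.5, P_RA = 9), mc),
    "P0_L")
})

test_that("forward solve and inverse estimation round-trip on random parameters", {
  mc <- model_constants()
  for (p in random_params(50, seed = 7)) {
    st <- solve_equilibrium(p, mc)
    back <- estimate_parameters(st, mc)
    expect_equal(back$S_L, p$S_L, tolerance = 1e-6)
    expect_equal(back$S_R, p$S_R, tolerance = 1e-6)
    expect_equal(back$R, p$R, tolerance = 1e-6)
    expect_equal(back$V, p$V, tolerance = 1e-6)
    # and states round-trip the other way
    st2 <- solve_equilibrium(back, mc)
    expect_equal(st2$AP, st$AP, tolerance = 1e-6)
    expect_equal(st2$P_LA, st$P_LA, tolerance = 1e-6)
  }
})

test_that("equilibrium solution satisfies all three equations and symmetry", {
  mc <- model_constants(P0_L = 2.1, k_L = 1.2, P0_R = 2.1, k_R = 1.2)
  # identical left/right curves and slopes force P_LA = P_RA
  st <- solve_equilibrium(eq_params(S_L = 30, S_R = 30, R = 0.7, V = 25), mc)
  expect_equal(st$P_LA, st$P_RA, tolerance = 1e-9)
  # residuals of the defining equations
  mc2 <- model_constants()
  p <- eq_params(S_L = 33, S_R = 31, R = 0.66, V = 24.8)
  s <- solve_equilibrium(p, mc2)
  expect_lt(abs(s$CO - frank_starling_co(p$S_L, s$P_LA, mc2$P0_L, mc2$k_L)), 1e-8)
  expect_lt(abs(s$CO - frank_starling_co(p$S_R, s$P_RA, mc2$P0_R, mc2$k_R)), 1e-8)
  expect_lt(abs(s$CO - venous_return_co(p$V, s$P_LA, s$P_RA, mc2)), 1e-8)
  expect_equal(s$AP, p$R * s$CO + s$P_RA)
  expect_error(solve_equilibrium(eq_params(30, 30, 0.7, 1), mc2), "no feasible")
})

test_that("target determination is self-consistent and clamps pressure goals", {
  mc <- model_constants()
  base <- hemo_state(AP = 87, CO = 118, P_LA = 17, P_RA = 9.1)
  par <- estimate_parameters(base, mc)

  # asking for the current state returns the current parameters
  tg_self <- compute_targets(base$AP, base$P_LA, par$S_R, par$R, mc)
  expect_equal(tg_self$S_L_star, par$S_L, tolerance = 1e-8)
  expect_equal(tg_self$V_star, par$V, tolerance = 1e-8)

  # plugging (S_L*, V*) back reproduces (AP*, P_LA*) for randomized goals
  set.seed(11)
  for (i in 1:25) {
    ap_s <- runif(1, 72, 95)
    pla_s <- runif(1, 10, 18)
    tg <- compute_targets(ap_s, pla_s, par$S_R, par$R, mc)
    st <- solve_equilibrium(eq_params(tg$S_L_star, par$S_R, par$R, tg$V_star), mc)
    expect_equal(st$AP, ap_s, tolerance = 1e-6)
    expect_equal(st$P_LA, pla_s, tolerance = 1e-6)
  }

  # raising AP* raises both S_L* and V*
  tg_lo <- compute_targets(75, 16, par$S_R, par$R, mc)
  tg_hi <- compute_targets(85, 16, par$S_R, par$R, mc)
  expect_gt(tg_hi$S_L_star, tg_lo$S_L_star)
  expect_gt(tg_hi$V_star, tg_lo$V_star)

  # safety clamps: AP* floor 70, P_LA* cap 18, with flags
  tg_cl <- compute_targets(60, 22, par$S_R, par$R, mc)
  expect_equal(tg_cl$AP_star, 70)
  expect_equal(tg_cl$P_LA_star, 18)
  expect_true(tg_cl$clamped_AP)
  expect_true(tg_cl$clamped_PLA)
  expect_false(tg_self$clamped_AP)
})
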