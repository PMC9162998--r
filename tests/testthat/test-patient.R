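run_to_steady <- function(patient, rate, minutes = 60, dt = 0.5) {
  plant <- plant_init(patient)
  st <- NULL
  for (i in seq_len(minutes / dt)) {
    out <- plant_step(patient, plant, landiolol_rate = rate, dt = dt,
                      noise = FALSE)
    plant <- out$plant
    st <- out$true
  }
  list(plant = plant, state = st)
}

test_that("default patient reproduces the heart-failure baseline", {
  p <- make_hf_patient()
  expect_equal(p$baseline_state$AP, 87)
  expect_equal(p$baseline_state$P_LA, 17)
  expect_equal(p$baseline_state$HR, 129)
  # construction round-trips: solving the estimated parameters returns baseline
  st <- solve_equilibrium(p$params, p$constants)
  expect_equal(st$AP, 87, tolerance = 1e-8)
  expect_equal(st$CO, 118, tolerance = 1e-8)
  expect_equal(st$P_LA, 17, tolerance = 1e-8)
  expect_equal(st$P_RA, 9.1, tolerance = 1e-8)
})

test_that("ensemble patients are seed-deterministic and perturbed", {
  a <- make_hf_patient(seed = 5, ensemble = TRUE)
  b <- make_hf_patient(seed = 5, ensemble = TRUE)
  expect_identical(a, b)
  c <- make_hf_patient(seed = 6, ensemble = TRUE)
  expect_false(isTRUE(all.equal(a$baseline_state$AP, c$baseline_state$AP)))
  expect_false(isTRUE(all.equal(a$baseline_state$AP, 87)))
})

test_that("drug-free plant is a fixed point of the dynamics", {
  p <- make_hf_patient()
  plant <- plant_init(p)
  for (i in 1:30) {
    out <- plant_step(p, plant, 0, 0, 0, dt = 1 / 6, noise = FALSE)
    plant <- out$plant
    expect_equal(out$true$AP, 87, tolerance = 1e-7)
    expect_equal(out$true$P_LA, 17, tolerance = 1e-7)
    expect_equal(out$true$HR, 129)
  }
})

test_that("landiolol kinetics match the one-compartment closed form", {
  p <- make_hf_patient()
  rate <- 26
  css <- rate / (p$pk$k_e * p$pk$Vd)
  half_life <- log(2) / p$pk$k_e
  st <- run_to_steady(p, rate, minutes = ceiling(7 * half_life), dt = 1 / 6)
  expect_equal(st$plant$C, css, tolerance = 0.01)
  # exact solution at finite time, checked step against closed form
  plant <- plant_init(p)
  out <- plant_step(p, plant, rate, dt = 2.5, noise = FALSE)
  expect_equal(out$plant$C, css * (1 - exp(-p$pk$k_e * 2.5)), tolerance = 1e-12)
})

test_that("with no elimination, concentration times Vd equals infused mass", {
  cfg <- default_config()
  cfg$patient$pk$k_e <- 0
  p <- make_hf_patient(cfg)
  plant <- plant_init(p)
  mass <- 0
  set.seed(1)
  for (i in 1:40) {
    r <- runif(1, 0, 50)
    out <- plant_step(p, plant, r, dt = 0.25, noise = FALSE)
    plant <- out$plant
    mass <- mass + r * 0.25
  }
  expect_equal(plant$C * p$pk$Vd, mass, tolerance = 1e-12)
})

test_that("steady-state dose response is monotone for S_L, HR, CO and AP", {
  p <- make_hf_patient()
  rates <- c(0, 5, 15, 30, 60)
  states <- lapply(rates, function(r) run_to_steady(p, r, minutes = 45))
  s_l <- sapply(states, function(s) s$plant$S_L_current)
  hr <- sapply(states, function(s) s$state$HR)
  co <- sapply(states, function(s) s$state$CO)
  ap <- sapply(states, function(s) s$state$AP)
  expect_true(all(diff(s_l) < 0))
  expect_true(all(diff(hr) < 0))
  expect_true(all(diff(co) < 0))
  expect_true(all(diff(ap) < 0))
})

test_that("volume handling: dextran expands and furosemide drains stressed volume", {
  p <- make_hf_patient()
  plant <- plant_init(p)
  out <- plant_step(p, plant, dextran_rate = 0.6, dt = 2, noise = FALSE)
  expect_equal(out$plant$V_current, p$params$V + p$dextran_fraction * 0.6 * 2,
               tolerance = 1e-12)
  out2 <- plant_step(p, out$plant, furosemide = 5, dt = 1, noise = FALSE)
  booked <- p$furo$gain * 5
  drained <- booked * (1 - exp(-p$furo$onset * 1))
  expect_equal(out2$plant$pending_diuresis, booked - drained, tolerance = 1e-12)
  expect_equal(out2$plant$V_current, out$plant$V_current - drained,
               tolerance = 1e-12)
  # P_LA falls when volume is drained
  expect_lt(out2$true$P_LA, out$true$P_LA)
})

test_that("parameter estimation recovers the plant's instantaneous truth noise-free", {
  run <- default_noisefree_run()
  p <- attr(run, "patient")
  for (i in seq(1, nrow(run), by = 7)) {
    est <- estimate_parameters(
      list(AP = run$AP_true[i], CO = run$CO_true[i],
           P_LA = run$P_LA_true[i], P_RA = run$P_RA_true[i]),
      p$constants)
    expect_equal(est$S_L, run$S_L_true[i], tolerance = 1e-6)
    expect_equal(est$V, run$V_true[i], tolerance = 1e-6)
    expect_equal(est$S_R, p$params$S_R, tolerance = 1e-6)
    expect_equal(est$R, p$params$R, tolerance = 1e-6)
  }
})
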