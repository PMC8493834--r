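test_that("Nernst potential matches the closed form and is monotone", {
  expect_equal(nernst_potential(4, 4, 310.15), 0)
  # physiological HEK solutions: 4 mM out / 130 mM in at 37 C
  expect_rel_equal(nernst_potential(4, 130, 310.15), -93.04, 1e-3)
  e1 <- nernst_potential(4, 130, 310.15)
  e2 <- nernst_potential(8, 130, 310.15)
  expect_gt(e2, e1)
  expect_error(nernst_potential(-1, 130, 310), "positive")
})

test_that("cell configuration requires exactly one reversal specification", {
  expect_error(cell_config(0.1), "exactly one")
  expect_error(cell_config(0.1, E_K = -93, K_out = 4, K_in = 130,
                           temperature = 310), "exactly one")
  cc <- cell_config(0.1, K_out = 4, K_in = 130, temperature = 310.15)
  expect_rel_equal(cc$E_K, -93.04, 1e-3)
  expect_error(cell_config(-1, E_K = -93), "g_kr")
})

test_that("initial state is the offset-corrected holding steady state", {
  pr <- short_protocol()
  s0 <- initial_state(wt_params, test_cell(v_off = 0), pr)
  expect_equal(unclass(s0), unclass(gate_steady_state(wt_params, -80)))
  s5 <- initial_state(wt_params, test_cell(v_off = 5), pr)
  expect_equal(unclass(s5), unclass(gate_steady_state(wt_params, -85)))
})

test_that("gating trajectories stay on the simplex and hold steady states", {
  hold <- voltage_protocol(-80, list(list(protocol_segment("step", 500, -80))),
                           dt = 0.5)
  g <- simulate_gating(wt_params, hold, test_cell())
  s0 <- gate_steady_state(wt_params, -80)
  expect_lt(max(abs(g$Oa - s0[["Oa"]])), 1e-8)
  expect_lt(max(abs(g$h - s0[["h"]])), 1e-8)

  st <- simulate_gating(wt_params, build_staircase_protocol(dt = 0.5),
                        test_cell())
  expect_lt(max(abs(st$Oa + st$C1a + st$C2a - 1)), 1e-8)
  expect_true(all(st$h >= -1e-8 & st$h <= 1 + 1e-8))
  expect_true(all(st$O >= -1e-8 & st$O <= 1 + 1e-8))
})

test_that("h relaxes along its closed-form exponential at fixed voltage", {
  # jump from -80 mV holding to 0 mV: h relaxes from h_inf(-80) toward
  # h_inf(0) with time constant tau_h(0)
  pr <- voltage_protocol(-80, list(list(
    protocol_segment("step", 200, -80),
    protocol_segment("step", 300, 0))), dt = 0.5)
  for (method in c("analytic", "ode")) {
    g <- simulate_gating(wt_params, pr, test_cell(),
                         sim_settings(method = method))
    rt0 <- evaluate_rates(wt_params, 0)
    h0 <- gate_steady_state(wt_params, -80)[["h"]]
    tl <- g$t[g$t >= 200] - 200
    h_closed <- rt0$h_inf + (h0 - rt0$h_inf) * exp(-tl / rt0$tau_h)
    expect_lt(max(abs(g$h[g$t >= 200] - h_closed)), 1e-6)
  }
})

test_that("analytic and adaptive integrators agree; tolerances converge", {
  pr <- short_protocol()
  ga <- simulate_gating(wt_params, pr, test_cell())
  go <- simulate_gating(wt_params, pr, test_cell(), sim_settings(method = "ode"))
  expect_lt(max(abs(ga$O - go$O)), 1e-6)
  gt <- simulate_gating(wt_params, pr, test_cell(),
                        sim_settings(method = "ode", atol = 5e-9, rtol = 5e-9))
  expect_lt(max(abs(go$O - gt$O)), 1e-4)
})

test_that("ramps integrate consistently across both methods", {
  pr <- voltage_protocol(-80, list(list(
    protocol_segment("step", 100, -80),
    protocol_segment("ramp", 300, -80, 40),
    protocol_segment("ramp", 300, 40, -100))), dt = 0.5)
  ga <- simulate_gating(wt_params, pr, test_cell(),
                        sim_settings(ramp_dt = 0.05))
  go <- simulate_gating(wt_params, pr, test_cell(), sim_settings(method = "ode"))
  expect_lt(max(abs(ga$O - go$O)), 1e-5)
})

test_that("current follows the Ohmic driving-force law", {
  pr <- short_protocol()
  # zero conductance, no leak: identically zero
  z <- simulate_current(wt_params, pr, test_cell(g_kr = 0))
  expect_true(all(z$current == 0))
  # held at E_K + v_off: zero driving force throughout
  hold <- voltage_protocol(E_K_37 + 5,
                           list(list(protocol_segment("step", 300, E_K_37 + 5))),
                           dt = 0.5)
  q <- simulate_current(wt_params, hold, test_cell(v_off = 5))
  expect_lt(max(abs(q$current)), 1e-10)
  # linear in conductance
  t1 <- simulate_current(wt_params, pr, test_cell(g_kr = 0.05))
  t2 <- simulate_current(wt_params, pr, test_cell(g_kr = 0.10))
  expect_equal(t2$current, 2 * t1$current, tolerance = 1e-12)
  # outward positive at depolarized voltages; tail at -110 mV inward
  st <- segment_table(pr)
  tt <- trace_times(t1)
  expect_gt(max(t1$current[tt >= st$t_start[2] & tt < st$t_end[2]]), 0)
  tail_i <- t1$current[tt >= st$t_start[3] + 1 & tt < st$t_end[3]]
  expect_lt(min(tail_i), 0)
})

test_that("voltage offset is equivalent to shifting the command", {
  pr <- short_protocol()
  delta <- 4
  shifted <- voltage_protocol(pr$holding - delta, list(lapply(
    pr$sweeps[[1]], function(s)
      protocol_segment(s$kind, s$duration_ms, s$v_start - delta,
                       s$v_end - delta))), dt = pr$dt)
  a <- simulate_gating(wt_params, shifted, test_cell(v_off = 0))
  b <- simulate_gating(wt_params, pr, test_cell(v_off = delta))
  expect_lt(max(abs(a$O - b$O)), 1e-12)
})

test_that("output grid refinement does not change common samples", {
  pr <- short_protocol()
  c1 <- simulate_current(wt_params, pr, test_cell(),
                         sim_settings(dt_out = 1))
  c2 <- simulate_current(wt_params, pr, test_cell(),
                         sim_settings(dt_out = 0.25))
  idx <- seq(1, length(c2$current), by = 4)
  expect_lt(max(abs(c2$current[idx] - c1$current)), 1e-9)
})

test_that("six-state Markov and factorized trajectories are equivalent", {
  pr <- short_protocol()
  g <- simulate_gating(wt_params, pr, test_cell())
  m <- simulate_markov(wt_params, pr, test_cell())
  expect_lt(max(abs(m$occupancy[, "O"] - g$O)), 1e-6)
  expect_lt(max(abs(rowSums(m$occupancy) - 1)), 1e-8)
  # equivalence also holds for the mutant kinetics
  g2 <- simulate_gating(r56q_params, pr, test_cell())
  m2 <- simulate_markov(r56q_params, pr, test_cell())
  expect_lt(max(abs(m2$occupancy[, "O"] - g2$O)), 1e-6)
})

test_that("simulated activation tails grow with test voltage to saturation", {
  act <- build_activation_protocol("oocyte_21C", dt = 1)
  tr <- simulate_current(wt_params, act, test_cell())
  gv <- build_gv_from_tails(tr, act)
  # normalized tail magnitude increases monotonically (up to saturation)
  rising <- gv$g_norm[gv$test_voltage <= 20]
  expect_true(all(diff(rising) > -1e-6))
  expect_gt(gv$g_norm[gv$test_voltage == 40], 0.95)
})

test_that("current traces round-trip through CSV", {
  pr <- short_protocol(dt = 1)
  tr <- simulate_current(wt_params, pr, test_cell())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$current, tr$current)
  expect_equal(back$dt, tr$dt)
  expect_equal(back$voltage, tr$voltage)
})
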