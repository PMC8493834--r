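# shared fixtures: bundled kinetics, a fast sampling interval for tests,
# and a short two-step protocol used where the full staircase is overkill

wt_params <- herg_reference_params("WT")
wt_rpr_params <- herg_reference_params("WT+RPR")
r56q_params <- herg_reference_params("R56Q")

E_K_37 <- nernst_potential(4, 130, 310.15)

test_cell <- function(g_kr = 0.1, v_off = 0, g_leak = 0, E_leak = -80) {
  cell_config(g_kr = g_kr, E_K = E_K_37, v_off = v_off,
              g_leak = g_leak, E_leak = E_leak)
}

# activation step + deep tail; short enough for tight tests
short_protocol <- function(dt = 0.5) {
  voltage_protocol(-80, list(list(
    protocol_segment("step", 100, -80),
    protocol_segment("step", 500, 40),
    protocol_segment("step", 400, -110))), dt = dt, id = "short_test")
}

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * abs(expected)),
              label = sprintf("%s within %g of %s",
                              paste(signif(object, 6), collapse = ","),
                              tol,
                              paste(signif(expected, 6), collapse = ",")))
}
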