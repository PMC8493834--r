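# table-driven check that every built-in protocol reproduces its printed
# numbers: voltages, durations, increments, sweep counts
test_that("built-in protocols match their published step tables", {
  act21 <- build_activation_protocol("oocyte_21C")
  expect_equal(n_sweeps(act21), 17)
  expect_equal(act21$holding, -100)
  expect_equal(act21$meta$test_voltage[1], -100)
  expect_equal(act21$meta$test_voltage[17], 60)
  expect_equal(unique(diff(act21$meta$test_voltage)), 10)
  st <- segment_table(act21)
  expect_true(all(st$t_end - st$t_start == rep(c(250, 750), 17)))
  expect_true(all(st$v_start[st$seg == 2] == -110))
  expect_equal(protocol_duration(act21), 17 * (250 + 750))

  act37 <- build_activation_protocol("hek_37C")
  expect_equal(n_sweeps(act37), 7)
  expect_equal(act37$holding, -80)
  expect_equal(act37$meta$test_voltage, seq(-50, 40, by = 15))
  st <- segment_table(act37)
  expect_equal(unique(st$t_end - st$t_start)[1:3], c(1500, 800, 200))
  expect_true(all(st$v_start[st$seg == 2] == -40))

  dea <- build_deactivation_protocol(c(-140, -120, -110, -90, -60))
  st <- segment_table(dea)
  expect_true(all(st$v_start[st$seg == 1] == 40))
  expect_true(all(st$t_end - st$t_start == rep(c(250, 750), 5)))
  # tails between -140 and -110 mV cover the linear-conductance range
  expect_true(sum(dea$meta$tail_voltage <= -110 &
                    dea$meta$tail_voltage >= -140) >= 3)

  ina <- build_inactivation_protocol_37C()
  expect_equal(n_sweeps(ina), 7)
  expect_equal(ina$meta$test_voltage, seq(-140, 40, by = 30))
  st <- segment_table(ina)
  expect_true(all(st$v_start[st$seg == 1] == 20))
  expect_true(all(st$t_end[st$seg == 1] - st$t_start[st$seg == 1] == 500))
  expect_true(all(st$t_end[st$seg == 2] - st$t_start[st$seg == 2] == 800))
})

test_that("protocol builders reject malformed input", {
  expect_error(build_deactivation_protocol(numeric(0)), "non-empty")
  expect_error(build_deactivation_protocol(c(-110, -110)), "duplicate")
  expect_error(build_deactivation_protocol(-200), "within")
  expect_error(build_activation_protocol("mystery"))
  expect_error(protocol_segment("step", 0, -80), "> 0")
  bad <- data.frame(duration_ms = c(100, 0), voltage_mV = c(-80, 0))
  expect_error(build_staircase_protocol(bad), "positive")
  expect_error(build_staircase_protocol(data.frame(x = 1)), "malformed")
})

test_that("the default staircase is deterministic and spans -120..+60 mV", {
  a <- build_staircase_protocol()
  b <- build_staircase_protocol()
  expect_identical(segment_table(a), segment_table(b))
  st <- segment_table(a)
  expect_gte(min(st$v_start), -120)
  expect_lte(max(st$v_start), 60)
  expect_equal(n_sweeps(a), 1)
  expect_gt(protocol_duration(a), 10000)
})

test_that("voltage_at follows the half-open segment convention", {
  pr <- voltage_protocol(-80, list(list(
    protocol_segment("step", 100, -80),
    protocol_segment("ramp", 100, -80, 0),
    protocol_segment("step", 50, 20))), dt = 1)
  expect_equal(voltage_at(pr, 0), -80)
  expect_equal(voltage_at(pr, 100), -80)       # ramp start
  expect_equal(voltage_at(pr, 150), -40)       # ramp midpoint interpolates
  expect_equal(voltage_at(pr, 200), 20)        # boundary -> later segment
  expect_error(voltage_at(pr, 250), "range")
  expect_error(voltage_at(pr, -1), "range")
})

test_that("rendering to samples and reloading preserves the voltage series", {
  pr <- build_staircase_protocol(dt = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sampled_protocol(pr, path, dt = 1)
  back <- load_sampled_protocol(path)
  t <- render_protocol(pr, 1)$time_ms
  expect_lt(max(abs(voltage_at(back, t) - voltage_at(pr, t))), 1e-9)
  expect_equal(protocol_duration(back), protocol_duration(pr))

  d <- utils::read.csv(path)
  shuffled <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d[sample(nrow(d)), ], shuffled, row.names = FALSE)
  expect_error(load_sampled_protocol(shuffled), "increasing")
  nonuni <- withr::local_tempfile(fileext = ".csv")
  d2 <- d[c(1, 2, 4, 8, 16), ]
  utils::write.csv(d2, nonuni, row.names = FALSE)
  expect_error(load_sampled_protocol(nonuni), "uniform")
})

test_that("protocol JSON round-trips", {
  pr <- build_activation_protocol("hek_37C")
  path <- withr::local_tempfile(fileext = ".json")
  write_protocol_json(pr, path)
  back <- read_protocol_json(path)
  expect_equal(segment_table(back), segment_table(pr))
  expect_equal(back$holding, pr$holding)
  expect_equal(back$dt, pr$dt)
})

test_that("the bundled complex AP waveform is long and loads from CSV", {
  v3 <- build_complex_ap_protocol(dt = 1)
  expect_gt(protocol_duration(v3), 5000)
  fx <- system.file("extdata", "complex_ap_synthetic.csv",
                    package = "hergkinetics", mustWork = TRUE)
  pr <- load_sampled_protocol(fx)
  expect_gt(protocol_duration(pr), 5000)
})

test_that("stylized AP anchors 90% repolarization correctly", {
  ap <- stylized_ap_spec()
  # V90 = 40 - 0.9*(40 - (-100)) = -86 mV, reached on the final ramp
  v90 <- ap$upstroke_mV - 0.9 * (ap$upstroke_mV - ap$hold_mV)
  t_on_ramp <- ap$upstroke_ms + ap$plateau_ms +
    (ap$plateau_end_mV - v90) / (ap$plateau_end_mV - ap$hold_mV) * ap$repol_ms
  expect_equal(ap$t90_ms, t_on_ramp)
  expect_gt(ap$t90_ms, 300); expect_lt(ap$t90_ms, 400)  # APD-like ~350 ms
  expect_error(stylized_ap_spec(plateau_end_mV = -150), "monotonic")
})

test_that("premature-stimulation sweeps differ only inside the step window", {
  ap <- stylized_ap_spec()
  pr <- build_premature_stimulation_protocol(ap, intervals = c(-80, 0, 100, 380),
                                             dt = 1)
  expect_equal(n_sweeps(pr), 4)
  expect_equal(pr$meta$coupling_ms, c(-80, 0, 100, 380))
  # interval 0: onset coincides with the 90%-repolarization time
  expect_equal(pr$meta$step_onset_ms[2], 500 + ap$t90_ms)
  # step amplitude 0 mV for 40 ms in every sweep
  sw <- sweep_times(pr)
  for (i in seq_len(4)) {
    o <- sw$t_start[i] + pr$meta$step_onset_ms[i]
    expect_equal(voltage_at(pr, o + 1), 0)
    expect_equal(voltage_at(pr, o + 39), 0)
  }
  # outside each sweep's own 40-ms window the waveforms are identical
  t_local <- seq(0, sw$t_end[1] - sw$t_start[1] - 1, by = 1)
  v <- lapply(seq_len(4), function(i)
    voltage_at(pr, sw$t_start[i] + t_local))
  for (i in 2:4) {
    mask <- t_local < pr$meta$step_onset_ms[i] - 1e-9 |
      t_local >= pr$meta$step_onset_ms[i] + 40
    mask_ref <- t_local < pr$meta$step_onset_ms[1] - 1e-9 |
      t_local >= pr$meta$step_onset_ms[1] + 40
    both <- mask & mask_ref
    expect_equal(v[[i]][both], v[[1]][both])
  }
  expect_error(build_premature_stimulation_protocol(ap, intervals = 500),
               "within")
  # a very short AP puts t90 + (-80 ms) before the upstroke
  brief <- stylized_ap_spec(plateau_ms = 5, repol_ms = 30)
  expect_error(
    build_premature_stimulation_protocol(brief, intervals = -80),
    "before the AP upstroke")
})

test_that("AP trains pace at the requested rate", {
  tr <- build_ap_train_protocol(n_beats = 3, rate_hz = 2, dt = 1)
  beats <- attr(tr, "beats")
  expect_equal(nrow(beats), 3)
  expect_equal(diff(beats$onset_ms), c(500, 500))
  expect_equal(protocol_duration(tr), 1500)
  expect_error(build_ap_train_protocol(rate_hz = 10), "period")
})
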