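test_that("rasterized tube masks have the right area and are disjoint", {
  layout <- default_phantom_layout()
  truth <- rasterize_layout(layout, pixel_size = 1)
  expect_setequal(unique(as.vector(truth$label_map)), c(1:9, 10))
  area <- pi * 12^2
  for (l in 1:9) {
    expect_lt(abs(sum(truth$label_map == l) - area) / area, 0.02)
  }
  # exhaustive check: every pixel center lies inside at most one disk
  xc <- (seq_len(nrow(truth$label_map)) - 0.5)
  yc <- (seq_len(ncol(truth$label_map)) - 0.5)
  hits <- matrix(0L, length(xc), length(yc))
  for (i in seq_len(nrow(layout$tubes))) {
    d2 <- outer((xc - layout$tubes$x_mm[i])^2,
                (yc - layout$tubes$y_mm[i])^2, `+`)
    hits <- hits + (d2 < 12^2)
  }
  expect_true(all(hits <= 1L))
})

test_that("degenerate layouts are handled", {
  empty <- phantom_layout(default_phantom_layout()$tubes[0, ])
  truth <- rasterize_layout(empty, pixel_size = 2)
  expect_true(all(truth$label_map == 10L))
  tubes <- default_phantom_layout()$tubes
  tubes$x_mm[2] <- tubes$x_mm[1] + 10  # overlapping disks
  tubes$y_mm[2] <- tubes$y_mm[1]
  expect_error(phantom_layout(tubes), "overlap")
  outside <- tubes[1, ]
  outside$x_mm <- 5
  expect_error(phantom_layout(outside), "outside the body")
})

test_that("inversion-recovery simulation matches its closed form", {
  t1 <- 1000
  truth <- uniform_truth(t1, 50)
  proto <- protocol_ir_gre(tr = 10000)
  st <- simulate_inversion_recovery(truth, proto)
  expected <- abs(1 - 2 * exp(-proto$ti_list / t1) + exp(-10000 / t1))
  expect_equal(as.vector(st$frames), expected, tolerance = 1e-12)
  # full recovery and analytic null point
  long <- simulate_inversion_recovery(
    truth, protocol_ir_gre(ti_list = 1e6, tr = 1e7))
  expect_equal(as.vector(long$frames), 1, tolerance = 1e-12)
  null <- simulate_inversion_recovery(
    truth, protocol_ir_gre(ti_list = t1 * log(2), tr = 1e7))
  expect_equal(as.vector(null$frames), 0, tolerance = 1e-12)
  expect_error(
    simulate_inversion_recovery(
      ground_truth_maps(matrix(1L, 1, 1), matrix(NA_real_, 1, 1),
                        matrix(50, 1, 1))),
    "truth invalid")
})

test_that("spin-echo simulation matches its closed form", {
  truth <- uniform_truth(1000, 45)
  st0 <- simulate_spin_echo(truth, protocol_se(te_list = c(0, 45),
                                               tr = 1e7))
  expect_equal(st0$frames[1, 1, 1], 1, tolerance = 1e-12)
  expect_equal(st0$frames[1, 1, 2], exp(-1), tolerance = 1e-12)
  st <- simulate_spin_echo(truth, protocol_se(tr = 10000))
  expect_equal(as.vector(st$frames),
               (1 - exp(-10)) * exp(-protocol_se()$te_list / 45),
               tolerance = 1e-12)
  expect_true(all(diff(as.vector(st$frames)) < 0))
})

test_that("MOLLI simulation is deterministic and reduces to IR at zero flip", {
  truth <- uniform_truth(800, 50)
  a <- simulate_molli(truth, protocol_molli(), noise_sd = 0.01, seed = 11)
  b <- simulate_molli(truth, protocol_molli(), noise_sd = 0.01, seed = 11)
  expect_identical(a$frames, b$frames)
  # weak-flip limit: samples proportional to the signed IR curve within
  # the transient-readout memory (~1%); fitted + corrected T1 within 1%
  for (t1 in c(400, 800, 1300)) {
    st <- simulate_molli(uniform_truth(t1, 50),
                         protocol_molli(flip_angle = 0.001))
    fit <- fit_molli_t1(st)
    expect_lt(abs(fit$values[1, 1] - t1) / t1, 0.01)
  }
})

test_that("MOLLI readout drives the apparent recovery faster than T1", {
  for (t1 in c(400, 1000, 1300)) {
    st <- molli_default_stack(t1)
    fit <- fit_molli_t1(st)
    expect_lt(fit$aux$t1_star[1, 1], t1)
  }
})

test_that("T2-prepared bSSFP signal decays with preparation time and
           carries the short-T1 positive bias", {
  truth_d <- uniform_truth(1090, 60)  # long-T1 tube
  truth_i <- uniform_truth(435, 41)   # short-T1 post-contrast tube
  st_d <- simulate_t2prep_bssfp(truth_d)
  expect_equal(which.max(st_d$frames[1, 1, ]), 1L)  # TEprep = 0 brightest
  bias_d <- fit_t2_monoexponential(st_d)$values[1, 1] - 60
  bias_i <- fit_t2_monoexponential(simulate_t2prep_bssfp(truth_i))$values[1, 1] - 41
  expect_gt(bias_d, 0)
  expect_gt(bias_i, bias_d)
})

test_that("weak-readout T2-prep limit recovers a pure exponential", {
  # joint limit: small flip angle AND short readout train, so both the
  # pulsing and the T1-recovery window before the k-space center vanish
  weak <- protocol_t2prep_bssfp(flip_angle = 5, readout_pulses = 3,
                                readout_tr = 0.5, ramp_pulses = 1,
                                recovery_beats = 20)
  for (tt in list(c(1090, 60), c(435, 41))) {
    st <- simulate_t2prep_bssfp(uniform_truth(tt[1], tt[2]), weak)
    fit <- fit_t2_monoexponential(st)
    expect_lt(abs(fit$values[1, 1] - tt[2]) / tt[2], 0.015)
  }
  # with the offset (3-parameter) model the recovery floor is absorbed
  # and truth is recovered under the default train at low flip angle
  p3 <- protocol_t2prep_bssfp(flip_angle = 5, recovery_beats = 20)
  st <- simulate_t2prep_bssfp(uniform_truth(1090, 60), p3)
  fit3 <- fit_t2_monoexponential(st, model = "3param")
  expect_equal(fit3$values[1, 1], 60, tolerance = 1e-4)
})

test_that("Bloch steppers never exceed the equilibrium magnetization", {
  for (tt in list(c(435, 41), c(1090, 60), c(1287, 70))) {
    s_molli <- phantomqa:::molli_compartment_signals(
      tt[1], tt[2], protocol_molli())
    expect_true(all(abs(s_molli$signal) <= 1 + 1e-12))
    s_prep <- phantomqa:::t2prep_compartment_signals(
      tt[1], tt[2], protocol_t2prep_bssfp())
    expect_true(all(s_prep >= 0 & s_prep <= 1 + 1e-12))
  }
})

test_that("dual-echo phase encodes off-resonance, including aliasing", {
  truth <- uniform_truth(850, 140, 4, 4)
  cond0 <- uniform_field_condition(truth, 3, b0_hz = 0)
  st0 <- simulate_dual_echo_gre(truth, cond0)
  expect_equal(Arg(st0$frames[, , 1]), Arg(st0$frames[, , 2]),
               tolerance = 1e-12)
  cond1 <- uniform_field_condition(truth, 3, b0_hz = 1)
  st1 <- simulate_dual_echo_gre(truth, cond1)
  dphi <- Arg(st1$frames[, , 2] * Conj(st1$frames[, , 1]))
  expect_equal(as.vector(dphi), rep(2 * pi * 1 * 2.5e-3, 16),
               tolerance = 1e-12)
  # above the aliasing limit 1/(2 dTE) = 200 Hz the recovered frequency
  # wraps by 1/dTE = 400 Hz
  cond_hi <- uniform_field_condition(truth, 3, b0_hz = 250)
  b0 <- compute_b0_map(simulate_dual_echo_gre(truth, cond_hi))
  expect_equal(b0$delta_f_hz[1, 1], 250 - 400, tolerance = 1e-9)
})

test_that("double-angle signals follow the actual flip angle", {
  truth <- uniform_truth(850, 140, 3, 3)
  cond <- uniform_field_condition(truth, 3)
  st <- simulate_double_angle(truth, cond)
  expect_equal(st$frames[1, 1, 2] / st$frames[1, 1, 1], 1,
               tolerance = 1e-12)  # 2 cos(60 deg) = 1
  cond$b1_relative_map[] <- 5 / 6   # true 50 degrees
  st2 <- simulate_double_angle(truth, cond)
  expect_equal(st2$frames[1, 1, 2] / (2 * st2$frames[1, 1, 1]),
               cos(50 * pi / 180), tolerance = 1e-12)
  expect_error(
    simulate_double_angle(truth, cond,
                          protocol_double_angle(c(60, 130))),
    "ratio 1:2")
})

test_that("temperature scaling shifts T1 up and T2 down, more for longer
           times", {
  truth <- rasterize_layout(default_phantom_layout(), 2)
  expect_equal(apply_temperature(truth, 22), truth)
  hot <- apply_temperature(truth, 38.8)
  cold <- apply_temperature(truth, 13.5)
  for (l in 1:9) {
    sel <- truth$label_map == l
    expect_gt(hot$t1_map[sel][1], cold$t1_map[sel][1])
    expect_lt(hot$t2_map[sel][1], cold$t2_map[sel][1])
  }
  # proportional slopes: longer-T1/T2 tubes spread more over the range
  spread_t1 <- vapply(1:9, function(l) {
    sel <- truth$label_map == l
    hot$t1_map[sel][1] - cold$t1_map[sel][1]
  }, numeric(1))
  ref_t1 <- vapply(1:9, function(l) {
    truth$t1_map[truth$label_map == l][1]
  }, numeric(1))
  expect_equal(order(spread_t1), order(ref_t1))
  expect_error(apply_temperature(truth, -500), "non-positive")
  bad <- default_temperature_coeffs(truth)
  bad$dt2_dC <- abs(bad$dt2_dC)
  expect_error(apply_temperature(truth, 30, bad), "dT2/dT")
})

test_that("Rician noise has the documented floor and is seed-reproducible", {
  truth <- uniform_truth(1000, 50, 320, 320)
  st <- simulate_spin_echo(truth, protocol_se(te_list = c(10, 20)))
  zero <- st
  zero$frames[] <- 0   # pure-noise region
  sigma <- 0.05
  n1 <- add_noise(zero, sigma, seed = 31)
  expect_equal(mean(n1$frames), sigma * sqrt(pi / 2), tolerance = 0.01)
  n2 <- add_noise(zero, sigma, seed = 31)
  expect_identical(n1$frames, n2$frames)
  expect_identical(add_noise(st, 0, seed = 1)$frames, st$frames)
  expect_true(all(add_noise(st, 0.01, seed = 2)$frames >= 0))
})
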