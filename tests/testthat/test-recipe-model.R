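test_that("calibration fixture carries the benchmark tube table verbatim", {
  cal <- calibration_fixture()
  expect_s3_class(cal, "calibration_table")
  expect_equal(nrow(cal), 10)  # nine tubes plus the outer matrix fill
  expect_equal(cal$tube_id, c(LETTERS[1:9], "outer"))
  a <- cal[cal$tube_id == "A", ]
  expect_equal(a$agarose_pct, 1.261)
  expect_equal(a$ni_mM, 3.139)
  expect_equal(a$t1_1p4T_ms, 821)
  expect_equal(a$t2_1p4T_ms, 40)
  i <- cal[cal$tube_id == "I", ]
  expect_equal(i$agarose_pct, 2.840)
  expect_equal(i$ni_mM, 2.502)
  expect_equal(i$t2_1p5T_ms, 41)
  expect_equal(i$t2_3T_ms, 40)
  # outer fill only has bench-relaxometer values
  expect_true(is.na(cal$t1_1p5T_ms[10]) && is.na(cal$t2_3T_ms[10]))
})

test_that("calibration CSV round trip is lossless and validated", {
  cal <- calibration_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(as.data.frame(back), as.data.frame(cal))
  bad <- as.data.frame(cal)
  names(bad)[2] <- "agar"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_error(read_calibration(path2), "missing columns")
})

test_that("relaxivity fit equals the independent normal-equations oracle", {
  cal <- calibration_fixture()
  for (field in c("1.4T", "1.5T", "3T")) {
    m <- fit_relaxivity_model(cal, field)
    cols <- phantomqa:::field_columns(field)
    df <- as.data.frame(cal)[1:9, ]
    o1 <- normal_equations_oracle(df, cols[["t1"]])
    o2 <- normal_equations_oracle(df, cols[["t2"]])
    expect_equal(c(m$r1_0, m$r1_ni, m$r1_ag), unname(o1),
                 tolerance = 1e-9)
    expect_equal(c(m$r2_0, m$r2_ni, m$r2_ag), unname(o2),
                 tolerance = 1e-9)
    expect_true(m$residual_sd_r1 > 0 && m$residual_sd_r2 > 0)
  }
})

test_that("benchmark-table fit reflects the dominant ingredient effects", {
  # The two concentration columns are strongly collinear in this
  # calibration; the main drivers are large and positive, while the
  # nickel-on-R1 cross coefficient is indistinguishable from zero (its
  # magnitude is far below the fit residual SD) and its sign is not a
  # stable feature of the data.
  m <- fit_relaxivity_model(calibration_fixture(), "1.4T")
  expect_gt(m$r1_ag, 0.5)
  expect_gt(m$r2_ni, 5)
  expect_gt(m$r2_ag, 0)
  expect_lt(abs(m$r1_ni), m$residual_sd_r1)
})

test_that("degenerate (collinear) calibrations are rejected", {
  df <- data.frame(tube_id = c("X", "Y", "Z"),
                   agarose_pct = c(1, 2, 3), ni_mM = c(2, 4, 6),
                   t1_1p4T_ms = c(900, 700, 500),
                   t1_1p5T_ms = NA, t1_3T_ms = NA,
                   t2_1p4T_ms = c(80, 50, 30),
                   t2_1p5T_ms = NA, t2_3T_ms = NA)
  expect_error(fit_relaxivity_model(df, "1.4T"), "degenerate")
  expect_error(fit_relaxivity_model(df[1:2, ], "1.4T"), "at least 3")
})

test_that("noiseless synthetic calibration is recovered to machine precision", {
  true <- list(r1_0 = 0.4, r1_ni = 0.7, r1_ag = 0.05,
               r2_0 = 0.6, r2_ni = 0.8, r2_ag = 9.5)
  grid <- expand.grid(agarose_pct = c(0.5, 1.5, 2.5),
                      ni_mM = c(0.5, 2, 4))
  r1 <- true$r1_0 + true$r1_ni * grid$ni_mM + true$r1_ag * grid$agarose_pct
  r2 <- true$r2_0 + true$r2_ni * grid$ni_mM + true$r2_ag * grid$agarose_pct
  df <- data.frame(tube_id = paste0("S", 1:9), grid,
                   t1_1p4T_ms = 1000 / r1, t1_1p5T_ms = NA, t1_3T_ms = NA,
                   t2_1p4T_ms = 1000 / r2, t2_1p5T_ms = NA, t2_3T_ms = NA)
  m <- fit_relaxivity_model(df, "1.4T")
  expect_equal(unlist(m[c("r1_0", "r1_ni", "r1_ag",
                          "r2_0", "r2_ni", "r2_ag")]),
               unlist(true), tolerance = 1e-12,
               ignore_attr = TRUE)
  # row order must not matter
  m2 <- fit_relaxivity_model(df[sample(9), ], "1.4T")
  expect_equal(m2[c("r1_0", "r1_ni", "r1_ag", "r2_0", "r2_ni", "r2_ag")],
               m[c("r1_0", "r1_ni", "r1_ag", "r2_0", "r2_ni", "r2_ag")],
               tolerance = 1e-12)
  # positive relaxivities imply T1 strictly decreases with added nickel
  t1_seq <- vapply(seq(0, 4, by = 0.5), function(ni) {
    predict_relaxation(1, ni, m)$t1_ms
  }, numeric(1))
  expect_true(all(diff(t1_seq) < 0))
})

test_that("forward prediction matches the calibration and the intercept case", {
  m <- fit_relaxivity_model(calibration_fixture(), "1.4T")
  p <- predict_relaxation(1.261, 3.139, m)  # tube A recipe
  # agreement in rate space within 3 fitted residual SDs
  expect_lt(abs(1000 / p$t1_ms - 1000 / 821), 3 * m$residual_sd_r1)
  expect_lt(abs(1000 / p$t2_ms - 1000 / 40), 3 * m$residual_sd_r2)
  m0 <- m
  m0$r1_0 <- 0.5; m0$r2_0 <- 10
  expect_equal(predict_relaxation(0, 0, m0)$t1_ms, 2000)
  expect_equal(predict_relaxation(0, 0, m0)$t2_ms, 100)
  expect_error(predict_relaxation(-1, 1, m), "non-negative")
  mneg <- m
  mneg$r2_0 <- -50
  expect_error(predict_relaxation(0, 0, mneg), "unphysical")
})

test_that("recipe design inverts prediction and honors feasibility bounds", {
  m <- fit_relaxivity_model(calibration_fixture(), "1.4T")
  set.seed(42)
  for (i in 1:20) {
    conc <- list(agarose_pct = runif(1, 0.2, 3), ni_mM = runif(1, 0.2, 4))
    p <- suppressWarnings(
      predict_relaxation(conc$agarose_pct, conc$ni_mM, m))
    rec <- design_recipe(p$t1_ms, p$t2_ms, m)
    expect_equal(rec$agarose_pct, conc$agarose_pct, tolerance = 1e-9)
    expect_equal(rec$ni_mM, conc$ni_mM, tolerance = 1e-9)
  }
  # intercept target maps to zero concentrations (synthetic model with
  # positive intercept rates)
  ms <- m
  ms$r1_0 <- 0.4; ms$r2_0 <- 2
  rec0 <- design_recipe(1000 / ms$r1_0, 1000 / ms$r2_0, ms)
  expect_equal(rec0$agarose_pct, 0, tolerance = 1e-9)
  expect_equal(rec0$ni_mM, 0, tolerance = 1e-9)
  expect_error(design_recipe(5000, 200, m), "infeasible target")
  msing <- m
  msing$r2_ni <- m$r1_ni; msing$r2_ag <- m$r1_ag; msing$r2_0 <- m$r1_0
  expect_error(design_recipe(600, 600, msing), "non-invertible")
})

test_that("designed recipe agrees with a brute-force grid search", {
  m <- fit_relaxivity_model(calibration_fixture(), "1.4T")
  rec <- design_recipe(600, 45, m)
  # exhaustive scan of the full 0-5% x 0-6 mM box on a 1e-3 grid,
  # minimizing the squared rate error
  ag <- seq(0, 5, by = 1e-3)
  ni <- seq(0, 6, by = 1e-3)
  target_r1 <- 1000 / 600
  target_r2 <- 1000 / 45
  best <- c(Inf, NA, NA)
  for (a in ag) {
    e <- (m$r1_0 + m$r1_ni * ni + m$r1_ag * a - target_r1)^2 +
      (m$r2_0 + m$r2_ni * ni + m$r2_ag * a - target_r2)^2
    j <- which.min(e)
    if (e[j] < best[1]) best <- c(e[j], a, ni[j])
  }
  # the valley is anisotropic (rate sensitivity ~7.8/mM vs ~0.7/%), so
  # the lattice optimum can sit a few steps off along agarose
  expect_lt(abs(rec$agarose_pct - best[2]), 5e-3)
  expect_lt(abs(rec$ni_mM - best[3]), 1.5e-3)
  # the analytic solution is at least as good as the best grid point
  err <- function(a, n) {
    (m$r1_0 + m$r1_ni * n + m$r1_ag * a - target_r1)^2 +
      (m$r2_0 + m$r2_ni * n + m$r2_ag * a - target_r2)^2
  }
  expect_lte(err(rec$agarose_pct, rec$ni_mM), best[1])
})

test_that("leave-one-out errors are finite and reported for every tube", {
  loo <- loo_prediction_errors(calibration_fixture(), "1.4T")
  expect_equal(nrow(loo), 9)
  expect_true(all(is.finite(loo$t1_err)) && all(is.finite(loo$t2_err)))
})
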