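make_series <- function(df, v = 0.1, m = 4, trt = "test") {
  incubation_series(df, bottle = sip_bottle(v_medium_L = v, dry_mass_g = m),
                    treatment = trt)
}

test_that("incubation series validates its structure", {
  ok <- data.frame(day = c(0, 10), dic_mM = c(32, 36))
  expect_s3_class(make_series(ok), "incubation_series")
  expect_error(make_series(data.frame(day = c(10, 0), dic_mM = c(1, 2))),
               "strictly increasing")
  expect_error(make_series(data.frame(day = c(5, 10), dic_mM = c(1, 2))),
               "day-0")
  expect_error(make_series(data.frame(day = c(0, 10), so4_mM = c(25, -1))),
               "negative concentration")
})

test_that("production rates follow dConc x V x 1000 / (m x dt)", {
  ser <- make_series(data.frame(day = c(0, 30), dic_mM = c(30, 36),
                                so4_mM = c(25, 25)), v = 0.1, m = 4)
  r <- production_rate(ser, "dic", c(0, 30))
  expect_equal(r$value, 6 * 0.1 * 1000 / (4 * 30), tolerance = 1e-12)
  expect_equal(r$value, 5.0)
  expect_equal(r$units, "umol g_dw^-1 d^-1")
  # no change, no rate
  expect_equal(production_rate(ser, "so4", c(0, 30))$value, 0)
  # published sulphide magnitude: 0.2 -> 5.9 mM over 30 d in ~3.4 g bottles
  ser2 <- make_series(data.frame(day = c(0, 30), h2s_mM = c(0.2, 5.9)),
                      v = 0.1, m = 3.39)
  expect_equal(production_rate(ser2, "h2s")$value, 5.6, tolerance = 0.01)
})

test_that("consumption yields negative rates and windows telescope", {
  ser <- make_series(data.frame(day = c(0, 10, 30),
                                so4_mM = c(25, 24, 20)), v = 0.1, m = 3.4)
  r_full <- production_rate(ser, "so4", c(0, 30))
  expect_lt(r_full$value, 0)
  r1 <- production_rate(ser, "so4", c(0, 10))
  r2 <- production_rate(ser, "so4", c(10, 30))
  # time-weighted additivity over adjacent windows
  expect_equal((r1$value * 10 + r2$value * 20) / 30, r_full$value,
               tolerance = 1e-12)
  expect_error(production_rate(ser, "so4", c(10, 10)), "day_end > day_start")
  expect_error(production_rate(ser, "h2s"), "no column")
})

test_that("methane oxidation estimator is exact for the closed two-pool oracle", {
  # forward construction: DIC pool of 1068 umol/g_dw at F 0.010936 receives
  # 132 umol/g_dw from CH4 at constant F 0.109512 over 30 days
  m <- 1; v <- 0.1
  f0 <- 0.010936; f_ch4 <- 0.109512
  n0 <- 1068; add <- 132
  f_end <- (n0 * f0 + add * f_ch4) / (n0 + add)
  ser <- make_series(data.frame(
    day = c(0, 30),
    d13c_ch4 = c(fraction_to_delta(f_ch4), NA),
    d13c_dic = fraction_to_delta(c(f0, f_end)),
    dic_mM = c(n0, n0 + add) * m / (v * 1000)), v = v, m = m)
  est <- methane_oxidation_rate(ser, c(0, 30))
  expect_equal(est$value, add / 30, tolerance = 1e-9)
  expect_equal(est$value, 4.4, tolerance = 1e-9)
  # zero label transfer, zero rate
  ser0 <- make_series(data.frame(day = c(0, 30),
                                 d13c_ch4 = c(10000, NA),
                                 d13c_dic = c(-11, -11),
                                 dic_mM = c(32, 32)))
  expect_equal(methane_oxidation_rate(ser0)$value, 0)
})

test_that("simulator round trip recovers the configured oxidation rate", {
  cfg <- sip_config(r_aom = 4.4, ch4_label_fraction = 0.1,
                    treatments = list(sip_treatment("DIC w/ 13CH4",
                                                    ch4_labelled = TRUE)))
  sim <- simulate_incubation(cfg)
  ser <- incubation_series(sim$geochem[, -1], bottle = cfg$bottle,
                           treatment = "DIC w/ 13CH4")
  for (d in c(10, 20, 30)) {
    expect_equal(methane_oxidation_rate(ser, c(0, d))$value, 4.4,
                 tolerance = 1e-9)
  }
  # the literal absolute-F excess reading gives a smaller estimate
  abs_est <- methane_oxidation_rate(ser, c(0, 30), excess_mode = "absolute")
  expect_lt(abs_est$value, 4.4)
})

test_that("oxidation estimator rejects unlabelled or incomplete series", {
  ser <- make_series(data.frame(day = c(0, 30), d13c_ch4 = c(-43, NA),
                                d13c_dic = c(-11, -12), dic_mM = c(32, 33)))
  expect_error(methane_oxidation_rate(ser), "unlabelled")
  ser2 <- make_series(data.frame(day = c(0, 30), d13c_dic = c(-11, 100),
                                 dic_mM = c(32, 33)))
  expect_error(methane_oxidation_rate(ser2), "d13c_ch4")
})
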