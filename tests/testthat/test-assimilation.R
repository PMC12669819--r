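test_that("lipid mass converts to carbon mass via the molecular formula", {
  # a hypothetical pure-carbon species passes through unchanged
  expect_equal(carbon_concentration(5, "C10"), 5)
  expect_equal(carbon_concentration(20.7, "C16H30O2"), 15.6361, tolerance = 1e-5)
  expect_equal(carbon_concentration(4.0, "C43H88O3"), 3.16285, tolerance = 1e-5)
  expect_error(carbon_concentration(1, "H4O2"), "no carbon")
})

test_that("medium fraction follows the treatment-specific averaging rules", {
  days <- c(0, 10, 20, 30)
  # constant series: the two modes agree
  const <- rep(5000, 4)
  expect_equal(medium_fraction(const, days, 30, "dic"),
               medium_fraction(const, days, 30, "ch4"))
  # DI13C treatment: sampling-day measured value
  dd <- c(5100, 5051, 4905, 4829)
  expect_equal(medium_fraction(dd, days, 30, "dic"),
               0.0611812, tolerance = 1e-6)
  # 13CH4 treatment: mean of all measurements through the sampling day
  rising <- c(-11, 205, 918, 1129)
  expect_equal(medium_fraction(rising, days, 30, "ch4"),
               delta_to_fraction(560.25))
  expect_equal(medium_fraction(rising, days, 30, "ch4"), 0.0171445,
               tolerance = 1e-5)
  # endpoint-pair alternative
  expect_equal(medium_fraction(rising, days, 30, "ch4", averaging = "endpoints"),
               delta_to_fraction(mean(c(-11, 1129))))
  expect_error(medium_fraction(rising[-1], days[-1], 30, "ch4"), "day-0")
  expect_error(medium_fraction(dd, days, 15, "dic"), "day 15")
})

test_that("assimilation rates reproduce hand arithmetic and published values", {
  # no label uptake, no assimilation
  a0 <- assimilation_rate(10, NULL, -61, -61, 0.06, 30)
  expect_equal(a0$value, 0)
  # hand case: 10 ug C, dF 0.006, F_med 0.06, 30 d
  dl <- fraction_to_delta(delta_to_fraction(-61) + 0.006)
  a <- assimilation_rate(10, NULL, dl, -61, 0.06, 30)
  expect_equal(a$value, 10 * 0.006 / (0.06 * 30) * 365, tolerance = 1e-9)
  expect_equal(a$value, 12.1667, tolerance = 1e-4)
  # C16:1w5c in the DI13C-with-CH4 incubation, day 30
  f_med <- delta_to_fraction(4829)
  a16 <- assimilation_rate(20.7, "C16H30O2", -61 + 393, -61, f_med, 30)
  expect_equal(a16$value, 13.32176, tolerance = 1e-5)
  expect_equal(a16$value, 13.6, tolerance = 0.1)
  expect_warning(assimilation_rate(10, NULL, -70, -61, 0.06, 30), "label loss")
  expect_error(assimilation_rate(10, NULL, -61, -61, 0.06, 0), "time")
})

test_that("turnover times reproduce the published worked values", {
  f_med <- delta_to_fraction(4829)
  t_croc <- turnover_time(-100 + 126, -100, f_med, 30)
  expect_equal(t_croc$value, 3.647, tolerance = 1e-3)
  expect_equal(t_croc$value, 3.6, tolerance = 0.1)
  t_c16 <- turnover_time(-61 + 393, -61, f_med, 30)
  expect_equal(t_c16$value, 1.1737, tolerance = 1e-3)
  expect_equal(t_c16$value, 1.2, tolerance = 0.1)
  expect_error(turnover_time(-61, -61, f_med, 30), "not positive")
})

test_that("assimilation x turnover equals the carbon concentration exactly", {
  f_med <- delta_to_fraction(4829)
  cases <- data.frame(conc = c(20.7, 1.3, 9.9),
                      formula = c("C16H30O2", "C20H42", "C14H28O2"),
                      d0 = c(-61, -100, -33), shift = c(393, 126, 172))
  for (i in seq_len(nrow(cases))) {
    a <- assimilation_rate(cases$conc[i], cases$formula[i],
                           cases$d0[i] + cases$shift[i], cases$d0[i],
                           f_med, 30)
    tt <- turnover_time(cases$d0[i] + cases$shift[i], cases$d0[i], f_med, 30)
    expect_equal(a$value * tt$value,
                 carbon_concentration(cases$conc[i], cases$formula[i]),
                 tolerance = 1e-9)
  }
})

test_that("estimates respond monotonically to the label shift", {
  f_med <- delta_to_fraction(4829)
  shifts <- seq(10, 400, by = 10)
  assim <- vapply(shifts, function(s) {
    assimilation_rate(20.7, "C16H30O2", -61 + s, -61, f_med, 30)$value
  }, 0)
  turn <- vapply(shifts, function(s) {
    turnover_time(-61 + s, -61, f_med, 30)$value
  }, 0)
  expect_true(all(diff(assim) > 0))
  expect_true(all(diff(turn) < 0))
})

test_that("worked estimates barely move when the VPDB ratio changes", {
  vals <- sapply(c(0.011180, 0.0111802), function(r) {
    f_med <- delta_to_fraction(4829, r)
    c(assim = assimilation_rate(20.7, "C16H30O2", 332, -61, f_med, 30,
                                r_vpdb = r)$value,
      turn = turnover_time(26, -100, f_med, 30, r_vpdb = r)$value)
  })
  expect_equal(vals[, 1], vals[, 2], tolerance = 0.005)
})
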