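test_that("with all rates zero every series stays at its initial value", {
  lip <- paperlike_lipids()
  lip$assim_ugC_gdw_yr <- 0
  cfg <- sip_config(lipids = lip,
                    treatments = list(
                      sip_treatment("DIC w/ CH4"),
                      sip_treatment("DI13C w/ CH4", dic_labelled = TRUE)))
  sim <- simulate_incubation(cfg)
  for (trt in unique(sim$geochem$treatment)) {
    g <- sim$geochem[sim$geochem$treatment == trt, ]
    for (col in c("d13c_ch4", "d13c_dic", "dic_mM", "so4_mM", "h2s_mM")) {
      if (all(is.na(g[[col]]))) next
      expect_equal(g[[col]], rep(g[[col]][1], nrow(g)), tolerance = 1e-12)
    }
    l <- sim$lipids[sim$lipids$treatment == trt, ]
    for (sp in unique(l$species)) {
      ls <- l[l$species == sp, ]
      expect_equal(ls$d13c_permil, rep(ls$d13c_permil[1], nrow(ls)),
                   tolerance = 1e-12)
    }
  }
})

test_that("both isotopes are conserved over all pools and lipids", {
  for (cfg in list(make_paperlike_config(noise = FALSE),
                   make_recovery_config(),
                   sip_config(r_aom = 3, r_osr = 1, r_dissolution = 2,
                              backflux_fraction = 0.2,
                              lipids = paperlike_lipids(),
                              treatments = list(
                                sip_treatment("DI13C w/ CH4",
                                              dic_labelled = TRUE))))) {
    sim <- simulate_incubation(cfg)
    for (trt in unique(sim$balance$treatment)) {
      b <- sim$balance[sim$balance$treatment == trt, ]
      expect_equal(b$c12_umol, rep(b$c12_umol[1], nrow(b)), tolerance = 1e-9)
      expect_equal(b$c13_umol, rep(b$c13_umol[1], nrow(b)), tolerance = 1e-9)
    }
  }
})

test_that("seeded runs are reproducible and seeds only move the noise", {
  cfg <- make_paperlike_config(noise = TRUE)
  s1 <- simulate_incubation(cfg, seed = 7)
  s2 <- simulate_incubation(cfg, seed = 7)
  expect_identical(s1$geochem, s2$geochem)
  expect_identical(s1$lipids, s2$lipids)
  s3 <- simulate_incubation(cfg, seed = 8)
  expect_false(identical(s1$geochem$d13c_dic, s3$geochem$d13c_dic))
  # noise-free skeleton identical: balances do not depend on the seed
  expect_identical(s1$balance, s3$balance)
})

test_that("halving the step changes day-30 outputs by less than 0.1 percent", {
  cfg1 <- make_paperlike_config(noise = FALSE)
  cfg2 <- cfg1; cfg2$step_days <- 0.5
  g1 <- simulate_incubation(cfg1)$geochem
  g2 <- simulate_incubation(cfg2)$geochem
  d301 <- g1[g1$day == 30, ]; d302 <- g2[g2$day == 30, ]
  for (col in c("d13c_dic", "dic_mM", "so4_mM", "h2s_mM")) {
    rel <- abs(d301[[col]] - d302[[col]]) /
      pmax(abs(d301[[col]]), 1)
    expect_true(all(rel < 1e-3), label = paste("step robustness:", col))
  }
})

test_that("spiked pools start at the configured mixing arithmetic", {
  cfg <- make_paperlike_config(noise = FALSE)
  sim <- simulate_incubation(cfg)
  g0 <- sim$geochem[sim$geochem$day == 0, ]
  d_dic <- g0$d13c_dic[g0$treatment == "DI13C w/ CH4"]
  f_expect <- 0.947 * delta_to_fraction(-11) + 0.053 * 0.99
  expect_equal(d_dic, fraction_to_delta(f_expect), tolerance = 1e-9)
  # about +5000 per mil, the scale the labelled incubations report
  expect_equal(d_dic, 5000, tolerance = 0.05)
  d_ch4 <- g0$d13c_ch4[g0$treatment == "DIC w/ 13CH4"]
  expect_equal(d_ch4, fraction_to_delta(0.9 * delta_to_fraction(-43) +
                                          0.1 * 0.99), tolerance = 1e-9)
  expect_equal(d_ch4, 10000, tolerance = 0.05)
})

test_that("paperlike trajectories show the expected qualitative behaviour", {
  sim <- simulate_incubation(make_paperlike_config(noise = FALSE))
  g <- sim$geochem
  # label transfer: delta-13C-DIC rises by order 10^3 per mil under 13CH4
  g13 <- g[g$treatment == "DIC w/ 13CH4", ]
  expect_gt(g13$d13c_dic[g13$day == 30], 500)
  # sulphide accumulates ~5-6 mM over 30 days
  expect_gt(g13$h2s_mM[g13$day == 30], 4.5)
  expect_lt(g13$h2s_mM[g13$day == 30], 6.5)
  # back-flux: delta-13C-CH4 rises in the DI13C design
  gdi <- g[g$treatment == "DI13C w/ CH4", ]
  expect_true(all(diff(gdi$d13c_ch4) > 0))
  # no methane, no CH4 column
  gno <- g[g$treatment == "DI13C w/o CH4", ]
  expect_true(all(is.na(gno$d13c_ch4)))
  # killed controls stay put
  gk <- g[g$treatment == "DI13C w/ CH4 killed", ]
  expect_equal(gk$d13c_dic, rep(gk$d13c_dic[1], nrow(gk)), tolerance = 1e-12)
})

test_that("back-flux is required for CH4 labelling in the DI13C design", {
  cfg <- make_paperlike_config(noise = FALSE)
  cfg$backflux_fraction <- 0
  g <- simulate_incubation(cfg)$geochem
  gdi <- g[g$treatment == "DI13C w/ CH4", ]
  expect_equal(gdi$d13c_ch4, rep(-43, nrow(gdi)), tolerance = 1e-9)
})

test_that("sulphate exhaustion halts the simulation with a diagnostic", {
  cfg <- sip_config(so4_umol = 50, r_aom = 10,
                    treatments = list(sip_treatment("DIC w/ CH4")))
  expect_error(simulate_incubation(cfg), "sulphate pool exhausted")
})

test_that("simulate() dispatches on the config and honours nsim", {
  cfg <- make_paperlike_config(noise = TRUE)
  reps <- simulate(cfg, nsim = 2, seed = 11)
  expect_length(reps, 2)
  expect_false(identical(reps[[1]]$geochem$d13c_dic,
                         reps[[2]]$geochem$d13c_dic))
})
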