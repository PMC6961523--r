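test_that("annual detrital carbon integral matches the configured input", {
  for (input in c(5, 20, 80)) {
    cfg <- forcing_config(years = 3, annual_benthic_C_input = input)
    frc <- generate_forcing(cfg)
    yearly <- tapply(frc$detritus_C_flux, frc$time %/% 365, sum)
    expect_equal(as.numeric(yearly), rep(input, 3), tolerance = 1e-3)
  }
})

test_that("detrital stoichiometry is Redfield and constant in time", {
  frc <- generate_forcing(forcing_config(years = 2))
  pos <- frc$detritus_C_flux > 0
  c_mmol <- frc$detritus_C_flux[pos] / bgc_units$g_per_mol_C * 1000
  expect_equal(frc$detritus_N_flux[pos] / c_mmol,
               rep(16 / 106, sum(pos)), tolerance = 1e-12)
  expect_equal(frc$detritus_P_flux[pos] / c_mmol,
               rep(1 / 106, sum(pos)), tolerance = 1e-12)
})

test_that("zero bloom amplitude with no autumn bloom silences the flux", {
  cfg <- forcing_config(years = 1, bloom_amplitude = 0,
                        autumn_bloom_fraction = 0)
  frc <- generate_forcing(cfg)
  expect_true(all(frc$detritus_C_flux == 0))
})

test_that("forcing is deterministic and has the right length", {
  cfg <- forcing_config(years = 2)
  f1 <- generate_forcing(cfg)
  f2 <- generate_forcing(cfg)
  expect_identical(f1, f2)
  expect_identical(nrow(f1), 2L * 365L)
  expect_true(all(f1$detritus_C_flux >= 0))
  expect_true(all(f1$bw_O2 >= 0 & f1$bw_NO3 >= 0 & f1$bw_Si >= 0))
})

test_that("invalid forcing configurations are rejected", {
  expect_error(forcing_config(annual_benthic_C_input = 0), "must be > 0")
  expect_error(forcing_config(autumn_bloom_fraction = 1), "\\[0, 1\\)")
  expect_error(forcing_config(strat_onset_doy = 300, remix_doy = 200),
               "later in the year")
  expect_error(forcing_config(m2_current_amp = -0.1), ">= 0")
})

test_that("tidal stress follows the quadratic drag law with a log-law Cd", {
  expect_equal(tidal_stress(0, 0, 0.03 / 7, 0:10), rep(0, 11))
  t1 <- tidal_stress(0.1, 0, 0.03 / 7, 0)
  t2 <- tidal_stress(0.2, 0, 0.03 / 7, 0)
  expect_equal(t2 / t1, 4) # doubling u quadruples the stress
  expect_error(tidal_stress(-0.1, 0, 0.03 / 7, 0), ">= 0")
})

test_that("stress envelope beats at the spring-neap period of 14.77 days", {
  days <- 0:119
  tau <- shelfbenthos:::daily_mean_stress(0.1, 0.035, 0.03 / 7, days,
                                          nsub = 240)
  pk <- which(diff(sign(diff(tau))) == -2) + 1
  tref <- vapply(pk, function(i) {
    y <- tau[(i - 1):(i + 1)]
    days[i] + 0.5 * (y[1] - y[3]) / (y[1] - 2 * y[2] + y[3])
  }, 0)
  expect_equal(mean(diff(tref)), 14.77, tolerance = 0.05 / 14.77)
})

test_that("spring-neap modulation strengthens with the S2/M2 ratio", {
  days <- 0:59
  ratio <- vapply(c(0.1, 0.2, 0.4), function(s2frac) {
    tau <- shelfbenthos:::daily_mean_stress(0.1, 0.1 * s2frac, 0.03 / 7,
                                            days)
    max(tau) / min(tau)
  }, 0)
  expect_true(all(diff(ratio) > 0))
})

test_that("observation fixtures reproduce truth without noise", {
  truth <- data.frame(site = "A", date = c(10, 20), quantity = "TOU",
                      value = c(5, 7))
  obs <- generate_observation_fixtures(truth, noise_cv = 0, replicates = 3,
                                       seed = 1)
  expect_identical(nrow(obs), 6L)
  expect_equal(obs$value, rep(truth$value, each = 3))
  expect_identical(as.vector(table(interaction(obs$date, obs$quantity))),
                   c(3L, 3L))
})

test_that("replicate mean of noisy fixtures converges to truth", {
  truth <- data.frame(site = "A", date = 1, quantity = "TOU", value = 5)
  obs <- generate_observation_fixtures(truth, noise_cv = 0.5,
                                       replicates = 1000, seed = 42)
  expect_equal(mean(obs$value), 5, tolerance = 0.05)
})

test_that("forcing CSV round-trips with a unit header", {
  frc <- generate_forcing(forcing_config(years = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_forcing_csv(frc, path)
  expect_match(readLines(path, n = 1), "^# units:")
  back <- read_forcing_csv(path)
  expect_equal(back$detritus_C_flux, frc$detritus_C_flux)
  expect_equal(back$bed_stress, frc$bed_stress)
})
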