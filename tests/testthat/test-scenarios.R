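test_that("A1 differs from A only in the four documented changes", {
  d <- scenario_diff(scenario_config("A"), scenario_config("A1"))
  # the partition-ratio change spans the two particulate fractions
  expect_setequal(d, c("om.refractory_breakdown_rate",
                       "om.frac_semilabile", "om.frac_refractory",
                       "biota.groups.deposit_feeders.mortality",
                       "biota.groups.suspension_feeders.mortality"))
  a1 <- scenario_config("A1")
  expect_equal(a1$om$refractory_breakdown_rate, 1e-5)
  expect_equal(a1$om$frac_semilabile / a1$om$frac_refractory, 1)
  expect_equal(a1$biota$groups$deposit_feeders$mortality, 0.004)
  expect_equal(a1$biota$groups$suspension_feeders$mortality, 0.002)
})

test_that("G0 differs from G only by disabling the modification", {
  expect_identical(scenario_diff(scenario_config("G"),
                                 scenario_config("G0")),
                   "permeable_enabled")
  g <- scenario_config("G")
  expect_equal(g$site$porosity, 0.44)
  expect_equal(g$site$permeability, 5e-11)
  expect_equal(scenario_config("A")$site$porosity, 0.68)
})

test_that("scenario files load with overrides and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "mytest", base = "A",
                            overrides = list(site = list(porosity = 0.5),
                                             years = 2)),
                       path, auto_unbox = TRUE)
  cfg <- load_scenario(path)
  expect_equal(cfg$site$porosity, 0.5)
  expect_equal(cfg$name, "mytest")
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(base = "A",
                            overrides = list(site = list(porsity = 0.5))),
                       bad, auto_unbox = TRUE)
  expect_error(load_scenario(bad), "site.porsity")
  expect_error(load_scenario("no-such-scenario"), "neither a builtin")
  expect_identical(load_scenario("A1")$name, "A1")
})

test_that("provenance tags are available for the headline parameters", {
  pr <- scenario_provenance()
  expect_true(all(c("literature", "calibration") %in% pr$provenance))
  expect_identical(
    pr$provenance[pr$key == "om.refractory_breakdown_rate"], "literature")
})

test_that("simulations are reproducible and conservative", {
  cfg <- short_scenario(years = 2)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_lt(max(s1$ledger), 1e-8)
  expect_true(all(s1$tables$D1 <= s1$tables$D2))
  expect_true(all(s1$tables$D2 <= cfg$nutrients$z_bed))
  expect_true(all(s1$tables$TOU >= 0))
  expect_true(all(s1$tables$pw_NO3 >= 0 & s1$tables$pw_Si >= 0))
})

test_that("zero detrital input starves the bed", {
  cfg <- short_scenario(years = 3)
  cfg$forcing$bloom_amplitude <- 0
  cfg$forcing$autumn_bloom_fraction <- 0
  sim <- run_simulation(cfg)
  first <- sim$tables[1:30, ]
  last <- final_year(sim)
  expect_lt(mean(last$TOU), 0.2 * mean(first$TOU))
  expect_lt(mean(last$deposit_feeders),
            0.5 * mean(first$deposit_feeders))
})

test_that("model-observation comparison round-trips and flags correctly", {
  tab <- data.frame(time = 0:9, TOU = seq(5, 6.8, by = 0.2),
                    D1 = rep(0.02, 10))
  truth <- data.frame(site = "A", date = c(2, 5), quantity = "TOU",
                      value = tab$TOU[c(3, 6)])
  obs <- generate_observation_fixtures(truth, noise_cv = 0, replicates = 3,
                                       seed = 1)
  cmp <- compare_observations(tab, obs)
  expect_equal(cmp$detail$bias, c(0, 0))
  expect_true(all(cmp$detail$within_range))
  expect_equal(cmp$summary$rmse, 0)
  # single replicate collapses the range to a point
  one <- obs[obs$replicate == 1, ]
  one$value <- one$value + 1 # model now outside the (degenerate) range
  cmp1 <- compare_observations(tab, one)
  expect_equal(cmp1$detail$obs_min, cmp1$detail$obs_max)
  expect_false(any(cmp1$detail$within_range))
  bad <- obs
  bad$quantity <- "nonsense"
  expect_error(compare_observations(tab, bad), "supported")
})

test_that("the CLI subcommands write unit-annotated CSV outputs", {
  dir <- withr::local_tempdir()
  # massbalance
  out1 <- file.path(dir, "box.csv")
  cli_main(c("massbalance", "--lambda", "2", "--input", "20",
             "--years", "6", "--out", out1))
  box <- utils::read.csv(out1, comment.char = "#")
  expect_equal(tail(box$Q, 1), 10, tolerance = 1e-3)
  # forcing then permeable on its stress column
  out2 <- file.path(dir, "forcing.csv")
  cfgj <- file.path(dir, "fcfg.json")
  jsonlite::write_json(list(years = 1), cfgj, auto_unbox = TRUE)
  cli_main(c("forcing", "--config", cfgj, "--out", out2))
  frc <- read_forcing_csv(out2)
  expect_equal(nrow(frc), 365)
  out3 <- file.path(dir, "coeff.csv")
  cli_main(c("permeable", "--stress", out2, "--out", out3, "--d1", "0.05"))
  co <- utils::read.csv(out3, comment.char = "#")
  expect_true(all(co$K_eff >= co$K0))
  expect_match(readLines(out3, n = 1), "K_adv=m2 s-1")
  # unknown subcommand and missing options fail loudly
  expect_error(cli_main(c("frobnicate")), "unknown subcommand")
  expect_error(cli_main(c("massbalance", "--lambda", "2")),
               "missing required option")
})
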